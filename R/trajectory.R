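#' Build an interleaved 2D radial trajectory
#'
#' Constructs the sampling pattern of an interleaved 2D radial acquisition:
#' `num_projections` diametric readouts with azimuths drawn from the uniform
#' set \eqn{\{j\pi/P : j = 0..P-1\}}, grouped into `num_interleaves`
#' interleaves. Interleave \eqn{m} (1-based index, offset \eqn{m-1}) receives
#' the azimuths \eqn{(m-1)\pi/P + i M \pi/P}, \eqn{i = 0..P/M-1}, so every
#' interleave covers \eqn{[0, \pi)} uniformly with angular spacing
#' \eqn{M\pi/P}. Readout sample \eqn{k} (0-based) maps to the radial offset
#' \eqn{(k - N/2)/N} in cycles/pixel, so each component of a k-space
#' coordinate lies in \eqn{[-0.5, 0.5)}.
#'
#' Projections are stored in acquisition order: all projections of
#' interleave 1 first, then interleave 2, and so on.
#'
#' @param num_projections total number of radial projections P.
#' @param num_interleaves number of interleaves M; must divide P.
#' @param samples_per_readout number of samples N per readout; must be even.
#'   The reconstruction matrix equals N and the pixel size is `fov_mm / N`.
#' @param fov_mm field of view in mm.
#' @param ordering `"sequential"` (default) assigns interleave offsets in
#'   acquisition order; `"bit-reversed"` permutes the offsets by bit
#'   reversal (M must then be a power of two).
#' @return an object of class `radial_trajectory` with fields `P`, `M`, `N`,
#'   `angles` (radians, per projection), `interleave_of` (1-based, per
#'   projection), `kx`, `ky` (N x P matrices, cycles/pixel), `fov_mm`,
#'   `matrix`, `pixel_mm`.
#' @examples
#' traj <- make_interleaved_radial(360, 24, 320, 320)
#' length(unique(traj$angles))           # 360 distinct azimuths
#' sum(traj$interleave_of == 1)          # 15 projections per interleave
#' @export
make_interleaved_radial <- function(num_projections, num_interleaves,
                                    samples_per_readout, fov_mm,
                                    ordering = c("sequential", "bit-reversed")) {
  ordering <- match.arg(ordering)
  P <- as.integer(num_projections)
  M <- as.integer(num_interleaves)
  N <- as.integer(samples_per_readout)
  if (is.na(P) || P <= 0 || is.na(M) || M <= 0 || is.na(N) || N <= 0)
    stop("projection, interleave and sample counts must be positive")
  if (P %% M != 0)
    stop("num_projections (", P, ") must be divisible by num_interleaves (", M, ")")
  if (N %% 2 != 0) stop("samples_per_readout must be even")
  if (!is.numeric(fov_mm) || fov_mm <= 0) stop("fov_mm must be positive")

  ppi <- P %/% M
  offsets <- 0:(M - 1)
  if (ordering == "bit-reversed") {
    if (bitwAnd(M, M - 1L) != 0L)
      stop("bit-reversed ordering requires a power-of-two interleave count")
    nb <- as.integer(round(log2(M)))
    offsets <- vapply(0:(M - 1), function(m) {
      r <- 0L
      for (b in seq_len(nb)) {
        r <- bitwOr(bitwShiftL(r, 1L), bitwAnd(m, 1L))
        m <- bitwShiftR(m, 1L)
      }
      r
    }, integer(1))
  }

  angles <- numeric(P)
  interleave_of <- integer(P)
  idx <- 1L
  for (m in seq_len(M)) {
    for (i in 0:(ppi - 1)) {
      angles[idx] <- (offsets[m] + i * M) * pi / P
      interleave_of[idx] <- m
      idx <- idx + 1L
    }
  }

  rad <- ((0:(N - 1)) - N / 2) / N
  kx <- outer(rad, cos(angles))
  ky <- outer(rad, sin(angles))

  structure(list(
    P = P, M = M, N = N,
    angles = angles, interleave_of = interleave_of,
    kx = kx, ky = ky,
    fov_mm = fov_mm, matrix = N, pixel_mm = fov_mm / N
  ), class = "radial_trajectory")
}

#' @export
print.radial_trajectory <- function(x, ...) {
  cat("radial_trajectory:", x$P, "projections in", x$M, "interleaves,",
      x$N, "samples/readout, FOV", x$fov_mm, "mm (",
      format(x$pixel_mm, digits = 3), "mm/px )\n")
  invisible(x)
}

# 1-based projection indices of one interleave (or all projections)
projection_set <- function(traj, interleave = NULL) {
  if (is.null(interleave)) return(seq_len(traj$P))
  if (length(interleave) != 1 || is.na(interleave) ||
      interleave < 1 || interleave > traj$M)
    stop("invalid interleave index: ", interleave)
  which(traj$interleave_of == interleave)
}

#' Density-compensation weights for a radial trajectory
#'
#' Ramp (|k|) weights with an analytic disc-segment weight for the
#' readout-centre sample. Each non-centre sample is weighted by the area of
#' its polar cell, \eqn{\pi |r| \Delta k / P_{eff}} with
#' \eqn{\Delta k = 1/N}; the centre sample receives the area of its share of
#' the central disc, \eqn{\pi \Delta k^2 / (4 P_{eff})}. Weights are
#' normalized by the total sampled disc area (\eqn{\pi/4}) so that for a
#' fully sampled acquisition the weighted adjoint reconstructs a unit delta
#' with unit peak.
#'
#' @param traj a `radial_trajectory`.
#' @param projections optional integer vector of projection indices to
#'   weight (default: all). `P_eff` is the number of projections used.
#' @return an `N x length(projections)` matrix of nonnegative weights.
#' @export
density_weights <- function(traj, projections = NULL) {
  stopifnot(inherits(traj, "radial_trajectory"))
  if (is.null(projections)) projections <- seq_len(traj$P)
  if (length(projections) == 0) stop("empty projection subset")
  N <- traj$N
  peff <- length(projections)
  rad <- abs(((0:(N - 1)) - N / 2) / N)
  w <- 4 * rad / (peff * N)          # (pi*|r|*dk/Peff) * (4/pi)
  w[rad == 0] <- 1 / (peff * N^2)    # (pi*dk^2/(4*Peff)) * (4/pi)
  matrix(w, nrow = N, ncol = peff)
}
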