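#' Non-uniform Fourier transform along a radial trajectory
#'
#' Evaluates the k-space coefficients of an image at the (non-Cartesian)
#' sample locations of a radial trajectory:
#' \deqn{s_j = \sum_{r,c} x[r,c]\,
#'       e^{-2\pi i (k_{x,j}(c - N/2) + k_{y,j}(r - N/2))},}
#' with the image origin at 0-based index \eqn{N/2} and k-space coordinates
#' in cycles/pixel. Implemented by Kaiser-Bessel gridding on a 2x
#' oversampled grid with analytic deapodization; the aliasing error is below
#' `1e-6` relative (checked against direct summation in the test suite).
#'
#' @param image square numeric or complex matrix whose side equals
#'   `traj$matrix`.
#' @param traj a [make_interleaved_radial()] trajectory.
#' @param projections optional projection subset (1-based indices).
#' @return complex matrix of samples, `N x length(projections)`.
#' @export
nufft_forward <- function(image, traj, projections = NULL) {
  stopifnot(inherits(traj, "radial_trajectory"))
  image <- as.matrix(image)
  if (nrow(image) != traj$matrix || ncol(image) != traj$matrix)
    stop("image must be ", traj$matrix, " x ", traj$matrix,
         " to match the trajectory")
  if (is.null(projections)) projections <- seq_len(traj$P)
  kx <- traj$kx[, projections, drop = FALSE]
  ky <- traj$ky[, projections, drop = FALSE]
  s <- nufft_forward_cpp(image + 0i, as.vector(kx), as.vector(ky),
                         .nufft_width)
  matrix(s, nrow = traj$N)
}

#' Adjoint non-uniform Fourier transform (gridding backbone)
#'
#' Returns \eqn{F^\dagger (W y)}: samples are optionally multiplied by
#' per-sample weights, spread back onto the Cartesian grid and inverse
#' transformed. With ramp density-compensation weights this is the
#' conventional gridding reconstruction.
#'
#' @param samples complex matrix (`N x P_eff`) or vector of k-space samples.
#' @param traj trajectory the samples belong to.
#' @param projections optional projection subset the samples correspond to.
#' @param weights optional nonnegative per-sample weights, same shape as
#'   `samples`.
#' @return complex image matrix, `traj$matrix` square.
#' @export
nufft_adjoint <- function(samples, traj, projections = NULL, weights = NULL) {
  stopifnot(inherits(traj, "radial_trajectory"))
  if (is.null(projections)) projections <- seq_len(traj$P)
  ns <- traj$N * length(projections)
  if (length(samples) != ns)
    stop("sample count (", length(samples), ") does not match trajectory subset (",
         ns, ")")
  y <- as.vector(samples) + 0i
  if (!is.null(weights)) {
    if (length(weights) != ns) stop("weights must match samples")
    y <- y * as.vector(weights)
  }
  kx <- traj$kx[, projections, drop = FALSE]
  ky <- traj$ky[, projections, drop = FALSE]
  nufft_adjoint_cpp(y, as.vector(kx), as.vector(ky), traj$matrix,
                    .nufft_width)
}

# Kaiser-Bessel kernel width on the 2x oversampled grid
.nufft_width <- 10L
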