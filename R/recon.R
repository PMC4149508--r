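#' k-space data container
#'
#' Binds complex radial k-space samples to their trajectory. Samples are
#' stored as an `N x P x C` complex array (readout sample, projection,
#' receive channel).
#'
#' @param samples complex array `N x P` or `N x P x C`.
#' @param traj the `radial_trajectory` the samples were acquired on.
#' @param noise_sd per-sample complex-noise standard deviation used in
#'   simulation, if known (`NA` otherwise).
#' @return an object of class `kspace_data`.
#' @export
kspace_data <- function(samples, traj, noise_sd = NA_real_) {
  stopifnot(inherits(traj, "radial_trajectory"))
  if (length(dim(samples)) == 2) dim(samples) <- c(dim(samples), 1L)
  d <- dim(samples)
  if (length(d) != 3 || d[1] != traj$N || d[2] != traj$P)
    stop("samples must be N x P (x C) = ", traj$N, " x ", traj$P, " (x C)")
  if (!all(is.finite(Re(samples))) || !all(is.finite(Im(samples))))
    stop("k-space samples must all be finite")
  structure(list(samples = samples, traj = traj, noise_sd = noise_sd),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  d <- dim(x$samples)
  cat("kspace_data:", d[1], "samples x", d[2], "projections x", d[3],
      "channel(s)\n")
  print(x$traj)
  invisible(x)
}

#' Per-interleave (or final) image container
#'
#' @param pixels square complex or numeric matrix.
#' @param interleave interleave index the image was reconstructed from
#'   (`NA` for a full-data image).
#' @param method reconstruction tag, `"LN"` (linear gridding) or `"CS"`
#'   (Total-Variation compressed sensing).
#' @param pixel_mm pixel size in mm.
#' @return an object of class `sub_image`.
#' @export
sub_image <- function(pixels, interleave = NA_integer_,
                      method = c("LN", "CS"), pixel_mm = NA_real_) {
  method <- match.arg(method)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels)) stop("sub-image grid must be square")
  if (!all(is.finite(Re(pixels))) || !all(is.finite(Im(pixels))))
    stop("sub-image pixels must be finite")
  structure(list(pixels = pixels, interleave = interleave, method = method,
                 pixel_mm = pixel_mm),
            class = "sub_image")
}

#' @export
print.sub_image <- function(x, ...) {
  cat("sub_image [", x$method, "]: ", nrow(x$pixels), "x", ncol(x$pixels),
      if (!is.na(x$interleave)) paste0(", interleave ", x$interleave), "\n",
      sep = "")
  invisible(x)
}

#' Reconstruction parameters for the compressed-sensing solver
#'
#' @param lam Total-Variation weight \eqn{\lambda \ge 0}. Interpreted
#'   relative to k-space data normalized so that the gridding sub-image of
#'   the same interleave has unit maximum magnitude, with the Fourier
#'   operator normalized to unit spectral norm and the data term averaged
#'   per sample (see the methods vignette). Default `1e-5`.
#' @param max_iters maximum number of FISTA iterations.
#' @param tol relative objective-change stopping tolerance.
#' @param tv_eps smoothing constant for the gradient magnitude; `0`
#'   (default) selects the exact isotropic TV handled by a dual proximal
#'   inner solve.
#' @param step `"auto"` (inverse Lipschitz, from power iteration) or a
#'   positive number.
#' @param inner_iters iterations of the dual TV-proximal solve.
#' @return an object of class `recon_params`.
#' @export
recon_params <- function(lam = 1e-5, max_iters = 100, tol = 1e-5,
                         tv_eps = 0, step = "auto", inner_iters = 30) {
  if (!is.numeric(lam) || lam < 0) stop("lam must be >= 0")
  if (max_iters < 1) stop("max_iters must be >= 1")
  if (tol < 0) stop("tol must be >= 0")
  structure(list(lam = lam, max_iters = as.integer(max_iters), tol = tol,
                 tv_eps = tv_eps, step = step,
                 inner_iters = as.integer(inner_iters)),
            class = "recon_params")
}

#' Linear gridding reconstruction
#'
#' Density compensation followed by (Kaiser-Bessel) gridding and FFT, per
#' channel, with multi-channel images combined as the root sum of squares.
#' With a single channel the complex image is returned.
#'
#' @param data a [kspace_data()] object.
#' @param interleave optional interleave index; if given, only that
#'   interleave's projections are used (the self-navigation sub-image
#'   pathway), otherwise all projections (the final-image pathway).
#' @return a [sub_image()] with `method = "LN"`.
#' @export
gridding_reconstruct <- function(data, interleave = NULL) {
  stopifnot(inherits(data, "kspace_data"))
  traj <- data$traj
  projs <- projection_set(traj, interleave)
  w <- density_weights(traj, projs)
  C <- dim(data$samples)[3]
  imgs <- vector("list", C)
  for (ch in seq_len(C)) {
    y <- data$samples[, projs, ch, drop = FALSE]
    dim(y) <- c(traj$N, length(projs))
    imgs[[ch]] <- nufft_adjoint(y, traj, projs, weights = w)
  }
  px <- if (C == 1) imgs[[1]] else {
    sq <- Reduce(`+`, lapply(imgs, function(m) Mod(m)^2))
    sqrt(sq)
  }
  sub_image(px, interleave = if (is.null(interleave)) NA_integer_ else
    as.integer(interleave), method = "LN", pixel_mm = traj$pixel_mm)
}

#' Isotropic total variation of an image
#'
#' Sum over pixels of the gradient magnitude
#' \eqn{\sqrt{|D_x x|^2 + |D_y x|^2}} using forward differences with
#' replicate boundary (zero difference at the last row/column).
#'
#' @param x numeric or complex matrix.
#' @return nonnegative scalar.
#' @export
tv_value <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  gx <- matrix(0 + 0i, n, m)
  gy <- matrix(0 + 0i, n, m)
  if (m > 1) gx[, -m] <- x[, -1] - x[, -m]
  if (n > 1) gy[-n, ] <- x[-1, ] - x[-n, ]
  sum(sqrt(Mod(gx)^2 + Mod(gy)^2))
}

# spectral norm of F'F for a projection subset, by power iteration seeded
# deterministically from the trajectory
op_lipschitz <- function(traj, projs, n_iter = 20) {
  n <- traj$matrix
  v <- matrix(complex(real = cos(seq_len(n * n)),
                      imaginary = sin(seq_len(n * n) * 0.7)), n, n)
  v <- v / sqrt(sum(Mod(v)^2))
  lam <- 0
  for (i in seq_len(n_iter)) {
    fv <- nufft_forward(v, traj, projs)
    av <- nufft_adjoint(fv, traj, projs)
    lam <- sqrt(sum(Mod(av)^2))
    v <- av / lam
  }
  lam
}

#' Compressed-sensing reconstruction of one interleave
#'
#' Approximately solves
#' \deqn{\hat x = \arg\min_x \|y - Fx\|_2^2 + \lambda R_{TV}(x)}
#' for the projections of one interleave by accelerated proximal-gradient
#' iteration (FISTA) with an exact isotropic-TV proximal step solved by fast
#' gradient projection on the dual. Before solving, the data are normalized
#' so that the gridding sub-image of the interleave has unit maximum
#' magnitude, the Fourier operator is rescaled to unit spectral norm, and
#' the data term is averaged per sample (divided by the sample count), so
#' that \eqn{\lambda} has the same meaning regardless of how many
#' projections an interleave holds; \eqn{\lambda} is interpreted in these
#' units (see the methods vignette). Multi-channel data are
#' solved per channel and combined as root sum of squares. The returned
#' iterate is the one with the lowest objective encountered, so the final
#' objective never exceeds the objective of the zero initializer.
#'
#' @param data a [kspace_data()] object.
#' @param interleave interleave index (1-based).
#' @param params a [recon_params()] object.
#' @param trace_objective if `TRUE`, attach the per-iteration objective
#'   values as attribute `"objective"`.
#' @return a [sub_image()] with `method = "CS"`.
#' @export
cs_reconstruct <- function(data, interleave, params = recon_params(),
                           trace_objective = FALSE) {
  stopifnot(inherits(data, "kspace_data"), inherits(params, "recon_params"))
  traj <- data$traj
  projs <- projection_set(traj, interleave)
  C <- dim(data$samples)[3]

  ln <- gridding_reconstruct(data, interleave)
  s <- max(Mod(ln$pixels))
  if (s == 0) s <- 1

  L0 <- op_lipschitz(traj, projs)       # spectral norm of F'F
  opn <- sqrt(L0)                       # operator normalization
  lam <- params$lam
  n <- traj$matrix

  chans <- vector("list", C)
  objtraces <- vector("list", C)
  for (ch in seq_len(C)) {
    y <- data$samples[, projs, ch, drop = FALSE]
    dim(y) <- c(traj$N, length(projs))
    y <- y / (s * opn)

    m_samp <- length(y)
    fwd <- function(x) nufft_forward(x, traj, projs) / opn
    adj <- function(r) nufft_adjoint(r, traj, projs) / opn
    objective <- function(x, fx) sum(Mod(y - fx)^2) / m_samp + lam * tv_value(x)

    L <- if (identical(params$step, "auto")) 2 / m_samp else 1 / params$step
    x <- matrix(0 + 0i, n, n)
    z <- x
    t <- 1
    obj0 <- sum(Mod(y)^2) / m_samp
    best <- x
    best_obj <- obj0
    prev_obj <- obj0
    objs <- numeric(0)
    for (k in seq_len(params$max_iters)) {
      fz <- fwd(z)
      g <- (2 / m_samp) * adj(fz - y)
      xn <- if (lam > 0)
        tv_prox_cpp(z - g / L, lam / L, params$inner_iters)
      else z - g / L
      fxn <- fwd(xn)
      obj <- objective(xn, fxn)
      # divergence guard on the data term: the TV term can transiently be
      # large for extreme lambda while the dual prox is still converging
      data_term <- sum(Mod(y - fxn)^2) / m_samp
      if (!is.finite(obj) || data_term > 10 * obj0)
        stop("CS reconstruction diverged at iteration ", k,
             " (data term ", format(data_term), " vs initial ", format(obj0), ")")
      if (obj < best_obj) {
        best_obj <- obj
        best <- xn
      }
      objs <- c(objs, obj)
      tn <- (1 + sqrt(1 + 4 * t^2)) / 2
      z <- xn + ((t - 1) / tn) * (xn - x)
      x <- xn
      t <- tn
      if (abs(prev_obj - obj) <= params$tol * max(abs(prev_obj), 1e-12)) break
      prev_obj <- obj
    }
    chans[[ch]] <- best * s     # undo data normalization (opn cancels in x)
    objtraces[[ch]] <- objs
  }

  px <- if (C == 1) chans[[1]] else sqrt(Reduce(`+`, lapply(chans, function(m) Mod(m)^2)))
  out <- sub_image(px, interleave = as.integer(interleave), method = "CS",
                   pixel_mm = traj$pixel_mm)
  if (trace_objective) attr(out, "objective") <- objtraces
  out
}
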