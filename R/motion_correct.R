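#' Linear phase ramp correcting one radial readout for a rigid displacement
#'
#' By the Fourier shift theorem a rigid in-plane displacement multiplies a
#' radial readout by a linear phase. For readout index \eqn{k = 0..N-1} and
#' a projection at azimuth \eqn{\theta}, the correction phase is
#' \deqn{\Delta\beta(k) = -2\pi\,\frac{k - N/2}{N}\,
#'       (\Delta x \cos\theta + \Delta y \sin\theta),}
#' i.e. the displacement projected onto the radial line. Multiplying the
#' acquired samples by \eqn{e^{i\Delta\beta}} undoes a corruption applied
#' with the conjugate ramp (the simulator's convention, see
#' [simulate_acquisition()]); the duality is exact by construction.
#'
#' @param traj a `radial_trajectory`.
#' @param projection projection index (1-based).
#' @param dx_px,dy_px displacement in pixels.
#' @return numeric vector of `N` phases (radians), linear in `k` and zero at
#'   the readout centre index `N/2`.
#' @export
phase_ramp <- function(traj, projection, dx_px, dy_px) {
  stopifnot(inherits(traj, "radial_trajectory"))
  if (projection < 1 || projection > traj$P) stop("invalid projection index")
  if (!is.finite(dx_px) || !is.finite(dy_px))
    stop("displacement must be finite")
  N <- traj$N
  th <- traj$angles[projection]
  r <- ((0:(N - 1)) - N / 2) / N
  -2 * pi * r * (dx_px * cos(th) + dy_px * sin(th))
}

#' Correct one interleave of k-space data for a rigid displacement
#'
#' Every projection of the interleave is multiplied by
#' \eqn{e^{i\Delta\beta}} from [phase_ramp()]; all other interleaves are
#' untouched.
#'
#' @param data a [kspace_data()] object.
#' @param interleave interleave index (1-based).
#' @param dx_px,dy_px displacement in pixels.
#' @return a new [kspace_data()] object.
#' @export
correct_interleave <- function(data, interleave, dx_px, dy_px) {
  stopifnot(inherits(data, "kspace_data"))
  traj <- data$traj
  projs <- projection_set(traj, interleave)
  samples <- data$samples
  for (p in projs) {
    ph <- exp(1i * phase_ramp(traj, p, dx_px, dy_px))
    for (ch in seq_len(dim(samples)[3]))
      samples[, p, ch] <- samples[, p, ch] * ph
  }
  kspace_data(samples, traj, data$noise_sd)
}

#' Motion-corrected final reconstruction
#'
#' Applies the per-interleave phase correction for the given motion trace
#' (converted from mm to pixels via the trajectory's pixel size), combines
#' all corrected interleaves, grids per channel and merges channels as the
#' square root of the sum of squares.
#'
#' @param data a [kspace_data()] object.
#' @param trace a [motion_trace()] whose length equals the interleave count.
#' @return a [sub_image()] holding the final image (magnitude for
#'   multi-channel data, complex for a single channel), `method = "LN"`.
#' @export
correct_and_reconstruct <- function(data, trace) {
  stopifnot(inherits(data, "kspace_data"), inherits(trace, "motion_trace"))
  traj <- data$traj
  if (length(trace) != traj$M)
    stop("trace length (", length(trace), ") does not match interleave count (",
         traj$M, ")")
  px <- trace_px(trace, traj$pixel_mm)
  corrected <- data
  for (m in seq_len(traj$M)) {
    if (px$dx_px[m] == 0 && px$dy_px[m] == 0) next
    corrected <- correct_interleave(corrected, m, px$dx_px[m], px$dy_px[m])
  }
  gridding_reconstruct(corrected)
}
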