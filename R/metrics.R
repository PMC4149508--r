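#' Motion-detection error statistics
#'
#' Per-interleave Euclidean distance between an estimated and a
#' ground-truth motion trace, with mean and standard deviation in mm, and
#' the relative average error (distance divided by the true displacement
#' magnitude, in percent) averaged over interleaves whose true displacement
#' is at least 0.5 mm - near-zero displacements are excluded to keep the
#' ratio bounded.
#'
#' Self-navigation estimates motion *relative to its reference sub-image*;
#' the absolute respiratory position of that reference is unobservable.
#' With `align = TRUE` (default) the ground truth is therefore re-expressed
#' relative to the estimate's reference interleave before distances are
#' taken; an estimate registered to a mid-inspiration reference is then not
#' charged for the reference's own (unknowable) displacement. When the two
#' traces share a reference this is a no-op.
#'
#' @param est,truth [motion_trace()] objects of equal length.
#' @param align re-express the truth relative to `est$reference_index`.
#' @return list with `distances_mm`, `mean_mm`, `sd_mm`, `relative_pct`
#'   (may be `NaN` when no interleave moves at least 0.5 mm).
#' @export
motion_error <- function(est, truth, align = TRUE) {
  if (length(est) != length(truth)) stop("traces must have equal length")
  tdx <- truth$dx_mm
  tdy <- truth$dy_mm
  if (align) {
    tdx <- tdx - tdx[est$reference_index]
    tdy <- tdy - tdy[est$reference_index]
  }
  d <- sqrt((est$dx_mm - tdx)^2 + (est$dy_mm - tdy)^2)
  mag <- sqrt(tdx^2 + tdy^2)
  sel <- mag >= 0.5
  list(distances_mm = d, mean_mm = mean(d), sd_mm = sd(d),
       relative_pct = if (any(sel)) 100 * mean(d[sel] / mag[sel]) else NaN)
}

#' Blood-pool SNR and blood-to-myocardium CNR
#'
#' \eqn{SNR = S_{blood} / \sigma_{noise}} and
#' \eqn{CNR = (S_{blood} - S_{myo}) / \sigma_{noise}}, where the `S` are
#' ROI means of the magnitude image and \eqn{\sigma_{noise}} is the
#' standard deviation inside a noise-only ROI outside the body.
#'
#' @param image magnitude (or complex) image.
#' @param roi_blood,roi_myo,roi_noise [make_ellipse_mask()] ROIs (or 0/1
#'   matrices); must be nonempty and pairwise disjoint.
#' @return list with `snr` and `cnr`.
#' @export
snr_cnr <- function(image, roi_blood, roi_myo, roi_noise) {
  img <- Mod(as.matrix(image))
  grids <- lapply(list(roi_blood, roi_myo, roi_noise), function(m)
    if (inherits(m, "roi_mask")) m$grid else m)
  if (any(vapply(grids, function(g) sum(g == 1) == 0, logical(1))))
    stop("all ROIs must be nonempty")
  if (sum(grids[[1]] * grids[[2]]) + sum(grids[[1]] * grids[[3]]) +
      sum(grids[[2]] * grids[[3]]) > 0)
    stop("ROIs must be pairwise disjoint")
  s_blood <- mean(img[grids[[1]] == 1])
  s_myo <- mean(img[grids[[2]] == 1])
  sn <- sd(img[grids[[3]] == 1])
  if (!is.finite(sn) || sn == 0) stop("noise ROI degenerate")
  list(snr = s_blood / sn, cnr = (s_blood - s_myo) / sn)
}

# Sample intensity profiles perpendicular to the centerline at points within
# the first segment_length_mm of arc length. Returns a list of profiles with
# the sampling offsets (px).
perp_profiles <- function(image, centerline, pixel_mm, segment_length_mm,
                          half_width_px, spacing_px = 0.5) {
  img <- Mod(as.matrix(image))
  n <- nrow(img)
  K <- nrow(centerline)
  if (K < 3) stop("centerline must have at least 3 points")
  seg <- c(0, cumsum(sqrt(diff(centerline[, 1])^2 + diff(centerline[, 2])^2)))
  keep <- which(seg * pixel_mm <= segment_length_mm)
  if (length(keep) < 3) keep <- seq_len(min(K, 3L))
  offs <- seq(-half_width_px, half_width_px, by = spacing_px)

  bilin <- function(x, y) {
    if (x < 1 || x > n || y < 1 || y > n) return(NA_real_)
    x0 <- floor(x); y0 <- floor(y)
    x1 <- min(x0 + 1, n); y1 <- min(y0 + 1, n)
    fx <- x - x0; fy <- y - y0
    img[y0, x0] * (1 - fx) * (1 - fy) + img[y0, x1] * fx * (1 - fy) +
      img[y1, x0] * (1 - fx) * fy + img[y1, x1] * fx * fy
  }

  out <- list()
  for (i in keep) {
    i0 <- max(1, i - 1); i1 <- min(K, i + 1)
    tx <- centerline[i1, 1] - centerline[i0, 1]
    ty <- centerline[i1, 2] - centerline[i0, 2]
    tn <- sqrt(tx^2 + ty^2)
    if (tn == 0) next
    nx <- -ty / tn; ny <- tx / tn
    prof <- vapply(offs, function(o)
      bilin(centerline[i, 1] + o * nx, centerline[i, 2] + o * ny),
      numeric(1))
    if (anyNA(prof)) next           # profile exits the image: skip point
    out[[length(out) + 1]] <- list(offsets = offs, values = prof)
  }
  if (length(out) == 0)
    stop("all centerline points skipped: profiles exit the image")
  out
}

# walk outward from the peak and return the interpolated offset at which the
# profile first crosses `level`; NA if it never does
cross_out <- function(offs, vals, peak_idx, side, level) {
  idx <- if (side > 0) peak_idx:length(vals) else peak_idx:1
  v <- vals[idx]
  below <- which(v <= level)
  if (length(below) == 0) return(NA_real_)
  j <- below[1]
  if (j == 1) return(offs[idx[1]])
  v1 <- v[j - 1]; v2 <- v[j]
  o1 <- offs[idx[j - 1]]; o2 <- offs[idx[j]]
  o1 + (o2 - o1) * (v1 - level) / (v1 - v2)
}

#' Percent vessel sharpness
#'
#' For each centerline point within the first `segment_length_mm` of arc
#' length, the perpendicular intensity profile is sampled (bilinear, 0.5 px
#' spacing). On each side of the local profile maximum the 20%-to-80% rise
#' distance (of the peak above the local per-side background, taken as that
#' side's profile minimum) is located by linear interpolation and converted
#' to a full edge width `d = rise / 0.6`; the per-edge sharpness is
#' `100 * pixel_mm / d_mm`, capped at 100, and %VS is the mean over all
#' edges. An ideal one-pixel edge scores 100%, an edge ramped linearly over
#' two pixels scores 50%. This operationalizes the vessel-sharpness score of
#' coronary MRA post-processing tools, whose exact formula is unpublished;
#' absolute values are therefore comparable only within this package.
#'
#' @param image magnitude (or complex) image.
#' @param centerline K x 2 matrix of (x, y) pixel coordinates along the
#'   vessel, ordered.
#' @param pixel_mm pixel size in mm.
#' @param segment_length_mm analyzed proximal arc length (default 20 mm).
#' @return %VS in `[0, 100]`.
#' @export
vessel_sharpness <- function(image, centerline, pixel_mm,
                             segment_length_mm = 20) {
  hw <- max(8, round(4 * 3 / pixel_mm))
  profs <- perp_profiles(image, centerline, pixel_mm, segment_length_mm, hw)
  edges <- c()
  for (pr in profs) {
    center_zone <- abs(pr$offsets) <= hw / 2
    pk <- which(center_zone)[which.max(pr$values[center_zone])]
    peak <- pr$values[pk]
    for (side in c(-1, 1)) {
      idx <- if (side > 0) pk:length(pr$values) else pk:1
      bg <- min(pr$values[idx])
      if (peak - bg <= 0) next
      l80 <- bg + 0.8 * (peak - bg)
      l20 <- bg + 0.2 * (peak - bg)
      o80 <- cross_out(pr$offsets, pr$values, pk, side, l80)
      o20 <- cross_out(pr$offsets, pr$values, pk, side, l20)
      if (is.na(o80) || is.na(o20)) next
      rise_px <- abs(o20 - o80)
      d_mm <- (rise_px / 0.6) * pixel_mm
      if (d_mm <= 0) next
      edges <- c(edges, min(100, 100 * pixel_mm / d_mm))
    }
  }
  if (length(edges) == 0) stop("no measurable vessel edges found")
  mean(edges)
}

#' Mean vessel diameter
#'
#' Mean full width at half maximum of the perpendicular intensity profiles
#' over the analyzed segment; the half level is taken per side between the
#' local profile maximum and the per-side background minimum.
#'
#' @inheritParams vessel_sharpness
#' @return mean diameter in mm.
#' @export
measure_diameter <- function(image, centerline, pixel_mm,
                             segment_length_mm = 20) {
  hw <- max(8, round(4 * 3 / pixel_mm))
  profs <- perp_profiles(image, centerline, pixel_mm, segment_length_mm, hw)
  widths <- c()
  for (pr in profs) {
    center_zone <- abs(pr$offsets) <= hw / 2
    pk <- which(center_zone)[which.max(pr$values[center_zone])]
    peak <- pr$values[pk]
    pos <- numeric(2)
    ok <- TRUE
    for (si in 1:2) {
      side <- c(-1, 1)[si]
      idx <- if (side > 0) pk:length(pr$values) else pk:1
      bg <- min(pr$values[idx])
      if (peak - bg <= 0) { ok <- FALSE; break }
      half <- bg + 0.5 * (peak - bg)
      o <- cross_out(pr$offsets, pr$values, pk, side, half)
      if (is.na(o)) { ok <- FALSE; break }
      pos[si] <- o
    }
    if (ok) widths <- c(widths, abs(pos[2] - pos[1]) * pixel_mm)
  }
  if (length(widths) == 0) stop("no measurable vessel widths found")
  mean(widths)
}

#' Agreement between a self-navigated and a reference respiratory trace
#'
#' Pearson correlation and least-squares linear regression of the
#' self-navigated superior-inferior displacement series on the reference
#' (e.g. diaphragmatic navigator) series. The regression slope is the
#' subject-specific correction factor relating heart to diaphragm
#' displacement.
#'
#' @param self_si,reference numeric series of equal length (>= 3), mm.
#' @return list with `cc`, `slope`, `intercept`.
#' @export
nav_agreement <- function(self_si, reference) {
  if (length(self_si) != length(reference) || length(self_si) < 3)
    stop("series must have equal length >= 3")
  if (sd(self_si) == 0 || sd(reference) == 0)
    stop("zero-variance input")
  fit <- lm(self_si ~ reference)
  list(cc = cor(self_si, reference),
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]))
}

#' Scan-time and efficiency arithmetic
#'
#' Self-navigation uses every heartbeat (100% scan efficiency), so relative
#' to a navigator-gated scan the acquisition-time reduction is
#' `100 * (nav - selfnav) / nav` percent and the scan-efficiency ratio is
#' `100 / nav_efficiency_pct`.
#'
#' @param selfnav_time_s,nav_time_s acquisition times in seconds.
#' @param nav_efficiency_pct navigator scan efficiency in percent.
#' @return list with `time_reduction_pct` and `efficiency_ratio`.
#' @export
protocol_arithmetic <- function(selfnav_time_s, nav_time_s,
                                nav_efficiency_pct) {
  if (selfnav_time_s <= 0 || nav_time_s <= 0 || nav_efficiency_pct <= 0)
    stop("all inputs must be positive")
  list(time_reduction_pct = 100 * (nav_time_s - selfnav_time_s) / nav_time_s,
       efficiency_ratio = 100 / nav_efficiency_pct)
}
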