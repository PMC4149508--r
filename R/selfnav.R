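#' Elliptical binary region-of-interest mask
#'
#' Pixel `(r, c)` (1-based) is inside iff
#' \eqn{((c - c_x)/a)^2 + ((r - c_y)/b)^2 \le 1}. The mask restricts the
#' registration similarity measure to the heart, excluding static tissue and
#' structures that move asynchronously.
#'
#' @param matrix grid side length.
#' @param center ellipse centre `c(cx, cy)` in pixels (x = column,
#'   y = row, 1-based).
#' @param semiaxes ellipse semiaxes `c(a, b)` in pixels, both positive.
#' @return an object of class `roi_mask` with fields `grid` (0/1 matrix),
#'   `center`, `semiaxes`.
#' @export
make_ellipse_mask <- function(matrix, center, semiaxes) {
  n <- as.integer(matrix)
  if (length(center) != 2 || length(semiaxes) != 2)
    stop("center and semiaxes must each have two elements")
  if (any(semiaxes <= 0)) stop("semiaxes must be positive")
  cc <- col(diag(n))
  rr <- row(diag(n))
  g <- ((cc - center[1]) / semiaxes[1])^2 +
    ((rr - center[2]) / semiaxes[2])^2 <= 1
  if (!any(g)) stop("ellipse does not intersect the grid (empty ROI)")
  structure(list(grid = g * 1L, center = center, semiaxes = semiaxes),
            class = "roi_mask")
}

#' Mean squared error restricted to a mask
#'
#' Mean of squared magnitude differences over the pixels where the mask
#' equals one; pixels outside the mask do not contribute.
#'
#' @param a,b images of equal size (numeric or complex).
#' @param mask an `roi_mask` (or 0/1 matrix) of the same size.
#' @return nonnegative scalar.
#' @export
masked_mse <- function(a, b, mask) {
  g <- if (inherits(mask, "roi_mask")) mask$grid else mask
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(g)))
    stop("image and mask dimensions must match")
  sel <- g == 1
  mean(Mod(a[sel] - b[sel])^2)
}

#' Options for translational registration
#'
#' @param search_px half-width of the coarse exhaustive integer-shift search
#'   that precedes gradient descent.
#' @param min_step descent terminates when the step length falls below this
#'   value (pixels).
#' @param max_steps maximum number of descent steps.
#' @param grad_h finite-difference half-width for the cost gradient (pixels).
#' @return a list of class `reg_opts`.
#' @export
reg_opts <- function(search_px = 8, min_step = 0.01, max_steps = 200,
                     grad_h = 0.05) {
  structure(list(search_px = as.integer(search_px), min_step = min_step,
                 max_steps = as.integer(max_steps), grad_h = grad_h),
            class = "reg_opts")
}

# cost of hypothesis d: masked MSE between the moving image pulled back by
# -d and the reference, over mask pixels whose interpolation support is
# inside the frame
reg_cost <- function(moving, reference, maskgrid, d) {
  tr <- translate_image(moving, -d[1], -d[2])
  valid <- attr(tr, "valid")
  sel <- maskgrid == 1 & valid
  if (!any(sel)) return(Inf)
  mean((tr[sel] - reference[sel])^2)
}

#' Estimate the in-plane translation between two sub-images
#'
#' Returns the displacement `(dx, dy)` (pixels) of the moving image's
#' content relative to the reference, i.e. the `d` minimizing the masked
#' mean squared error between the moving image translated by `-d` (bilinear
#' interpolation, zero fill, out-of-frame pixels excluded from the cost) and
#' the reference. Magnitude images normalized to unit maximum are compared.
#' A coarse exhaustive search over integer shifts precedes a fixed-step
#' gradient descent with step halving.
#'
#' @param moving,reference [sub_image()] objects (or plain matrices) of the
#'   same size.
#' @param mask an [make_ellipse_mask()] ROI.
#' @param opts a [reg_opts()] list.
#' @return numeric `c(dx, dy)` in pixels, with attributes `"cost"` (cost at
#'   the optimum) and `"steps"`.
#' @export
register_translation <- function(moving, reference, mask, opts = reg_opts()) {
  mv <- if (inherits(moving, "sub_image")) moving$pixels else moving
  rf <- if (inherits(reference, "sub_image")) reference$pixels else reference
  mv <- Mod(as.matrix(mv)); rf <- Mod(as.matrix(rf))
  if (!all(dim(mv) == dim(rf))) stop("sub-images must have the same size")
  if (max(mv) > 0) mv <- mv / max(mv)
  if (max(rf) > 0) rf <- rf / max(rf)
  g <- mask$grid
  if (!all(dim(g) == dim(mv))) stop("mask size must match the sub-images")

  # coarse integer-shift search
  best <- c(0, 0)
  best_cost <- reg_cost(mv, rf, g, best)
  for (ix in -opts$search_px:opts$search_px) {
    for (iy in -opts$search_px:opts$search_px) {
      cst <- reg_cost(mv, rf, g, c(ix, iy))
      if (cst < best_cost) {
        best_cost <- cst
        best <- c(ix, iy)
      }
    }
  }

  # gradient descent with step halving
  d <- best
  cost <- best_cost
  step <- 0.5
  h <- opts$grad_h
  steps <- 0L
  while (step >= opts$min_step && steps < opts$max_steps) {
    gx <- (reg_cost(mv, rf, g, d + c(h, 0)) -
             reg_cost(mv, rf, g, d - c(h, 0))) / (2 * h)
    gy <- (reg_cost(mv, rf, g, d + c(0, h)) -
             reg_cost(mv, rf, g, d - c(0, h))) / (2 * h)
    if (!is.finite(gx) || !is.finite(gy))
      stop("non-finite registration cost gradient at d = (",
           d[1], ", ", d[2], ")")
    gn <- sqrt(gx^2 + gy^2)
    if (gn == 0) break
    cand <- d - step * c(gx, gy) / gn
    ccost <- reg_cost(mv, rf, g, cand)
    if (!is.finite(ccost))
      stop("non-finite registration cost at d = (", cand[1], ", ", cand[2], ")")
    if (ccost < cost) {
      d <- cand
      cost <- ccost
    } else {
      step <- step / 2
    }
    steps <- steps + 1L
  }
  structure(d, cost = cost, steps = steps)
}

#' Per-interleave motion trace
#'
#' @param dx_mm,dy_mm per-interleave in-plane displacements in mm.
#' @param reference_index interleave serving as the zero of the trace; its
#'   displacement must be exactly `(0, 0)`.
#' @param pixel_mm pixel size used for mm/pixel conversion, if known.
#' @param si_mm optional per-interleave superior-inferior component.
#' @return an object of class `motion_trace`.
#' @export
motion_trace <- function(dx_mm, dy_mm, reference_index = 1L,
                         pixel_mm = NA_real_, si_mm = NULL) {
  if (length(dx_mm) != length(dy_mm)) stop("dx and dy must have equal length")
  ri <- as.integer(reference_index)
  if (ri < 1 || ri > length(dx_mm)) stop("reference_index out of range")
  if (dx_mm[ri] != 0 || dy_mm[ri] != 0)
    stop("displacement at the reference interleave must be exactly (0, 0)")
  structure(list(dx_mm = as.numeric(dx_mm), dy_mm = as.numeric(dy_mm),
                 reference_index = ri, pixel_mm = pixel_mm, si_mm = si_mm),
            class = "motion_trace")
}

#' @export
length.motion_trace <- function(x) length(x$dx_mm)

#' @export
print.motion_trace <- function(x, ...) {
  cat("motion_trace:", length(x), "interleaves, reference",
      x$reference_index, "\n")
  mag <- sqrt(x$dx_mm^2 + x$dy_mm^2)
  cat("  |d| range [", format(min(mag), digits = 3), ",",
      format(max(mag), digits = 3), "] mm\n")
  invisible(x)
}

#' Convert a motion trace to pixel units
#'
#' @param trace a [motion_trace()].
#' @param pixel_mm pixel size (defaults to the trace's own).
#' @return list with `dx_px`, `dy_px`.
#' @export
trace_px <- function(trace, pixel_mm = trace$pixel_mm) {
  if (is.na(pixel_mm)) stop("pixel_mm unknown; supply it explicitly")
  list(dx_px = trace$dx_mm / pixel_mm, dy_px = trace$dy_mm / pixel_mm)
}

#' Extract the per-interleave motion trace from sub-images
#'
#' Registers every sub-image to the reference sub-image inside the ROI mask.
#' The trace is expressed in the simulator/correction sign convention: a
#' positive trace entry is the displacement to feed [correct_interleave()],
#' which equals minus the apparent content displacement of that sub-image in
#' array coordinates (see the methods vignette for the convention ladder).
#'
#' @param sub_images list of [sub_image()] objects, one per interleave, all
#'   of equal size.
#' @param mask registration ROI, from [make_ellipse_mask()].
#' @param reference_index which sub-image serves as the reference (zero
#'   displacement). The default 1 keeps runs deterministic; pass
#'   `reference_index = "random"` with a seeded RNG to reproduce a random
#'   choice.
#' @param opts a [reg_opts()] list.
#' @return a [motion_trace()] with `pixel_mm` taken from the sub-images.
#' @export
extract_motion <- function(sub_images, mask, reference_index = 1L,
                           opts = reg_opts()) {
  M <- length(sub_images)
  if (M < 2) stop("need at least two sub-images")
  if (identical(reference_index, "random"))
    reference_index <- sample.int(M, 1)
  ri <- as.integer(reference_index)
  if (ri < 1 || ri > M) stop("reference_index out of range")
  pixel_mm <- sub_images[[ri]]$pixel_mm
  ref <- sub_images[[ri]]
  dx <- numeric(M)
  dy <- numeric(M)
  costs <- numeric(M)
  for (m in seq_len(M)) {
    if (m == ri) next
    d <- tryCatch(register_translation(sub_images[[m]], ref, mask, opts),
                  error = function(e)
                    stop("registration failed for interleave ", m, ": ",
                         conditionMessage(e)))
    dx[m] <- -d[1] * pixel_mm
    dy[m] <- -d[2] * pixel_mm
    costs[m] <- attr(d, "cost")
  }
  out <- motion_trace(dx, dy, reference_index = ri, pixel_mm = pixel_mm)
  attr(out, "registration_costs") <- costs
  out
}

#' Superior-inferior component of an in-plane motion trace
#'
#' Maps the in-plane displacements to patient coordinates and returns the
#' z (superior-inferior) component. `orientation` is the 3x3 rotation whose
#' columns are the image x axis, image y axis and slice normal expressed in
#' patient coordinates (the inverse of the patient-to-slice rotation).
#'
#' @param trace a [motion_trace()].
#' @param orientation orthonormal 3x3 matrix.
#' @return numeric vector of per-interleave SI displacements in mm.
#' @export
si_component <- function(trace, orientation) {
  if (!is.matrix(orientation) || !all(dim(orientation) == c(3, 3)))
    stop("orientation must be a 3x3 matrix")
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("orientation must be orthonormal")
  orientation[3, 1] * trace$dx_mm + orientation[3, 2] * trace$dy_mm
}
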