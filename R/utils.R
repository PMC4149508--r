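#' Normalized root-mean-square error between two images
#'
#' RMSE between the magnitudes of `x` and `ref`, normalized by the intensity
#' range of the reference. Because the overall intensity scale of an MR
#' reconstruction is arbitrary (it depends on density-compensation
#' normalization, coil gains and, for iterative reconstructions, on the data
#' scaling), `x` is by default first scaled by the least-squares optimal
#' scalar so that the statistic measures structural fidelity rather than
#' global gain.
#'
#' @param x image (numeric or complex matrix) to evaluate.
#' @param ref reference image of the same size.
#' @param scale if `TRUE` (default), apply the least-squares optimal global
#'   scaling of `x` onto `ref` before computing the error.
#' @return a single nonnegative number.
#' @export
nrmse <- function(x, ref, scale = TRUE) {
  a <- Mod(as.matrix(x))
  b <- Mod(as.matrix(ref))
  if (!all(dim(a) == dim(b))) stop("images must have the same dimensions")
  if (scale) {
    denom <- sum(a * a)
    alpha <- if (denom > 0) sum(a * b) / denom else 1
    a <- alpha * a
  }
  rng <- diff(range(b))
  if (rng == 0) stop("reference image has zero intensity range")
  sqrt(mean((a - b)^2)) / rng
}

# integer-shift with zero fill; t = c(tx, ty) moves content by +tx columns
# and +ty rows
shift_int <- function(img, tx, ty) {
  n <- nrow(img)
  m <- ncol(img)
  out <- matrix(0, n, m)
  if (is.complex(img)) out <- matrix(0 + 0i, n, m)
  sr <- seq_len(n) - ty
  sc <- seq_len(m) - tx
  okr <- sr >= 1 & sr <= n
  okc <- sc >= 1 & sc <= m
  out[okr, okc] <- img[sr[okr], sc[okc]]
  out
}

#' Translate an image by a (possibly fractional) pixel offset
#'
#' Content is moved by `+tx` pixels along columns (x) and `+ty` pixels along
#' rows (y) using bilinear interpolation; pixels drawn from outside the frame
#' are zero-filled. The attribute `"valid"` of the result is a logical matrix
#' marking pixels whose four interpolation neighbours all lie inside the
#' frame.
#'
#' @param img numeric or complex matrix.
#' @param tx,ty translation in pixels.
#' @return translated matrix with a `"valid"` attribute.
#' @export
translate_image <- function(img, tx, ty) {
  fx <- floor(tx); gx <- tx - fx
  fy <- floor(ty); gy <- ty - fy
  a00 <- shift_int(img, fx, fy)
  a10 <- shift_int(img, fx + 1, fy)
  a01 <- shift_int(img, fx, fy + 1)
  a11 <- shift_int(img, fx + 1, fy + 1)
  out <- (1 - gx) * (1 - gy) * a00 + gx * (1 - gy) * a10 +
    (1 - gx) * gy * a01 + gx * gy * a11
  one <- matrix(1, nrow(img), ncol(img))
  v <- (1 - gx) * (1 - gy) * shift_int(one, fx, fy) +
    gx * (1 - gy) * shift_int(one, fx + 1, fy) +
    (1 - gx) * gy * shift_int(one, fx, fy + 1) +
    gx * gy * shift_int(one, fx + 1, fy + 1)
  attr(out, "valid") <- v > 1 - 1e-9
  out
}

#' Shift an image by an exact (Fourier-domain, periodic) translation
#'
#' Content moves by `+tx` columns and `+ty` rows with wrap-around; unlike
#' [translate_image()] no interpolation low-pass is introduced, so the
#' operation is exact for any fractional shift. Used where an image must be
#' compared against a reference at a known sub-pixel offset without
#' penalizing either side for resampling.
#'
#' @param img numeric or complex matrix (square or rectangular, even sides).
#' @param tx,ty translation in pixels.
#' @return matrix of the same type as `img` (complex in, complex out).
#' @export
fourier_shift_image <- function(img, tx, ty) {
  n <- nrow(img)
  m <- ncol(img)
  was_real <- !is.complex(img)
  kr <- c(0:(n / 2 - 1), -(n / 2):-1) / n
  kc <- c(0:(m / 2 - 1), -(m / 2):-1) / m
  ph <- exp(-2i * pi * (outer(kr, rep(1, m)) * ty + outer(rep(1, n), kc) * tx))
  out <- stats::fft(stats::fft(img) * ph, inverse = TRUE) / (n * m)
  if (was_real) Re(out) else out
}

#' Write a matrix as a plain-text PGM (P2) image
#'
#' Utility export for quick visual inspection; intensities are linearly
#' mapped to 0..255.
#'
#' @param img numeric or complex matrix (magnitude is taken).
#' @param path output file path.
#' @export
write_pgm <- function(img, path) {
  m <- Mod(as.matrix(img))
  rng <- range(m)
  g <- if (diff(rng) > 0) round(255 * (m - rng[1]) / diff(rng)) else m * 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(g), nrow(g)), "255"), con)
  write.table(g, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# run code with a temporarily-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
  }
  force(code)
}
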