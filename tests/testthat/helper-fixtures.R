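# Shared fixtures, built once per test run and cached. Module tests run at a
# reduced scale (matrix 96, 160 projections in 8 interleaves) to keep the
# suite fast; the acceptance tests use the full desk-scale configuration.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small trajectory/phantom world: 96 matrix, 2 mm pixels, 8 interleaves of 20
small_world <- function() fixture("small_world", function() {
  traj <- make_interleaved_radial(160, 8, 96, 192)
  phantom <- make_phantom(96, traj$pixel_mm, seed = 5)
  list(traj = traj, phantom = phantom)
})

# noiseless static acquisition of the small world
small_static <- function() fixture("small_static", function() {
  w <- small_world()
  zt <- motion_trace(numeric(8), numeric(8), pixel_mm = w$traj$pixel_mm)
  list(data = simulate_acquisition(w$phantom, w$traj, zt, noise_sd = 0),
       zero_trace = zt)
})

# a moderately smooth deterministic test image: band-limited random field
# tapered to compact support inside the field of view (as a real object is)
smooth_field <- function(n, seed = 3) {
  set.seed(seed)
  f <- matrix(rnorm(n * n), n, n)
  k <- outer(exp(-((seq_len(n) - n / 2)^2) / (2 * (n / 12)^2)),
             exp(-((seq_len(n) - n / 2)^2) / (2 * (n / 12)^2)))
  sm <- Re(stats::fft(stats::fft(f) * stats::fft(k / sum(k)), inverse = TRUE)) / n^2
  sm <- sm - min(sm)
  win <- outer(sin(pi * (seq_len(n) - 0.5) / n)^2,
               sin(pi * (seq_len(n) - 0.5) / n)^2)
  sm <- sm * win
  sm / max(sm)
}

# direct (slow) non-uniform DFT oracle used against the gridding NUFFT
direct_nudft <- function(image, kx, ky) {
  n <- nrow(image)
  ctr <- n / 2
  vapply(seq_along(kx), function(j) {
    ph <- exp(-2i * pi * (kx[j] * (col(image) - 1 - ctr) +
                            ky[j] * (row(image) - 1 - ctr)))
    sum(image * ph)
  }, complex(1))
}

# exact Fourier-domain (circular) sub-pixel shift, independent of the
# package's operators: content moves by +tx, +ty
fourier_shift <- function(img, tx, ty) {
  n <- nrow(img)
  kk <- c(0:(n / 2 - 1), -(n / 2):-1) / n
  px <- exp(-2i * pi * outer(rep(1, n), kk) * tx)
  py <- exp(-2i * pi * outer(kk, rep(1, n)) * ty)
  Re(stats::fft(stats::fft(img) * px * py, inverse = TRUE)) / n^2
}
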