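# internal helpers: seed derivation, small numerics

# Derive a child seed from a master seed and a stream index so that
# per-nucleus / per-iteration randomness is reproducible in isolation.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  m <- 2147483563
  s <- (as.numeric(seed) %% m)
  ((s * 48271 + 11 + as.numeric(stream) * 104729) %% m) + 1
}

# uniform random direction in the plane times a magnitude
runif_vec <- function(n, lo, hi) {
  theta <- stats::runif(n, 0, 2 * pi)
  r <- stats::runif(n, lo, hi)
  cbind(r * cos(theta), r * sin(theta))
}

# separable Gaussian convolution with zero padding (sigma in pixels);
# direct (non-FFT) so that pixels outside the kernel support stay exactly 0
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur_rows <- function(m) {
    nr <- nrow(m)
    out <- matrix(0, nr, ncol(m))
    for (s in -r:r) {
      src <- max(1L, 1L - s):min(nr, nr - s)
      out[src + s, ] <- out[src + s, ] + k[s + r + 1L] * m[src, ]
    }
    out
  }
  t(blur_rows(t(blur_rows(mat))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
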