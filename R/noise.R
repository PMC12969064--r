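# Pink (1/f) noise by spectral synthesis: a white Gaussian spectrum is
# shaped by f^(-1/2) so the power spectral density falls as 1/f, then
# transformed back to the time domain. The exponent is fixed here; it is a
# property of the generator, not a tuning knob.
PINK_PSD_EXPONENT <- -1

#' Generate a reproducible pink-noise series
#'
#' Produces a discretely sampled realisation of 1/f ("pink") noise by
#' spectral synthesis: independent complex Gaussian Fourier coefficients are
#' weighted by `f^(-1/2)` (so power falls as `1/f`), inverse-transformed, and
#' the resulting real series is normalised to zero sample mean and unit
#' sample standard deviation. Multiplying by a strength `sigma` therefore
#' scales the sample standard deviation exactly.
#'
#' The series is used as a piecewise-constant external forcing on the phase
#' velocities: pink noise is band-limited, so holding each sample constant
#' over one integration step is well-posed.
#'
#' @param n_steps Number of samples; at least 2.
#' @param dt Sampling interval, s; positive. Determines the physical
#'   frequency axis of the spectrum (and is recorded), but not the shape.
#' @param seed Integer seed; the same `(n_steps, dt, seed)` always yields a
#'   bit-identical series.
#'
#' @return A numeric vector of length `n_steps` with attributes `dt` and
#'   `seed`.
#' @export
#' @examples
#' eta <- pink_noise(1024, dt = 0.1, seed = 42)
#' c(mean(eta), sd(eta)) # ~0, 1
pink_noise <- function(n_steps, dt, seed) {
  if (!is.numeric(n_steps) || length(n_steps) != 1 || n_steps < 2) {
    stop("`n_steps` must be a single integer >= 2")
  }
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("`dt` must be a single positive number")
  }
  n <- as.integer(n_steps)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  # One-sided spectrum over the positive FFT bins.
  n_pos <- n %/% 2L
  f <- seq_len(n_pos) / (n * dt)
  amp <- f^(PINK_PSD_EXPONENT / 2)
  z <- complex(
    real = stats::rnorm(n_pos), imaginary = stats::rnorm(n_pos)
  ) * amp
  spec <- complex(length.out = n)
  spec[2:(n_pos + 1L)] <- z
  # Hermitian symmetry so the inverse transform is real; for even n the
  # Nyquist bin is its own conjugate and must be real.
  if (n %% 2L == 0L) {
    spec[n_pos + 1L] <- complex(real = Re(z[n_pos]) * sqrt(2))
    if (n_pos >= 2L) {
      spec[seq.int(n, n_pos + 2L)] <- Conj(spec[seq.int(2L, n_pos)])
    }
  } else {
    spec[seq.int(n, n_pos + 2L)] <- Conj(spec[seq.int(2L, n_pos + 1L)])
  }
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x <- x / stats::sd(x)
  structure(x, dt = dt, seed = as.integer(seed))
}

# Independent per-oscillator noise substreams for one run: substream seeds
# are drawn once from the run seed, so the five series are mutually
# independent and the whole set is reproducible from a single integer.
noise_substream_seeds <- function(seed, n_streams = 5L) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) + 1L)
  sample.int(.Machine$integer.max - 1L, n_streams)
}
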