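#' Default logarithmic frequency grid
#' @param fmin,fmax band edges, Hz.
#' @param n number of bands.
#' @return numeric vector of band center frequencies, Hz, increasing.
#' @export
default_freq_grid <- function(fmin = 0.5, fmax = 100, n = 32)
  exp(seq(log(fmin), log(fmax), length.out = n))

#' Continuous wavelet transform with a complex Morlet wavelet
#'
#' FFT-based CWT with the analytic Morlet wavelet (center frequency
#' parameter \code{omega0}, default 6) on an explicit frequency grid;
#' the scale for band frequency f is \eqn{s = \omega_0 / (2\pi f)}.
#' Energy-preserving (L2) normalization: time-averaged band power of
#' white noise is flat across bands, and a pure tone's power ridge falls
#' within one grid step of the tone frequency.
#'
#' @param trace a [trace_record()] (or numeric vector plus \code{dt}).
#' @param freqs band center frequencies, Hz, all in (0, Nyquist).
#' @param omega0 Morlet center frequency parameter (dimensionless).
#' @param dt sampling interval when \code{trace} is a bare vector.
#' @return a \code{wavelet_decomp}: \code{coefficients} (complex,
#'   bands x time), \code{freqs} (Hz), \code{omega0}, \code{dt}.
#' @examples
#' tr <- trace_record(sin(2 * pi * 10 * seq(0, 5, by = 1e-3)), dt = 1e-3)
#' d <- cwt_morlet(tr, freqs = default_freq_grid())
#' d$freqs[which.max(band_power(d))]
#' @export
cwt_morlet <- function(trace, freqs = default_freq_grid(), omega0 = 6,
                       dt = NULL) {
  if (inherits(trace, "trace_record")) {
    x <- trace$samples; dt <- trace$dt
  } else {
    x <- as.numeric(trace)
    if (is.null(dt)) stop("dt required for a bare numeric series")
  }
  nyq <- 1 / (2 * dt)
  if (any(freqs <= 0) || any(freqs >= nyq))
    stop("all frequencies must lie strictly within (0, Nyquist = ",
         nyq, " Hz)")
  n <- length(x)
  npad <- 2^ceiling(log2(2 * n))
  xh <- stats::fft(c(x, rep(0, npad - n)))
  w <- 2 * pi * (0:(npad - 1)) / (npad * dt)
  w[w > pi / dt] <- w[w > pi / dt] - 2 * pi / dt
  co <- matrix(0i, length(freqs), n)
  for (k in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[k])
    psi_hat <- pi^-0.25 * sqrt(2 * pi * s / dt) *
      exp(-(s * w - omega0)^2 / 2) * (w > 0)
    co[k, ] <- stats::fft(xh * psi_hat, inverse = TRUE)[1:n] / npad
  }
  structure(list(coefficients = co, freqs = freqs, omega0 = omega0,
                 dt = dt),
            class = "wavelet_decomp")
}

#' @export
print.wavelet_decomp <- function(x, ...) {
  cat(sprintf("<wavelet_decomp> %d bands (%.3g-%.3g Hz) x %d samples, Morlet omega0 = %g\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              ncol(x$coefficients), x$omega0))
  invisible(x)
}

#' Time-averaged power per wavelet band
#' @param decomp a [cwt_morlet()] decomposition.
#' @return numeric vector, mean |coefficient|^2 per band.
#' @export
band_power <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomp"))
  rowMeans(abs(decomp$coefficients)^2)
}

#' Raw-signal wavelet power spectrum
#'
#' Convenience wrapper: CWT of the raw trace and its time-averaged power
#' per band.
#'
#' @inheritParams cwt_morlet
#' @return data.frame with \code{band_hz} and \code{power}.
#' @export
raw_power <- function(trace, freqs = default_freq_grid(), omega0 = 6,
                      dt = NULL) {
  d <- cwt_morlet(trace, freqs = freqs, omega0 = omega0, dt = dt)
  data.frame(band_hz = d$freqs, power = band_power(d))
}
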