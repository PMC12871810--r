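#' Augmented Dickey-Fuller unit-root test
#'
#' OLS Dickey-Fuller regression with a constant and no trend:
#' \deqn{\Delta y_t = \alpha + \rho\, y_{t-1} +
#'   \sum_{j=1}^{p} \gamma_j \Delta y_{t-j} + \varepsilon_t,}
#' with the test statistic the t-ratio of \eqn{\rho}. The null
#' hypothesis is that the series contains a unit root (a stochastic
#' trend, i.e. non-stationarity); a high p-value means insufficient
#' evidence to reject non-stationarity. P-values come from the MacKinnon
#' response-surface approximation for the constant-only case.
#'
#' @param x numeric series (or a [trace_record()]).
#' @param lags lag order p: a non-negative integer, or \code{"aic"} to
#'   select p in 0..\code{max_lag} by Akaike information criterion.
#' @param max_lag cap for automatic selection; default the Schwert rule
#'   \code{floor(12 * (n/100)^0.25)}.
#' @return an \code{adf_result}: \code{statistic}, \code{p_value},
#'   \code{lags}, \code{n} (regression observations).
#' @examples
#' adf_test(cumsum(rnorm(500)))$p_value   # unit root: high p
#' adf_test(rnorm(500))$p_value           # stationary: ~ 0
#' @export
adf_test <- function(x, lags = "aic", max_lag = NULL) {
  if (inherits(x, "trace_record")) x <- x$samples
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L) stop("series too short for an ADF regression")
  if (stats::var(x) == 0) stop("constant series: ADF undefined")
  if (identical(lags, "aic")) {
    if (is.null(max_lag)) max_lag <- floor(12 * (n / 100)^0.25)
    max_lag <- min(max_lag, n %/% 3L)
    fits <- lapply(0:max_lag, function(p) adf_ols(x, p, trim = max_lag))
    best <- which.min(vapply(fits, `[[`, 1, "aic"))
    res <- adf_ols(x, best - 1L)
    p <- best - 1L
  } else {
    p <- as.integer(lags)
    stopifnot(p >= 0L)
    res <- adf_ols(x, p)
  }
  structure(list(statistic = res$stat,
                 p_value = mackinnon_p(res$stat),
                 lags = p, n = res$nobs),
            class = "adf_result")
}

#' @export
print.adf_result <- function(x, ...) {
  cat(sprintf("<adf_result> tau = %.4f, p = %.4g (lags = %d, n = %d); H0: unit root\n",
              x$statistic, x$p_value, x$lags, x$n))
  invisible(x)
}

# Dickey-Fuller OLS; trim > lags holds the estimation sample fixed
# across lag orders for information-criterion comparison.
adf_ols <- function(x, lags, trim = lags) {
  n <- length(x)
  dx <- diff(x)
  xl <- x[-n]
  k <- max(lags, trim)
  nobs <- length(dx) - k
  if (nobs < lags + 3L) stop("series too short for lag order ", lags)
  y <- dx[(k + 1):length(dx)]
  X <- cbind(xl[(k + 1):length(xl)], 1)
  if (lags > 0)
    for (j in 1:lags)
      X <- cbind(X, dx[(k + 1 - j):(length(dx) - j)])
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  s2 <- sum(res^2) / (nobs - ncol(X))
  XtXinv <- chol2inv(chol(crossprod(X)))
  stat <- unname(fit$coefficients[1] / sqrt(s2 * XtXinv[1, 1]))
  list(stat = stat, nobs = nobs,
       aic = nobs * log(sum(res^2) / nobs) + 2 * ncol(X))
}

# MacKinnon (1994, updated 2010) response-surface p-value approximation,
# constant / no-trend case.
mackinnon_p <- function(stat) {
  tau_star <- -1.61; tau_min <- -18.83; tau_max <- 2.74
  smallp <- c(2.1659, 1.4412, 3.8269e-2)
  largep <- c(1.7339, 9.3202e-1, -1.2745e-1, -1.0368e-2)
  if (stat > tau_max) return(1)
  if (stat < tau_min) return(0)
  co <- if (stat <= tau_star) smallp else largep
  stats::pnorm(sum(co * stat^(seq_along(co) - 1)))
}

#' Per-band stationarity profile of a wavelet decomposition
#'
#' Runs the ADF unit-root test on the real part of each band's
#' coefficient series (the signed band-limited fluctuation; set
#' \code{envelope = TRUE} to use the magnitude envelope instead). Band
#' series are decimated to about \code{samples_per_cycle} samples per
#' wavelet period before the regression, because the CWT output is
#' heavily oversampled relative to each band's bandwidth. Constant band
#' series are reported degenerate with p = NA. No aggregation across
#' bands is performed; the full profile is returned.
#'
#' @param decomp a [cwt_morlet()] decomposition.
#' @param lags lag order per band; integer or \code{"aic"}.
#' @param samples_per_cycle decimation target, samples per band period.
#' @param envelope test |coefficient| instead of the real part.
#' @return a \code{stationarity_profile} data.frame: \code{band_hz},
#'   \code{adf_stat}, \code{p_value}, \code{lags}, \code{n},
#'   \code{degenerate}.
#' @export
adf_profile <- function(decomp, lags = "aic", samples_per_cycle = 20,
                        envelope = FALSE) {
  stopifnot(inherits(decomp, "wavelet_decomp"))
  rows <- lapply(seq_along(decomp$freqs), function(k) {
    f <- decomp$freqs[k]
    series <- if (envelope) abs(decomp$coefficients[k, ])
              else Re(decomp$coefficients[k, ])
    stride <- max(1L, round(1 / (f * decomp$dt) / samples_per_cycle))
    series <- series[seq(1L, length(series), by = stride)]
    if (length(series) < 50L || stats::var(series) == 0)
      return(data.frame(band_hz = f, adf_stat = NA_real_,
                        p_value = NA_real_, lags = NA_integer_,
                        n = length(series), degenerate = TRUE))
    r <- adf_test(series, lags = lags)
    data.frame(band_hz = f, adf_stat = r$statistic, p_value = r$p_value,
               lags = r$lags, n = r$n, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stationarity_profile", "data.frame")
  out
}
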