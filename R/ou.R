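#' Fit an Ornstein-Uhlenbeck model to a trace
#'
#' The series is mean-centered; the time constant tau is the decay
#' constant of a least-squares fit of \eqn{\exp(-\mathrm{lag}/\tau)} to
#' the empirical autocorrelation function over lags from 0 up to the
#' first lag where the ACF drops below 0.05 (capped at \code{max_lag});
#' the noise amplitude sigma is the SD of the linearly detrended signal;
#' mu is the raw mean. Adding a constant offset to the trace leaves tau
#' and sigma unchanged.
#'
#' @param trace a [trace_record()] (or numeric vector plus \code{dt}).
#' @param max_lag maximum ACF lag used in the fit, s (default 1).
#' @param dt sampling interval when \code{trace} is a bare vector.
#' @return an \code{ou_params}: \code{tau} (s), \code{sigma} (signal
#'   units), \code{mu}, and \code{fit} diagnostics (\code{rmse},
#'   \code{n_lags}, \code{max_lag}).
#' @examples
#' ou <- gen_ou(tau = 0.05, sigma = 1, dt = 1e-3, n = 30000, seed = 1)
#' fit_ou(ou)
#' @export
fit_ou <- function(trace, max_lag = 1, dt = NULL) {
  if (inherits(trace, "trace_record")) {
    x <- trace$samples; dt <- trace$dt
  } else {
    x <- as.numeric(trace)
    if (is.null(dt)) stop("dt required for a bare numeric series")
  }
  mu <- mean(x)
  xc <- x - mu
  if (stats::var(xc) == 0) stop("degenerate series: zero variance")
  ml <- min(round(max_lag / dt), length(x) - 2L)
  ac <- as.numeric(stats::acf(xc, lag.max = ml, plot = FALSE,
                              demean = FALSE)$acf)
  cut <- which(ac < 0.05)[1]
  if (!is.na(cut)) ac <- ac[seq_len(max(cut, 5L))]
  lags <- (seq_along(ac) - 1) * dt
  tau0 <- max(c(lags[ac > exp(-1)], dt))
  fit <- tryCatch(
    stats::nls(ac ~ exp(-lags / tau), data = list(ac = ac, lags = lags),
               start = list(tau = tau0)),
    error = function(e)
      stop("exponential ACF fit failed (start tau = ", signif(tau0, 3),
           " s, ", length(ac), " lags): ", conditionMessage(e)))
  sigma <- stats::sd(stats::residuals(
    stats::lm(xc ~ seq_along(xc))))
  structure(list(tau = stats::coef(fit)[["tau"]], sigma = sigma, mu = mu,
                 fit = list(rmse = sqrt(mean(stats::residuals(fit)^2)),
                            n_lags = length(ac), max_lag = max_lag)),
            class = "ou_params")
}

#' @export
print.ou_params <- function(x, ...) {
  cat(sprintf("<ou_params> tau = %.4g s, sigma = %.4g, mu = %.4g (ACF fit RMSE %.3g over %d lags)\n",
              x$tau, x$sigma, x$mu, x$fit$rmse, x$fit$n_lags))
  invisible(x)
}

#' Simulate the OU process of a fitted parameter set
#'
#' Thin wrapper over [gen_ou()] using the fitted (tau, sigma, mu) and a
#' fixed time step, typically the original sampling interval of the LFP
#' the parameters came from.
#'
#' @param params an \code{ou_params} (from [fit_ou()]) or a list with
#'   \code{tau}, \code{sigma}, \code{mu}.
#' @param n number of samples.
#' @param dt time step, s.
#' @param seed integer RNG seed.
#' @param scheme passed to [gen_ou()].
#' @return a \code{trace_record}.
#' @export
simulate_fitted <- function(params, n, dt, seed = 1,
                            scheme = c("exact", "euler")) {
  stopifnot(!is.null(params$tau), !is.null(params$sigma))
  gen_ou(tau = params$tau, sigma = params$sigma,
         mu = if (is.null(params$mu)) 0 else params$mu,
         dt = dt, n = n, seed = seed, scheme = match.arg(scheme))
}
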