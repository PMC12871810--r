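#' Steady-state inactivation curve with Boltzmann fit
#'
#' Per prepulse voltage, the test-pulse peak is the extremum of the
#' repeat-averaged current within the test window (most negative
#' excursion for inward currents; flip with \code{polarity}); peaks are
#' normalized by the maximum across voltages and fitted with the
#' Boltzmann availability \eqn{1/(1+\exp((V-V_{1/2})/k))}, k > 0, so
#' availability falls with depolarization. Shifting all voltages by a
#' constant shifts the fitted half-inactivation voltage by exactly that
#' constant.
#'
#' @param sweeps a [gen_inactivation_sweeps()]-style \code{sweep_set}.
#' @param polarity \code{"negative"} (inward, default) or
#'   \code{"positive"}.
#' @param window \code{"test"} to restrict to the test-pulse window
#'   (default) or \code{"full"}.
#' @return an \code{inactivation_curve}: \code{voltages},
#'   \code{normalized} (I/Imax), \code{v_half} (mV), \code{slope} (mV),
#'   \code{rmse}, \code{converged}.
#' @export
inactivation_curve <- function(sweeps, polarity = c("negative", "positive"),
                               window = c("test", "full")) {
  stopifnot(inherits(sweeps, "sweep_set"))
  polarity <- match.arg(polarity)
  window <- match.arg(window)
  idx <- if (window == "test")
    sweeps$test_window[1]:sweeps$test_window[2]
  else seq_len(dim(sweeps$currents)[3])
  sgn <- if (polarity == "negative") -1 else 1
  peaks <- vapply(seq_along(sweeps$voltages), function(vi) {
    avg <- colMeans(sweeps$currents[vi, , idx, drop = FALSE][1, , ])
    max(sgn * avg)
  }, 1)
  if (all(peaks == 0)) stop("all-zero currents; nothing to fit")
  norm <- peaks / max(peaks)
  V <- sweeps$voltages
  start <- list(vh = V[which.min(abs(norm - 0.5))], k = 5)
  fit <- tryCatch(
    minpack.lm::nlsLM(norm ~ 1 / (1 + exp((V - vh) / k)),
                      data = list(norm = norm, V = V), start = start,
                      lower = c(-Inf, 1e-3)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Boltzmann fit did not converge; raw curve returned")
    return(structure(list(voltages = V, normalized = norm,
                          v_half = NA_real_, slope = NA_real_,
                          rmse = NA_real_, converged = FALSE),
                     class = "inactivation_curve"))
  }
  cf <- stats::coef(fit)
  structure(list(voltages = V, normalized = norm,
                 v_half = unname(cf["vh"]), slope = unname(cf["k"]),
                 rmse = sqrt(mean(stats::residuals(fit)^2)),
                 converged = TRUE),
            class = "inactivation_curve")
}

#' @export
print.inactivation_curve <- function(x, ...) {
  cat(sprintf("<inactivation_curve> V1/2 = %.2f mV, k = %.2f mV (RMSE %.3g)\n",
              x$v_half, x$slope, x$rmse))
  invisible(x)
}

#' Non-stationary noise profile of current sweeps
#'
#' Per voltage and time point, residuals are each repeat minus the
#' repeat-averaged current; their SD across repeats (divisor n-1) forms
#' the residual-SD trace. The maximum noise variability is the maximum
#' of that trace over time (within the test-pulse window by default) and
#' over voltages. Adding any common waveform to all repeats at a voltage
#' leaves the profile unchanged.
#'
#' @param sweeps a \code{sweep_set} with >= 2 repeats per voltage.
#' @param window \code{"test"} (default) or \code{"full"}: range over
#'   which the maximum is taken (the SD trace itself always spans the
#'   full sweep).
#' @return a \code{noise_profile}: \code{sd_traces} (voltage x time
#'   matrix, pA), \code{max_noise_variability} (pA),
#'   \code{voltage_at_max} (mV), \code{time_at_max} (s),
#'   \code{time_averaged_sd} (per voltage, over the max window).
#' @export
noise_profile <- function(sweeps, window = c("test", "full")) {
  stopifnot(inherits(sweeps, "sweep_set"))
  window <- match.arg(window)
  d <- dim(sweeps$currents)
  if (d[2] < 2L) stop("need at least 2 repeats per voltage")
  sd_traces <- t(vapply(seq_len(d[1]), function(vi) {
    x <- sweeps$currents[vi, , ]           # repeats x time
    res <- sweep(x, 2, colMeans(x))
    apply(res, 2, stats::sd)
  }, numeric(d[3])))
  idx <- if (window == "test")
    sweeps$test_window[1]:sweeps$test_window[2]
  else seq_len(d[3])
  sub <- sd_traces[, idx, drop = FALSE]
  at <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  structure(list(sd_traces = sd_traces,
                 max_noise_variability = max(sub),
                 voltage_at_max = sweeps$voltages[at[1]],
                 time_at_max = (idx[at[2]] - 1) * sweeps$dt,
                 time_averaged_sd = rowMeans(sub)),
            class = "noise_profile")
}

#' @export
print.noise_profile <- function(x, ...) {
  cat(sprintf("<noise_profile> max noise variability %.3g pA at %g mV, t = %.4g s\n",
              x$max_noise_variability, x$voltage_at_max, x$time_at_max))
  invisible(x)
}

#' Peak-alignment diagnostics for residual noise
#'
#' Where in the sweep does the residual SD peak relative to the peak of
#' the mean current? Current-amplitude-dependent (e.g. gating) noise
#' concentrates its largest deviations near the current peak; additive
#' homoscedastic noise shows no systematic alignment.
#'
#' @param sweeps a \code{sweep_set}.
#' @param polarity as in [inactivation_curve()].
#' @return data.frame per voltage: \code{voltage_mV},
#'   \code{t_current_peak}, \code{t_sd_max}, \code{offset_s},
#'   \code{degenerate} (TRUE when the SD trace is all zero).
#' @export
peak_alignment_check <- function(sweeps,
                                 polarity = c("negative", "positive")) {
  stopifnot(inherits(sweeps, "sweep_set"))
  polarity <- match.arg(polarity)
  sgn <- if (polarity == "negative") -1 else 1
  np <- noise_profile(sweeps, window = "test")
  idx <- sweeps$test_window[1]:sweeps$test_window[2]
  rows <- lapply(seq_along(sweeps$voltages), function(vi) {
    avg <- colMeans(sweeps$currents[vi, , idx, drop = FALSE][1, , ])
    sdv <- np$sd_traces[vi, idx]
    tp <- (idx[which.max(sgn * avg)] - 1) * sweeps$dt
    degen <- all(sdv == 0)
    ts <- if (degen) NA_real_ else (idx[which.max(sdv)] - 1) * sweeps$dt
    data.frame(voltage_mV = sweeps$voltages[vi], t_current_peak = tp,
               t_sd_max = ts, offset_s = ts - tp, degenerate = degen)
  })
  do.call(rbind, rows)
}
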