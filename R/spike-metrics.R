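#' Spike train container
#'
#' @param times spike times in seconds, strictly increasing.
#' @param peak_indices optional sample indices of the peaks.
#' @param onset_rapidness optional per-spike peak dV/dt, V/s (aligned
#'   1:1 with \code{times}; NA where undefined).
#' @param dt sampling interval of the source trace, s (NA if unknown).
#' @return an object of class \code{spike_train}.
#' @export
spike_train <- function(times, peak_indices = NULL, onset_rapidness = NULL,
                        dt = NA_real_) {
  times <- as.numeric(times)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("spike times must be strictly increasing")
  if (!is.null(onset_rapidness) && length(onset_rapidness) != length(times))
    stop("onset_rapidness must align 1:1 with spike times")
  if (!is.null(peak_indices)) peak_indices <- as.integer(peak_indices)
  structure(list(times = times, peak_indices = peak_indices,
                 onset_rapidness = onset_rapidness, dt = dt),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes", length(x$times)))
  if (length(x$times) > 1L)
    cat(sprintf(", span %.3f s, mean rate %.2f Hz", diff(range(x$times)),
                (length(x$times) - 1) / diff(range(x$times))))
  cat("\n")
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Threshold-based spike detection
#'
#' One spike per contiguous supra-threshold excursion (strict
#' \code{>} crossing; samples exactly at threshold do not trigger), timed
#' at the sample of the local extremum. Peaks closer than
#' \code{refractory} after a registered peak are suppressed. Negative
#' polarity (extracellular MEA peaks) inverts the comparison.
#'
#' @param trace a [trace_record()].
#' @param threshold detection threshold in trace units.
#' @param refractory dead time after an accepted peak, s (>= 0).
#' @param polarity \code{"positive"} (default) or \code{"negative"}.
#' @return a [spike_train()] with \code{times} and \code{peak_indices}.
#' @examples
#' syn <- gen_membrane_trace(duration = 2, seed = 1)
#' detect_spikes(syn$trace, threshold = -20)
#' @export
detect_spikes <- function(trace, threshold, refractory = 2e-3,
                          polarity = c("positive", "negative")) {
  stopifnot(inherits(trace, "trace_record"), refractory >= 0)
  polarity <- match.arg(polarity)
  v <- trace$samples
  if (any(!is.finite(v))) stop("trace contains non-finite samples")
  if (polarity == "negative") { v <- -v; threshold <- -threshold }
  above <- v > threshold
  if (!any(above))
    return(spike_train(numeric(0), integer(0), dt = trace$dt))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  peaks <- apply(seg, 1, function(s) s[1] - 1L + which.max(v[s[1]:s[2]]))
  # refractory suppression relative to the last accepted peak
  keep <- logical(length(peaks))
  last <- -Inf
  for (i in seq_along(peaks)) {
    if ((peaks[i] - last) * trace$dt > refractory) {
      keep[i] <- TRUE
      last <- peaks[i]
    }
  }
  peaks <- peaks[keep]
  spike_train(times = (peaks - 1L) * trace$dt, peak_indices = peaks,
              dt = trace$dt)
}

#' Per-spike peak onset rapidness (max dV/dt of the rising phase)
#'
#' dV/dt is computed by central finite differences (one-sided at the
#' trace edges) over a window ending at each spike peak; the reported
#' value is the maximum within that depolarizing segment, in V/s.
#' Spikes whose window does not fit in the trace are flagged NA and
#' listed in attribute \code{excluded}.
#'
#' @param trace a [trace_record()] in mV.
#' @param spikes a [spike_train()] with \code{peak_indices}.
#' @param window window length before each peak, s (default 2 ms; must
#'   cover >= 3 samples).
#' @return numeric vector of V/s aligned with the spikes; attribute
#'   \code{excluded} holds indices of flagged spikes.
#' @export
onset_rapidness <- function(trace, spikes, window = 2e-3) {
  stopifnot(inherits(trace, "trace_record"), inherits(spikes, "spike_train"))
  if (is.null(spikes$peak_indices)) stop("spike train lacks peak_indices")
  w <- round(window / trace$dt)
  if (w < 3L) stop("window must cover at least 3 samples")
  dv <- finite_diff(trace$samples, trace$dt)  # mV/s
  out <- rep(NA_real_, length(spikes$times))
  for (i in seq_along(out)) {
    p <- spikes$peak_indices[i]
    if (p - w < 1L) next
    out[i] <- max(dv[(p - w):p]) / 1000
  }
  structure(out, excluded = which(is.na(out)))
}

# central differences, one-sided at the edges
finite_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Local variation of an interspike-interval series
#'
#' \deqn{Lv = \frac{1}{n-1}\sum_{i=1}^{n-1}
#'   \frac{3 (T_i - T_{i+1})^2}{(T_i + T_{i+1})^2}}
#' 0 for perfectly regular firing; expectation 1 for Poisson firing, and
#' \eqn{3/(2\kappa+1)} for gamma-renewal ISIs of shape \eqn{\kappa}.
#' Invariant to uniform time rescaling.
#'
#' @param isis interspike intervals, s (> 0, length >= 2).
#' @return the Lv statistic (dimensionless scalar).
#' @examples
#' local_variation(c(1, 2, 1, 2, 1))  # exactly 1/3
#' @export
local_variation <- function(isis) {
  isis <- as.numeric(isis)
  if (length(isis) < 2L) stop("need at least 2 ISIs")
  if (any(!is.finite(isis)) || any(isis <= 0))
    stop("all ISIs must be positive and finite")
  a <- isis[-length(isis)]
  b <- isis[-1]
  mean(3 * (a - b)^2 / (a + b)^2)
}

#' Basic spike-train statistics
#'
#' @param spikes a [spike_train()] (or numeric spike times).
#' @param duration recording duration, s (> 0).
#' @param n_bins number of ISI histogram bins.
#' @return a \code{spike_stats} list: \code{isis} (s), \code{inst_freq}
#'   (Hz, 1/ISI), \code{mean_rate} (Hz), \code{lv}, and
#'   \code{isi_histogram} (\code{breaks}, \code{prob}; probabilities sum
#'   to 1).
#' @export
spike_stats <- function(spikes, duration, n_bins = 30) {
  if (inherits(spikes, "spike_train")) spikes <- spikes$times
  stopifnot(duration > 0)
  isis <- diff(spikes)
  hist <- if (length(isis)) {
    h <- graphics::hist(isis, breaks = n_bins, plot = FALSE)
    list(breaks = h$breaks, prob = h$counts / sum(h$counts))
  } else list(breaks = numeric(0), prob = numeric(0))
  structure(list(
    isis = isis,
    inst_freq = if (length(isis)) 1 / isis else numeric(0),
    mean_rate = length(spikes) / duration,
    lv = if (length(isis) >= 2) local_variation(isis) else NA_real_,
    isi_histogram = hist
  ), class = "spike_stats")
}

#' @export
print.spike_stats <- function(x, ...) {
  cat(sprintf("<spike_stats> mean rate %.2f Hz, %d ISIs, Lv = %s\n",
              x$mean_rate, length(x$isis),
              ifelse(is.na(x$lv), "NA", sprintf("%.3f", x$lv))))
  invisible(x)
}
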