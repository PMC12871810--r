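#' Phase-space trajectory
#'
#' @param coords numeric matrix, one row per time point, one column per
#'   coordinate (any dimension; the membrane embedding uses 2).
#' @param dt sampling interval, s.
#' @return object of class \code{phase_trajectory}.
#' @export
phase_trajectory <- function(coords, dt) {
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) stop("trajectory coordinates must be finite")
  if (nrow(coords) < 3L) stop("need at least 3 points")
  stopifnot(dt > 0)
  structure(list(coords = coords, dt = dt), class = "phase_trajectory")
}

#' Embed a voltage trace in (V, dV/dt) phase space
#'
#' The trajectory lives in the plane of the membrane potential and its
#' time derivative (central differences, one-sided at the edges).
#' Standardization to unit variance per axis -- V (mV) and dV/dt (V/s)
#' are incommensurate -- is applied at distance-computation time by
#' [lyapunov_exponent()]; set \code{standardize = TRUE} to bake it into
#' the coordinates instead.
#'
#' @param trace a [trace_record()].
#' @param standardize scale each axis to unit variance now.
#' @return a [phase_trajectory()] with columns \code{v} and \code{dvdt}.
#' @export
phase_embed <- function(trace, standardize = FALSE) {
  stopifnot(inherits(trace, "trace_record"))
  v <- trace$samples
  if (any(!is.finite(v))) stop("trace contains non-finite samples")
  coords <- cbind(v = v, dvdt = finite_diff(v, trace$dt))
  if (standardize) {
    s <- apply(coords, 2, stats::sd)
    s[s == 0] <- 1
    coords <- sweep(coords, 2, s, "/")
  }
  phase_trajectory(coords, trace$dt)
}

#' Local-divergence Lyapunov exponent of a phase trajectory
#'
#' For each reference point \eqn{Y_i}, the nearest Euclidean neighbour
#' \eqn{Y_{i^*}} outside a Theiler exclusion window (and above a minimum
#' initial separation) is tracked forward, and
#' \deqn{\lambda(i) = \frac{1}{(K_{max}-K_{min}+1)\,dt}
#'   \sum_{K=K_{min}}^{K_{max}} \frac{1}{K}
#'   \ln\frac{\|Y_{i+K}-Y_{i^*+K}\|}{\|Y_i-Y_{i^*}\|}.}
#' The global exponent is the mean of \eqn{\lambda(i)} over references
#' with an admissible neighbour. Positive values indicate exponential
#' divergence of nearby trajectories (dynamical instability); a neutral
#' (periodic) orbit gives values near zero.
#'
#' Coordinates are standardized to unit variance per axis before
#' distances unless \code{standardize = FALSE} (the exponent itself is
#' invariant to any common rescaling). References whose expansion window
#' would cross the end of the series are dropped. The minimum-separation
#' floor keeps exactly recurrent points (separations at rounding level)
#' from amplifying floating-point noise into the log-ratio.
#'
#' @param traj a [phase_trajectory()].
#' @param kmin,kmax expansion range in samples, 1 <= kmin <= kmax.
#' @param theiler exclusion window, samples (neighbours with
#'   \code{|i - i*| <= theiler} are inadmissible).
#' @param min_sep minimum admissible initial separation, in standardized
#'   units.
#' @param standardize scale axes to unit variance before distances.
#' @param n_ref optional cap on the number of reference points; when
#'   set, references are taken evenly spaced along the trajectory
#'   (deterministic), keeping the cost linear in \code{n_ref} for long
#'   recordings. Neighbour candidates always span the whole trajectory.
#' @return a \code{lyapunov_series}: \code{lambda_i} (1/s, NA where
#'   skipped), \code{ref_indices}, \code{global_lambda},
#'   \code{n_skipped}, \code{config}.
#' @examples
#' x <- numeric(2000); x[1] <- 0.2
#' for (t in 1:1999) x[t + 1] <- 4 * x[t] * (1 - x[t])
#' lyapunov_exponent(phase_trajectory(matrix(x), dt = 1),
#'                   kmax = 5)$global_lambda  # ~ log(2)
#' @export
lyapunov_exponent <- function(traj, kmin = 1L, kmax = 10L, theiler = 10L,
                              min_sep = 1e-6, standardize = TRUE,
                              n_ref = NULL) {
  stopifnot(inherits(traj, "phase_trajectory"),
            kmin >= 1L, kmin <= kmax, theiler >= 0L)
  coords <- traj$coords
  n <- nrow(coords)
  if (n < kmax + 2L) stop("trajectory shorter than the expansion range")
  if (standardize) {
    s <- apply(coords, 2, stats::sd)
    s[s == 0] <- 1
    coords <- sweep(coords, 2, s, "/")
  }
  nref <- n - kmax
  ks <- kmin:kmax
  idx <- seq_len(nref)
  refs <- if (!is.null(n_ref) && n_ref < nref)
    unique(round(seq(1L, nref, length.out = n_ref)))
  else idx
  lam <- rep(NA_real_, length(refs))
  names(lam) <- NULL
  base <- coords[idx, , drop = FALSE]
  for (r in seq_along(refs)) {
    i <- refs[r]
    diffs <- base - matrix(coords[i, ], nref, ncol(coords), byrow = TRUE)
    d0 <- sqrt(rowSums(diffs^2))
    cand <- which(abs(idx - i) > theiler & d0 > min_sep)
    if (!length(cand)) next
    j <- cand[which.min(d0[cand])]
    dk <- sqrt(rowSums((coords[i + ks, , drop = FALSE] -
                        coords[j + ks, , drop = FALSE])^2))
    dk <- pmax(dk, min_sep)
    lam[r] <- sum(log(dk / d0[j]) / ks) / ((kmax - kmin + 1) * traj$dt)
  }
  if (all(is.na(lam)))
    stop("no reference point has an admissible neighbour")
  structure(list(lambda_i = lam, ref_indices = refs,
                 global_lambda = mean(lam, na.rm = TRUE),
                 n_skipped = sum(is.na(lam)),
                 config = list(kmin = kmin, kmax = kmax, theiler = theiler,
                               min_sep = min_sep,
                               standardize = standardize, dt = traj$dt)),
            class = "lyapunov_series")
}

#' @export
print.lyapunov_series <- function(x, ...) {
  cat(sprintf("<lyapunov_series> global lambda = %.4g /s over %d refs (%d skipped)\n",
              x$global_lambda, length(x$lambda_i) - x$n_skipped,
              x$n_skipped))
  invisible(x)
}

#' Per-spike Lyapunov exponents from peri-spike windows
#'
#' Computes the local-divergence exponent on the (V, dV/dt) trajectory of
#' a window centered on each spike peak, yielding a per-spike series
#' aligned 1:1 with the spikes -- the series fed to
#' [classify_quartiles()] for Markov state-transition analysis of
#' instability. Spikes without a full window are flagged NA and listed in
#' attribute \code{excluded}.
#'
#' Two neighbour pools are available. \code{"within"} searches for each
#' reference's nearest neighbour inside the same window (a sliding-pass
#' estimate of that window's own dynamics). \code{"ensemble"} pools the
#' peri-spike windows of all other spikes as the candidate set: every
#' action potential is one pass through the same phase-space region, so
#' the ensemble supplies the true recurrences a short single pass lacks,
#' and the divergence between a spike and its most similar other spike
#' measures spike-to-spike waveform instability directly.
#'
#' @param trace a [trace_record()].
#' @param spikes a [spike_train()] with \code{peak_indices}.
#' @param window total window length centered on each peak, s
#'   (default 10 ms).
#' @param kmin,kmax,theiler,min_sep passed to [lyapunov_exponent()];
#'   \code{theiler} defaults to 5 for the short windows (within mode
#'   only; ensemble mode excludes the whole own window).
#' @param neighbors \code{"within"} (default) or \code{"ensemble"}.
#' @param max_ref_per_spike reference-point cap per window (ensemble
#'   mode), evenly spaced; keeps the cost linear in the spike count.
#' @return numeric vector of per-spike global exponents (1/s), NA where
#'   excluded; attribute \code{excluded}.
#' @export
lyapunov_per_spike <- function(trace, spikes, window = 1e-2, kmin = 1L,
                               kmax = 10L, theiler = 5L, min_sep = 1e-6,
                               neighbors = c("within", "ensemble"),
                               max_ref_per_spike = 20L) {
  stopifnot(inherits(trace, "trace_record"), inherits(spikes, "spike_train"))
  neighbors <- match.arg(neighbors)
  if (is.null(spikes$peak_indices)) stop("spike train lacks peak_indices")
  half <- round(window / (2 * trace$dt))
  if (2 * half + 1 < kmax + 2) stop("window shorter than the expansion range")
  n <- length(trace$samples)
  out <- rep(NA_real_, length(spikes$times))
  ok <- which(spikes$peak_indices - half >= 1L &
              spikes$peak_indices + half <= n)
  if (neighbors == "within") {
    for (i in ok) {
      p <- spikes$peak_indices[i]
      sub <- trace_record(trace$samples[(p - half):(p + half)], trace$dt,
                          units = trace$units)
      lam <- tryCatch(
        lyapunov_exponent(phase_embed(sub), kmin = kmin, kmax = kmax,
                          theiler = theiler, min_sep = min_sep),
        error = function(e) NULL)
      if (!is.null(lam)) out[i] <- lam$global_lambda
    }
    return(structure(out, excluded = which(is.na(out))))
  }
  out[ok] <- lyap_spike_ensemble(trace, spikes$peak_indices[ok], half,
                                 kmin, kmax, min_sep, max_ref_per_spike)
  structure(out, excluded = which(is.na(out)))
}

# ensemble-neighbour per-spike exponents: references in each window,
# nearest-neighbour candidates in all other windows
lyap_spike_ensemble <- function(trace, peaks, half, kmin, kmax, min_sep,
                                max_ref) {
  w <- 2L * half + 1L
  ns <- length(peaks)
  dv <- finite_diff(trace$samples, trace$dt)
  # coords: (spike, offset) -> row
  rows <- lapply(peaks, function(p) {
    idx <- (p - half):(p + half)
    cbind(trace$samples[idx], dv[idx])
  })
  coords <- do.call(rbind, rows)
  s <- apply(coords, 2, stats::sd)
  s[s == 0] <- 1
  coords <- sweep(coords, 2, s, "/")
  usable <- seq_len(w - kmax)                  # offsets with room to expand
  spike_of <- rep(seq_len(ns), each = w)
  cand_rows <- which((rep(seq_len(w), ns) %in% usable))
  ks <- kmin:kmax
  ref_off <- if (length(usable) > max_ref)
    unique(round(seq(1L, length(usable), length.out = max_ref)))
  else seq_along(usable)
  lam <- rep(NA_real_, ns)
  for (si in seq_len(ns)) {
    cands <- cand_rows[spike_of[cand_rows] != si]
    vals <- numeric(0)
    for (o in usable[ref_off]) {
      ri <- (si - 1L) * w + o
      d0 <- sqrt(rowSums((coords[cands, , drop = FALSE] -
                          matrix(coords[ri, ], length(cands), 2,
                                 byrow = TRUE))^2))
      adm <- which(d0 > min_sep)
      if (!length(adm)) next
      j <- cands[adm[which.min(d0[adm])]]
      dk <- sqrt(rowSums((coords[ri + ks, , drop = FALSE] -
                          coords[j + ks, , drop = FALSE])^2))
      dk <- pmax(dk, min_sep)
      vals <- c(vals, sum(log(dk / d0[adm[which.min(d0[adm])]]) / ks) /
                        ((kmax - kmin + 1) * trace$dt))
    }
    if (length(vals)) lam[si] <- mean(vals)
  }
  lam
}
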