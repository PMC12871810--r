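#' Gamma-renewal spike train with known local variation
#'
#' ISIs are iid gamma with shape \code{shape} and scale
#' \code{1/(shape * rate)}, so the mean ISI is \code{1/rate} and the
#' expected local variation is \code{3/(2*shape + 1)} (1 for Poisson
#' firing, 0 in the regular limit).
#'
#' @param rate mean firing rate, spikes/s (> 0).
#' @param shape gamma ISI shape parameter kappa (> 0).
#' @param n_spikes number of spikes (>= 2).
#' @param seed integer RNG seed.
#' @return a [spike_train()] with \code{times}; attribute \code{isis}.
#' @examples
#' st <- gen_gamma_train(rate = 5, shape = 2, n_spikes = 100, seed = 1)
#' local_variation(diff(st$times))  # ~ 3/(2*2+1)
#' @export
gen_gamma_train <- function(rate, shape, n_spikes, seed) {
  stopifnot(rate > 0, shape > 0, n_spikes >= 2)
  set.seed(as.integer(seed))
  isis <- stats::rgamma(n_spikes - 1L, shape = shape,
                        scale = 1 / (shape * rate))
  spike_train(times = cumsum(c(1 / rate, isis)))
}

#' Simulate a discrete-time Markov chain over states 1..3
#'
#' @param P 3x3 row-stochastic transition matrix.
#' @param n chain length (>= 1).
#' @param seed integer RNG seed.
#' @param init initial distribution; default the stationary distribution
#'   of \code{P}.
#' @return integer vector of states in \{1, 2, 3\}.
#' @export
simulate_markov_states <- function(P, n, seed, init = NULL) {
  P <- as.matrix(P)
  stopifnot(nrow(P) == 3L, ncol(P) == 3L, all(P >= 0),
            max(abs(rowSums(P) - 1)) < 1e-8)
  if (is.null(init)) {
    ev <- eigen(t(P))
    k <- which.min(abs(ev$values - 1))
    init <- abs(Re(ev$vectors[, k])); init <- init / sum(init)
  }
  set.seed(as.integer(seed))
  s <- integer(n)
  s[1] <- sample.int(3L, 1L, prob = init)
  for (t in seq_len(n - 1L))
    s[t + 1L] <- sample.int(3L, 1L, prob = P[s[t], ])
  s
}

# Biphasic spike template: logistic rise whose maximum slope is the
# onset rapidness, then exponential repolarization. Returns offsets
# (samples, peak at 0) and values (mV above baseline).
spike_template <- function(rapidness_V_s, amplitude_mV, dt,
                           decay_tau = 1.5e-3) {
  k <- 4 * rapidness_V_s * 1000 / amplitude_mV  # logistic steepness, 1/s
  t_rise <- 12 / k                              # 0.25% -> 99.75% span
  n_pre <- ceiling(t_rise / dt)
  n_post <- ceiling(5 * decay_tau / dt)
  off <- (-n_pre):n_post
  tt <- off * dt
  v <- ifelse(tt <= 0,
              amplitude_mV / (1 + exp(-k * (tt + t_rise / 2))),
              amplitude_mV * exp(-tt / decay_tau))
  # taper the residual logistic foot so the template starts at 0
  v <- v - v[1] * (1 - seq_along(v) / length(v))
  list(offsets = off, values = v, peak_at = n_pre + 1L)
}

#' Synthetic spiking membrane-potential trace with Markov onset states
#'
#' Emulates an intracellular recording whose per-spike peak onset
#' rapidness (max dV/dt of the rising phase) follows a 3-state Markov
#' chain: each spike draws its state from \code{transition} and its
#' target rapidness from the corresponding class mean (with relative
#' jitter), and its rising phase is a logistic segment whose analytic
#' maximum slope equals that target. Ground truth (spike times, states,
#' rapidness) is returned alongside the trace.
#'
#' @param duration trace length, s.
#' @param dt sampling interval, s (default 1e-4, i.e. 10 kHz).
#' @param rate mean firing rate, spikes/s.
#' @param isi_shape gamma shape of the ISI process (regular-ish default 8).
#' @param min_isi absolute refractory floor added to every ISI, s; the
#'   gamma part is rescaled so the mean rate is preserved. Keeps
#'   irregular (low-shape) trains from overlapping spike templates.
#' @param class_means onset-rapidness class means, V/s, length 3
#'   (class 1 = slowest).
#' @param transition 3x3 row-stochastic state transition matrix.
#' @param rapidness_jitter relative SD of per-spike rapidness around its
#'   class mean.
#' @param amplitude_mV,baseline_mV spike height above baseline and
#'   resting level.
#' @param noise_sd additive membrane-noise SD, mV.
#' @param noise_tau correlation time of the membrane noise, s: 0 (default)
#'   gives white (iid) noise; positive values give Ornstein-Uhlenbeck
#'   noise with that decorrelation time and stationary SD
#'   \code{noise_sd}. Fast channel flicker is emulated by a short
#'   \code{noise_tau}, slow synaptic-like fluctuation by a long one.
#' @param seed integer RNG seed.
#' @return list with \code{trace} (a \code{trace_record}), \code{spikes}
#'   (ground-truth [spike_train()] with true \code{onset_rapidness}), and
#'   \code{states} (ground-truth integer states per spike).
#' @export
gen_membrane_trace <- function(duration, dt = 1e-4, rate = 8,
                               isi_shape = 8, min_isi = 0.012,
                               class_means = c(60, 100, 150),
                               transition = diag(3) * 0.85 + 0.05,
                               rapidness_jitter = 0.02,
                               amplitude_mV = 70, baseline_mV = -60,
                               noise_sd = 0.5, noise_tau = 0, seed = 1) {
  stopifnot(duration > 0, length(class_means) == 3L,
            abs(duration / dt - round(duration / dt)) < 1e-6)
  n <- round(duration / dt)
  set.seed(as.integer(seed))
  # spike times from a gamma renewal process with a refractory floor,
  # truncated to the trace; gamma mean rescaled to preserve the rate
  gmean <- max(1 / rate - min_isi, 1e-3)
  isis <- min_isi + stats::rgamma(ceiling(duration * rate * 2) + 20,
                                  shape = isi_shape,
                                  scale = gmean / isi_shape)
  times <- cumsum(c(0.1, isis))
  margin <- 12 * amplitude_mV / (4 * min(class_means) * 1000) + 7.5e-3
  times <- times[times < duration - margin]
  n_spk <- length(times)
  if (n_spk < 1L) stop("duration too short for any spike")
  tpl_width <- margin
  if (tpl_width > min(diff(c(0, times))))
    stop("spike template wider than the minimum ISI; lower rate or raise rapidness")
  states <- simulate_markov_states(transition, n_spk,
                                   seed = as.integer(seed) + 1L)
  set.seed(as.integer(seed) + 2L)
  rapid <- class_means[states] *
    (1 + rapidness_jitter * stats::rnorm(n_spk))
  v <- rep(baseline_mV, n)
  peak_idx <- integer(n_spk)
  for (i in seq_len(n_spk)) {
    tpl <- spike_template(rapid[i], amplitude_mV, dt)
    p <- round(times[i] / dt) + 1L
    idx <- p + tpl$offsets
    keep <- idx >= 1L & idx <= n
    v[idx[keep]] <- v[idx[keep]] + tpl$values[keep]
    peak_idx[i] <- p
  }
  if (noise_sd > 0) {
    v <- v + if (noise_tau > 0)
      gen_ou(tau = noise_tau, sigma = noise_sd, mu = 0, dt = dt, n = n,
             seed = as.integer(seed) + 3L)$samples
    else stats::rnorm(n, sd = noise_sd)
  }
  list(trace = trace_record(v, dt = dt, units = "mV",
                            channel_id = "synthetic-membrane"),
       spikes = spike_train(times = (peak_idx - 1L) * dt,
                            peak_indices = peak_idx,
                            onset_rapidness = rapid, dt = dt),
       states = states)
}

#' Ornstein-Uhlenbeck process
#'
#' Mean-reverting Gaussian process with time constant \code{tau} and
#' stationary standard deviation \code{sigma}. The default scheme is the
#' exact discrete transition
#' \eqn{X_{t+dt} = \mu + (X_t-\mu)e^{-dt/\tau} + \sigma\sqrt{1-e^{-2dt/\tau}}\,\xi};
#' \code{"euler"} is the fixed-step Euler-Maruyama update, matching a
#' fixed-step simulator.
#'
#' @param tau mean-reversion time constant, s (> 0).
#' @param sigma stationary SD, signal units (>= 0).
#' @param mu process mean.
#' @param dt sampling interval, s.
#' @param n number of samples (>= 2).
#' @param seed integer RNG seed.
#' @param scheme \code{"exact"} or \code{"euler"}.
#' @param x0 initial value; default a stationary draw (exact) so the
#'   series is stationary from the first sample.
#' @param units trace units label.
#' @return a \code{trace_record}.
#' @examples
#' ou <- gen_ou(tau = 0.05, sigma = 1, mu = 0, dt = 1e-3, n = 5000, seed = 1)
#' @export
gen_ou <- function(tau, sigma, mu = 0, dt = 1e-3, n = 1000, seed = 1,
                   scheme = c("exact", "euler"), x0 = NULL, units = "uV") {
  scheme <- match.arg(scheme)
  stopifnot(tau > 0, sigma >= 0, n >= 2)
  set.seed(as.integer(seed))
  x <- numeric(n)
  if (is.null(x0)) x0 <- mu + sigma * stats::rnorm(1)
  x[1] <- x0
  if (sigma == 0) {
    a <- if (scheme == "exact") exp(-dt / tau) else 1 - dt / tau
    for (t in 2:n) x[t] <- mu + (x[t - 1] - mu) * a
  } else if (scheme == "exact") {
    a <- exp(-dt / tau)
    b <- sigma * sqrt(1 - a^2)
    e <- stats::rnorm(n - 1)
    for (t in 2:n) x[t] <- mu + (x[t - 1] - mu) * a + b * e[t - 1]
  } else {
    # Euler-Maruyama with diffusion chosen so the stationary SD is sigma
    b <- sigma * sqrt(2 * dt / tau)
    e <- stats::rnorm(n - 1)
    for (t in 2:n) x[t] <- x[t - 1] + (mu - x[t - 1]) * dt / tau +
        b * e[t - 1]
  }
  trace_record(x, dt = dt, units = units, channel_id = "synthetic-ou")
}

#' Gaussian random walk (unit-root positive control)
#'
#' Cumulative sum of iid Gaussian steps; contains a unit root by
#' construction, so an ADF test should fail to reject non-stationarity.
#'
#' @param n number of samples (>= 10).
#' @param step_sd SD of the iid increments.
#' @param seed integer RNG seed.
#' @param dt sampling interval, s.
#' @param units trace units label.
#' @return a \code{trace_record}.
#' @export
gen_random_walk <- function(n, step_sd = 1, seed = 1, dt = 1e-3,
                            units = "uV") {
  stopifnot(n >= 10)
  set.seed(as.integer(seed))
  steps <- if (step_sd == 0) rep(0, n) else stats::rnorm(n, sd = step_sd)
  trace_record(cumsum(steps), dt = dt, units = units,
               channel_id = "synthetic-walk")
}

#' Steady-state inactivation sweep set with injected trace noise
#'
#' Emulates a voltage-clamp steady-state inactivation protocol: for each
#' conditioning prepulse voltage V the test-pulse current is a common
#' kinetic waveform scaled by the Boltzmann availability
#' \eqn{1/(1+\exp((V-V_{1/2})/k))}, and each repeat adds iid Gaussian
#' trace noise. Inward currents are negative.
#'
#' @param voltages prepulse voltages, mV, strictly increasing
#'   (default -100..-20 in 10 mV steps).
#' @param v_half half-inactivation voltage, mV.
#' @param slope Boltzmann slope factor k, mV (> 0).
#' @param peak_pA test-pulse peak current at full availability, pA
#'   (negative = inward).
#' @param tau_act,tau_decay activation and decay time constants, s.
#' @param n_repeats repeats per voltage (>= 2).
#' @param noise_sd trace noise SD, pA; scalar or one value per voltage
#'   (heteroscedastic disease-like presets).
#' @param dt sampling interval, s (default 5e-5, i.e. 20 kHz).
#' @param baseline_s,pulse_s pre-pulse baseline and test-pulse durations, s.
#' @param seed integer RNG seed.
#' @return a \code{sweep_set}: \code{currents} (voltage x repeat x time
#'   array, pA), \code{voltages}, \code{dt}, \code{test_window} (sample
#'   range of the test pulse), plus the ground-truth parameters as
#'   attribute \code{truth}.
#' @export
gen_inactivation_sweeps <- function(voltages = seq(-100, -20, by = 10),
                                    v_half = -50, slope = 5,
                                    peak_pA = -500,
                                    tau_act = 0.5e-3, tau_decay = 2e-3,
                                    n_repeats = 10, noise_sd = 5,
                                    dt = 5e-5, baseline_s = 2.5e-3,
                                    pulse_s = 2e-2, seed = 1) {
  stopifnot(all(diff(voltages) > 0), n_repeats >= 2, slope > 0)
  noise_sd <- rep_len(noise_sd, length(voltages))
  n_base <- round(baseline_s / dt)
  n_pulse <- round(pulse_s / dt)
  nt <- n_base + n_pulse
  tp <- (seq_len(n_pulse) - 1) * dt
  g <- (1 - exp(-tp / tau_act)) * exp(-tp / tau_decay)
  g <- g / max(g)
  avail <- 1 / (1 + exp((voltages - v_half) / slope))
  set.seed(as.integer(seed))
  cur <- array(0, dim = c(length(voltages), n_repeats, nt))
  for (vi in seq_along(voltages)) {
    mean_wave <- c(rep(0, n_base), peak_pA * avail[vi] * g)
    for (r in seq_len(n_repeats)) {
      noise <- if (noise_sd[vi] > 0) stats::rnorm(nt, sd = noise_sd[vi]) else 0
      cur[vi, r, ] <- mean_wave + noise
    }
  }
  structure(list(currents = cur, voltages = voltages, dt = dt,
                 test_window = c(n_base + 1L, nt)),
            class = "sweep_set",
            truth = list(v_half = v_half, slope = slope, peak_pA = peak_pA,
                         noise_sd = noise_sd, availability = avail))
}

#' @export
print.sweep_set <- function(x, ...) {
  d <- dim(x$currents)
  cat(sprintf("<sweep_set> %d voltages (%g..%g mV) x %d repeats x %d samples @ %g kHz\n",
              d[1], min(x$voltages), max(x$voltages), d[2], d[3],
              1e-3 / x$dt))
  invisible(x)
}
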