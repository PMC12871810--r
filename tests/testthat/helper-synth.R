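# shared fixtures built in code

# trace with three triangular spikes at known peak samples
make_three_spike_trace <- function(dt = 1e-4, baseline = -60, peak = 10) {
  n <- 3000
  v <- rep(baseline, n)
  peaks <- c(500L, 1500L, 2500L)
  for (p in peaks) {
    up <- seq(baseline, peak, length.out = 21)
    dn <- seq(peak, baseline, length.out = 31)[-1]
    v[(p - 20):(p + 30)] <- c(up, dn)
  }
  list(trace = trace_record(v, dt), peaks = peaks)
}

# naive double-loop reference implementation of the divergence exponent
naive_lyapunov <- function(coords, dt, kmin = 1L, kmax = 10L,
                           theiler = 10L, min_sep = 1e-6,
                           standardize = TRUE) {
  coords <- as.matrix(coords)
  if (standardize) {
    s <- apply(coords, 2, sd); s[s == 0] <- 1
    coords <- sweep(coords, 2, s, "/")
  }
  n <- nrow(coords)
  nref <- n - kmax
  lam <- rep(NA_real_, nref)
  for (i in seq_len(nref)) {
    best <- NA; bestd <- Inf
    for (j in seq_len(nref)) {
      if (abs(i - j) <= theiler) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d > min_sep && d < bestd) { bestd <- d; best <- j }
    }
    if (is.na(best)) next
    acc <- 0
    for (K in kmin:kmax) {
      dk <- sqrt(sum((coords[i + K, ] - coords[best + K, ])^2))
      acc <- acc + log(max(dk, min_sep) / bestd) / K
    }
    lam[i] <- acc / ((kmax - kmin + 1) * dt)
  }
  list(lambda_i = lam, global_lambda = mean(lam, na.rm = TRUE))
}

# two parallel orbits whose separation grows exactly as d0 * exp(g*K*dt)
exp_pair_trajectory <- function(m = 60, g = 1, dt = 0.01, eps = 1e-3) {
  t1 <- cbind(x = 0:m, y = rep(0, m + 1))
  t2 <- cbind(x = 0:m, y = eps * exp(g * (0:m) * dt))
  phase_trajectory(rbind(t1, t2), dt = dt)
}

logistic_map <- function(n, x0 = 0.2, r = 4) {
  x <- numeric(n); x[1] <- x0
  for (t in seq_len(n - 1)) x[t + 1] <- r * x[t] * (1 - x[t])
  x
}
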