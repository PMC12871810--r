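test_that("phase embedding produces (V, dV/dt) coordinates", {
  # linear ramp: derivative constant, one-sided at the edges
  tr <- trace_record(c(0, 1, 2, 3), dt = 1)
  pt <- phase_embed(tr)
  expect_equal(unname(pt$coords[, 2]), c(1, 1, 1, 1))

  # sine: standardized trajectory is a circle
  tt <- seq(0, 1, by = 1e-3)
  tr <- trace_record(30 * sin(2 * pi * 5 * tt), dt = 1e-3)
  pt <- phase_embed(tr, standardize = TRUE)
  radii <- sqrt(rowSums(pt$coords^2))
  inner <- radii[10:(length(radii) - 10)]  # edge derivatives are one-sided
  expect_lt(max(inner) / min(inner), 1.02)

  # constant trace: all phase points identical; estimator refuses
  flat <- trace_record(rep(-60, 100), dt = 1e-3)
  expect_error(lyapunov_exponent(phase_embed(flat)), "admissible")

  expect_error(phase_embed(trace_record(c(1, Inf, 3), 1)), "non-finite")
})

test_that("logistic map exponent is near log(2) and sine is neutral", {
  x <- logistic_map(5000)
  lam <- lyapunov_exponent(phase_trajectory(matrix(x), dt = 1),
                           kmin = 1, kmax = 5)
  expect_gt(lam$global_lambda, 0.55)
  expect_lt(lam$global_lambda, 0.80)

  f <- 5; dt <- 1e-3
  tr <- trace_record(30 * sin(2 * pi * f * (0:4999) * dt), dt = dt)
  lam_sine <- lyapunov_exponent(phase_embed(tr))
  expect_lt(abs(lam_sine$global_lambda), 0.05 * 2 * pi * f)
  # the two regimes are separated
  expect_gt(lam$global_lambda, 0.4)
})

test_that("a constructed exponentially separating pair returns the rate", {
  g <- 1.5
  traj <- exp_pair_trajectory(m = 60, g = g, dt = 0.01, eps = 1e-3)
  lam <- lyapunov_exponent(traj, kmin = 1, kmax = 10, theiler = 5,
                           standardize = FALSE)
  # interior references of the first orbit recover g exactly
  interior <- lam$lambda_i[5:40]
  expect_equal(interior, rep(g, length(interior)), tolerance = 1e-10)
})

test_that("the exponent is invariant to uniform trajectory rescaling", {
  x <- logistic_map(800)
  t1 <- phase_trajectory(cbind(x[-length(x)], x[-1]), dt = 1)
  t2 <- phase_trajectory(cbind(x[-length(x)], x[-1]) * 37.5, dt = 1)
  l1 <- lyapunov_exponent(t1, kmax = 5)
  l2 <- lyapunov_exponent(t2, kmax = 5)
  expect_equal(l1$global_lambda, l2$global_lambda, tolerance = 1e-12)
})

test_that("vectorized implementation equals the naive double-loop oracle", {
  set.seed(51)
  for (case in 1:3) {
    coords <- switch(case,
      matrix(logistic_map(300, x0 = 0.31)),
      cbind(rnorm(200), rnorm(200)),
      cbind(sin(seq(0, 20, length.out = 250)),
            cos(seq(0, 20, length.out = 250))))
    fast <- lyapunov_exponent(phase_trajectory(coords, dt = 0.1),
                              kmin = 2, kmax = 7, theiler = 4)
    slow <- naive_lyapunov(coords, dt = 0.1, kmin = 2, kmax = 7,
                           theiler = 4)
    expect_equal(fast$lambda_i, slow$lambda_i, tolerance = 1e-12)
    expect_equal(fast$global_lambda, slow$global_lambda,
                 tolerance = 1e-12)
  }
})

test_that("reference subsampling approximates the full estimate", {
  x <- logistic_map(3000)
  traj <- phase_trajectory(matrix(x), dt = 1)
  full <- lyapunov_exponent(traj, kmax = 5)
  sub <- lyapunov_exponent(traj, kmax = 5, n_ref = 400)
  expect_length(sub$lambda_i, 400)
  expect_equal(sub$global_lambda, full$global_lambda, tolerance = 0.1)
})

test_that("per-spike exponents align with spikes and flag short windows", {
  syn <- gen_membrane_trace(duration = 6, noise_sd = 0.3, seed = 13)
  st <- detect_spikes(syn$trace, threshold = -20)
  lam <- lyapunov_per_spike(syn$trace, st, window = 8e-3)
  expect_length(lam, length(st$times))
  ok <- !is.na(lam)
  expect_gt(sum(ok), length(st$times) - 3)
  # stereotyped spikes at similar ISIs give a tight exponent series
  expect_lt(sd(lam[ok]) / abs(mean(lam[ok])), 0.5)

  # ensemble mode returns values on the same alignment
  lam2 <- lyapunov_per_spike(syn$trace, st, window = 8e-3,
                             neighbors = "ensemble")
  expect_length(lam2, length(st$times))
  expect_gt(sum(!is.na(lam2)), length(st$times) - 3)

  # a single spike yields a length-1 series the Markov stage rejects
  one <- spike_train(st$times[1], st$peak_indices[1], dt = st$dt)
  lam1 <- lyapunov_per_spike(syn$trace, one, window = 8e-3)
  expect_length(lam1, 1)
  expect_error(classify_quartiles(lam1), "at least 4")
})

test_that("two-population windows give a bimodal exponent series", {
  # windows alternating between smooth and rough fluctuation
  set.seed(52)
  dt <- 2e-4
  n_win <- 40; w <- 50
  v <- numeric(n_win * w)
  truth <- rep(c(1L, 2L), n_win / 2)
  for (i in seq_len(n_win)) {
    idx <- ((i - 1) * w + 1):(i * w)
    base <- sin(seq(0, 4 * pi, length.out = w)) * 5
    v[idx] <- if (truth[i] == 1) base else base + rnorm(w, sd = 2)
  }
  tr <- trace_record(v - 60, dt)
  peaks <- as.integer((seq_len(n_win) - 1) * w + w / 2)
  st <- spike_train((peaks - 1) * dt, peaks, dt = dt)
  lam <- lyapunov_per_spike(tr, st, window = 40 * dt, theiler = 2)
  ok <- !is.na(lam)
  # rough windows carry systematically higher divergence
  expect_gt(median(lam[ok & truth == 2]), median(lam[ok & truth == 1]))
})
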