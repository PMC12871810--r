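test_that("detect_spikes handles flat, clean, and boundary traces", {
  flat <- trace_record(rep(-60, 1000), dt = 1e-4)
  expect_length(detect_spikes(flat, threshold = -20)$times, 0)

  fix <- make_three_spike_trace()
  st <- detect_spikes(fix$trace, threshold = -20)
  expect_identical(st$peak_indices, fix$peaks)
  expect_equal(st$times, (fix$peaks - 1) * 1e-4)

  # touching the threshold exactly does not trigger (strict >)
  v <- rep(-60, 100); v[50] <- -20
  expect_length(detect_spikes(trace_record(v, 1e-4), -20)$times, 0)
  v[50] <- -19.999
  expect_length(detect_spikes(trace_record(v, 1e-4), -20)$times, 1)

  expect_error(detect_spikes(trace_record(c(1, NA, 3), 1e-4), 0),
               "non-finite")
})

test_that("refractory suppression and negative polarity work", {
  v <- rep(-60, 400)
  v[c(100, 110)] <- 0           # two crossings 1 ms apart
  tr <- trace_record(v, 1e-4)
  expect_length(detect_spikes(tr, -20, refractory = 2e-3)$times, 1)
  expect_length(detect_spikes(tr, -20, refractory = 0.5e-3)$times, 2)

  v2 <- rep(0, 300); v2[150] <- -80
  st <- detect_spikes(trace_record(v2, 1e-4), threshold = -40,
                      polarity = "negative")
  expect_identical(st$peak_indices, 150L)
})

test_that("detection on synthetic traces is near-perfect at high SNR", {
  # SNR 10 (70 mV spikes, 7 mV band-limited membrane noise, 1 ms
  # correlation time emulating the recording low-pass); a detection
  # within 2 ms (the refractory scale) of a true peak is the same event
  syn <- gen_membrane_trace(duration = 20, noise_sd = 7,
                            noise_tau = 1e-3, seed = 8)
  st <- detect_spikes(syn$trace, threshold = -20)
  truth <- syn$spikes$peak_indices
  w <- round(2e-3 / syn$trace$dt)
  hits <- sum(vapply(truth, function(p)
    any(abs(st$peak_indices - p) <= w), logical(1)))
  expect_gte(hits / length(truth), 0.99)
  false_pos <- sum(vapply(st$peak_indices, function(p)
    all(abs(truth - p) > w), logical(1)))
  expect_identical(false_pos, 0L)
})

test_that("onset rapidness matches analytic derivatives", {
  dt <- 1e-4
  # linear ramp of 20 V/s into a peak: exact under central differences
  ramp <- seq(-60, -60 + 20 * 1000 * 0.005, length.out = 51)  # 5 ms
  v <- c(rep(-60, 50), ramp, seq(ramp[51], -60, length.out = 30))
  tr <- trace_record(v, dt)
  st <- spike_train(times = (100 - 1) * dt, peak_indices = 101L, dt = dt)
  expect_equal(onset_rapidness(tr, st, window = 2e-3)[1], 20,
               tolerance = 1e-10)

  # sine rising segment: max dV/dt = 2*pi*f*A
  f <- 100; A <- 30
  tt <- seq(0, 1 / f / 4, by = dt)       # quarter period up to the peak
  v <- A * sin(2 * pi * f * tt)
  tr <- trace_record(c(rep(0, 40), v), dt)
  st <- spike_train(times = (40 + length(tt) - 1) * dt,
                    peak_indices = 40L + length(tt), dt = dt)
  got <- onset_rapidness(tr, st, window = 2.5e-3)[1]
  expect_equal(got * 1000, 2 * pi * f * A, tolerance = 0.01)

  # 5-sample hand case: central-difference max = 250 V/s at 4th sample
  v <- c(rep(-60, 30), -60, -55, -40, -10, 10, 5, 0, -20, -40, -60)
  tr <- trace_record(v, dt)
  st <- spike_train(times = 34 * dt, peak_indices = 35L, dt = dt)
  expect_equal(onset_rapidness(tr, st, window = 1e-3)[1],
               (10 - (-40)) / (2 * dt) / 1000)

  # spike too close to the start is flagged and excluded
  st2 <- spike_train(times = c(2 * dt, 34 * dt),
                     peak_indices = c(3L, 35L), dt = dt)
  r <- onset_rapidness(tr, st2, window = 1e-3)
  expect_true(is.na(r[1]))
  expect_identical(attr(r, "excluded"), 1L)
})

test_that("local variation: hand cases and analytic calibration", {
  expect_identical(local_variation(rep(0.25, 50)), 0)
  expect_equal(local_variation(rep(c(1, 2), 10)), 1 / 3)

  set.seed(31)
  expect_equal(local_variation(rexp(1e4)), 1, tolerance = 0.03)

  # invariance to uniform time rescaling
  set.seed(32)
  isis <- rgamma(500, 2, 2)
  expect_identical(local_variation(isis), local_variation(isis * 17.3))

  expect_error(local_variation(0.5), "at least 2")
  expect_error(local_variation(c(0.1, 0, 0.2)), "positive")
})

test_that("Lv calibration on gamma-renewal trains (3/(2k+1))", {
  for (k in c(1, 2, 4)) {
    st <- gen_gamma_train(rate = 5, shape = k, n_spikes = 1e4, seed = k)
    expect_equal(local_variation(diff(st$times)), 3 / (2 * k + 1),
                 tolerance = 0.03)
  }
})

test_that("spike_stats computes rates, frequencies and histograms", {
  times <- seq(0.25, by = 0.5, length.out = 10)
  ss <- spike_stats(times, duration = 5)
  expect_equal(ss$mean_rate, 2)

  ss <- spike_stats(c(0, 0.1, 0.3), duration = 1)
  expect_equal(ss$inst_freq, c(10, 5))

  st <- gen_gamma_train(rate = 5, shape = 2, n_spikes = 2000, seed = 9)
  ss <- spike_stats(st, duration = max(st$times), n_bins = 40)
  expect_equal(sum(ss$isi_histogram$prob), 1)
  # histogram mode near the gamma density mode (k-1)/(k*rate) = 0.1
  mids <- head(ss$isi_histogram$breaks, -1) +
    diff(ss$isi_histogram$breaks) / 2
  expect_lt(abs(mids[which.max(ss$isi_histogram$prob)] - 0.1), 0.05)

  # single spike: rate defined, ISI fields empty
  ss <- spike_stats(0.5, duration = 2)
  expect_equal(ss$mean_rate, 0.5)
  expect_length(ss$isis, 0)
  expect_true(is.na(ss$lv))
})
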