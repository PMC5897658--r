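test_that("the Bessel low-pass has unit DC gain and the expected rise time", {
  fs <- 1e5; fc <- 2000
  dc <- channelkit:::bessel_lowpass(rep(1, 3000), fc, fs, 8)
  expect_equal(dc[length(dc)], 1, tolerance = 1e-6)
  step <- c(rep(0, 500), rep(1, 3000))
  for (ord in c(4, 8)) {
    y <- channelkit:::bessel_lowpass(step, fc, fs, ord)
    rise <- (which(y >= 0.9)[1] - which(y >= 0.1)[1]) / fs
    expect_equal(rise, 0.3321 / fc, tolerance = 0.10)
  }
  tr <- current_trace(seq_len(1000) / fs, rep(2.5, 1000))
  expect_equal(filter_trace(tr, fc)$current[900], 2.5, tolerance = 1e-6)
  expect_error(filter_trace(tr, fs), "Nyquist")
})

test_that("half-threshold idealization recovers square openings exactly", {
  fs <- 25000
  t <- seq(0, 0.1 - 1 / fs, by = 1 / fs)
  i <- rep(0, length(t))
  openings <- list(c(0.010, 0.001), c(0.030, 0.002), c(0.060, 0.005))
  for (op in openings) {
    i[t >= op[1] & t < op[1] + op[2]] <- -4.5
  }
  tr <- current_trace(t, i)
  ev <- idealize_half_threshold(tr, baseline = 0, open_level = -4.5)
  op_ev <- ev[ev$state == "open", ]
  expect_equal(nrow(op_ev), 3L)
  expect_equal(op_ev$duration, c(0.001, 0.002, 0.005), tolerance = 1e-9)
  expect_equal(op_ev$mean_amp, rep(-4.5, 3))
})

test_that("openings briefer than the dead time are censored", {
  fs <- 25000
  t <- seq(0, 0.05 - 1 / fs, by = 1 / fs)
  i <- rep(0, length(t))
  i[t >= 0.010 & t < 0.0103] <- -4.5   # 0.3 ms < 446 us
  i[t >= 0.030 & t < 0.031] <- -4.5    # 1 ms, survives
  tr <- current_trace(t, i)
  ev <- idealize_half_threshold(tr, baseline = 0, open_level = -4.5)
  op_ev <- ev[ev$state == "open", ]
  expect_equal(nrow(op_ev), 1L)
  expect_equal(op_ev$duration, 0.001, tolerance = 1e-9)
  expect_true(all(op_ev$duration >= 446e-6))
})

test_that("idealization matches generator ground truth after censoring both", {
  tr <- generate_single_channel_trace(amp = -4.5, duration = 20,
                                      noise = noise_spec(0, seed = 13))
  ev <- idealize_half_threshold(tr, baseline = 0, open_level = -4.5)
  truth <- censor_events(attr(tr, "truth_events"))
  expect_equal(ev$state, truth$state)
  expect_equal(ev$duration, truth$duration, tolerance = 1e-12)
})

test_that("censoring removes open time but never creates it", {
  set.seed(99)
  for (rep in 1:5) {
    tr <- generate_single_channel_trace(duration = 5,
                                        mean_open = 1e-3,
                                        noise = noise_spec(0, seed = rep))
    raw <- attr(tr, "truth_events")
    cen <- censor_events(raw)
    open_raw <- sum(raw$duration[raw$state == "open"])
    open_cen <- sum(cen$duration[cen$state == "open"])
    expect_lte(open_cen, open_raw + 1e-12)
    expect_equal(sum(cen$duration), sum(raw$duration), tolerance = 1e-12)
  }
})

test_that("amplitude analysis recovers the open-channel current within 0.1 pA", {
  for (amp in c(-4.5, -2.4)) {
    tr <- generate_single_channel_trace(amp = amp, duration = 30,
                                        filter_fc = 2000,
                                        noise = noise_spec(0.5, seed = 17))
    ev <- idealize_half_threshold(tr, baseline = 0, open_level = amp)
    f <- fit_amplitude_histogram(tr, ev)
    expect_lt(abs(f$mean_amp - amp), 0.1)
    expect_gt(f$sd, 0)
  }
  # noiseless record: sd degenerates to 0 with a flag
  trc <- generate_single_channel_trace(duration = 5, noise = noise_spec(0, seed = 3))
  evc <- idealize_half_threshold(trc, baseline = 0, open_level = -4.5)
  fc <- fit_amplitude_histogram(trc, evc)
  expect_identical(fc$sd, 0)
  expect_true(fc$degenerate)
})

test_that("level auto-estimation finds the two amplitude modes", {
  tr <- generate_single_channel_trace(amp = -4.5, duration = 20,
                                      filter_fc = 2000,
                                      noise = noise_spec(0.4, seed = 23))
  ev <- idealize_half_threshold(tr)
  expect_equal(attr(ev, "baseline"), 0, tolerance = 0.1)
  expect_equal(attr(ev, "open_level"), -4.5, tolerance = 0.15)
})

test_that("time-averaged open probability behaves as a renewal process", {
  fs <- 25000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  i <- rep(0, length(t)); i[t < 0.1] <- -5
  ev <- idealize_half_threshold(current_trace(t, i), baseline = 0, open_level = -5)
  expect_equal(single_channel_po(ev), 10, tolerance = 1e-3)
  # amplitude scaling leaves P_o untouched
  ev2 <- idealize_half_threshold(current_trace(t, 3 * i), baseline = 0, open_level = -15)
  expect_equal(single_channel_po(ev2), single_channel_po(ev))
  # stochastic record: 5/45 ms dwells over 60 s gives ~10%
  tr <- generate_single_channel_trace(duration = 60, noise = noise_spec(0, seed = 31))
  evs <- idealize_half_threshold(tr, baseline = 0, open_level = -4.5)
  expect_equal(single_channel_po(evs), 10, tolerance = 0.12)
  expect_error(single_channel_po(evs, n_channels = 0), ">= 1")
})

test_that("flat traces yield zero open events and amplitude fits fail cleanly", {
  t <- seq_len(5000) / 25000
  flat <- current_trace(t, rnorm(5000, 0, 0.2))
  ev <- idealize_half_threshold(flat)
  expect_equal(sum(ev$state == "open"), 0L)
  expect_equal(single_channel_po(ev), 0)
  expect_error(fit_amplitude_histogram(flat, ev), "no open events")
  expect_error(idealize_half_threshold(flat, baseline = 1, open_level = 1),
               "differ")
})
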