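test_that("generators are pure functions of their seed", {
  prot <- mk_protocol(2, 3)
  a <- generate_whole_cell_trace(wt_rates(), prot, noise = noise_spec(5, seed = 9))
  b <- generate_whole_cell_trace(wt_rates(), prot, noise = noise_spec(5, seed = 9))
  expect_identical(a$current, b$current)
  sc_a <- generate_single_channel_trace(duration = 2, noise = noise_spec(0.5, seed = 4))
  sc_b <- generate_single_channel_trace(duration = 2, noise = noise_spec(0.5, seed = 4))
  expect_identical(sc_a$current, sc_b$current)
  expect_identical(attr(sc_a, "truth_events"), attr(sc_b, "truth_events"))
})

test_that("non-desensitizing whole-cell traces rise monotonically to plateau", {
  rts <- rate_set(0, 0, 25, 5000)
  tr <- generate_whole_cell_trace(rts, glut_protocol(2, exchange_tau = 0.012))
  i_s <- tr$current
  # inward current: monotone decrease (increase in magnitude) to plateau
  expect_true(all(diff(i_s[tr$time < 0.2]) <= 1e-9))
  plateau <- i_s[tr$time > 1.5]
  expect_lt(diff(range(plateau)), 1e-3 * max(abs(i_s)))
  truth <- ground_truth(tr)
  expect_equal(truth$rates$k_o, 25)
})

test_that("desensitization analysis closes the loop on a generated trace", {
  tr <- generate_whole_cell_trace(fast_gating_rates(0.17, 0.69), glut_protocol(10))
  d <- analyze_desensitization(tr)
  expect_equal(d$D, 0.17 / (0.17 + 0.69), tolerance = 0.02)
})

test_that("synaptic generator honors component weights and linearity", {
  # two equal components: tau_w is the plain mean
  tr <- generate_synaptic_trace(50, data.frame(A = c(1, 1), tau = c(0.1, 0.5)),
                                noise = noise_spec(0))
  f <- fit_deactivation(tr, 2)
  expect_equal(f$tau_report, 0.3, tolerance = 1e-3)
  # doubling the amplitude doubles the fitted peak, tau unchanged
  tr1 <- generate_synaptic_trace(20, data.frame(A = 1, tau = 0.307))
  tr2 <- generate_synaptic_trace(40, data.frame(A = 1, tau = 0.307))
  f1 <- fit_deactivation(tr1, 1); f2 <- fit_deactivation(tr2, 1)
  expect_equal(f2$peak / f1$peak, 2, tolerance = 1e-6)
  expect_equal(f2$tau_report, f1$tau_report, tolerance = 1e-9)
})

test_that("single-channel dwell process has the right open fraction", {
  tr <- generate_single_channel_trace(amp = -4.5, mean_open = 5e-3,
                                      mean_closed = 45e-3, duration = 120,
                                      noise = noise_spec(0, seed = 21))
  dw <- attr(tr, "truth_dwells")
  expect_true(all(dw$duration > 0))
  open_frac <- sum(dw$duration[dw$state == "open"]) / sum(dw$duration)
  expect_equal(open_frac, 0.10, tolerance = 0.015)
  expect_false(attr(tr, "short_record"))
  expect_true(attr(generate_single_channel_trace(duration = 0.05,
                                                 noise = noise_spec(0, seed = 1)),
                   "short_record"))
})

test_that("I-V generator is linear without Mg and zero at V_rev", {
  wt <- woodhull_fit(1, -3, 5.9, 0.45)
  v <- seq(-100, 60, by = 20)
  iv0 <- generate_iv_dataset(wt, v, mg = 0, noise_rel = 0)
  expect_equal(iv0$no_mg$i, iv0$mg$i, tolerance = 1e-12)
  iv <- generate_iv_dataset(wt, c(v, -3), mg = 1, noise_rel = 0)
  expect_equal(iv$no_mg$i[iv$no_mg$v_mV == -3], 0)
  expect_equal(iv$mg$i[iv$mg$v_mV == -3], 0)
})

test_that("dose-response generator matches the Hill forward model", {
  truth <- hill_fit(1.6, 1.4)
  dr <- generate_dose_response(truth, c(0.4, 1.6, 6.4), noise_rel = 0)
  expect_equal(dr$response[2], 0.5)              # half-maximal at EC50
  expect_true(all(diff(dr$response) > 0))        # monotone without noise
  pot <- hill_fit(9.5, 1.5, I_max = 570, mode = "potentiation")
  expect_equal(hill_response(9.5, pot), 285)
})
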