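test_that("single-exponential deactivation is recovered within 1%", {
  tr <- generate_synaptic_trace(20, data.frame(A = 1, tau = 0.307))
  f <- fit_deactivation(tr)
  expect_equal(f$n_components, 1L)
  expect_equal(f$tau_report, 0.307, tolerance = 0.01)
})

test_that("double-exponential decays are recovered and ordered", {
  tr <- generate_synaptic_trace(100, data.frame(A = c(1, 1), tau = c(0.2, 0.8)))
  f <- fit_deactivation(tr, 2)
  expect_equal(f$tau1, 0.2, tolerance = 1e-3)
  expect_equal(f$tau2, 0.8, tolerance = 1e-3)
  expect_lte(f$tau1, f$tau2)
  expect_equal(f$tau_report, 0.5, tolerance = 1e-3)
  # tau_w collapses to the single tau as one amplitude vanishes
  tr1 <- generate_synaptic_trace(100, data.frame(A = c(1, 1e-7), tau = c(0.3, 0.9)))
  f1 <- fit_deactivation(tr1, 2)
  expect_equal(f1$tau_report, 0.3, tolerance = 1e-3)
})

test_that("auto mode selects components by the extra-sum-of-squares test", {
  one <- generate_synaptic_trace(50, data.frame(A = 1, tau = 0.3),
                                 noise = noise_spec(0.5, seed = 2))
  expect_equal(fit_deactivation(one, "auto")$n_components, 1L)
  two <- generate_synaptic_trace(50, data.frame(A = c(1, 1), tau = c(0.05, 0.6)),
                                 noise = noise_spec(0.5, seed = 2))
  expect_equal(fit_deactivation(two, "auto")$n_components, 2L)
})

test_that("potentiation, deceleration, and charge transfer follow the printed summaries", {
  expect_equal(potentiation_percent(-37, -20), 85)
  expect_equal(potentiation_percent(-20, -20), 0)
  expect_equal(potentiation_percent(-40, -20), 100)
  expect_equal(deceleration(0.499, 0.307), 1.63, tolerance = 0.005)
  expect_equal(deceleration(0.507, 0.323), 1.57, tolerance = 0.005)
  expect_equal(deceleration(0.3, 0.3), 1)
  expect_equal(charge_transfer_factor(140.8, 1.57), 3.79, tolerance = 0.01)
  expect_equal(charge_transfer_factor(98.7, 1.63), 3.26, tolerance = 0.01)
  expect_equal(charge_transfer_factor(0, 1), 1)
  expect_error(potentiation_percent(-10, 0), "non-zero")
  expect_error(deceleration(-1, 1), "> 0")
})

test_that("charge-transfer factor matches the integrated-area oracle", {
  ctl <- generate_synaptic_trace(20, data.frame(A = 1, tau = 0.307),
                                 duration = 4)
  ster <- generate_synaptic_trace(39.74, data.frame(A = 1, tau = 0.499),
                                  duration = 4)
  s <- synaptic_summary(ctl, ster)
  # oracle: trapezoidal areas of the two model decays
  area <- function(tr) {
    f <- fit_deactivation(tr, 1)
    abs(f$A1) * f$tau1
  }
  expect_equal(s$charge_transfer, area(ster) / area(ctl), tolerance = 0.02)
})

test_that("summary quantities are invariant to a shared amplitude scale", {
  ctl <- generate_synaptic_trace(20, data.frame(A = 1, tau = 0.307))
  ster <- generate_synaptic_trace(35, data.frame(A = 1, tau = 0.499))
  s1 <- synaptic_summary(ctl, ster)
  scale_trace <- function(tr, k) { tr$current <- tr$current * k; tr }
  s2 <- synaptic_summary(scale_trace(ctl, 3.7), scale_trace(ster, 3.7))
  expect_equal(s2$potentiation, s1$potentiation, tolerance = 1e-9)
  expect_equal(s2$deceleration, s1$deceleration, tolerance = 1e-9)
  expect_equal(s2$charge_transfer, s1$charge_transfer, tolerance = 1e-9)
})

test_that("degenerate synaptic traces are rejected or flagged", {
  t <- seq(0, 2, by = 1e-4)
  prot <- application_protocol(protocol_epoch(0, 0.005, glutamate = 1000),
                               exchange_tau = 1e-3)
  flat <- current_trace(t, rep(-50, length(t)), protocol = prot)
  expect_error(fit_deactivation(flat), "does not decay")
  # truncated decay: < 3 tau of record
  short <- generate_synaptic_trace(50, data.frame(A = 1, tau = 0.5),
                                   duration = 0.8)
  expect_warning(fit_deactivation(short, 1), "3 time constants")
})
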