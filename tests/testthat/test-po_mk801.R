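# Unit tests run at 2 kHz sampling with shorter epochs than a full
# experiment; the estimator is linear in the sample count, and the full
# 10 kHz / 30 s conditions are exercised by the acceptance suite.

po_trace <- function(rates, fs = 2000, glut = 8, mk_dur = 20, noise = noise_spec()) {
  generate_whole_cell_trace(rates, mk_protocol(glut, mk_dur),
                            sampling_rate = fs, noise = noise)
}

test_that("fit_po recovers the wild-type open probability", {
  tr <- po_trace(wt_rates())
  r <- two_step_pipeline(tr)
  expect_equal(r$po$P_o, open_probability(27.8, 200), tolerance = 0.3 / 12.2)
  expect_true(r$po$converged)
  # Eq-5 consistency between k_o and P_o is exact
  expect_identical(r$po$P_o, open_probability(r$po$k_o, 200))
})

test_that("fit_po recovers a strongly reduced open probability", {
  tr <- po_trace(v558i_rates())
  r <- two_step_pipeline(tr)
  expect_lt(abs(r$po$P_o - open_probability(1.33, 200)), 0.3)  # pp
})

test_that("fitted k_o increases with ground-truth k_o (block-onset ordering)", {
  fitted <- vapply(c(1, 5, 27.8, 100), function(ko) {
    r <- two_step_pipeline(po_trace(wt_rates(k_o = ko)))
    r$po$k_o
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("k_u-free fit reduces to the irreversible case when k_u = 0", {
  tr <- po_trace(wt_rates())
  d <- analyze_desensitization(tr)
  irr <- fit_po(tr, d)
  rev <- fit_po_with_unblock(tr, d)
  expect_lt(rev$k_u, 1e-3)
  expect_equal(rev$P_o, irr$P_o, tolerance = 0.01)
})

test_that("k_u-free fit recovers a genuinely reversible block", {
  tr <- po_trace(wt_rates(k_u = 0.5))
  d <- analyze_desensitization(tr)
  f <- fit_po_with_unblock(tr, d)
  expect_equal(f$k_o, 27.8, tolerance = 0.05)
  expect_equal(f$k_u, 0.5, tolerance = 0.05)
  expect_false(f$boundary_warning)
})

test_that("larger k_u leaves a larger residual plateau current", {
  prot <- mk_protocol(5, 40)
  plateaus <- vapply(c(0, 0.2, 1), function(ku) {
    occ <- simulate_occupancies(wt_rates(k_u = ku), prot, seq(0, 45, 5e-3))
    occ$p_O[length(occ$t)]
  }, numeric(1))
  expect_true(all(diff(plateaus) > 0))
})

test_that("a non-decaying current under MK-801 is flagged non-converged", {
  tr <- po_trace(wt_rates())
  d <- analyze_desensitization(tr)
  # replace the MK-801 epoch by a flat continuation of the pre-MK current
  mk_sel <- tr$time >= 8
  tr$current[mk_sel] <- mean(tr$current[tr$time > 7.8 & tr$time < 8])
  expect_warning(f <- fit_po(tr, d), "does not decay")
  expect_false(f$converged)
})

test_that("protocol errors are reported for missing epochs", {
  tr_no_mk <- generate_whole_cell_trace(wt_rates(), glut_protocol(5),
                                        sampling_rate = 2000)
  d <- analyze_desensitization(tr_no_mk)
  expect_error(fit_po(tr_no_mk, d), "no glutamate \\+ MK-801 epoch")
  prot_no_ctl <- application_protocol(
    protocol_epoch(0, 10, glutamate = 1000, mk801 = 1), exchange_tau = 0)
  tr_no_ctl <- generate_whole_cell_trace(wt_rates(), prot_no_ctl,
                                         sampling_rate = 2000)
  expect_error(fit_po(tr_no_ctl, d), "control")
  expect_error(two_step_pipeline(tr_no_ctl), "glutamate-only epoch")
})

test_that("pinned and free current scales give the same P_o on clean data", {
  tr <- po_trace(wt_rates())
  d <- analyze_desensitization(tr)
  free <- fit_po(tr, d, scale_mode = "free")
  pinned <- fit_po(tr, d, scale_mode = "pinned")
  expect_equal(pinned$P_o, free$P_o, tolerance = 0.01)
})
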