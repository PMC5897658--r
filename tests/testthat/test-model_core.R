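test_that("two-state equilibrium and occupancy conservation hold", {
  rts <- rate_set(k_d = 0, k_r = 0, k_o = 100, k_c = 200)
  occ <- simulate_occupancies(rts, glut_protocol(1), seq(0, 1, by = 1e-4))
  expect_equal(occ$p_O[length(occ$t)], 100 / 300, tolerance = 1e-6)
  total <- occ$p_D + occ$p_R + occ$p_O + occ$p_B
  expect_lt(max(abs(total - 1)), 1e-8)
})

test_that("conservation holds across random rate sets and protocols", {
  set.seed(42)
  for (i in 1:10) {
    rts <- rate_set(stats::runif(1, 0, 5), stats::runif(1, 0.1, 5),
                    stats::runif(1, 0, 100), stats::runif(1, 50, 500),
                    k_b = 25, k_u = stats::runif(1, 0, 1))
    prot <- mk_protocol(2, 3, exchange_tau = sample(c(0, 0.012), 1))
    occ <- simulate_occupancies(rts, prot, seq(0, 5, by = 1e-3))
    total <- occ$p_D + occ$p_R + occ$p_O + occ$p_B
    expect_lt(max(abs(total - 1)), 1e-8)
    expect_true(all(occ$p_O >= -1e-12 & occ$p_O <= 1 + 1e-12))
  }
})

test_that("piecewise propagator matches the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  t_grid <- seq(0, 30, by = 0.01)
  for (rts in list(wt_rates(), v558i_rates())) {
    A <- channelkit:::scheme_generator(rts, mk801 = 1)
    occ <- sim_const_mk(rts, t_grid)
    idx <- c(2L, 51L, 1001L, length(t_grid))   # spot-check against expm
    for (k in idx) {
      oracle <- as.numeric(Matrix::expm(A * t_grid[k]) %*% c(0, 1, 0, 0))
      got <- c(occ$p_D[k], occ$p_R[k], occ$p_O[k], occ$p_B[k])
      expect_lt(max(abs(got - oracle)), 1e-8)
    }
  }
})

test_that("stiff-ODE integration agrees with the propagator", {
  skip_if_not_installed("deSolve")
  rts <- wt_rates()
  A <- channelkit:::scheme_generator(rts, mk801 = 1)
  t_grid <- seq(0, 10, by = 0.01)
  occ <- sim_const_mk(rts, t_grid)
  sol <- deSolve::lsoda(c(0, 1, 0, 0), t_grid,
                        function(t, y, p) list(as.numeric(A %*% y)),
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(sol[, 2:5] -
                    cbind(occ$p_D, occ$p_R, occ$p_O, occ$p_B))), 1e-6)
})

test_that("steady state matches its closed form and flags absorbing block", {
  rts <- rate_set(0, 1, 100, 200)   # k_d = 0
  expect_equal(unname(steady_state(rts, 0)[["O"]]), 100 / 300)
  ss <- steady_state(wt_rates(), 0)
  expect_equal(unname(ss[["O"]]),
               (27.8 / 200) / (1 + 0.17 / 0.69 + 27.8 / 200), tolerance = 1e-12)
  # cross-check by long-time simulation
  occ <- simulate_occupancies(wt_rates(), glut_protocol(60), seq(0, 60, 0.01))
  expect_equal(occ$p_O[length(occ$t)], unname(ss[["O"]]), tolerance = 1e-6)
  abs_ss <- steady_state(wt_rates(), 1)
  expect_equal(unname(abs_ss[["B"]]), 1)
  expect_true(attr(abs_ss, "absorbing"))
  expect_error(steady_state(rate_set(1, 0, 10, 200), 0), "degenerate")
})

test_that("blocked occupancy is non-decreasing under irreversible MK-801", {
  occ <- simulate_occupancies(wt_rates(), mk_protocol(2, 10), seq(0, 12, 1e-3))
  pb <- occ$p_B
  expect_true(all(diff(pb) >= -1e-12))
})

test_that("open_probability implements 100 k_o/(k_o + k_c) with bounds", {
  expect_equal(open_probability(200, 200), 50)
  expect_equal(open_probability(0, 200), 0)
  expect_equal(signif(open_probability(23.46, 200), 3), 10.5)
  expect_error(open_probability(10, 0), "k_c")
  expect_error(open_probability(-1, 200), "k_o")
  # strictly increasing in k_o, always below 100
  po <- open_probability(c(1, 5, 50, 500, 5e4), 200)
  expect_true(all(diff(po) > 0))
  expect_true(all(po >= 0 & po < 100))
})

test_that("mendelian_activity reproduces the heterozygous-carrier mixture", {
  expect_equal(mendelian_activity(10, 1, "recessive"), 77.5)
  expect_equal(mendelian_activity(10, 1, "independent"), 55)
  expect_equal(mendelian_activity(10, 1, "dominant"), 32.5)
  expect_equal(mendelian_activity(7, 7, "dominant"), 100)
  expect_error(mendelian_activity(10, 1, "codominant"))
  expect_error(mendelian_activity(101, 1, "dominant"), "0, 100")
})

test_that("rate sets and protocols serialize to JSON and back", {
  td <- withr::local_tempdir()
  rts <- wt_rates(k_u = 0.3)
  p1 <- file.path(td, "r.json")
  write_rate_set(rts, p1)
  expect_equal(unclass(read_rate_set(p1)), unclass(rts))
  prot <- mk_protocol(2, 5, exchange_tau = 0.012)
  p2 <- file.path(td, "p.json")
  write_protocol(prot, p2)
  back <- read_protocol(p2)
  expect_equal(back$epochs, prot$epochs)
  expect_equal(back$exchange_tau, 0.012)
})

test_that("validation rejects bad rates, grids, and protocols", {
  expect_error(rate_set(-0.1, 1, 1, 200), ">= 0")
  expect_error(simulate_occupancies(wt_rates(), glut_protocol(1),
                                    c(0, 0.1, 0.15, 0.4)), "uniform")
  expect_error(simulate_occupancies(wt_rates(), glut_protocol(1),
                                    c(0, 0.1, 0.1)), "increasing")
  expect_error(application_protocol(rbind(
    protocol_epoch(0, 2, glutamate = 1000),
    protocol_epoch(1, 3, glutamate = 1000))), "overlap")
  expect_error(application_protocol(protocol_epoch(0, 1, glutamate = -5)),
               ">= 0")
})
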