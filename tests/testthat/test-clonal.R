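test_that("drug-free growth matches the closed form to 1e-6 relative", {
  p <- clonal_params(rho_S = 0.5, f_R0 = 0, delta_S = 0, delta_R = 0,
                     N0 = 1e5)
  tr <- simulate_clonal(p, no_drug, t_grid = c(0, 4))
  expect_equal(tr$total[2], 1e5 * exp(2), tolerance = 1e-6)
  expect_equal(tr$TR, c(0, 0))
})

test_that("equal rates make the total trajectory independent of the split", {
  for (f in c(0, 0.01, 0.3)) {
    p <- clonal_params(rho_S = 0.4, rho_R = 0.4, delta_S = 1.1,
                       delta_R = 1.1, f_R0 = f)
    tr <- simulate_clonal(p, tmz16, t_grid = obs_days5)
    p0 <- clonal_params(rho_S = 0.4, rho_R = 0.4, delta_S = 1.1,
                        delta_R = 1.1, f_R0 = 0)
    tr0 <- simulate_clonal(p0, tmz16, t_grid = obs_days5)
    expect_equal(tr$total, tr0$total, tolerance = 1e-12)
  }
})

test_that("a standard pulsed course is biphasic and matches an RK4 oracle", {
  p <- clonal_params(rho_S = 0.3, rho_R = 0.45, delta_S = 1.4,
                     delta_R = 0.03, f_R0 = 0.01, N0 = 1e5)
  tr <- simulate_clonal(p, tmz16, t_grid = 0:16)
  # decline then regrowth, with the late log-slope at rho_R - delta_R
  expect_lt(tr$total[5], tr$total[1])
  expect_gt(tr$total[17], tr$total[9])
  late_slope <- (log(tr$total[17]) - log(tr$total[16]))
  expect_equal(late_slope, p$rho_R - p$delta_R, tolerance = 1e-3)
  oracle <- rk4_clonal(p, tmz16, t_end = 16, dt = 1e-3)
  expect_equal(tr$total[17], unname(oracle["total"]), tolerance = 1e-4)
})

test_that("solution is linear in N0 without a carrying capacity", {
  p1 <- clonal_params(f_R0 = 0.02, N0 = 1e4)
  p2 <- clonal_params(f_R0 = 0.02, N0 = 3e4)
  t1 <- simulate_clonal(p1, tmz16, t_grid = obs_days5)
  t2 <- simulate_clonal(p2, tmz16, t_grid = obs_days5)
  expect_equal(3 * t1$S, t2$S, tolerance = 1e-12)
  expect_equal(3 * t1$R, t2$R, tolerance = 1e-12)
  expect_equal(t1$mgmt, t2$mgmt, tolerance = 1e-12)
})

test_that("drug-free pure-sensitive populations keep MGMT at baseline", {
  p <- clonal_params(f_R0 = 0, delta_R = 0)
  tr <- simulate_clonal(p, no_drug, t_grid = 0:10)
  expect_equal(tr$mgmt, rep(1, 11))
})

test_that("MGMT is non-decreasing when selection favors the resistant clone", {
  p <- clonal_params(rho_S = 0.3, rho_R = 0.4, delta_S = 1.2,
                     delta_R = 0.05, f_R0 = 0.01)
  tr <- simulate_clonal(p, tmz16, t_grid = seq(0, 16, by = 0.5))
  expect_true(all(diff(tr$mgmt) >= -1e-12))
})

test_that("logistic growth saturates at K and converges under tolerance refinement", {
  p <- clonal_params(rho_S = 0.6, rho_R = 0.6, delta_S = 0, delta_R = 0,
                     f_R0 = 0.1, N0 = 1e4, K = 5e4)
  coarse <- simulate_clonal(p, no_drug, t_grid = c(0, 5, 30),
                            rtol = 1e-6, atol = 1e-6)
  fine <- simulate_clonal(p, no_drug, t_grid = c(0, 5, 30),
                          rtol = 1e-7, atol = 1e-7)
  # refinement moves the solution by no more than the coarse accuracy
  # request (global error, a few steps' worth of the per-step tolerance)
  expect_lt(abs(coarse$total[2] - fine$total[2]) / fine$total[2], 5e-6)
  expect_equal(coarse$total[3], 5e4, tolerance = 1e-3)
  oracle <- rk4_clonal(p, no_drug, t_end = 5, dt = 1e-3, drug = "placebo")
  expect_equal(fine$total[2], unname(oracle["total"]), tolerance = 1e-5)
})

test_that("parameter validation enforces the resistance ordering", {
  expect_error(clonal_params(delta_S = 0.1, delta_R = 0.5), "delta_R")
  expect_error(clonal_params(f_R0 = 1), "f_R0")
  expect_error(simulate_clonal(clonal_params(), tmz16, t_grid = c(4, 2)),
               "strictly increasing")
})
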