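test_that("with no transient entry the model reduces to the single-population ODE", {
  ap <- adaptive_params(beta = 0)
  ta <- simulate_adaptive(ap, tmz16, t_grid = 0:16)
  cp <- clonal_params(rho_S = ap$rho_S, rho_R = ap$rho_R,
                      delta_S = ap$delta_S, delta_R = ap$delta_R, f_R0 = 0)
  tc <- simulate_clonal(cp, tmz16, t_grid = 0:16)
  expect_equal(ta$S, tc$S, tolerance = 1e-8)
  expect_equal(ta$TR, rep(0, 17))
  expect_equal(ta$R, rep(0, 17))
})

test_that("without conversion the transient pool equals the entry integral", {
  ap <- adaptive_params(gamma_max = 0, tau = 8, a_max = 40)
  fine <- seq(0, 16, by = 0.01)
  tr <- simulate_adaptive(ap, tmz16, t_grid = fine, delta_a = 0.01)
  u <- drug_exposure(tmz16, "TMZ", fine)
  flux <- ap$beta * u * tr$S
  quad <- cumsum(c(0, diff(fine) * (head(flux, -1) + tail(flux, -1)) / 2))
  i <- length(fine)
  expect_equal(quad[i], tr$TR[i], tolerance = 1e-4)
  mid <- which(fine == 8)
  expect_equal(quad[mid], tr$TR[mid], tolerance = 1e-4)
})

test_that("tau = 0 with fast conversion matches a direct S->R ODE oracle", {
  ap <- adaptive_params(tau = 0, gamma_max = 1e3, a_max = 5)
  tr <- simulate_adaptive(ap, tmz16, t_grid = obs_days5, delta_a = 0.01)
  # instantaneous-transit oracle: entry flux feeds R directly
  deriv <- function(t, y, parms) {
    u <- drug_exposure(tmz16, "TMZ", t)
    list(c(ap$rho_S * y[1] - (ap$delta_S + ap$beta) * u * y[1],
           ap$rho_R * y[2] - ap$delta_R * u * y[2] + ap$beta * u * y[1]))
  }
  sol <- deSolve::lsoda(c(S = ap$N0, R = 0), c(0, 4, 9, 12, 16), deriv,
                        NULL, rtol = 1e-10, atol = 1e-8)
  expect_equal(tr$total[-1], unname(sol[-1, "S"] + sol[-1, "R"]),
               tolerance = 1e-2)
})

test_that("pure transfer conserves cells to machine precision", {
  ap <- adaptive_params(rho_S = 0, delta_S = 0, rho_R = 0, delta_R = 0,
                        beta = 0.4, gamma_max = 0.6, tau = 3)
  tr <- simulate_adaptive(ap, tmz16, t_grid = 0:16)
  expect_equal(tr$total, rep(ap$N0, 17), tolerance = 1e-13)
  expect_true(all(tr$S >= 0 & tr$TR >= 0 & tr$R >= 0))
})

test_that("grid refinement converges with empirical order at least 1", {
  ap <- adaptive_reference_params()
  ref <- simulate_adaptive(ap, tmz16, t_grid = obs_days5, delta_a = 0.0125)
  errs <- vapply(c(0.2, 0.1, 0.05), function(h) {
    tr <- simulate_adaptive(ap, tmz16, t_grid = obs_days5, delta_a = h)
    max(abs(tr$total - ref$total) / ref$total)
  }, numeric(1))
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(orders >= 1))
})

test_that("after washout resistance persists and MGMT rises monotonically", {
  ap <- adaptive_reference_params()
  ro <- reference_readout()
  tr <- simulate_adaptive(ap, tmz16, t_grid = seq(0, 28, by = 1),
                          delta_a = 0.05, readout = ro)
  post <- tr$day >= 18  # exposure ends at day 18
  expect_true(all(diff(tr$R[post]) >= 0))       # no back-conversion
  expect_true(all(diff(tr$mgmt[post]) >= -1e-12))
  expect_true(all(tr$mgmt[post] <= ro$alpha + 1e-12))
})

test_that("age snapshots integrate to the transient pool and transport exactly", {
  ap <- adaptive_reference_params()
  tr <- simulate_adaptive(ap, tmz16, t_grid = 0:16, delta_a = 0.05,
                          snapshot_days = c(4, 9))
  sn <- age_snapshots(tr)
  for (d in c(4, 9)) {
    s <- sn[sn$day == d, ]
    expect_equal(sum(s$density) * 0.05, tr$TR[tr$day == d],
                 tolerance = 1e-10)
    expect_true(all(s$density >= 0))
    # entry is drug-gated from day 0, so no cell can be older than t
    expect_equal(sum(s$density[s$age > d]), 0)
  }
})

test_that("degenerate configurations are rejected", {
  expect_error(adaptive_params(tau = 10, a_max = 8), "a_max")
  expect_error(simulate_adaptive(adaptive_params(), tmz16,
                                 t_grid = c(0, 4.03), delta_a = 0.05),
               "divide")
})
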