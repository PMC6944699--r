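test_that("AICc matches its closed form and penalizes extra parameters", {
  ds <- generate_dataset(paperlike_scenarios()$clonal_full_course,
                         noise_model(), seed = 6)$dataset
  ro <- reference_readout()
  spec <- fit_spec("clonal", free = list(rho_R = c(0.05, 1.5),
                                         f_R0 = c(1e-4, 0.5)),
                   log_scale = "f_R0", n_starts = 4, seed = 1)
  rep <- compare_models(ds, spec, spec, readout = ro)
  expect_equal(rep$delta_aicc, 0)
  expect_identical(rep$verdict, "indeterminate")
})

test_that("late-window MGMT misfit is additive and totals the fit's MGMT RSS", {
  scen <- paperlike_scenarios()$full_course
  ds <- generate_dataset(scen, noise_model(), seed = 2)$dataset
  ro <- reference_readout()
  spec <- fit_spec("clonal",
                   free = list(rho_S = c(0.05, 1.5), rho_R = c(0.05, 1.5),
                               delta_S = c(0.2, 4), f_R0 = c(1e-4, 0.5),
                               alpha = c(2, 100)),
                   log_scale = c("f_R0", "alpha"), n_starts = 6, seed = 3)
  ens <- fit_model(ds, spec, readout = ro)
  all_win <- mgmt_misfit(ens$best, ds, c(0, 16), "clonal", ro)
  expect_equal(all_win, ens$best$rss_mgmt, tolerance = 1e-8)
  parts <- mgmt_misfit(ens$best, ds, c(0, 9), "clonal", ro) +
    mgmt_misfit(ens$best, ds, c(10, 16), "clonal", ro)
  expect_equal(parts, all_win, tolerance = 1e-10)
  expect_error(mgmt_misfit(ens$best, ds, c(5, 6), "clonal", ro),
               "no MGMT observations")
})

test_that("noise-free data from the fitted model give zero misfit", {
  scen <- paperlike_scenarios()$clonal_full_course
  tr <- simulate_scenario(scen)
  ds <- dataset_from_trajectory(tr, scen$schedule)
  fit <- structure(list(params = c(unlist(unclass(clonal_reference_params())[
    c("rho_S", "rho_R", "delta_S", "delta_R", "f_R0", "N0")]), alpha = 20)),
    class = "fit_result")
  expect_equal(mgmt_misfit(fit, ds, c(12, 16), "clonal",
                           reference_readout()), 0, tolerance = 1e-12)
})

test_that("channel mismatch between the rival specs is rejected", {
  ds <- generate_dataset(paperlike_scenarios()$full_course,
                         noise_model(), seed = 0)$dataset
  s1 <- fit_spec("clonal", free = list(rho_R = c(0.05, 1.5)),
                 weights = c(count = 1, mgmt = 1), n_starts = 2, seed = 1)
  s2 <- fit_spec("adaptive", free = list(beta = c(0.02, 2)),
                 weights = c(count = 1, mgmt = 0), n_starts = 2, seed = 1)
  expect_error(compare_models(ds, s1, s2), "channel mismatch")
})

test_that("a single-dataset comparison is reproducible and well-formed", {
  ds <- generate_dataset(paperlike_scenarios()$full_course,
                         noise_model(), seed = 1)$dataset
  ro <- reference_readout()
  db_c <- persisterdyn:::default_free_bounds("clonal", TRUE)
  db_a <- persisterdyn:::default_free_bounds("adaptive", TRUE)
  sc <- fit_spec("clonal", free = db_c$free, log_scale = db_c$log_scale,
                 n_starts = 4, seed = 2)
  sa <- fit_spec("adaptive", free = db_a$free, log_scale = db_a$log_scale,
                 n_starts = 4, seed = 2)
  r1 <- compare_models(ds, sc, sa, readout = ro)
  r2 <- compare_models(ds, sc, sa, readout = ro)
  expect_identical(r1$delta_aicc, r2$delta_aicc)
  expect_identical(r1$verdict, r2$verdict)
  expect_true(r1$verdict %in% c("clonal", "adaptive", "indeterminate"))
  expect_equal(r1$delta_aicc, r1$clonal$aicc - r1$adaptive$aicc)
  expect_gte(r1$clonal$rss_mgmt_late, 0)
  expect_gte(r1$adaptive$rss_mgmt_late, 0)
})
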