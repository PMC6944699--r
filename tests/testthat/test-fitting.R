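noise_free_clonal_dataset <- function() {
  scen <- paperlike_scenarios()$clonal_full_course
  tr <- simulate_scenario(scen)
  dataset_from_trajectory(tr, scen$schedule)
}

test_that("residuals vanish on data generated from the same parameters", {
  ds <- noise_free_clonal_dataset()
  truth <- unclass(clonal_reference_params())
  r <- model_residuals("clonal", c(truth, alpha = 20), ds,
                       readout = reference_readout())
  expect_equal(max(abs(r)), 0, tolerance = 1e-10)
  expect_false(attr(r, "penalized"))
})

test_that("counts 10x the model give log10 residuals of exactly -1", {
  ds <- noise_free_clonal_dataset()
  ds2 <- time_course_dataset(
    transform(as.data.frame(ds), count = count * 10),
    schedule = dataset_schedule(ds))
  r <- model_residuals("clonal", c(unclass(clonal_reference_params()),
                                   alpha = 20), ds2,
                       readout = reference_readout())
  ch <- attr(r, "channel")
  expect_equal(unname(r[ch == "count"]), rep(-1, 5), tolerance = 1e-10)
  expect_equal(max(abs(r[ch == "mgmt"])), 0, tolerance = 1e-10)
})

test_that("the summed squared residuals match an independently coded loss", {
  scen <- paperlike_scenarios()$clonal_full_course
  ds <- generate_dataset(scen, noise_model(), seed = 5)$dataset
  ro <- reference_readout()
  w <- c(count = 1, mgmt = 0.7)
  set.seed(21)
  for (i in 1:5) {
    pars <- list(rho_S = runif(1, 0.1, 0.8), rho_R = runif(1, 0.1, 0.8),
                 delta_S = runif(1, 0.8, 2), f_R0 = 10^runif(1, -3, -1),
                 alpha = runif(1, 5, 40))
    r <- model_residuals("clonal", pars, ds, readout = ro, weights = w)
    # independent loss: direct simulation + explicit double loop
    cp <- clonal_params(rho_S = pars$rho_S, rho_R = pars$rho_R,
                        delta_S = pars$delta_S, f_R0 = pars$f_R0)
    tr <- simulate_clonal(cp, scen$schedule, sort(unique(c(0, ds$day))),
                          readout = readout_params(alpha = pars$alpha,
                                                   c_tr = ro$c_tr))
    loss <- 0
    for (i_row in seq_len(nrow(ds))) {
      pred <- tr[tr$day == ds$day[i_row], ]
      loss <- loss +
        w[["count"]] * (log10(pred$total) - log10(ds$count[i_row]))^2 +
        w[["mgmt"]] * (log2(pred$mgmt) - log2(ds$mgmt_fold[i_row]))^2
    }
    expect_equal(sum(r^2), loss, tolerance = 1e-10)
    expect_equal(sum(r^2),
                 w[["count"]] * attr(r, "rss_counts") +
                   w[["mgmt"]] * attr(r, "rss_mgmt"),
                 tolerance = 1e-10)
  }
})

test_that("a single identifiable rate is recovered from noise-free data", {
  p <- clonal_params(rho_S = 0.5, f_R0 = 0, delta_S = 0, delta_R = 0)
  tr <- simulate_clonal(p, no_drug, t_grid = obs_days5)
  ds <- dataset_from_trajectory(tr, no_drug)
  spec <- fit_spec("clonal", free = list(rho_S = c(0.05, 1.5)),
                   fixed = list(f_R0 = 0, delta_S = 0, delta_R = 0),
                   n_starts = 5, seed = 2)
  ens <- fit_model(ds, spec, drug = "placebo")
  expect_equal(ens$best$params[["rho_S"]], 0.5, tolerance = 1e-6)
  rng <- feasible_parameter_range(ens, "rho_S")
  expect_lt(rng[2] - rng[1], 1e-6)
})

test_that("multi-start fitting is deterministic under a fixed seed", {
  scen <- paperlike_scenarios()$clonal_full_course
  ds <- generate_dataset(scen, noise_model(), seed = 1)$dataset
  spec <- fit_spec("clonal",
                   free = list(rho_R = c(0.05, 1.5), f_R0 = c(1e-4, 0.5)),
                   log_scale = "f_R0", n_starts = 6, seed = 9)
  e1 <- fit_model(ds, spec, readout = reference_readout())
  e2 <- fit_model(ds, spec, readout = reference_readout())
  expect_identical(lapply(e1$results, `[[`, "params"),
                   lapply(e2$results, `[[`, "params"))
  expect_identical(e1$best$rss_total, e2$best$rss_total)
  # results are sorted and respect the bounds
  rss <- vapply(e1$results, `[[`, numeric(1), "rss_total")
  expect_true(!is.unsorted(rss))
  for (r in e1$results) {
    expect_true(r$params[["f_R0"]] >= 1e-4 - 1e-12 &&
                  r$params[["f_R0"]] <= 0.5 + 1e-12)
  }
})

test_that("the feasible set is monotone in the feasibility threshold", {
  scen <- paperlike_scenarios()$clonal_full_course
  ds <- generate_dataset(scen, noise_model(), seed = 2)$dataset
  base <- list(model_id = "clonal",
               free = list(rho_S = c(0.05, 1.5), rho_R = c(0.05, 1.5),
                           delta_S = c(0.2, 4), f_R0 = c(1e-4, 0.5)))
  sizes <- vapply(c(0.01, 0.05, 0.5), function(eps) {
    spec <- fit_spec("clonal", free = base$free, log_scale = "f_R0",
                     n_starts = 10, seed = 3, feasibility_epsilon = eps)
    length(fit_model(ds, spec, readout = reference_readout())$feasible)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("freeing a parameter never worsens the best objective", {
  scen <- paperlike_scenarios()$clonal_full_course
  ds <- generate_dataset(scen, noise_model(), seed = 4)$dataset
  ro <- reference_readout()
  fixed_spec <- fit_spec("clonal",
                         free = list(rho_R = c(0.05, 1.5)),
                         fixed = list(f_R0 = 0.004),
                         n_starts = 8, seed = 5)
  e_fixed <- fit_model(ds, fixed_spec, readout = ro)
  free_spec <- fit_spec("clonal",
                        free = list(rho_R = c(0.05, 1.5),
                                    f_R0 = c(1e-4, 0.5)),
                        log_scale = "f_R0", n_starts = 8, seed = 5)
  e_free <- fit_model(ds, free_spec, readout = ro,
                      extra_starts = list(c(rho_R = e_fixed$best$params[["rho_R"]],
                                            f_R0 = 0.004)))
  expect_lte(e_free$best$rss_total, e_fixed$best$rss_total + 1e-10)
})

test_that("invalid fit specifications are rejected", {
  expect_error(fit_spec("clonal", free = list(rho_S = c(2, 1))), "ordered")
  expect_error(fit_spec("clonal", free = list(rho_S = c(0.1, 1)),
                        log_scale = "tau"), "log_scale")
  expect_error(fit_spec("clonal", free = list(f_R0 = c(0, 0.5)),
                        log_scale = "f_R0"), "positive lower bounds")
  ds <- noise_free_clonal_dataset()
  expect_error(feasible_parameter_range(
    fit_model(ds, fit_spec("clonal", free = list(rho_R = c(0.05, 1.5)),
                           n_starts = 2, seed = 1),
              readout = reference_readout()), "nope"),
    "unknown parameter")
})
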