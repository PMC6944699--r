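test_that("zero noise reproduces the model predictions exactly", {
  scen <- paperlike_scenarios()$full_course
  gen <- generate_dataset(scen, noise_model(count_cv = 0, mgmt_sd_log2 = 0,
                                            detection_floor = 0), seed = 1)
  truth <- simulate_scenario(scen)
  for (r in unique(gen$dataset$replicate_id)) {
    sub <- gen$dataset[gen$dataset$replicate_id == r, ]
    expect_equal(sub$count, truth$total[match(sub$day, truth$day)],
                 tolerance = 1e-12)
    expect_equal(sub$mgmt_fold, truth$mgmt[match(sub$day, truth$day)],
                 tolerance = 1e-12)
  }
})

test_that("generation is deterministic per seed and regenerable from ground truth", {
  scen <- paperlike_scenarios()$full_course
  g1 <- generate_dataset(scen, noise_model(), seed = 7)
  g2 <- generate_dataset(scen, noise_model(), seed = 7)
  expect_identical(as.data.frame(g1$dataset), as.data.frame(g2$dataset))
  g3 <- generate_dataset(g1$ground_truth$scenario, g1$ground_truth$noise,
                         seed = g1$ground_truth$seed)
  expect_identical(as.data.frame(g1$dataset), as.data.frame(g3$dataset))
  expect_false(identical(
    as.data.frame(g1$dataset),
    as.data.frame(generate_dataset(scen, noise_model(), seed = 8)$dataset)))
})

test_that("empirical count CV over many seeds matches the nominal 15%", {
  scen <- paperlike_scenarios()$full_course
  counts <- do.call(rbind, lapply(0:19, function(s) {
    ds <- generate_dataset(scen, noise_model(), seed = s)$dataset
    tapply(ds$count, ds$day, function(x) x)
  }))
  truth <- simulate_scenario(scen)
  for (j in seq_along(obs_days5)) {
    x <- unlist(counts[, j])
    cv <- stats::sd(x) / mean(x)
    expect_gte(cv, 0.10)
    expect_lte(cv, 0.20)
  }
})

test_that("the full-course world shows MGMT onset then plateau", {
  scen <- paperlike_scenarios()$full_course
  tr <- simulate_scenario(scen)
  m <- function(d) tr$mgmt[tr$day == d]
  expect_gt(m(9) / m(0), 2)     # onset by day 9
  expect_lt(m(16) / m(12), 1.3) # plateau by day 16
})

test_that("stopping treatment early yields less resistance", {
  sc <- paperlike_scenarios()
  final_R <- vapply(c("early_stop_d3", "early_stop_d6", "full_course"),
                    function(nm) {
                      tr <- simulate_scenario(sc[[nm]])
                      tr$R[tr$day == 16] / tr$total[tr$day == 16]
                    }, numeric(1))
  expect_lt(final_R[["early_stop_d3"]], final_R[["full_course"]])
  expect_lt(final_R[["early_stop_d3"]], final_R[["early_stop_d6"]])
  expect_lt(final_R[["early_stop_d6"]], final_R[["full_course"]])
})

test_that("washout keeps the MGMT readout non-decreasing after treatment ends", {
  scen <- paperlike_scenarios()$washout
  tr <- simulate_scenario(scen, t_grid = seq(0, 28, by = 0.5))
  post <- tr$day >= 18
  expect_true(all(diff(tr$mgmt[post]) >= -1e-12))
})

test_that("the detection floor censors low counts", {
  scen <- paperlike_scenarios()$full_course
  gen <- generate_dataset(scen, noise_model(detection_floor = 5e4), seed = 0)
  expect_true(all(gen$dataset$count >= 5e4))
})

test_that("the scenario library covers the experimental arms", {
  sc <- paperlike_scenarios()
  expect_gte(length(sc), 5)
  expect_true(all(c("full_course", "clonal_full_course", "early_stop_d3",
                    "early_stop_d6", "washout", "tmz_tsa_d3") %in%
                    names(sc)))
  expect_error(scenario_config("bad", tmz16, obs_days = c(0, 20),
                               horizon = 16, model_id = "adaptive",
                               true_params = adaptive_params()),
               "obs_days")
})
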