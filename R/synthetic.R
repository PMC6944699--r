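#' Noise model for synthetic observations
#'
#' Counts receive multiplicative lognormal noise (scale-free across the
#' several-decade dynamic range of the dip-and-regrowth curve), mean-one so
#' the expected observed count equals the model prediction. MGMT
#' fold-changes receive additive Gaussian noise on log2 scale, the
#' qPCR-native unit. Counts below the detection floor are reported at the
#' floor, mimicking a "not detectable" outcome.
#'
#' @param count_cv coefficient of variation of the count noise (default
#'   0.15).
#' @param mgmt_sd_log2 standard deviation of the MGMT noise in log2 units
#'   (default 0.25).
#' @param n_replicates biological replicates per observation day
#'   (default 3).
#' @param detection_floor minimum reportable count, cells (default 100).
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(count_cv = 0.15, mgmt_sd_log2 = 0.25,
                        n_replicates = 3, detection_floor = 100) {
  stopifnot(count_cv >= 0, mgmt_sd_log2 >= 0, n_replicates >= 1,
            detection_floor >= 0)
  structure(list(count_cv = count_cv, mgmt_sd_log2 = mgmt_sd_log2,
                 n_replicates = as.integer(n_replicates),
                 detection_floor = detection_floor),
            class = "noise_model")
}

#' Scenario: one simulated experiment
#'
#' Bundles a treatment schedule, the observation design, the generating
#' model and its true parameters, and the observation model.
#'
#' @param name scenario label.
#' @param schedule a [treatment_schedule()].
#' @param obs_days observation days, all within `[0, horizon]`.
#' @param horizon simulation horizon, days.
#' @param model_id `"clonal"` or `"adaptive"`.
#' @param true_params a [clonal_params()] or [adaptive_params()] object
#'   matching `model_id`.
#' @param readout a [readout_params()].
#' @param kappa_tsa TR-specific kill rate applied while a `"TSA"` schedule
#'   entry is active (adaptive model only).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(name, schedule, obs_days, horizon, model_id,
                            true_params, readout = readout_params(),
                            kappa_tsa = 0) {
  stopifnot(inherits(schedule, "treatment_schedule"),
            model_id %in% c("clonal", "adaptive"))
  obs_days <- sort(unique(as.numeric(obs_days)))
  if (any(obs_days < 0) || any(obs_days > horizon)) {
    stop("obs_days must lie within [0, horizon]", call. = FALSE)
  }
  structure(list(name = name, schedule = schedule, obs_days = obs_days,
                 horizon = horizon, model_id = model_id,
                 true_params = true_params, readout = readout,
                 kappa_tsa = kappa_tsa),
            class = "scenario_config")
}

#' Simulate the noise-free truth of a scenario
#'
#' @param scenario a [scenario_config()].
#' @param t_grid output days (default: the scenario's observation days plus
#'   day 0).
#' @param delta_a adaptive solver age step.
#' @return a `trajectory`.
#' @export
simulate_scenario <- function(scenario, t_grid = NULL, delta_a = 0.05) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (is.null(t_grid)) t_grid <- sort(unique(c(0, scenario$obs_days)))
  if (scenario$model_id == "clonal") {
    simulate_clonal(scenario$true_params, scenario$schedule, t_grid,
                    readout = scenario$readout)
  } else {
    has_tsa <- "TSA" %in% names(scenario$schedule$entries)
    simulate_adaptive(scenario$true_params, scenario$schedule, t_grid,
                      delta_a = delta_a, readout = scenario$readout,
                      tsa_drug = if (has_tsa) "TSA" else NULL,
                      kappa_tsa = if (has_tsa) scenario$kappa_tsa else 0)
  }
}

#' Generate a noisy synthetic dataset from a scenario
#'
#' Draws `n_replicates` noisy observations of counts and MGMT fold-change
#' at each observation day from the scenario's noise-free truth. A fixed
#' seed makes the output bit-reproducible; the returned ground-truth record
#' (true parameters, noise configuration, seed, noise-free trajectory)
#' suffices to regenerate the dataset exactly.
#'
#' @param scenario a [scenario_config()].
#' @param noise a [noise_model()].
#' @param seed integer seed. The caller's RNG state is restored on exit.
#' @param delta_a adaptive solver age step for the truth simulation.
#' @return list with elements `dataset` (a `time_course_dataset`) and
#'   `ground_truth`.
#' @export
generate_dataset <- function(scenario, noise = noise_model(), seed = 0,
                             delta_a = 0.05) {
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(noise, "noise_model"))
  truth <- simulate_scenario(scenario, delta_a = delta_a)
  obs <- truth[match(scenario$obs_days, truth$day), ]

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  sdlog <- sqrt(log(1 + noise$count_cv^2))
  rows <- vector("list", noise$n_replicates)
  for (r in seq_len(noise$n_replicates)) {
    counts <- obs$total *
      exp(stats::rnorm(nrow(obs), mean = -sdlog^2 / 2, sd = sdlog))
    counts <- pmax(counts, noise$detection_floor)
    mg <- 2^(log2(obs$mgmt) +
               stats::rnorm(nrow(obs), sd = noise$mgmt_sd_log2))
    rows[[r]] <- data.frame(replicate_id = sprintf("rep%d", r),
                            day = obs$day, count = counts, mgmt_fold = mg)
  }
  dataset <- time_course_dataset(
    do.call(rbind, rows), schedule = scenario$schedule,
    provenance = sprintf("synthetic scenario '%s', %s model, seed %d",
                         scenario$name, scenario$model_id, seed))
  list(dataset = dataset,
       ground_truth = list(scenario = scenario, noise = noise, seed = seed,
                           truth = as.data.frame(obs)))
}

#' Reference parameter sets of the simulated study
#'
#' `adaptive_reference_params()` is the adaptive-model ground truth used by
#' the packaged scenarios. Its values were chosen once so that the
#' simulated experiment reproduces the qualitative timeline of TMZ
#' resistance acquisition in U251 cells: strong drug-induced death over the
#' first days, a transient non-proliferating pool dominating roughly days
#' 4-12, MGMT onset around day 9 rising to a plateau by day 16, and
#' regrowth of a stably resistant population.
#'
#' `clonal_reference_params()` is the clonal-selection description of the
#' same experiment. The initial resistant fraction is set to `f_R0 =
#' 0.004`, the geometric center of the 0.02-6.97 percent range that
#' clonal-selection fits of such count data admit; with `rho_S` shared
#' with the adaptive world, the remaining kinetics (`rho_R`, `delta_S`)
#' were matched once by least squares (log10 counts, log2 MGMT at the
#' observation days) to the noise-free adaptive reference curve and frozen
#' here as constants. The matching keeps the two in-silico worlds
#' observationally comparable, as both frameworks were conceived as
#' explanations of one experiment.
#'
#' @return a parameter object of the corresponding class.
#' @export
adaptive_reference_params <- function() adaptive_params()

#' @rdname adaptive_reference_params
#' @export
clonal_reference_params <- function() clonal_params()

#' Reference MGMT observation model
#'
#' Expression ratio `alpha = 20` between resistant and sensitive cells.
#' Transient-state cells carry `c_tr = 1`: MGMT is reported as a
#' fold-change over the untreated baseline, and persister cells express
#' the same basal level as sensitive cells (the MGMT-high phenotype
#' belongs to the emerging resistant cells), so on the fold-change scale
#' their relative level is 1, not 0.
#' @return a `readout_params` object.
#' @export
reference_readout <- function() readout_params(alpha = 20, c_tr = 1)

#' The packaged experiment scenarios
#'
#' Named scenario set emulating the longitudinal design:
#' \describe{
#'   \item{full_course}{TMZ every 3 days through day 16, adaptive truth,
#'     observations at days 0, 4, 9, 12, 16.}
#'   \item{clonal_full_course}{same design generated by the clonal model
#'     (matched reference parameters).}
#'   \item{early_stop_d3, early_stop_d6}{treatment stopped after 3,
#'     respectively 6 days; cells followed to day 16.}
#'   \item{washout}{full 16-day course, then no drug out to day 28.}
#'   \item{tmz_tsa_d3}{TMZ from day 0 plus a transient-state-specific
#'     kill (TSA analogue) sustained from day 3, out to day 30.}
#' }
#'
#' @return named list of [scenario_config()] objects.
#' @export
paperlike_scenarios <- function() {
  obs5 <- c(0, 4, 9, 12, 16)
  ap <- adaptive_reference_params()
  cp <- clonal_reference_params()
  ro <- reference_readout()
  tmz16 <- tmz_schedule(16)
  list(
    full_course = scenario_config(
      "full_course", tmz16, obs5, 16, "adaptive", ap, ro),
    clonal_full_course = scenario_config(
      "clonal_full_course", tmz16, obs5, 16, "clonal", cp, ro),
    early_stop_d3 = scenario_config(
      "early_stop_d3", tmz_schedule(3), obs5, 16, "adaptive", ap, ro),
    early_stop_d6 = scenario_config(
      "early_stop_d6", tmz_schedule(6), obs5, 16, "adaptive", ap, ro),
    washout = scenario_config(
      "washout", tmz16, c(0, 4, 9, 12, 16, 20, 24, 28), 28,
      "adaptive", ap, ro),
    tmz_tsa_d3 = scenario_config(
      "tmz_tsa_d3",
      treatment_schedule(
        schedule_entry("TMZ", seq(0, 27, by = 3), "window", window_days = 3),
        schedule_entry("TSA", seq(3, 27, by = 3), "window", window_days = 3)),
      seq(0, 30, by = 3), 30, "adaptive", ap, ro, kappa_tsa = 8)
  )
}
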