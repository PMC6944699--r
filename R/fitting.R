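default_param_list <- function(model_id) {
  obj <- switch(model_id,
                clonal = clonal_params(),
                adaptive = adaptive_params(),
                stop("unknown model_id '", model_id, "'", call. = FALSE))
  unclass(obj)
}

build_model_params <- function(model_id, values) {
  defaults <- default_param_list(model_id)
  values <- values[names(values) %in% names(defaults)]
  full <- utils::modifyList(defaults, as.list(values))
  do.call(switch(model_id, clonal = clonal_params, adaptive = adaptive_params),
          full)
}

#' Specification of a least-squares fit
#'
#' Defines which model is fitted, which parameters are free (with bounds
#' and optional log10 search scale), which are held fixed, the channel
#' weights, and the multi-start configuration. The special parameter name
#' `"alpha"` refers to the MGMT expression ratio of the observation model
#' and may be fitted alongside the kinetic parameters.
#'
#' @param model_id `"clonal"` or `"adaptive"`.
#' @param free named list of length-2 numeric bounds `c(lower, upper)` for
#'   each free parameter.
#' @param fixed named list of parameter values overriding the model
#'   defaults.
#' @param log_scale character vector of free parameters searched on log10
#'   scale (sensible for rates and fractions spanning decades).
#' @param weights named vector `c(count = , mgmt = )` of channel weights;
#'   set `mgmt = 0` for counts-only fitting.
#' @param n_starts number of multi-start initializations (Latin hypercube
#'   over the transformed bounds).
#' @param seed integer seed making the start draw (hence the whole fit)
#'   deterministic.
#' @param feasibility_epsilon fits with total RSS within
#'   `(1 + feasibility_epsilon)` of the best are classified feasible
#'   (default 0.05).
#' @param maxiter per-start optimizer iteration cap.
#' @return an object of class `fit_spec`.
#' @export
fit_spec <- function(model_id = c("clonal", "adaptive"), free, fixed = list(),
                     log_scale = character(0),
                     weights = c(count = 1, mgmt = 1),
                     n_starts = 50, seed = 1, feasibility_epsilon = 0.05,
                     maxiter = 60) {
  model_id <- match.arg(model_id)
  stopifnot(is.list(free), length(free) >= 1L, !is.null(names(free)),
            all(nzchar(names(free))))
  for (nm in names(free)) {
    b <- free[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1L] >= b[2L]) {
      stop("bounds for '", nm, "' must be finite and ordered", call. = FALSE)
    }
  }
  if (!all(log_scale %in% names(free))) {
    stop("log_scale names must be free parameters", call. = FALSE)
  }
  if (any(log_scale %in% names(free)[vapply(free, function(b) b[1L] <= 0,
                                            logical(1))])) {
    bad <- intersect(log_scale,
                     names(free)[vapply(free, function(b) b[1L] <= 0,
                                        logical(1))])
    stop("log-scaled parameter(s) need positive lower bounds: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  weights <- weights[c("count", "mgmt")]
  if (anyNA(weights) || any(weights < 0)) {
    stop("weights must be named c(count=, mgmt=) and non-negative",
         call. = FALSE)
  }
  stopifnot(n_starts >= 1, feasibility_epsilon > 0)
  structure(list(model_id = model_id, free = free, fixed = fixed,
                 log_scale = log_scale, weights = weights,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 feasibility_epsilon = feasibility_epsilon,
                 maxiter = maxiter),
            class = "fit_spec")
}

#' Residuals of a model against a time-course dataset
#'
#' Count residuals are taken on log10 scale (`log10(model) - log10(obs)`),
#' appropriate for the orders-of-magnitude dynamic range of the
#' dip-and-regrowth curve; MGMT residuals on log2 fold-change scale, the
#' qPCR-native unit, only where MGMT was observed. Each channel residual is
#' multiplied by the square root of its weight, so the summed squares
#' decompose as `rss_total = w_count * rss_counts + w_mgmt * rss_mgmt`.
#' Replicates contribute independent rows. If the simulation fails or
#' returns non-positive predictions, a constant penalty vector is returned
#' (flagged via `attr(, "penalized")`) so optimizers can continue.
#'
#' @param model_id `"clonal"` or `"adaptive"`.
#' @param params named numeric vector or list of parameter values
#'   (unspecified model parameters take their defaults; `"alpha"` updates
#'   the readout).
#' @param dataset a `time_course_dataset`.
#' @param readout a [readout_params()].
#' @param weights channel weights as in [fit_spec()].
#' @param delta_a age step for the adaptive solver.
#' @param drug cytotoxic schedule entry id.
#' @param penalty residual magnitude used on simulation failure.
#' @return numeric residual vector with attributes `channel`
#'   (`"count"`/`"mgmt"` per element), `rss_counts`, `rss_mgmt`
#'   (unweighted per-channel sums of squares) and `penalized`.
#' @export
model_residuals <- function(model_id, params, dataset,
                            readout = readout_params(),
                            weights = c(count = 1, mgmt = 1),
                            delta_a = 0.1, drug = "TMZ", penalty = 1e3) {
  stopifnot(inherits(dataset, "time_course_dataset"))
  params <- as.list(params)
  schedule <- dataset_schedule(dataset)
  if (is.null(schedule)) {
    stop("dataset carries no treatment schedule", call. = FALSE)
  }
  if (!is.null(params$alpha)) {
    readout <- readout_params(alpha = params$alpha, c_tr = readout$c_tr,
                              mode = readout$mode,
                              baseline_n = readout$baseline_n)
  }
  days <- sort(unique(dataset$day))
  t_grid <- sort(unique(c(0, days)))
  w_count <- weights[["count"]]; w_mgmt <- weights[["mgmt"]]
  use_mgmt <- w_mgmt > 0 & !is.na(dataset$mgmt_fold)
  n_resid <- nrow(dataset) + sum(use_mgmt)

  traj <- tryCatch({
    mp <- build_model_params(model_id, params)
    if (model_id == "clonal") {
      simulate_clonal(mp, schedule, t_grid, readout = readout, drug = drug)
    } else {
      simulate_adaptive(mp, schedule, t_grid, delta_a = delta_a,
                        readout = readout, drug = drug)
    }
  }, error = function(e) NULL)

  fail <- is.null(traj) || any(!is.finite(traj$total)) ||
    any(traj$total[match(days, traj$day)] <= 0)
  if (fail) {
    out <- rep(penalty, n_resid)
    attr(out, "channel") <- c(rep("count", nrow(dataset)),
                              rep("mgmt", sum(use_mgmt)))
    attr(out, "rss_counts") <- penalty^2 * nrow(dataset)
    attr(out, "rss_mgmt") <- penalty^2 * sum(use_mgmt)
    attr(out, "penalized") <- TRUE
    return(out)
  }

  idx <- match(dataset$day, traj$day)
  res_count <- log10(traj$total[idx]) - log10(dataset$count)
  res_mgmt <- log2(traj$mgmt[idx[use_mgmt]]) -
    log2(dataset$mgmt_fold[use_mgmt])
  out <- c(sqrt(w_count) * res_count, sqrt(w_mgmt) * res_mgmt)
  attr(out, "channel") <- c(rep("count", length(res_count)),
                            rep("mgmt", length(res_mgmt)))
  attr(out, "rss_counts") <- sum(res_count^2)
  attr(out, "rss_mgmt") <- sum(res_mgmt^2)
  attr(out, "penalized") <- FALSE
  out
}

to_opt_scale <- function(x, names_, log_scale) {
  ifelse(names_ %in% log_scale, log10(x), x)
}
from_opt_scale <- function(x, names_, log_scale) {
  ifelse(names_ %in% log_scale, 10^x, x)
}

#' Multi-start least-squares fit of a model to a dataset
#'
#' Draws `n_starts` initial points by Latin hypercube over the (log-scaled
#' where flagged) bounds and refines each with a bounded Levenberg-
#' Marquardt least-squares routine ([minpack.lm::nls.lm()]). The returned
#' ensemble, sorted by total RSS, is the unit of practical-identifiability
#' analysis: many near-equally-good fits with very different parameter
#' values reveal a parameter the data do not constrain.
#'
#' @param dataset a `time_course_dataset` (must carry its schedule).
#' @param spec a [fit_spec()].
#' @param readout a [readout_params()]; a free `"alpha"` overrides its
#'   expression ratio during fitting.
#' @param delta_a age step used by the adaptive solver during fitting.
#' @param drug cytotoxic schedule entry id.
#' @param extra_starts optional list of named parameter vectors appended to
#'   the Latin-hypercube starts (values for every free parameter).
#' @return an object of class `fit_ensemble`: list with `results` (all
#'   starts, sorted by `rss_total`), `best`, `feasible` (fits within
#'   `1 + feasibility_epsilon` of the best RSS), and the echoed `spec`.
#' @export
fit_model <- function(dataset, spec, readout = readout_params(),
                      delta_a = 0.1, drug = "TMZ", extra_starts = NULL) {
  stopifnot(inherits(dataset, "time_course_dataset"),
            inherits(spec, "fit_spec"))
  free_names <- names(spec$free)
  k <- length(free_names)
  n_obs <- nrow(dataset) +
    if (spec$weights[["mgmt"]] > 0) sum(!is.na(dataset$mgmt_fold)) else 0L
  if (n_obs < k) {
    stop("fewer observations than free parameters", call. = FALSE)
  }
  lower_nat <- vapply(spec$free, `[`, numeric(1), 1L)
  upper_nat <- vapply(spec$free, `[`, numeric(1), 2L)
  lower <- to_opt_scale(lower_nat, free_names, spec$log_scale)
  upper <- to_opt_scale(upper_nat, free_names, spec$log_scale)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)
  H <- lhs::randomLHS(spec$n_starts, k)
  starts <- sweep(sweep(H, 2L, upper - lower, `*`), 2L, lower, `+`)
  if (!is.null(extra_starts)) {
    extra <- do.call(rbind, lapply(extra_starts, function(v) {
      to_opt_scale(unlist(v)[free_names], free_names, spec$log_scale)
    }))
    starts <- rbind(starts, pmin(pmax(extra, rep(lower, each = nrow(extra))),
                                 rep(upper, each = nrow(extra))))
  }

  resid_fn <- function(x) {
    vals <- as.list(from_opt_scale(x, free_names, spec$log_scale))
    names(vals) <- free_names
    model_residuals(spec$model_id, c(vals, spec$fixed), dataset,
                    readout = readout, weights = spec$weights,
                    delta_a = delta_a, drug = drug)
  }

  results <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = spec$maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    par_nat <- from_opt_scale(fit$par, free_names, spec$log_scale)
    names(par_nat) <- free_names
    r <- resid_fn(fit$par)
    results[[i]] <- structure(list(
      params = c(par_nat, unlist(spec$fixed)),
      rss_total = sum(r^2),
      rss_counts = attr(r, "rss_counts"),
      rss_mgmt = attr(r, "rss_mgmt"),
      penalized = attr(r, "penalized"),
      converged = fit$info %in% 1:4,
      n_evaluations = fit$niter,
      start = stats::setNames(from_opt_scale(starts[i, ], free_names,
                                             spec$log_scale), free_names)
    ), class = "fit_result")
  }
  results <- Filter(Negate(is.null), results)
  if (!length(results)) {
    stop("all optimization starts failed; starts were:\n",
         paste(utils::capture.output(print(starts)), collapse = "\n"),
         call. = FALSE)
  }
  ord <- order(vapply(results, `[[`, numeric(1), "rss_total"))
  results <- results[ord]
  best <- results[[1L]]
  rss <- vapply(results, `[[`, numeric(1), "rss_total")
  feasible <- results[rss <= (1 + spec$feasibility_epsilon) * best$rss_total]
  structure(list(results = results, best = best, feasible = feasible,
                 spec = spec, n_obs = n_obs),
            class = "fit_ensemble")
}

#' @export
print.fit_ensemble <- function(x, ...) {
  cat(sprintf(
    "<fit_ensemble: %s model, %d start(s), %d feasible, best RSS %.4g>\n",
    x$spec$model_id, length(x$results), length(x$feasible),
    x$best$rss_total))
  cat("best parameters:\n")
  print(signif(x$best$params, 4L))
  invisible(x)
}

#' Feasible range of a fitted parameter
#'
#' Spread of a parameter across all fits whose loss is within the
#' feasibility threshold of the best fit: the computational device for
#' practical identifiability. A wide range (e.g. a factor of 10 or more
#' between min and max) shows the data do not pin the parameter down.
#'
#' @param ensemble a `fit_ensemble`.
#' @param param_name name of a fitted (or fixed) parameter.
#' @return numeric `c(min, max)` over the feasible subset.
#' @export
feasible_parameter_range <- function(ensemble, param_name) {
  stopifnot(inherits(ensemble, "fit_ensemble"))
  vals <- vapply(ensemble$feasible, function(r) {
    if (!param_name %in% names(r$params)) {
      stop("unknown parameter '", param_name, "'", call. = FALSE)
    }
    r$params[[param_name]]
  }, numeric(1))
  c(min = min(vals), max = max(vals))
}
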