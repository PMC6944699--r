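#' Define one drug entry of a treatment schedule
#'
#' A schedule entry maps a list of dosing times to a time-varying, unitless
#' exposure function. Two conventions are supported: `"window"` mode, where
#' each dose produces full exposure for a fixed number of days (appropriate
#' when the drug is re-dosed before the previous dose has cleared, as in a
#' 50 uM TMZ course re-dosed every 3 days), and `"decay"` mode, where each
#' dose contributes an exponentially decaying exposure.
#'
#' Doses in micromolar are metadata only; the dynamic models consume the
#' unitless `effect_level` in `[0, 1]`.
#'
#' @param drug drug identifier, e.g. `"TMZ"` or `"TSA"`.
#' @param dose_times strictly increasing vector of dosing days (>= 0).
#' @param mode `"window"` or `"decay"`.
#' @param window_days exposure window per dose, days (window mode).
#' @param decay_rate exponential clearance rate, per day (decay mode).
#' @param effect_level unitless peak effect in `[0, 1]`.
#' @return an object of class `schedule_entry`.
#' @export
schedule_entry <- function(drug, dose_times, mode = c("window", "decay"),
                           window_days = NULL, decay_rate = NULL,
                           effect_level = 1) {
  mode <- match.arg(mode)
  stopifnot(is.character(drug), length(drug) == 1L, nzchar(drug))
  dose_times <- as.numeric(dose_times)
  if (length(dose_times) == 0L) {
    stop("schedule entry for '", drug, "' has no dose times", call. = FALSE)
  }
  if (any(dose_times < 0)) {
    stop("dose_times must be >= 0", call. = FALSE)
  }
  if (is.unsorted(dose_times, strictly = TRUE)) {
    stop("dose_times must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(effect_level) || effect_level < 0 || effect_level > 1) {
    stop("effect_level must lie in [0, 1]", call. = FALSE)
  }
  if (mode == "window") {
    if (is.null(window_days) || window_days < 0) {
      stop("window mode requires window_days >= 0", call. = FALSE)
    }
    decay_rate <- NULL
  } else {
    if (is.null(decay_rate) || decay_rate < 0) {
      stop("decay mode requires decay_rate >= 0", call. = FALSE)
    }
    window_days <- NULL
  }
  structure(
    list(drug = drug, dose_times = dose_times, mode = mode,
         window_days = window_days, decay_rate = decay_rate,
         effect_level = as.numeric(effect_level)),
    class = "schedule_entry"
  )
}

#' Assemble a multi-drug treatment schedule
#'
#' @param ... objects created by [schedule_entry()].
#' @return an object of class `treatment_schedule`.
#' @examples
#' sched <- treatment_schedule(
#'   schedule_entry("TMZ", seq(0, 15, by = 3), "window", window_days = 3)
#' )
#' drug_exposure(sched, "TMZ", c(0, 7.2, 18.5))
#' @export
treatment_schedule <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1L]]) &&
      !inherits(entries[[1L]], "schedule_entry")) {
    entries <- entries[[1L]]
  }
  ok <- vapply(entries, inherits, logical(1), "schedule_entry")
  if (!all(ok)) stop("all arguments must be schedule_entry objects", call. = FALSE)
  drugs <- vapply(entries, `[[`, character(1), "drug")
  if (anyDuplicated(drugs)) stop("duplicate drug ids in schedule", call. = FALSE)
  names(entries) <- drugs
  structure(list(entries = entries), class = "treatment_schedule")
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat("<treatment_schedule>", length(x$entries), "drug(s)\n")
  for (e in x$entries) {
    cat(sprintf("  %s: %d dose(s) at {%s} d, %s mode, effect %.3g\n",
                e$drug, length(e$dose_times),
                paste(format(e$dose_times), collapse = ", "),
                e$mode, e$effect_level))
  }
  invisible(x)
}

#' Standard pulsed TMZ course
#'
#' Convenience constructor for the canonical course: one dose every
#' `interval` days from day 0 while treatment lasts, each dose covered by a
#' window equal to the inter-dose interval, so exposure is effectively
#' continuous at `effect_level` until `treat_days` after the last dose's
#' window closes.
#'
#' @param treat_days duration of treatment, days; doses are placed at
#'   `seq(0, treat_days - epsilon, by = interval)`.
#' @param interval inter-dose interval, days (default 3).
#' @param effect_level unitless effect in `[0, 1]`.
#' @param drug drug id (default `"TMZ"`).
#' @return a `treatment_schedule` with a single entry.
#' @export
tmz_schedule <- function(treat_days = 16, interval = 3, effect_level = 1,
                         drug = "TMZ") {
  stopifnot(treat_days > 0, interval > 0)
  doses <- seq(0, treat_days - 1e-9, by = interval)
  treatment_schedule(
    schedule_entry(drug, doses, "window", window_days = interval,
                   effect_level = effect_level)
  )
}

#' Time-varying drug exposure
#'
#' Evaluates the unitless exposure of `drug_id` at times `t`. Window mode
#' returns `effect_level` whenever `t` lies in `[dose, dose + window)` for
#' any dose, else 0. Decay mode sums `exp(-decay_rate * (t - dose))` over
#' past doses, scaled by `effect_level` and capped at `effect_level`.
#' A drug absent from the schedule has exposure 0 everywhere.
#'
#' @param schedule a `treatment_schedule`.
#' @param drug_id drug identifier.
#' @param t vector of times, days (>= 0).
#' @return numeric vector of exposures in `[0, effect_level]`.
#' @export
drug_exposure <- function(schedule, drug_id, t) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("exposure requested at negative time", call. = FALSE)
  e <- schedule$entries[[drug_id]]
  if (is.null(e)) return(rep(0, length(t)))
  if (e$mode == "window") {
    hit <- vapply(t, function(ti) {
      any(ti >= e$dose_times & ti < e$dose_times + e$window_days)
    }, logical(1))
    ifelse(hit, e$effect_level, 0)
  } else {
    val <- vapply(t, function(ti) {
      past <- e$dose_times[e$dose_times <= ti]
      if (!length(past)) return(0)
      e$effect_level * sum(exp(-e$decay_rate * (ti - past)))
    }, numeric(1))
    pmin(val, e$effect_level)
  }
}

# Times at which any exposure function is non-smooth, restricted to
# [t0, t1]. Solvers split the integration at these points.
exposure_breakpoints <- function(schedule, t0, t1) {
  pts <- numeric(0)
  for (e in schedule$entries) {
    pts <- c(pts, e$dose_times)
    if (e$mode == "window") pts <- c(pts, e$dose_times + e$window_days)
  }
  pts <- sort(unique(pts))
  pts[pts > t0 + 1e-12 & pts < t1 - 1e-12]
}

#' Serialize / deserialize a treatment schedule as YAML
#'
#' @param schedule a `treatment_schedule`.
#' @param path file path.
#' @return `read_schedule` returns a `treatment_schedule`;
#'   `write_schedule` returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  lst <- lapply(schedule$entries, function(e) {
    out <- list(drug = e$drug, dose_times = as.numeric(e$dose_times),
                mode = e$mode, effect_level = e$effect_level)
    if (e$mode == "window") out$window_days <- e$window_days
    else out$decay_rate <- e$decay_rate
    out
  })
  yaml::write_yaml(unname(lst), path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  lst <- yaml::read_yaml(path)
  entries <- lapply(lst, function(e) {
    schedule_entry(e$drug, unlist(e$dose_times), e$mode,
                   window_days = e$window_days, decay_rate = e$decay_rate,
                   effect_level = e$effect_level)
  })
  treatment_schedule(entries)
}
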