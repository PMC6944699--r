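#' Stochastic (agent-bookkeeping) simulation of the adaptive model
#'
#' Exact event-driven Monte Carlo realization of the adaptive framework,
#' used as an independent oracle for the deterministic age-structured
#' solver. Division, death, transient-state entry and mature conversion
#' fire with exponential clocks at the current per-capita rates; the
#' maturation of each transient cell is deterministic, exactly `tau` days
#' after its entry (its age is tracked individually). Exposure is frozen
#' between schedule breakpoints, which is exact for window-mode schedules.
#'
#' Intended for desk scale (`n0` up to ~1e4): the mean over many seeded
#' realizations converges to the mean-field age-structured solution.
#'
#' @inheritParams simulate_adaptive
#' @param horizon simulation end time, days.
#' @param n0 initial (integer) number of sensitive cells.
#' @param seed integer seed; a fixed seed reproduces the realization
#'   exactly. The caller's RNG state is restored on exit.
#' @param record_days days at which to record compartment counts
#'   (default `0:horizon`).
#' @param max_events safety cap on the number of stochastic events.
#' @return a `trajectory` with integer-valued compartments; `mgmt` is `NA`
#'   where the population is extinct.
#' @export
simulate_adaptive_stochastic <- function(params, schedule, horizon, n0,
                                         seed = NULL,
                                         record_days = NULL,
                                         readout = readout_params(),
                                         drug = "TMZ",
                                         max_events = 2e7) {
  stopifnot(inherits(params, "adaptive_params"),
            inherits(schedule, "treatment_schedule"),
            horizon > 0, n0 >= 1)
  if (n0 > 1e4) stop("n0 too large for agent-level simulation (<= 1e4)",
                     call. = FALSE)
  if (is.null(record_days)) record_days <- seq(0, horizon, by = 1)
  record_days <- sort(unique(as.numeric(record_days)))
  stopifnot(all(record_days >= 0), all(record_days <= horizon))

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }

  p <- params
  tau0 <- p$tau <= 0

  # young transient cells: FIFO of maturation times (entry + tau); deaths
  # mark entries dead, divisions may append out of order.
  cap <- 1024L
  q_time <- numeric(cap); q_alive <- logical(cap)
  q_head <- 1L; q_tail <- 0L
  n_young <- 0L; n_mat <- 0L
  S <- as.integer(n0); R <- 0L
  push <- function(tm) {
    if (q_tail == cap) {
      cap <<- cap * 2L
      q_time <<- c(q_time, numeric(cap / 2L))
      q_alive <<- c(q_alive, logical(cap / 2L))
    }
    q_tail <<- q_tail + 1L
    q_time[q_tail] <<- tm; q_alive[q_tail] <<- TRUE
    n_young <<- n_young + 1L
  }
  next_mat_cache <- Inf; cache_ok <- FALSE
  next_mat <- function() {
    if (!cache_ok) {
      while (q_head <= q_tail && !q_alive[q_head]) q_head <<- q_head + 1L
      next_mat_cache <<- if (n_young == 0L) Inf else {
        idx <- q_head:q_tail
        min(q_time[idx][q_alive[idx]])
      }
      cache_ok <<- TRUE
    }
    next_mat_cache
  }
  pick_young <- function() {
    idx <- q_head:q_tail
    alive <- idx[q_alive[idx]]
    if (length(alive) == 1L) alive else alive[sample.int(length(alive), 1L)]
  }

  brk <- c(exposure_breakpoints(schedule, 0, horizon), horizon)
  brk_i <- 1L
  rec_i <- 1L
  n_rec <- length(record_days)
  recS <- integer(n_rec); recTR <- integer(n_rec); recR <- integer(n_rec)

  # buffered uniform draws (the loop is RNG-call dominated otherwise)
  buf <- stats::runif(4096L); bi <- 0L
  draw <- function() {
    if (bi == 4096L) { buf <<- stats::runif(4096L); bi <<- 0L }
    bi <<- bi + 1L
    buf[bi]
  }

  # per-capita rate constants
  k_s_div <- p$rho_S; k_y <- p$mu_TR + p$rho_TR
  k_m <- p$mu_TR + p$rho_TR + p$gamma_max; k_r_div <- p$rho_R

  t <- 0
  u <- drug_exposure(schedule, drug, 0)
  u_entry <- if (p$drug_gated_entry) u else 1
  next_brk <- if (brk_i <= length(brk)) brk[brk_i] else Inf
  ev <- 0
  repeat {
    # record everything due at the current time before any further event
    while (rec_i <= n_rec && record_days[rec_i] <= t + 1e-12) {
      recS[rec_i] <- S; recTR[rec_i] <- n_young + n_mat; recR[rec_i] <- R
      rec_i <- rec_i + 1L
    }
    if (rec_i > n_rec) break

    a_s_div <- k_s_div * S
    a_s_die <- p$delta_S * u * S
    a_s_ent <- p$beta * u_entry * S
    a_y <- k_y * n_young
    a_m <- k_m * n_mat
    a_r_div <- k_r_div * R
    a_r_die <- p$delta_R * u * R
    tot <- a_s_div + a_s_die + a_s_ent + a_y + a_m + a_r_div + a_r_die

    nm <- next_mat()
    t_det <- min(next_brk, nm, record_days[rec_i])
    t_ev <- if (tot > 0) t - log(draw()) / tot else Inf
    if (t_ev >= t_det) {
      t <- t_det
      if (t >= nm - 1e-15 && nm <= t_det) {
        # maturation: pop the cell reaching age tau
        while (q_head <= q_tail && !q_alive[q_head]) q_head <- q_head + 1L
        idx <- q_head:q_tail
        alive <- idx[q_alive[idx]]
        j <- alive[which.min(q_time[alive])]
        q_alive[j] <- FALSE
        n_young <- n_young - 1L; n_mat <- n_mat + 1L
        cache_ok <- FALSE
      } else if (t >= next_brk - 1e-15) {
        u <- drug_exposure(schedule, drug, min(t + 1e-9, horizon))
        u_entry <- if (p$drug_gated_entry) u else 1
        brk_i <- brk_i + 1L
        next_brk <- if (brk_i <= length(brk)) brk[brk_i] else Inf
      }
      # if t_det was a record day the while-loop at the top handles it
      next
    }
    t <- t_ev
    ev <- ev + 1L
    if (ev > max_events) stop("stochastic simulation exceeded max_events",
                              call. = FALSE)
    r <- draw() * tot
    if (r < a_s_div) {
      S <- S + 1L
    } else if ((r <- r - a_s_div) < a_s_die) {
      S <- S - 1L
    } else if ((r <- r - a_s_die) < a_s_ent) {
      S <- S - 1L
      if (tau0) n_mat <- n_mat + 1L else { push(t + p$tau); cache_ok <- FALSE }
    } else if ((r <- r - a_s_ent) < a_y) {
      if (r < p$mu_TR * n_young) {            # young death
        j <- pick_young(); q_alive[j] <- FALSE
        n_young <- n_young - 1L
      } else {                                 # young division (inherits age)
        j <- pick_young(); push(q_time[j])
      }
      cache_ok <- FALSE
    } else if ((r <- r - a_y) < a_m) {
      if (r < p$mu_TR * n_mat) {
        n_mat <- n_mat - 1L
      } else if (r < (p$mu_TR + p$rho_TR) * n_mat) {
        n_mat <- n_mat + 1L
      } else {                                 # maturation-conversion
        n_mat <- n_mat - 1L; R <- R + 1L
      }
    } else if ((r <- r - a_m) < a_r_div) {
      R <- R + 1L
    } else {
      R <- R - 1L
    }
  }

  total <- recS + recTR + recR
  expr <- recS + readout$c_tr * recTR + readout$alpha * recR
  mg <- ifelse(total > 0,
               if (readout$mode == "average") expr / total
               else expr / readout$baseline_n,
               NA_real_)
  new_trajectory(record_days, as.numeric(recS), as.numeric(recTR),
                 as.numeric(recR), mg, model_id = "adaptive_stochastic",
                 params = params)
}
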