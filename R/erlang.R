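#' Erlang-chain (linear chain trick) approximation of the adaptive model
#'
#' Replaces the fixed maturation age `tau` by `n_stages` sequential
#' sub-compartments, each left at rate `n_stages / tau`, followed by a
#' mature compartment converting to resistance at `gamma_max`. As
#' `n_stages` grows, the Erlang-distributed residence time concentrates on
#' `tau` and the solution converges to the sharp age-structured model; the
#' chain therefore serves as an independent deterministic cross-check of
#' [simulate_adaptive()] (it is used in tests, not in fitting).
#'
#' With `n_stages = 1` the maturation delay is exponential with mean `tau`.
#' With `tau = 0` the chain is skipped and entering cells are immediately
#' mature.
#'
#' @inheritParams simulate_adaptive
#' @param n_stages number of maturation sub-compartments, >= 1.
#' @param rtol,atol solver tolerances.
#' @return a `trajectory` whose `TR` column is the summed chain occupancy.
#' @export
erlang_chain_approx <- function(params, schedule, t_grid, n_stages,
                                readout = readout_params(), drug = "TMZ",
                                rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "adaptive_params"),
            inherits(schedule, "treatment_schedule"))
  n_stages <- as.integer(n_stages)
  if (n_stages < 1L) stop("n_stages must be >= 1", call. = FALSE)
  t_grid <- as.numeric(t_grid)
  if (is.unsorted(t_grid, strictly = TRUE) || t_grid[1L] < 0) {
    stop("t_grid must be strictly increasing with t_grid[1] >= 0",
         call. = FALSE)
  }
  use_chain <- params$tau > 0
  n_chain <- if (use_chain) n_stages else 0L
  k_stage <- if (use_chain) n_stages / params$tau else 0

  deriv <- function(t, y, parms) {
    u <- drug_exposure(schedule, drug, t)
    u_entry <- if (params$drug_gated_entry) u else 1
    S <- y[1L]; R <- y[length(y)]
    Tm <- y[length(y) - 1L]
    dS <- params$rho_S * S - (params$delta_S * u + params$beta * u_entry) * S
    inflow <- params$beta * u_entry * S
    dy <- numeric(length(y))
    dy[1L] <- dS
    decay_tr <- params$mu_TR - params$rho_TR
    if (n_chain > 0L) {
      prev <- inflow
      for (j in seq_len(n_chain)) {
        Tj <- y[1L + j]
        dy[1L + j] <- prev - (k_stage + decay_tr) * Tj
        prev <- k_stage * Tj
      }
      dy[length(y) - 1L] <- prev - (params$gamma_max + decay_tr) * Tm
    } else {
      dy[length(y) - 1L] <- inflow - (params$gamma_max + decay_tr) * Tm
    }
    dy[length(y)] <- params$rho_R * R - params$delta_R * u * R +
      params$gamma_max * Tm
    list(dy)
  }

  y <- c(params$N0, numeric(n_chain), 0, 0)
  t0 <- t_grid[1L]; t1 <- t_grid[length(t_grid)]
  brk <- c(t0, exposure_breakpoints(schedule, t0, t1), t1)
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = length(y))
  out[1L, ] <- y
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    times <- sort(unique(c(a, t_grid[t_grid > a & t_grid <= b], b)))
    sol <- deSolve::lsoda(y, times, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    idx <- match(round(t_grid, 12L), round(sol[, 1L], 12L))
    take <- which(!is.na(idx) & t_grid > a)
    out[take, ] <- sol[idx[take], -1L, drop = FALSE]
    y <- sol[nrow(sol), -1L]
  }
  S <- pmax(out[, 1L], 0)
  TRtot <- pmax(rowSums(out[, 2L:(ncol(out) - 1L), drop = FALSE]), 0)
  R <- pmax(out[, ncol(out)], 0)
  mg <- mgmt_readout(S, TRtot, R, readout)
  new_trajectory(t_grid, S, TRtot, R, mg, model_id = "adaptive_erlang",
                 params = params)
}
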