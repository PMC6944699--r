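#' Parameters of the adaptive (acquired-resistance) model
#'
#' Framework with zero initial resistant cells: under drug, sensitive cells
#' enter an age-structured transient ("TR", drug-tolerant persister) state
#' in which, by default, they neither proliferate nor die; after a
#' maturation age `tau` they convert irreversibly into resistant cells at
#' rate `gamma_max`. The governing system is
#' \deqn{dS/dt = \rho_S S - (\delta_S + \beta) u(t) S,}
#' \deqn{\partial n/\partial t + \partial n/\partial a =
#'   (\rho_{TR} - \mu_{TR} - \gamma(a)) n, \qquad n(t, 0) = \beta u(t) S(t),}
#' \deqn{dR/dt = \rho_R R - \delta_R u(t) R + \int \gamma(a) n(t,a)\,da,}
#' with `gamma(a) = gamma_max * [a >= tau]` (or a smooth Hill variant).
#'
#' @param rho_S,delta_S,rho_R,delta_R as in [clonal_params()], per day.
#' @param beta drug-induced S -> TR entry rate at full exposure, per day.
#' @param mu_TR death rate of transient cells, per day (default 0: the
#'   persister state is death-protected).
#' @param rho_TR proliferation rate of transient cells, per day (default 0:
#'   the persister state is non-proliferating).
#' @param tau maturation age, days: transient cells younger than `tau`
#'   cannot convert.
#' @param gamma_max TR -> R conversion rate for ages >= `tau`, per day.
#' @param N0 initial (pure sensitive) population, cells.
#' @param a_max truncation of the age domain, days; must exceed `tau`. The
#'   terminal age bin is absorbing: cells older than `a_max` keep
#'   converting at `gamma_max`.
#' @param drug_gated_entry logical; if `FALSE`, entry into the transient
#'   state proceeds at rate `beta` irrespective of exposure.
#' @param gamma_hill_n if finite, replaces the step maturation rate by the
#'   smooth form `gamma_max * a^n / (a^n + tau^n)`.
#' @return an object of class `adaptive_params`.
#' @export
adaptive_params <- function(rho_S = 0.4, delta_S = 1.2, rho_R = 0.5,
                            delta_R = 0.03, beta = 0.35, mu_TR = 0,
                            rho_TR = 0, tau = 8, gamma_max = 0.6, N0 = 1e5,
                            a_max = 30, drug_gated_entry = TRUE,
                            gamma_hill_n = Inf) {
  stopifnot(rho_S >= 0, delta_S >= 0, rho_R >= 0, delta_R >= 0, beta >= 0,
            mu_TR >= 0, rho_TR >= 0, tau >= 0, gamma_max >= 0, N0 > 0,
            gamma_hill_n > 0)
  if (a_max <= tau) {
    stop("a_max must exceed the maturation age tau", call. = FALSE)
  }
  structure(as.list(environment()), class = "adaptive_params")
}

# Per-bin conversion rate averaged along the characteristic of one step:
# a cell at bin midpoint age a ages to a + h during the step.
gamma_bar_bins <- function(params, h, n_bins) {
  a_mid <- (seq_len(n_bins) - 0.5) * h
  if (is.finite(params$gamma_hill_n)) {
    a <- a_mid + h / 2
    g <- params$gamma_max * a^params$gamma_hill_n /
      (a^params$gamma_hill_n + params$tau^params$gamma_hill_n)
  } else {
    overlap <- pmax(0, a_mid + h - pmax(a_mid, params$tau))
    g <- params$gamma_max * overlap / h
  }
  g[n_bins] <- params$gamma_max  # absorbing terminal bin (age >= a_max - h > tau)
  g
}

#' Simulate the adaptive age-structured model
#'
#' Solves the transport equation for the transient-state age density along
#' characteristics with time step equal to the age step (`delta_a`), which
#' represents age transport exactly and avoids numerical diffusion;
#' reaction terms (entry, maturation-conversion, death, proliferation) are
#' integrated exactly within each step under the step-frozen exposure.
#' Pure transfer (all proliferation and death rates zero) conserves
#' `S + TR + R` to machine precision.
#'
#' @param params an [adaptive_params()] object.
#' @param schedule a [treatment_schedule()].
#' @param t_grid strictly increasing output days; every point must be a
#'   multiple of `delta_a` from `t_grid[1]`, and dose times should align
#'   with the step grid (they do for integer dosing days and the default
#'   step).
#' @param delta_a age/time step, days (default 0.05).
#' @param readout a [readout_params()] for the MGMT channel.
#' @param drug schedule entry carrying the cytotoxic exposure.
#' @param tsa_drug optional schedule entry (e.g. `"TSA"`) whose exposure
#'   applies the transient-state-specific kill rate `kappa_tsa`.
#' @param kappa_tsa TR-specific additional death rate at full `tsa_drug`
#'   exposure, per day.
#' @param snapshot_days days at which to store the full age density.
#' @return a `trajectory`; age snapshots, when requested, via
#'   [age_snapshots()].
#' @examples
#' tr <- simulate_adaptive(adaptive_params(), tmz_schedule(16), t_grid = 0:16)
#' @export
simulate_adaptive <- function(params, schedule, t_grid, delta_a = 0.05,
                              readout = readout_params(), drug = "TMZ",
                              tsa_drug = NULL, kappa_tsa = 0,
                              snapshot_days = NULL) {
  stopifnot(inherits(params, "adaptive_params"),
            inherits(schedule, "treatment_schedule"), kappa_tsa >= 0,
            delta_a > 0)
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 1L || t_grid[1L] < 0 ||
      is.unsorted(t_grid, strictly = TRUE)) {
    stop("t_grid must be strictly increasing with t_grid[1] >= 0",
         call. = FALSE)
  }
  h <- delta_a
  t0 <- t_grid[1L]
  k_rec <- round((t_grid - t0) / h)
  if (any(abs(t0 + k_rec * h - t_grid) > 1e-9)) {
    stop("delta_a must divide the t_grid spacing", call. = FALSE)
  }
  n_steps <- k_rec[length(k_rec)]
  n_bins <- max(2L, as.integer(round(params$a_max / h)))

  gbar <- gamma_bar_bins(params, h, n_bins)
  snap_k <- if (is.null(snapshot_days)) integer(0) else
    round((as.numeric(snapshot_days) - t0) / h)

  S <- params$N0; R <- 0
  m <- numeric(n_bins)  # cell mass per age bin
  rec <- matrix(0, nrow = length(t_grid), ncol = 3L,
                dimnames = list(NULL, c("S", "TR", "R")))
  snaps <- list()
  record <- function(k, S, m, R) {
    i <- match(k, k_rec)
    if (!is.na(i)) rec[i, ] <<- c(S, sum(m), R)
    if (k %in% snap_k) {
      snaps[[length(snaps) + 1L]] <<- data.frame(
        day = t0 + k * h, age = (seq_len(n_bins) - 0.5) * h, density = m / h)
    }
  }
  record(0L, S, m, R)

  # step factors cached across steps with identical exposures
  last_u <- NA_real_; last_utsa <- NA_real_
  f <- conv_frac <- NULL
  fS <- inflow_coef <- fR <- fR_half <- NULL

  for (k in seq_len(n_steps)) {
    t_mid <- t0 + (k - 0.5) * h
    u <- drug_exposure(schedule, drug, t_mid)
    u_tsa <- if (is.null(tsa_drug)) 0 else
      drug_exposure(schedule, tsa_drug, t_mid)
    if (!identical(u, last_u) || !identical(u_tsa, last_utsa)) {
      mu_eff <- params$mu_TR + kappa_tsa * u_tsa
      lam <- mu_eff + gbar - params$rho_TR
      f <- exp(-lam * h)
      conv_frac <- ifelse(abs(lam) > 1e-14, gbar * (1 - f) / lam, gbar * h)
      u_entry <- if (params$drug_gated_entry) u else 1
      r_S <- params$rho_S - params$delta_S * u - params$beta * u_entry
      fS <- exp(r_S * h)
      inflow_coef <- if (abs(r_S) > 1e-14) {
        params$beta * u_entry * (fS - 1) / r_S
      } else params$beta * u_entry * h
      r_R <- params$rho_R - params$delta_R * u
      fR <- exp(r_R * h); fR_half <- exp(r_R * h / 2)
      last_u <- u; last_utsa <- u_tsa
    }
    converted <- sum(m * conv_frac)
    m_f <- m * f
    inflow <- S * inflow_coef
    m <- c(inflow, m_f[-n_bins])
    m[n_bins] <- m[n_bins] + m_f[n_bins]
    S <- S * fS
    R <- R * fR + converted * fR_half
    record(k, S, m, R)
  }

  mg <- mgmt_readout(pmax(rec[, "S"], 0), pmax(rec[, "TR"], 0),
                     pmax(rec[, "R"], 0), readout)
  new_trajectory(t_grid, rec[, "S"], rec[, "TR"], rec[, "R"], mg,
                 model_id = "adaptive",
                 age_snapshots = if (length(snaps)) do.call(rbind, snaps),
                 params = params)
}

#' Transient-state-targeted intervention (HDAC-inhibitor analogue)
#'
#' Adds a kill rate acting only on the transient compartment while the
#' `"TSA"` exposure in `schedule` is active, emulating combination of the
#' chemotherapy course with trichostatin A, which selectively eliminates
#' persister cells. With `kappa_tsa = 0` the result is identical to
#' [simulate_adaptive()].
#'
#' @inheritParams simulate_adaptive
#' @param kappa_tsa TR-specific kill rate at full TSA exposure, per day.
#' @param tsa_drug schedule entry carrying the TSA exposure.
#' @return a `trajectory`.
#' @export
tsa_intervention <- function(params, schedule, t_grid, kappa_tsa,
                             delta_a = 0.05, readout = readout_params(),
                             drug = "TMZ", tsa_drug = "TSA",
                             snapshot_days = NULL) {
  simulate_adaptive(params, schedule, t_grid, delta_a = delta_a,
                    readout = readout, drug = drug, tsa_drug = tsa_drug,
                    kappa_tsa = kappa_tsa, snapshot_days = snapshot_days)
}
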