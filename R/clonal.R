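#' Parameters of the clonal-selection model
#'
#' Two-compartment ODE framework in which a resistant subpopulation of
#' initial fraction `f_R0` pre-exists and is selected by treatment:
#' \deqn{dS/dt = \rho_S S g(N) - \delta_S u(t) S, \quad
#'       dR/dt = \rho_R R g(N) - \delta_R u(t) R,}
#' with `u(t)` the unitless drug exposure, `g(N) = 1` by default or the
#' logistic factor `1 - N/K` when a carrying capacity `K` is supplied.
#' Proliferation and baseline death are merged into the net rates `rho_*`;
#' drug effect is a separate additive death term gated by exposure.
#'
#' @param rho_S,rho_R net proliferation rates of sensitive / resistant
#'   cells, per day, >= 0.
#' @param delta_S,delta_R drug-induced death rates at full exposure, per
#'   day; resistance means `delta_R <= delta_S`.
#' @param f_R0 initial resistant fraction, in `[0, 1)`.
#' @param N0 initial total population, cells > 0.
#' @param K carrying capacity in cells (default `Inf`: exponential growth).
#' @return an object of class `clonal_params`.
#' @export
clonal_params <- function(rho_S = 0.4, rho_R = 0.44, delta_S = 0.50,
                          delta_R = 0.03, f_R0 = 0.004, N0 = 1e5, K = Inf) {
  stopifnot(rho_S >= 0, rho_R >= 0, delta_S >= 0, delta_R >= 0,
            f_R0 >= 0, f_R0 < 1, N0 > 0, K > 0)
  if (delta_R > delta_S) {
    stop("delta_R must not exceed delta_S (resistant cells die less under drug)",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "clonal_params")
}

#' Simulate the clonal-selection model
#'
#' Integrates the two-compartment selection ODE over `t_grid` under the
#' exposure encoded by `schedule`. When growth is exponential (`K = Inf`)
#' and all schedule entries use window exposure, the system is linear with
#' piecewise-constant coefficients and is propagated exactly (piecewise
#' matrix exponential, here scalar exponentials since S and R decouple).
#' Otherwise stiff-safe adaptive integration (`deSolve::lsoda`) is used,
#' restarted at every exposure discontinuity so doses are never stepped
#' over.
#'
#' @param params a [clonal_params()] object.
#' @param schedule a [treatment_schedule()].
#' @param t_grid strictly increasing output times, days, `t_grid[1] >= 0`.
#'   Simulation starts at `t_grid[1]` from `N0`.
#' @param readout a [readout_params()] object for the attached MGMT channel.
#' @param drug schedule entry providing the cytotoxic exposure
#'   (default `"TMZ"`).
#' @param rtol,atol solver tolerances (adaptive path only).
#' @return a `trajectory` with `TR = 0` throughout.
#' @examples
#' sched <- tmz_schedule(16)
#' tr <- simulate_clonal(clonal_params(), sched, t_grid = 0:16)
#' @export
simulate_clonal <- function(params, schedule, t_grid,
                            readout = readout_params(), drug = "TMZ",
                            rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "clonal_params"),
            inherits(schedule, "treatment_schedule"))
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 1L || t_grid[1L] < 0 ||
      is.unsorted(t_grid, strictly = TRUE)) {
    stop("t_grid must be strictly increasing with t_grid[1] >= 0",
         call. = FALSE)
  }
  S0 <- params$N0 * (1 - params$f_R0)
  R0 <- params$N0 * params$f_R0

  all_window <- all(vapply(schedule$entries, function(e) e$mode == "window",
                           logical(1)))
  if (is.infinite(params$K) && all_window) {
    out <- clonal_piecewise_exact(params, schedule, t_grid, drug, S0, R0)
  } else {
    out <- clonal_desolve(params, schedule, t_grid, drug, S0, R0, rtol, atol)
  }
  S <- pmax(out$S, 0); R <- pmax(out$R, 0)
  mg <- mgmt_readout(S, 0, R, readout)
  new_trajectory(t_grid, S, rep(0, length(t_grid)), R, mg,
                 model_id = "clonal", params = params)
}

# Exact propagation: within each interval between exposure breakpoints the
# exposure is constant, so S and R evolve as plain exponentials.
clonal_piecewise_exact <- function(params, schedule, t_grid, drug, S0, R0) {
  t0 <- t_grid[1L]; t1 <- t_grid[length(t_grid)]
  brk <- c(t0, exposure_breakpoints(schedule, t0, t1), t1)
  S <- numeric(length(t_grid)); R <- numeric(length(t_grid))
  s <- S0; r <- R0
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    u <- drug_exposure(schedule, drug, (a + b) / 2)
    rs <- params$rho_S - params$delta_S * u
    rr <- params$rho_R - params$delta_R * u
    inside <- which(t_grid >= a - 1e-12 & t_grid <= b + 1e-12)
    S[inside] <- s * exp(rs * (t_grid[inside] - a))
    R[inside] <- r * exp(rr * (t_grid[inside] - a))
    s <- s * exp(rs * (b - a)); r <- r * exp(rr * (b - a))
  }
  # t0 itself (loop writes it from the first segment, but be explicit)
  S[1L] <- S0; R[1L] <- R0
  list(S = S, R = R)
}

clonal_desolve <- function(params, schedule, t_grid, drug, S0, R0,
                           rtol, atol) {
  t0 <- t_grid[1L]; t1 <- t_grid[length(t_grid)]
  brk <- c(t0, exposure_breakpoints(schedule, t0, t1), t1)
  deriv <- function(t, y, parms) {
    u <- drug_exposure(schedule, drug, t)
    g <- if (is.infinite(params$K)) 1 else 1 - (y[1L] + y[2L]) / params$K
    list(c(params$rho_S * y[1L] * g - params$delta_S * u * y[1L],
           params$rho_R * y[2L] * g - params$delta_R * u * y[2L]))
  }
  y <- c(S = S0, R = R0)
  Sout <- numeric(length(t_grid)); Rout <- numeric(length(t_grid))
  Sout[1L] <- S0; Rout[1L] <- R0
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    times <- sort(unique(c(a, t_grid[t_grid > a & t_grid <= b], b)))
    sol <- deSolve::lsoda(y, times, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0) {
      stop(sprintf(
        "clonal solver failure in [%g, %g] at params rho_S=%g rho_R=%g delta_S=%g delta_R=%g f_R0=%g",
        a, b, params$rho_S, params$rho_R, params$delta_S, params$delta_R,
        params$f_R0), call. = FALSE)
    }
    idx <- match(round(t_grid, 12L), round(sol[, "time"], 12L))
    take <- which(!is.na(idx) & t_grid > a)
    Sout[take] <- sol[idx[take], "S"]
    Rout[take] <- sol[idx[take], "R"]
    y <- c(S = sol[nrow(sol), "S"], R = sol[nrow(sol), "R"])
  }
  list(S = Sout, R = Rout)
}
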