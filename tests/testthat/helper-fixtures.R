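# Shared fixtures, built in code.

tmz16 <- tmz_schedule(16)
no_drug <- treatment_schedule(
  schedule_entry("placebo", 0, "window", window_days = 0))
obs_days5 <- c(0, 4, 9, 12, 16)

# noise-free single-replicate dataset from a trajectory
dataset_from_trajectory <- function(traj, schedule) {
  time_course_dataset(
    data.frame(replicate_id = "rep1", day = traj$day, count = traj$total,
               mgmt_fold = traj$mgmt),
    schedule = schedule)
}

# independent fixed-step RK4 integrator for the clonal ODE (test oracle)
rk4_clonal <- function(params, schedule, t_end, dt = 1e-3, drug = "TMZ") {
  n <- ceiling(t_end / dt)
  y <- c(params$N0 * (1 - params$f_R0), params$N0 * params$f_R0)
  deriv <- function(t, y) {
    u <- drug_exposure(schedule, drug, t)
    g <- if (is.infinite(params$K)) 1 else 1 - sum(y) / params$K
    c(params$rho_S * y[1] * g - params$delta_S * u * y[1],
      params$rho_R * y[2] * g - params$delta_R * u * y[2])
  }
  t <- 0
  for (i in seq_len(n)) {
    h <- min(dt, t_end - t)
    k1 <- deriv(t, y)
    k2 <- deriv(t + h / 2, y + h / 2 * k1)
    k3 <- deriv(t + h / 2, y + h / 2 * k2)
    k4 <- deriv(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  c(S = y[1], R = y[2], total = sum(y))
}
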