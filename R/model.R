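#' Clock-gated starch degradation rate
#'
#' Closed-form diel profile of the starch degradation rate that realizes
#' sucrose homeostasis when the subjective photoperiod matches the external
#' one. The profile is set by the internal schedule: it decreases over the
#' subjective light phase `[0, tau_L)`, increases over the subjective dark
#' phase `[tau_L, 1)`, and peaks at dawn (the dark-side limit t -> 1, value
#' `a * tau_L * beta_p^kappa`). When `tau_L < 1 - gamma` (extremely short
#' subjective photoperiod) sucrose homeostasis cannot be maintained and the
#' light-phase rate is 0.
#'
#' @param core a [core_params()] object.
#' @param cond a [condition_params()] object.
#' @param t time of day as a fraction in \[0, 1); dawn at 0. Vectorized.
#' @return Numeric vector of degradation rates (>= 0).
#' @export
#' @examples
#' co <- core_params(a = 1, gamma = 0.5, beta_p = 1)
#' cn <- condition_params(H = 2, tau_L = 2 / 3, photoperiod = 2 / 3)
#' degradation_rate(co, cn, c(0, 0.5, 0.999))
degradation_rate <- function(core, cond, t) {
  stopifnot(inherits(core, "core_params"), inherits(cond, "condition_params"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop_("`t` must be finite numeric")
  if (any(t < 0 | t >= 1))
    stop_("`t` must lie in [0, 1) (time of day as a day fraction)")
  cpp_beta_gate(t, core$a, core$gamma, core$beta_p, core$kappa, cond$tau_L)
}

# Degradation rate at ZT hours on [0, 24]. Dawn convention: ZT0 and ZT24 take
# the dark-side limit (the daily peak), because ZT0 harvests precede lights-on.
beta_at_zt <- function(core, cond, zt_hours) {
  if (any(zt_hours < 0 | zt_hours > 24))
    stop_("`zt_hours` must lie within [0, 24]")
  tod <- zt_hours / 24
  dawn <- zt_hours == 0 | zt_hours == 24
  out <- numeric(length(tod))
  if (any(!dawn))
    out[!dawn] <- cpp_beta_gate(tod[!dawn], core$a, core$gamma, core$beta_p,
                                core$kappa, cond$tau_L)
  # dark branch at t = 1: a * tauL * beta_p^kappa
  out[dawn] <- core$a * cond$tau_L * core$beta_p^core$kappa
  out
}

#' Right-hand side of the starch-sucrose ODE system
#'
#' Under external light, starch gains `a * gamma` and loses the degradation
#' flux `beta_t * C^kappa`; sucrose gains `a * (1 - gamma)` plus the
#' degradation flux and is consumed at rate `H * S`. In the dark the
#' photosynthesis terms vanish. The degradation flux is evaluated with
#' `max(C, 0)` so starch can never be driven negative by it.
#'
#' @param state numeric `c(C, S)`, both >= 0.
#' @param t time of day as a fraction in \[0, 1).
#' @param core,cond model parameters; the external photoperiod in `cond`
#'   decides the light/dark branch.
#' @param beta_fn optional function `t -> rate` overriding the closed-form
#'   degradation profile.
#' @return Numeric `c(dC, dS)`.
#' @export
ode_rhs <- function(state, t, core, cond, beta_fn = NULL) {
  if (length(state) != 2L || any(!is.finite(state)))
    stop_("`state` must be finite c(C, S)")
  if (any(state < 0)) stop_("negative state: C and S must be >= 0")
  check_scalar(t, "t", 0, 1)
  if (t >= 1) stop_("`t` must lie in [0, 1)")
  beta <- if (is.null(beta_fn)) {
    degradation_rate(core, cond, t)
  } else {
    beta_fn(t)
  }
  deg <- beta * max(state[1], 0)^core$kappa
  light <- t < cond$photoperiod
  if (light) {
    c(core$a * core$gamma - deg,
      core$a * (1 - core$gamma) + deg - cond$H * state[2])
  } else {
    c(-deg, deg - cond$H * state[2])
  }
}

#' Homeostatic initial state
#'
#' The steady diel solution when degradation is perfectly adjusted to the
#' photoperiod: residual starch at dawn `C(0) = 1 / beta_p` and constant
#' sucrose `S(0) = a * tau_L / H`.
#'
#' @inheritParams degradation_rate
#' @return Named numeric `c(C0, S0)`.
#' @export
homeostatic_initial_state <- function(core, cond) {
  stopifnot(inherits(core, "core_params"), inherits(cond, "condition_params"))
  c(C0 = 1 / core$beta_p, S0 = core$a * cond$tau_L / cond$H)
}

#' Simulate the diel starch-sucrose trajectory
#'
#' Fixed-step fourth-order Runge-Kutta integration of the piecewise ODE
#' system over `n_days` days, starting from the homeostatic initial state.
#' Integration restarts at every light/dark switch (both the external
#' photoperiod boundary and the subjective dusk of the degradation profile),
#' so no step straddles a discontinuity. The degradation flux within a step is
#' capped so starch cannot go negative; a warning reports any capped step.
#'
#' @param theta a [theta_full()] parameter set.
#' @param condition `"LD"` or `"SD"`.
#' @param n_days number of simulated days (>= 1); the default 6 with the final
#'   three days past the initial-condition transient.
#' @param dt nominal step size in days; default 1/1440 (one minute). Segments
#'   between switch points are subdivided into equal steps no longer than `dt`.
#' @param init optional `c(C0, S0)` overriding the homeostatic initial state.
#' @return A tibble of class `diel_trajectory` with columns `time` (days),
#'   `day`, `zt_hour`, `C`, `S`.
#' @export
simulate_trajectory <- function(theta, condition = "LD", n_days = 6,
                                dt = 1 / 1440, init = NULL) {
  stopifnot(inherits(theta, "theta_full"))
  if (n_days < 1 || n_days != round(n_days)) stop_("`n_days` must be integer >= 1")
  check_scalar(dt, "dt", 0, 1, strict_lower = TRUE)
  cond <- cond_of(theta, condition)
  if (is.null(init)) init <- homeostatic_initial_state(theta$core, cond)
  times <- seq(0, n_days, by = dt)
  sim <- cpp_simulate(theta$core$a, theta$core$gamma, theta$core$beta_p,
                      theta$core$kappa, cond$H, cond$tau_L, cond$photoperiod,
                      init[[1]], init[[2]], as.integer(n_days), dt, times)
  if (!sim$ok)
    stop_("integration blew up (non-finite state); parameters: a=",
          theta$core$a, " gamma=", theta$core$gamma, " beta_p=",
          theta$core$beta_p, " H=", cond$H, " tau_L=", cond$tau_L)
  if (sim$n_capped > 0)
    warning("degradation flux cap bound at ", sim$n_capped,
            " RK4 stage evaluations", call. = FALSE)
  day <- pmin(floor(times), n_days - 1)
  out <- tibble::tibble(time = times, day = as.integer(day),
                        zt_hour = 24 * (times - day), C = sim$C, S = sim$S)
  class(out) <- c("diel_trajectory", class(out))
  attr(out, "condition") <- cond$label
  out
}

#' Model-predicted starch and sucrose at sampled ZT hours
#'
#' Simulates `n_days` days (default 6) and evaluates the trajectory at the
#' requested ZT offsets within the final simulated day, past the
#' initial-condition transient. These are the model means used by the
#' likelihood. ZT 24 maps to the end point of the day.
#'
#' @inheritParams simulate_trajectory
#' @param zt_hours sample times in hours within \[0, 24\].
#' @param eval_day day (1-based) whose profile is returned; default `n_days`.
#' @return A tibble with columns `zt_hour`, `starch`, `sucrose`.
#' @export
predicted_profile <- function(theta, condition = "LD", zt_hours, n_days = 6,
                              dt = 1 / 1440, eval_day = n_days) {
  stopifnot(inherits(theta, "theta_full"))
  if (any(zt_hours < 0 | zt_hours > 24)) stop_("`zt_hours` must be in [0, 24]")
  if (eval_day < 1 || eval_day > n_days) stop_("`eval_day` outside 1..n_days")
  cond <- cond_of(theta, condition)
  init <- homeostatic_initial_state(theta$core, cond)
  times <- (eval_day - 1) + zt_hours / 24
  ord <- order(times)
  sim <- cpp_simulate(theta$core$a, theta$core$gamma, theta$core$beta_p,
                      theta$core$kappa, cond$H, cond$tau_L, cond$photoperiod,
                      init[[1]], init[[2]], as.integer(n_days), dt,
                      times[ord])
  if (!sim$ok) stop_("integration blew up (non-finite state)")
  C <- S <- numeric(length(times))
  C[ord] <- sim$C
  S[ord] <- sim$S
  tibble::tibble(zt_hour = zt_hours, starch = C, sucrose = S)
}
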