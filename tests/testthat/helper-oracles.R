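# Independent numerical oracles used across the suite. These deliberately do
# not reuse the package's closed forms or compiled integrator.

# Homeostatic degradation profile solved numerically: on the orbit with
# tau_L = P the sucrose balance dS/dt = 0 fixes the degradation flux at each
# instant, and starch follows the linear orbit of the sucrose-homeostasis
# identity (dC/dt = a - H*S0 under light, -H*S0 under dark). beta is the
# required flux divided by C^kappa, with C obtained by explicit quadrature of
# the piecewise-constant slope (no closed form used).
oracle_beta_homeostatic <- function(a, gamma, H, beta_p, tau, t,
                                    kappa = 2 / 3, n_grid = 200000) {
  S0 <- a * tau / H
  slope <- function(u) ifelse(u < tau, a - H * S0, -H * S0)
  # quadrature for C(t) from C(0) = 1/beta_p, split at the dusk kink
  C_piece <- function(from, to) {
    if (to <= from) return(0)
    grid <- seq(from, to, length.out = max(2, ceiling(n_grid * (to - from))))
    mid <- (grid[-1] + grid[-length(grid)]) / 2
    sum(slope(mid) * diff(grid))
  }
  C_at <- function(tt) {
    1 / beta_p + C_piece(0, min(tt, tau)) + C_piece(tau, tt)
  }
  flux <- function(u) {
    if (u < tau) H * S0 - a * (1 - gamma) else H * S0
  }
  vapply(t, function(tt) {
    f <- flux(tt)
    max(f, 0) / C_at(tt)^kappa
  }, numeric(1))
}

# Analytic orbit of the sucrose-homeostasis identity: S constant, C piecewise
# linear with slopes a(1 - tau) (light) and -a*tau (dark).
oracle_orbit_C <- function(a, beta_p, tau, t) {
  ifelse(t < tau, 1 / beta_p + a * (1 - tau) * t,
         1 / beta_p + a * (1 - tau) * tau - a * tau * (t - tau))
}

# Brute-force WAIC: direct transcription of the formula without log-sum-exp.
oracle_waic <- function(ll) {
  M <- nrow(ll)
  t1 <- -2 * sum(log(colMeans(exp(ll))))
  t2 <- 2 * sum(apply(ll, 2, var))
  list(waic = t1 + t2, lppd_term = t1, penalty_term = t2)
}

# Random valid parameter set on the homeostatic orbit (tau_L = P >= 1 - gamma)
random_homeostatic_theta <- function() {
  P_ld <- runif(1, 0.45, 0.75)
  P_sd <- runif(1, 0.2, 0.45)
  gamma <- runif(1, 1 - P_sd, 0.95)  # both conditions above the zero-light rule
  theta_full(
    core = core_params(a = runif(1, 0.5, 2), gamma = gamma,
                       beta_p = runif(1, 0.5, 4)),
    ld = condition_params(H = runif(1, 1, 5), tau_L = P_ld, photoperiod = P_ld,
                          label = "LD"),
    sd = condition_params(H = runif(1, 1, 5), tau_L = P_sd, photoperiod = P_sd,
                          label = "SD"),
    sigma_c2 = 1e-4, sigma_s2 = 1e-4
  )
}

# Small noiseless paired dataset from a theta (single batch, no dispersion)
noiseless_pair <- function(theta, seed = 1) {
  th0 <- theta
  th0$sigma_c2 <- 1e-12
  th0$sigma_s2 <- 1e-12
  des <- study_design(n_batches = 1, batch_dispersion = 0, seed = seed)
  ld <- predicted_profile(theta, "LD", des$ld_zts)
  sd_ <- predicted_profile(theta, "SD", des$sd_zts)
  list(ld = diel_series(des$ld_zts, ld$starch, ld$sucrose, condition = "LD"),
       sd = diel_series(des$sd_zts, sd_$starch, sd_$sucrose,
                        condition = "SD"))
}
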