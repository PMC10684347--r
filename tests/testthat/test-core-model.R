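co_ref <- core_params(a = 1, gamma = 0.5, beta_p = 1)
cn_ref <- condition_params(H = 2, tau_L = 2 / 3, photoperiod = 2 / 3)

test_that("closed-form degradation rate matches hand-derived anchor values", {
  # dawn (dark-side limit): a * tauL * beta_p^kappa
  expect_equal(degradation_rate(co_ref, cn_ref, 1 - 1e-12), 2 / 3,
               tolerance = 1e-9)
  # light onset: a * (gamma - 1 + tauL) * beta_p^kappa
  expect_equal(degradation_rate(co_ref, cn_ref, 0), 1 / 6, tolerance = 1e-12)
  # tau_L = 1 - gamma boundary: light-phase numerator vanishes
  cn0 <- condition_params(H = 2, tau_L = 0.5, photoperiod = 0.5)
  expect_equal(degradation_rate(co_ref, cn0, c(0, 0.2, 0.49)), rep(0, 3))
  # below the boundary (extremely short subjective photoperiod): clamped to 0
  cn_short <- condition_params(H = 2, tau_L = 0.3, photoperiod = 0.3)
  expect_equal(degradation_rate(co_ref, cn_short, 0.1), 0)
  expect_gt(degradation_rate(co_ref, cn_short, 0.9), 0)
})

test_that("degradation rate validates its time domain and parameters", {
  expect_error(degradation_rate(co_ref, cn_ref, 1), "\\[0, 1\\)")
  expect_error(degradation_rate(co_ref, cn_ref, -0.1), "\\[0, 1\\)")
  expect_error(degradation_rate(co_ref, cn_ref, NaN), "finite")
  expect_error(core_params(a = -1, gamma = 0.5, beta_p = 1), "domain")
  expect_error(core_params(a = 1, gamma = 1.2, beta_p = 1), "domain")
  expect_error(condition_params(H = 0, tau_L = 0.5, photoperiod = 0.5), "domain")
})

test_that("closed-form beta agrees with the numerical homeostasis oracle", {
  withr::with_seed(42, {
    for (rep in 1:3) {
      a <- runif(1, 0.5, 2)
      gamma <- runif(1, 0.4, 0.9)
      H <- runif(1, 1, 4)
      beta_p <- runif(1, 0.5, 3)
      tau <- runif(1, max(1 - gamma, 0.2), 0.8)
      co <- core_params(a, gamma, beta_p)
      cn <- condition_params(H, tau, tau)
      ts <- seq(0.002, 0.998, length.out = 100)
      got <- degradation_rate(co, cn, ts)
      want <- oracle_beta_homeostatic(a, gamma, H, beta_p, tau, ts)
      expect_equal(got, want, tolerance = 1e-6)
    }
    # the tau_L = 1 - gamma zero-light boundary
    gamma <- 0.6
    tau <- 0.4
    co <- core_params(1.3, gamma, 2)
    cn <- condition_params(2.5, tau, tau)
    ts <- seq(0.002, 0.998, length.out = 100)
    expect_equal(degradation_rate(co, cn, ts),
                 oracle_beta_homeostatic(1.3, gamma, 2.5, 2, tau, ts),
                 tolerance = 1e-6)
  })
})

test_that("beta profile is monotone within phases and peaks at dawn", {
  tl <- seq(0, cn_ref$tau_L - 1e-9, length.out = 200)
  td <- seq(cn_ref$tau_L, 1 - 1e-9, length.out = 200)
  bl <- degradation_rate(co_ref, cn_ref, tl)
  bd <- degradation_rate(co_ref, cn_ref, td)
  expect_true(all(diff(bl) <= 0))
  expect_true(all(diff(bd) >= 0))
  expect_equal(max(c(bl, bd)), bd[length(bd)])  # supremum at the dawn limit
})

test_that("ode_rhs implements the piecewise balance equations", {
  # C = 0: degradation term vanishes
  expect_equal(ode_rhs(c(0, 0.1), 0.1, co_ref, cn_ref,
                       beta_fn = function(t) 5)[1], co_ref$a * co_ref$gamma)
  dark <- ode_rhs(c(0, 0.1), 0.9, co_ref, cn_ref, beta_fn = function(t) 5)
  expect_equal(dark[1], 0)
  # direct substitution under light
  co <- core_params(a = 1, gamma = 0.4, beta_p = 1)
  cn <- condition_params(H = 2, tau_L = 0.5, photoperiod = 0.5)
  # choose beta so that beta * C^kappa = 0.1
  C <- 0.3
  beta <- 0.1 / C^co$kappa
  got <- ode_rhs(c(C, 0.2), 0.25, co, cn, beta_fn = function(t) beta)
  expect_equal(got, c(0.3, 0.3), tolerance = 1e-12)
  expect_error(ode_rhs(c(-0.1, 0.2), 0.25, co, cn), "negative state")
})

test_that("homeostatic initial state follows the steady solution", {
  expect_equal(homeostatic_initial_state(co_ref, cn_ref),
               c(C0 = 1, S0 = 1 / 3))
  expect_equal(homeostatic_initial_state(
    core_params(1, 0.5, beta_p = 4), cn_ref)[["C0"]], 0.25)
  expect_equal(homeostatic_initial_state(
    core_params(2, 0.5, 1), condition_params(1, 2 / 3, 0.5))[["S0"]], 4 / 3)
})

test_that("homeostasis identity: matched tau_L yields constant sucrose and
           piecewise-linear starch", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      th <- random_homeostatic_theta()
      for (cc in c("LD", "SD")) {
        cond <- if (cc == "LD") th$ld else th$sd
        tr <- simulate_trajectory(th, cc, n_days = 6)
        S0 <- th$core$a * cond$tau_L / cond$H
        expect_lt(max(abs(tr$S - S0)) / S0, 1e-6)
        # starch piecewise linear: matches the analytic orbit on every day
        tod <- tr$time - floor(pmin(tr$time, 6 - 1e-12))
        want <- oracle_orbit_C(th$core$a, th$core$beta_p, cond$tau_L, tod)
        expect_equal(tr$C, want, tolerance = 1e-6)
      }
    }
  })
})

test_that("daily carbon balance holds on the homeostatic orbit", {
  withr::with_seed(3, {
    th <- random_homeostatic_theta()
    cond <- th$ld
    # integral of fixation into starch over light = integral of degradation
    # flux over the day; flux = beta * C^kappa along the orbit
    f <- function(t) {
      degradation_rate(th$core, cond, t) *
        oracle_orbit_C(th$core$a, th$core$beta_p, cond$tau_L, t)^th$core$kappa
    }
    flux_day <- stats::integrate(Vectorize(f), 0, cond$tau_L,
                                 rel.tol = 1e-10)$value +
      stats::integrate(Vectorize(f), cond$tau_L, 1, rel.tol = 1e-10)$value
    fix_light <- th$core$a * th$core$gamma * cond$tau_L
    expect_equal(flux_day, fix_light, tolerance = 1e-6)
  })
})

test_that("RK4 trajectory converges at fixed order under step halving", {
  th <- default_theta()
  t1 <- simulate_trajectory(th, "LD", n_days = 3, dt = 1 / 720)
  t2 <- simulate_trajectory(th, "LD", n_days = 3, dt = 1 / 1440)
  common <- intersect(t1$time, t2$time)
  i1 <- match(common, t1$time)
  i2 <- match(common, t2$time)
  expect_lt(max(abs(t1$C[i1] - t2$C[i2]) / pmax(abs(t2$C[i2]), 1)), 1e-8)
  expect_lt(max(abs(t1$S[i1] - t2$S[i2]) / pmax(abs(t2$S[i2]), 1)), 1e-8)
})

test_that("increasing beta_p decreases residual starch at dawn", {
  dawn_c <- vapply(c(1, 2, 4), function(bp) {
    th <- default_theta()
    th$core$beta_p <- bp
    tr <- simulate_trajectory(th, "SD", n_days = 6, dt = 1 / 1440)
    tr$C[nrow(tr)]
  }, numeric(1))
  expect_true(all(diff(dawn_c) < 0))
})

test_that("predicted_profile is periodic on-orbit and detects broken
           homeostasis", {
  th <- default_theta(tauL_LD = 16 / 24)  # on-orbit under LD
  zts <- c(0, 1, 2, 4, 8, 12, 15, 16, 20, 23, 24)
  pp <- predicted_profile(th, "LD", zts)
  expect_equal(pp$starch[zts == 0], pp$starch[zts == 24], tolerance = 1e-7)
  expect_lt(max(abs(pp$sucrose - th$core$a * th$ld$tau_L / th$ld$H)), 1e-6)
  # off-orbit (tau_L != photoperiod): sucrose oscillates
  th2 <- default_theta(tauL_LD = 14 / 24)
  pp2 <- predicted_profile(th2, "LD", zts)
  expect_gt(max(pp2$sucrose) - min(pp2$sucrose), 1e-3)
  expect_error(predicted_profile(th, "LD", c(-1, 5)), "\\[0, 24\\]")
})
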