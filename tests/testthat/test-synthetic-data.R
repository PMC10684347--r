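test_that("zero-noise, zero-dispersion generation reproduces the model means", {
  th <- default_theta(sigma_c = 1e-9, sigma_s = 1e-9)
  des <- study_design(n_batches = 2, batch_dispersion = 0, seed = 1)
  out <- generate_wildtype(th, des)
  expect_length(out, 4)  # LD + SD per batch
  for (s in out) {
    mu <- predicted_profile(th, s$condition[1], s$zt_hour)
    expect_equal(s$starch, mu$starch, tolerance = 1e-6)
    expect_equal(s$sucrose, mu$sucrose, tolerance = 1e-6)
  }
})

test_that("generation is reproducible under the design seed", {
  des <- study_design(n_batches = 2, seed = 99)
  a <- generate_wildtype(design = des)
  b <- generate_wildtype(design = des)
  expect_identical(lapply(a, as.data.frame), lapply(b, as.data.frame))
  # and a zero-delta mutant equals wild type under the same seed
  m <- generate_mutant(default_theta(), c(a = 0), des, genotype = "WT")
  expect_equal(lapply(a, function(s) s[c("zt_hour", "starch", "sucrose")]),
               lapply(m, function(s) s[c("zt_hour", "starch", "sucrose")]))
})

test_that("noise calibration: empirical residual SD matches sigma", {
  sigma_c <- 0.5
  # concentrations scaled well above sigma so the truncation at 0 is inert
  th <- default_theta(sigma_c = sigma_c, sigma_s = 0.25)
  th$core$a <- 10
  th$core$beta_p <- 0.5
  des <- study_design(n_batches = 455, batch_dispersion = 0, seed = 5)
  out <- generate_wildtype(th, des)
  mu_ld <- predicted_profile(th, "LD", des$ld_zts)$starch
  mu_sd <- predicted_profile(th, "SD", des$sd_zts)$starch
  res <- unlist(lapply(out, function(s) {
    mu <- if (s$condition[1] == "LD") mu_ld else mu_sd
    s$starch - mu
  }))
  expect_gte(length(res), 10000)
  expect_gt(sd(res), 0.49)
  expect_lt(sd(res), 0.51)
  # moment check of normality: skewness ~ 0, excess kurtosis ~ 0
  z <- (res - mean(res)) / sd(res)
  expect_lt(abs(mean(z^3)), 0.08)
  expect_lt(abs(mean(z^4) - 3), 0.2)
})

test_that("batch dispersion acts on a and H with the configured spread", {
  th <- default_theta(sigma_c = 1e-9, sigma_s = 1e-9)
  des <- study_design(n_batches = 40, batch_dispersion = 0.2, seed = 11)
  out <- generate_wildtype(th, des)
  truth <- attr(out, "truth")
  a_vals <- vapply(truth, function(t) t$core$a, numeric(1))
  expect_gt(sd(log(a_vals)), 0.1)
  expect_lt(sd(log(a_vals)), 0.3)
  gamma_vals <- vapply(truth, function(t) t$core$gamma, numeric(1))
  expect_true(all(gamma_vals == th$core$gamma))  # only a and H vary
})

test_that("mutant generator validates the deviated parameter domain", {
  th <- default_theta()
  expect_error(generate_mutant(th, c(gamma = 0.5)), "gamma")
  expect_error(generate_mutant(th, c(beta_p = -5)), "beta_p")
  expect_error(generate_mutant(th, c(foo = 1)), "named")
  # all 128 masks with small in-domain deviations: in-domain theta or error,
  # never silent clipping
  masks <- enumerate_models(7)
  delta_unit <- c(a = 0.1, gamma = 0.05, H_LD = 0.2, tauL_LD = -1 / 24,
                  H_SD = 0.2, tauL_SD = 1 / 24, beta_p = -0.3)
  des <- study_design(n_batches = 1, batch_dispersion = 0, seed = 2)
  for (i in seq(1, 128, by = 9)) {
    d <- delta_unit[masks[i, ]]
    if (length(d) == 0) d <- c(a = 0)
    out <- generate_mutant(th, d, des)
    v_true <- dielstarch:::theta_vec(attr(out, "truth")[[1]])
    expect_length(dielstarch:::validate_theta_vec(v_true), 0)
  }
})

test_that("strong beta_p loss leaves more residual starch at end of night", {
  th <- default_theta(sigma_c = 1e-9, sigma_s = 1e-9)
  des <- study_design(n_batches = 1, batch_dispersion = 0, seed = 3)
  wt <- generate_wildtype(th, des)
  mt <- generate_mutant(th, c(beta_p = -0.75 * th$core$beta_p), des)
  wt_ld <- wt[[1]]
  mt_ld <- mt[[1]]
  expect_gt(mt_ld$starch[mt_ld$zt_hour == 24],
            wt_ld$starch[wt_ld$zt_hour == 24])
})

test_that("a tau_L deviation breaks sucrose homeostasis in that condition", {
  th <- default_theta(tauL_LD = 16 / 24, sigma_c = 1e-9, sigma_s = 1e-9)
  des <- study_design(n_batches = 1, batch_dispersion = 0, seed = 4)
  mt <- generate_mutant(th, c(tauL_LD = -2 / 24), des)
  s_ld <- mt[[1]]$sucrose
  expect_gt(max(s_ld) - min(s_ld), 1e-3)
})

test_that("synthetic maltose inverts to the generating degradation profile", {
  th <- default_theta(sigma_c = 1e-9, sigma_s = 1e-9)
  des <- study_design(n_batches = 1, batch_dispersion = 0, seed = 6)
  s <- generate_wildtype(th, des)[[1]]
  s <- generate_maltose(s, th, scale = 1, noise_sd = 0)
  beta_hat <- s$maltose / s$starch^th$core$kappa
  beta_true <- dielstarch:::beta_at_zt(th$core, th$ld, s$zt_hour)
  expect_equal(beta_hat, beta_true, tolerance = 1e-9)
  # scale invariance after max-1 standardization
  s10 <- generate_maltose(s, th, scale = 10, noise_sd = 0)
  p1 <- standardize_max1(estimate_beta(s$maltose, s$starch, s$zt_hour))
  p10 <- standardize_max1(estimate_beta(s10$maltose, s10$starch, s10$zt_hour))
  expect_equal(p1$beta, p10$beta, tolerance = 1e-12)
  # zero starch gives zero maltose
  s0 <- s
  s0$starch[3] <- 0
  expect_equal(generate_maltose(s0, th, 1, 0)$maltose[3], 0)
})
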