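test_that("log-likelihood equals the sum of independent Normal log-densities", {
  th <- default_theta()
  des <- study_design(n_batches = 1, batch_dispersion = 0, seed = 61)
  wt <- generate_wildtype(th, des)
  pair <- pair_series(wt, "WT", 1)
  cfg <- sampler_config()
  got <- log_likelihood(th, pair, cfg)
  # independent oracle: per-observation dnorm against predicted profiles
  mu_ld <- predicted_profile(th, "LD", pair$ld$zt_hour, dt = cfg$dt)
  mu_sd <- predicted_profile(th, "SD", pair$sd$zt_hour, dt = cfg$dt)
  want <- c(dnorm(pair$ld$starch, mu_ld$starch, sqrt(th$sigma_c2), log = TRUE),
            dnorm(pair$ld$sucrose, mu_ld$sucrose, sqrt(th$sigma_s2), log = TRUE),
            dnorm(pair$sd$starch, mu_sd$starch, sqrt(th$sigma_c2), log = TRUE),
            dnorm(pair$sd$sucrose, mu_sd$sucrose, sqrt(th$sigma_s2), log = TRUE))
  expect_equal(got$pointwise, want, tolerance = 1e-10)
  expect_equal(got$total, sum(want), tolerance = 1e-10)
})

test_that("zero-residual log-likelihood has the closed normalization form", {
  th <- default_theta()
  th$sigma_c2 <- 1
  th$sigma_s2 <- 1
  pair <- noiseless_pair(th)
  # observations equal the model means (generated at the solver's own grid)
  cfg <- sampler_config(dt = 1 / 1440)
  got <- log_likelihood(th, pair, cfg)
  N <- length(got$pointwise)
  expect_equal(got$total, -N / 2 * log(2 * pi), tolerance = 1e-7)
  # doubling the variance with zero residuals strictly decreases the loglik
  th2 <- th
  th2$sigma_c2 <- 2
  th2$sigma_s2 <- 2
  expect_lt(log_likelihood(th2, pair, cfg)$total, got$total)
})

test_that("kernel-density MAP estimates behave on known samples", {
  expect_warning(m <- map_estimate(rep(3, 500)), "degenerate")
  expect_equal(m, 3)
  withr::with_seed(63, {
    x <- rnorm(10000, 5, 1)
    expect_gt(map_estimate(x), 4.9)
    expect_lt(map_estimate(x), 5.1)
    bimod <- c(rnorm(7000, 0, 0.5), rnorm(3000, 4, 0.5))
    expect_lt(abs(map_estimate(bimod)), 0.3)  # heavier mode wins
  })
  expect_error(map_estimate(rnorm(50)), ">= 100")
})

test_that("HDI is the shortest interval at the requested mass", {
  withr::with_seed(63, x <- rexp(20000))
  h <- hdi(x, 0.9)
  expect_lt(h[["lower"]], 0.05)  # skewed density: HDI hugs zero
  expect_gt(mean(x >= h[1] & x <= h[2]), 0.88)
  expect_lt(mean(x >= h[1] & x <= h[2]), 0.92)
  # shorter than the central interval
  ci <- quantile(x, c(0.05, 0.95))
  expect_lt(diff(h), diff(ci) + 1e-9)
})

test_that("split R-hat and ESS flag stuck versus mixed chains", {
  withr::with_seed(64, {
    good <- matrix(rnorm(4000), 1000, 4)
    expect_lt(dielstarch:::split_rhat(good), 1.01)
    bad <- cbind(matrix(rnorm(3000), 1000, 3), rnorm(1000, 5))
    expect_gt(dielstarch:::split_rhat(bad), 1.5)
    expect_gt(dielstarch:::ess_bulk(good), 3000)
    ar <- matrix(0, 1000, 4)
    for (ch in 1:4) {
      e <- rnorm(1000)
      for (i in 2:1000) ar[i, ch] <- 0.9 * ar[i - 1, ch] + e[i]
    }
    expect_lt(dielstarch:::ess_bulk(ar), 1000)
  })
})

test_that("ESS broadly agrees with an established implementation", {
  skip_if_not_installed("coda")
  withr::with_seed(65, {
    ar <- matrix(0, 2000, 2)
    for (ch in 1:2) {
      e <- rnorm(2000)
      for (i in 2:2000) ar[i, ch] <- 0.7 * ar[i - 1, ch] + e[i]
    }
    ours <- dielstarch:::ess_bulk(ar)
    theirs <- sum(vapply(1:2, function(ch)
      unname(coda::effectiveSize(coda::mcmc(ar[, ch]))), numeric(1)))
    expect_lt(abs(ours - theirs) / theirs, 0.5)
  })
})

test_that("posterior recovery on clean data covers the generating values", {
  th <- default_theta(sigma_c = 0.005, sigma_s = 0.0025)
  wt <- generate_wildtype(th, study_design(n_batches = 1,
                                           batch_dispersion = 0, seed = 66))
  pair <- pair_series(wt, "WT", 1)
  fit <- sample_posterior(pair,
                          config = sampler_config(n_warmup = 400,
                                                  n_iter = 400),
                          seed = 67)
  sm <- summary(fit)
  truth <- dielstarch:::theta_vec(th)
  for (p in c("a", "H_LD", "tauL_LD", "H_SD", "tauL_SD", "beta_p")) {
    row <- sm[sm$parameter == p, ]
    expect_lt(abs(row$map - truth[[p]]) / truth[[p]], 0.1)
  }
  expect_lt(abs(24 * (sm$map[sm$parameter == "tauL_LD"] - th$ld$tau_L)), 1)
})

test_that("prior bounds excluding the truth pile mass at the bound", {
  th <- default_theta(sigma_c = 0.01, sigma_s = 0.005)
  wt <- generate_wildtype(th, study_design(n_batches = 1,
                                           batch_dispersion = 0, seed = 68))
  pair <- pair_series(wt, "WT", 1)
  pri <- default_priors(pair)
  pri$upper[["a"]] <- 0.8  # truth is a = 1
  fit <- sample_posterior(pair, priors = pri,
                          config = sampler_config(n_chains = 2,
                                                  n_warmup = 200,
                                                  n_iter = 200),
                          seed = 69)
  a_draws <- as.vector(fit$draws[, , "a"])
  # truth (a = 1) is outside the allowed (0, 0.8): mass hugs the upper bound
  expect_gt(mean(a_draws), 0.6)
  expect_gt(hdi(a_draws)[["upper"]], 0.78)
})

test_that("both MCMC backends target the same posterior", {
  # moderate noise: the posterior is wide enough that both random-walk
  # backends traverse it within test-sized runs (at very low noise the
  # target narrows to a curved ridge neither crosses quickly)
  th <- default_theta()
  wt <- generate_wildtype(th, study_design(n_batches = 1,
                                           batch_dispersion = 0, seed = 70))
  pair <- pair_series(wt, "WT", 1)
  f1 <- sample_posterior(pair, config = sampler_config(
    n_chains = 2, n_warmup = 500, n_iter = 1000, backend = "mwg"), seed = 71)
  f2 <- sample_posterior(pair, config = sampler_config(
    n_chains = 2, n_warmup = 1500, n_iter = 2500, backend = "rwm"), seed = 72)
  # Monte-Carlo SE via batch means (robust to residual autocorrelation that
  # the acf-based ESS underestimates on short random-walk chains)
  mcse_bm <- function(fit, p) {
    ms <- c()
    for (ch in seq_len(fit$n_chains)) {
      x <- fit$draws[, ch, p]
      b <- split(x, ceiling(seq_along(x) / (length(x) / 15)))
      ms <- c(ms, vapply(b, mean, numeric(1)))
    }
    sd(ms) / sqrt(length(ms))
  }
  for (p in c("a", "tauL_LD", "tauL_SD", "beta_p")) {
    d1 <- dielstarch:::pooled_draws(f1, p)
    d2 <- dielstarch:::pooled_draws(f2, p)
    mcse <- sqrt(mcse_bm(f1, p)^2 + mcse_bm(f2, p)^2)
    sd_pool <- sd(c(d1, d2))
    expect_lt(abs(mean(d1) - mean(d2)), 4 * mcse + 0.1 * sd_pool)
  }
})

test_that("fit_batch_set isolates failures and orders batch effects", {
  th <- default_theta(sigma_c = 0.01, sigma_s = 0.005)
  series <- list()
  for (i in seq_along(c(0.8, 1.0, 1.2))) {
    v <- dielstarch:::theta_vec(th)
    v["a"] <- v["a"] * c(0.8, 1.0, 1.2)[i]
    thb <- dielstarch:::theta_from_vec(v, th)
    b <- generate_wildtype(thb, study_design(n_batches = 1,
                                             batch_dispersion = 0,
                                             seed = 80 + i))
    for (s in b) s$batch <- as.character(i)
    series <- c(series, lapply(b, function(s) {
      s$batch <- as.character(i)
      s
    }))
  }
  # a batch with a missing SD series
  lone <- series[[1]]
  lone$batch <- "9"
  series <- c(series, list(lone))
  fits <- fit_batch_set(series, config = sampler_config(n_chains = 2,
                                                        n_warmup = 300,
                                                        n_iter = 300),
                        seed = 90)
  expect_length(fits, 4)
  expect_s3_class(fits[["WT.9"]], "error")
  expect_match(conditionMessage(fits[["WT.9"]]), "exactly one LD")
  a_maps <- vapply(c("WT.1", "WT.2", "WT.3"), function(k)
    map_estimate(fits[[k]], "a"), numeric(1))
  expect_true(all(diff(a_maps) > 0))
})
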