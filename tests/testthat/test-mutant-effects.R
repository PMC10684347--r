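PN <- dielstarch:::PARAM_NAMES

test_that("log2 fold change arithmetic and the 1.5 threshold", {
  wt <- stats::setNames(c(1, 0.7, 3, 0.7, 2, 1 / 3, 2), PN)
  expect_equal(log2_fold_change(wt, wt)$log2fc, rep(0, 7))
  expect_false(any(log2_fold_change(wt, wt)$significant))
  mut <- wt
  mut["a"] <- 2 * wt["a"]        # +1, not significant
  mut["beta_p"] <- wt["beta_p"] / 4  # -2, significant
  fc <- log2_fold_change(mut, wt)
  expect_equal(fc$log2fc[fc$parameter == "a"], 1)
  expect_false(fc$significant[fc$parameter == "a"])
  expect_equal(fc$log2fc[fc$parameter == "beta_p"], -2)
  expect_true(fc$significant[fc$parameter == "beta_p"])
  # inclusive boundary
  mut2 <- wt
  mut2["H_LD"] <- wt["H_LD"] * 2^1.5
  expect_true(log2_fold_change(mut2, wt)$significant[3])
  # antisymmetry
  expect_equal(log2_fold_change(mut, wt)$log2fc,
               -log2_fold_change(wt, mut)$log2fc)
  wt0 <- wt
  wt0["a"] <- 0
  expect_error(log2_fold_change(mut, wt0), "non-positive")
})

test_that("delta tau_L resampling distribution behaves as constructed", {
  withr::with_seed(41, {
    wt_draws <- rnorm(4000, 16 / 24, 0.3 / 24)
    # identical draw sets: centred at zero within Monte-Carlo error
    d0 <- delta_tau_distribution(wt_draws, wt_draws, n_resample = 20000)
    mcse <- sd(d0$samples) / sqrt(length(d0$samples))
    expect_lt(abs(d0$mean), 3 * mcse)
    # exact -1 h shift
    d1 <- delta_tau_distribution(wt_draws - 1 / 24, wt_draws,
                                 n_resample = 20000)
    expect_lt(abs(d1$mean - (-1)), 4 * sd(d1$samples) / sqrt(20000) + 0.02)
    # point-mass mutant vs posterior wild type: negated shifted marginal
    dp <- delta_tau_distribution(15 / 24, wt_draws, n_resample = 20000)
    expect_equal(mean(dp$samples), 24 * (15 / 24 - mean(wt_draws)),
                 tolerance = 0.02)
    expect_equal(sd(dp$samples), 24 * sd(wt_draws), tolerance = 0.02)
    # antisymmetry of the difference construction
    dr <- delta_tau_distribution(wt_draws, wt_draws - 1 / 24,
                                 n_resample = 20000)
    expect_lt(abs(dr$mean + d1$mean), 0.05)
    expect_error(delta_tau_distribution(wt_draws, wt_draws, n_resample = 50),
                 ">= 100")
  })
})

make_delta_fit <- function(mask_names, draws_list, theta_wt) {
  mask <- stats::setNames(rep(FALSE, 7), PN)
  mask[mask_names] <- TRUE
  pars <- c(mask_names, "sigma_c", "sigma_s")
  n <- if (length(draws_list)) length(draws_list[[1]]) else 1000
  draws <- array(NA_real_, c(n, 1, length(pars)),
                 dimnames = list(NULL, NULL, pars))
  for (p in mask_names) draws[, 1, p] <- draws_list[[p]]
  draws[, 1, "sigma_c"] <- abs(rnorm(n, 0.03, 0.003))
  draws[, 1, "sigma_s"] <- abs(rnorm(n, 0.015, 0.002))
  structure(list(
    fit = structure(list(draws = draws, n_chains = 1, n_samples = n),
                    class = "diel_fit"),
    mask = mask, mask_string = dielstarch:::mask_string(mask),
    theta_wt = theta_wt), class = "delta_fit")
}

make_wt_fit <- function(n = 1000) {
  draws <- array(NA_real_, c(n, 1, 9),
                 dimnames = list(NULL, NULL, dielstarch:::FULL_NAMES))
  v <- dielstarch:::theta_vec(default_theta())
  for (p in dielstarch:::FULL_NAMES)
    draws[, 1, p] <- rnorm(n, v[[p]], 0.02 * max(abs(v[[p]]), 0.1))
  structure(list(draws = draws, n_chains = 1, n_samples = n),
            class = "diel_fit")
}

test_that("assess_mutant pins unflagged parameters at exactly zero log2fc", {
  withr::with_seed(43, {
    theta_wt <- dielstarch:::theta_vec(default_theta())[PN]
    wt_fit <- make_wt_fit()
    # empty mask: everything pinned, delta tau centred near 0
    sel0 <- make_delta_fit(character(), list(), theta_wt)
    e0 <- assess_mutant(sel0, wt_fit, mutant = "null", n_resample = 5000)
    expect_identical(e0$log2fc$log2fc, rep(0, 7))
    expect_false(any(e0$log2fc$significant))
    expect_lt(abs(e0$dtau_ld$mean), 0.2)
    # beta_p collapsed to a quarter: flagged significant
    sel <- make_delta_fit("beta_p",
                          list(beta_p = rnorm(1000, theta_wt[["beta_p"]] / 4,
                                              0.01)),
                          theta_wt)
    e <- assess_mutant(sel, wt_fit, mutant = "deg", n_resample = 5000)
    fc <- e$log2fc
    expect_true(fc$significant[fc$parameter == "beta_p"])
    expect_equal(fc$log2fc[fc$parameter != "beta_p"], rep(0, 6))
    # tau_L deviation propagates into the delta tau distribution
    sel_tau <- make_delta_fit("tauL_LD",
                              list(tauL_LD = rnorm(1000,
                                                   theta_wt[["tauL_LD"]] -
                                                     1.4 / 24, 0.1 / 24)),
                              theta_wt)
    et <- assess_mutant(sel_tau, wt_fit, mutant = "clock", n_resample = 5000)
    expect_lt(abs(et$dtau_ld$mean - (-1.4)), 0.25)
    tab <- effects_table(list(e0, e, et))
    expect_equal(nrow(tab), 21)
    expect_true(all(c("mutant", "parameter", "log2fc", "dtau_ld_map") %in%
                      names(tab)))
  })
})
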