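#' Enumerate sparse deviation models
#'
#' All 2^n masks of which parameters deviate from wild type, in deterministic
#' binary-counting order (first parameter is the least significant bit; the
#' first row is the empty mask).
#'
#' @param n_params number of parameters (default 7) or a character vector of
#'   parameter names to enumerate over.
#' @return A logical matrix (2^n rows) with parameter-name columns.
#' @export
enumerate_models <- function(n_params = 7) {
  nms <- if (is.character(n_params)) n_params else PARAM_NAMES[seq_len(n_params)]
  n <- length(nms)
  if (n < 1) stop_("`n_params` must be >= 1")
  idx <- 0:(2^n - 1)
  m <- sapply(seq_len(n) - 1L, function(b) bitwAnd(idx, bitwShiftL(1L, b)) > 0)
  m <- matrix(m, nrow = 2^n, dimnames = list(NULL, nms))
  m
}

mask_string <- function(mask7) paste(as.integer(mask7[PARAM_NAMES]), collapse = "")

full_mask <- function(mask) {
  out <- stats::setNames(rep(FALSE, 7), PARAM_NAMES)
  if (is.character(mask)) out[mask] <- TRUE
  else if (!is.null(names(mask))) out[names(mask)[as.logical(mask)]] <- TRUE
  else stop_("`mask` must be named or a character vector of parameter names")
  out
}

#' Widely applicable information criterion from pointwise log-likelihoods
#'
#' `waic = -2 * sum_i log( mean_j P(X_i | theta_j) ) + 2 * sum_i Var_j( log
#' P(X_i | theta_j) )`, computed stably via log-sum-exp, with the sample
#' variance over draws. Lower is better.
#'
#' @param pointwise_loglik draws x observations matrix of log-likelihoods.
#' @return `list(waic, lppd_term, penalty_term)`; `waic` is their sum and the
#'   penalty is always >= 0.
#' @export
waic <- function(pointwise_loglik) {
  m <- as.matrix(pointwise_loglik)
  if (nrow(m) < 2 || ncol(m) < 1)
    stop_("need >= 2 draws and >= 1 observation")
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_("non-finite log-likelihood at draw ", bad[1, 1], ", observation ",
          bad[1, 2])
  M <- nrow(m)
  lse <- apply(m, 2, function(col) {
    mx <- max(col)
    mx + log(sum(exp(col - mx)))
  })
  lppd_term <- -2 * sum(lse - log(M))
  penalty_term <- 2 * sum(apply(m, 2, var))
  list(waic = lppd_term + penalty_term, lppd_term = lppd_term,
       penalty_term = penalty_term)
}

#' Fit one sparse deviation model for a mutant
#'
#' The mutant parameter vector is `theta_wt + Delta`: components flagged by
#' `mask` are sampled (as the mutant value, bounded by the prior domain, with
#' `Delta` recorded as the difference from the wild-type anchor), unflagged
#' components are pinned at the wild-type point estimates. The mutant's noise
#' SDs are always re-estimated. WAIC is computed from the stored pointwise
#' log-likelihoods.
#'
#' @param mask logical/character mask over the seven model parameters (a row
#'   of [enumerate_models()], a named logical vector, or parameter names).
#' @param pair mutant paired data, `list(ld = , sd = )`.
#' @param theta_wt named numeric of wild-type point estimates over the seven
#'   parameters (e.g. [map_theta()] of the matched wild-type fit).
#' @param priors [prior_spec()] giving the parameter domains (and noise
#'   bounds); default [default_priors()] of the mutant pair.
#' @param config a [sampler_config()].
#' @param seed optional integer seed.
#' @param theta_template as in [sample_posterior()].
#' @return A list of class `delta_fit`: the `diel_fit` over the free
#'   components, `mask`, `theta_wt`, `delta_draws`, and `waic` (a
#'   `waic_result`).
#' @export
fit_delta_model <- function(mask, pair, theta_wt,
                            priors = default_priors(pair),
                            config = sampler_config(), seed = NULL,
                            theta_template = default_theta()) {
  check_pair(pair)
  mask <- full_mask(mask)
  if (is.null(names(theta_wt)) || !all(PARAM_NAMES %in% names(theta_wt)))
    stop_("`theta_wt` must be named over the seven model parameters")
  theta_wt <- theta_wt[PARAM_NAMES]
  free <- c(which(mask), 8L, 9L)  # flagged components + the two noise SDs
  lo <- unname(priors$lower[free])
  hi <- unname(priors$upper[free])
  base <- unname(c(theta_wt, 0.1, 0.1))
  if (any(lo >= hi) || any(theta_wt[mask] < priors$lower[1:7][mask]) ||
      any(theta_wt[mask] > priors$upper[1:7][mask]))
    stop_("infeasible deviation bounds: wild-type anchor at or outside the ",
          "prior domain for ", paste(PARAM_NAMES[mask], collapse = ", "))
  run <- function() {
    run_chains(base = base, free_idx = as.integer(free - 1L), lo = lo, hi = hi,
               pair = pair, config = config, theta_template = theta_template,
               free_names = FULL_NAMES[free])
  }
  fit <- if (!is.null(seed)) withr::with_seed(seed, run()) else run()
  fit$seed <- seed
  w <- waic(fit$pointwise_loglik)
  delta <- fit$draws
  flagged <- PARAM_NAMES[mask]
  for (p in flagged) delta[, , p] <- delta[, , p] - theta_wt[[p]]
  structure(list(fit = fit, mask = mask, mask_string = mask_string(mask),
                 theta_wt = theta_wt, delta_draws = delta,
                 waic = structure(c(w, list(mask = mask)),
                                  class = "waic_result")),
            class = "delta_fit")
}

#' Select the optimal deviation model by WAIC
#'
#' Minimum-WAIC entry; ties are broken toward fewer flagged parameters, then
#' lexicographic mask order.
#'
#' @param results list of `delta_fit` (or `waic_result`) objects.
#' @return The selected element of `results`.
#' @export
select_model <- function(results) {
  if (length(results) == 0) stop_("empty result list")
  wa <- vapply(results, function(r) {
    if (inherits(r, "delta_fit")) r$waic$waic else r$waic
  }, numeric(1))
  masks <- lapply(results, function(r) {
    if (inherits(r, "delta_fit")) r$mask else r$mask
  })
  size <- vapply(masks, sum, numeric(1))
  ms <- vapply(masks, mask_string, character(1))
  results[[order(wa, size, ms)[1]]]
}

#' Fit all sparse deviation models for one mutant and select by WAIC
#'
#' Enumerates the masks over `candidate_params` (all seven by default: 128
#' models), fits each with [fit_delta_model()], and selects the
#' minimum-WAIC model. Reduced candidate sets (e.g. 4 parameters, 16 models)
#' give a fast screening mode.
#'
#' @inheritParams fit_delta_model
#' @param candidate_params parameters allowed to deviate; masks are
#'   enumerated over these (others stay pinned in every model).
#' @return A list: `table` (tibble with `mask`, `waic`, `lppd_term`,
#'   `penalty_term`, `rank`, `selected`), `selected` (`delta_fit`), `fits`.
#' @export
select_mutant_model <- function(pair, theta_wt,
                                candidate_params = PARAM_NAMES,
                                priors = default_priors(pair),
                                config = sampler_config(), seed = NULL,
                                theta_template = default_theta()) {
  masks <- enumerate_models(candidate_params)
  fits <- vector("list", nrow(masks))
  for (i in seq_len(nrow(masks))) {
    mk <- stats::setNames(as.logical(masks[i, ]), colnames(masks))
    fits[[i]] <- fit_delta_model(mk, pair, theta_wt, priors, config,
                                 seed = if (is.null(seed)) NULL else seed + i,
                                 theta_template = theta_template)
  }
  sel <- select_model(fits)
  tab <- tibble::tibble(
    mask = vapply(fits, `[[`, character(1), "mask_string"),
    n_free = vapply(fits, function(f) sum(f$mask), numeric(1)),
    waic = vapply(fits, function(f) f$waic$waic, numeric(1)),
    lppd_term = vapply(fits, function(f) f$waic$lppd_term, numeric(1)),
    penalty_term = vapply(fits, function(f) f$waic$penalty_term, numeric(1))
  )
  tab$rank <- rank(tab$waic, ties.method = "first")
  tab$selected <- tab$mask == sel$mask_string
  list(table = tab[order(tab$rank), ], selected = sel, fits = fits)
}
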