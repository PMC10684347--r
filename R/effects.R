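#' Per-parameter log2 fold change between mutant and wild type
#'
#' `log2(theta_mutant / theta_wt)` for each of the seven model parameters,
#' flagged as a significant defect when `|log2fc| >= threshold` (default 1.5,
#' inclusive at the boundary).
#'
#' @param theta_mut,theta_wt named numeric point estimates (MAP) over the
#'   seven model parameters; wild-type values must be strictly positive.
#' @param threshold significance threshold on |log2fc|.
#' @return A tibble with columns `parameter`, `log2fc`, `significant`.
#' @export
log2_fold_change <- function(theta_mut, theta_wt, threshold = 1.5) {
  theta_mut <- theta_mut[PARAM_NAMES]
  theta_wt <- theta_wt[PARAM_NAMES]
  if (any(is.na(theta_mut)) || any(is.na(theta_wt)))
    stop_("point estimates must cover all seven model parameters")
  if (any(theta_wt <= 0) || any(theta_mut <= 0))
    stop_("fold change undefined: non-positive point estimate")
  fc <- log2(theta_mut / theta_wt)
  tibble::tibble(parameter = PARAM_NAMES, log2fc = unname(fc),
                 significant = unname(abs(fc) >= threshold))
}

#' Posterior distribution of the subjective-photoperiod shift
#'
#' Monte-Carlo distribution of `Delta tau_L = tau_L(mutant) - tau_L(wild
#' type)` in hours, built by independently resampling tau_L from the two
#' posterior sample sets. Under long days a negative shift means a reduced
#' ability to lengthen the subjective photoperiod; under short days a
#' positive shift means a reduced ability to shorten it.
#'
#' @param draws_mut,draws_wt numeric vectors of tau_L posterior draws (day
#'   fractions) for the chosen condition; a length-1 vector is treated as a
#'   point mass (a parameter pinned to the wild-type anchor).
#' @param n_resample number of resampled differences (>= 100).
#' @return A list: `samples` (hours), `map`, `mean`, `hdi` (95%).
#' @export
delta_tau_distribution <- function(draws_mut, draws_wt, n_resample = 10000) {
  if (n_resample < 100) stop_("`n_resample` must be >= 100")
  if (length(draws_mut) < 1 || length(draws_wt) < 1)
    stop_("draw sets must be non-empty")
  d <- (sample(draws_mut, n_resample, replace = TRUE) -
          sample(draws_wt, n_resample, replace = TRUE)) * 24
  list(samples = d,
       map = if (sd(d) > 0) map_estimate(d) else d[1],
       mean = mean(d), hdi = hdi(d))
}

mutant_tau_draws <- function(selected, condition) {
  par <- if (condition == "LD") "tauL_LD" else "tauL_SD"
  if (selected$mask[[par]]) {
    as.vector(selected$fit$draws[, , par])
  } else {
    selected$theta_wt[[par]]  # pinned: point mass at the wild-type anchor
  }
}

#' Summarize the impact of a genetic defect
#'
#' Assembles, for one mutant's selected deviation model: per-parameter log2
#' fold changes (parameters pinned by the model are exactly 0, structurally),
#' significance flags, and the Delta tau_L posterior distributions for both
#' photoperiods (computed against the wild-type posterior even when tau_L is
#' pinned, in which case the mutant marginal is the anchor point mass).
#'
#' @param selected a `delta_fit` (the WAIC-selected model, from
#'   [select_mutant_model()] or [fit_delta_model()]).
#' @param wt_fit the matched wild-type `diel_fit` (supplies tau_L draws).
#' @param mutant mutant label.
#' @param n_resample resample size for the Delta tau_L distributions.
#' @param threshold significance threshold on |log2fc|.
#' @return A list of class `effect_summary`: `mutant`, `log2fc` (tibble),
#'   `dtau_ld`, `dtau_sd` (as in [delta_tau_distribution()]),
#'   `theta_mut_map`.
#' @export
assess_mutant <- function(selected, wt_fit, mutant = "mutant",
                          n_resample = 10000, threshold = 1.5) {
  stopifnot(inherits(selected, "delta_fit"))
  if (!inherits(wt_fit, "diel_fit"))
    stop_("`wt_fit` must be the wild-type diel_fit (draws are required for ",
          "Delta tau_L)")
  theta_wt <- selected$theta_wt
  theta_mut <- theta_wt
  for (p in PARAM_NAMES[selected$mask])
    theta_mut[[p]] <- map_estimate(as.vector(selected$fit$draws[, , p]))
  fc <- log2_fold_change(theta_mut, theta_wt, threshold)
  # pinned parameters are identical by construction; force exact zeros so no
  # floating-point drift can flag them
  fc$log2fc[!selected$mask] <- 0
  fc$significant[!selected$mask] <- FALSE
  dtau <- lapply(c(LD = "LD", SD = "SD"), function(cc) {
    wt_par <- if (cc == "LD") "tauL_LD" else "tauL_SD"
    delta_tau_distribution(mutant_tau_draws(selected, cc),
                           as.vector(wt_fit$draws[, , wt_par]),
                           n_resample = n_resample)
  })
  structure(list(mutant = mutant, log2fc = fc, dtau_ld = dtau$LD,
                 dtau_sd = dtau$SD, theta_mut_map = theta_mut,
                 theta_wt_map = theta_wt, mask = selected$mask),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat("Mutant effect summary:", x$mutant, "\n")
  sig <- x$log2fc$parameter[x$log2fc$significant]
  cat("  significant defects (|log2fc| >= 1.5):",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  cat(sprintf("  Delta tau_L (LD): MAP %+.2f h [%.2f, %.2f]\n",
              x$dtau_ld$map, x$dtau_ld$hdi[1], x$dtau_ld$hdi[2]))
  cat(sprintf("  Delta tau_L (SD): MAP %+.2f h [%.2f, %.2f]\n",
              x$dtau_sd$map, x$dtau_sd$hdi[1], x$dtau_sd$hdi[2]))
  invisible(x)
}

#' Tidy one-row-per-parameter effects table
#'
#' @param effects list of `effect_summary` objects (or a single one).
#' @return A tibble: `mutant`, `parameter`, `log2fc`, `significant`,
#'   `dtau_ld_map`, `dtau_ld_lower`, `dtau_ld_upper`, `dtau_sd_map`,
#'   `dtau_sd_lower`, `dtau_sd_upper`.
#' @export
effects_table <- function(effects) {
  if (inherits(effects, "effect_summary")) effects <- list(effects)
  dplyr::bind_rows(lapply(effects, function(e) {
    dplyr::mutate(e$log2fc, mutant = e$mutant,
                  dtau_ld_map = e$dtau_ld$map,
                  dtau_ld_lower = e$dtau_ld$hdi[[1]],
                  dtau_ld_upper = e$dtau_ld$hdi[[2]],
                  dtau_sd_map = e$dtau_sd$map,
                  dtau_sd_lower = e$dtau_sd$hdi[[1]],
                  dtau_sd_upper = e$dtau_sd$hdi[[2]],
                  .before = 1)
  }))
}
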