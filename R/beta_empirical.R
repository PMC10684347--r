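#' Empirical starch-degradation-rate profile from maltose and starch
#'
#' Maltose is the immediate product of starch breakdown, which acts on the
#' granule surface (starch amount to the power kappa), so the degradation
#' rate is estimated, up to a scale factor, as
#' `beta_t = maltose_t / starch_t^kappa`. Time points with zero starch but
#' positive maltose have no defined rate and are masked (NA) with a warning;
#' zero maltose with zero starch gives 0.
#'
#' @param maltose,starch equal-length non-negative measurement vectors.
#' @param zt_hours sample times in hours.
#' @param kappa granule-surface exponent (default 2/3).
#' @return A tibble of class `beta_profile` with columns `zt_hour`, `beta`;
#'   attributes `standardized` (FALSE) and `source` ("empirical").
#' @export
estimate_beta <- function(maltose, starch, zt_hours = seq_along(maltose),
                          kappa = 2 / 3) {
  n <- length(maltose)
  if (length(starch) != n || length(zt_hours) != n)
    stop_("maltose, starch and zt_hours must have equal lengths")
  if (any(maltose < 0, na.rm = TRUE) || any(starch < 0, na.rm = TRUE))
    stop_("maltose and starch must be non-negative")
  beta <- ifelse(starch > 0, maltose / starch^kappa,
                 ifelse(maltose == 0, 0, NA_real_))
  if (anyNA(beta))
    warning("undefined rate (starch = 0 with maltose > 0) at ZT ",
            paste(zt_hours[is.na(beta)], collapse = ", "),
            "; points masked", call. = FALSE)
  beta_profile(zt_hours, beta, standardized = FALSE, source = "empirical")
}

beta_profile <- function(zt_hours, beta, standardized, source) {
  out <- tibble::tibble(zt_hour = zt_hours, beta = beta)
  class(out) <- c("beta_profile", class(out))
  attr(out, "standardized") <- standardized
  attr(out, "source") <- source
  out
}

#' Model-predicted degradation-rate profile at sampled ZT hours
#'
#' Closed-form profile of [degradation_rate()] evaluated at the empirical ZT
#' grid. Dawn convention: ZT0 observations are assigned the dark-side limit
#' (the daily peak), since harvest at ZT0 precedes light onset; ZT24 likewise.
#'
#' @param theta a [theta_full()].
#' @param condition `"LD"` or `"SD"`.
#' @param zt_hours sample times in hours within \[0, 24\].
#' @return A `beta_profile` with `source = "predicted"`.
#' @export
predicted_beta_profile <- function(theta, condition = "LD", zt_hours) {
  stopifnot(inherits(theta, "theta_full"))
  cond <- cond_of(theta, condition)
  beta_profile(zt_hours, beta_at_zt(theta$core, cond, zt_hours),
               standardized = FALSE, source = "predicted")
}

#' Standardize a degradation-rate profile to maximum 1
#'
#' Empirical beta estimates are relative values (the maltose proportionality
#' constant is unknown), so both empirical and predicted profiles are
#' rescaled to a common maximum of 1 before comparison. Idempotent; preserves
#' zeros and ordering.
#'
#' @param profile a `beta_profile`.
#' @return The rescaled `beta_profile` with `standardized = TRUE`.
#' @export
standardize_max1 <- function(profile) {
  stopifnot(inherits(profile, "beta_profile"))
  mx <- max(profile$beta, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    stop_("cannot standardize: no positive beta value")
  profile$beta <- profile$beta / mx
  attr(profile, "standardized") <- TRUE
  profile
}

#' Compare empirical and predicted degradation-rate profiles
#'
#' Mean absolute error between two max-1-standardized profiles on the same ZT
#' grid, plus the qualitative trend checks: a decreasing trend during the
#' light period and an increasing trend during the dark period, assessed by
#' the sign of the within-phase Spearman correlation of the empirical
#' profile. Masked (NA) points are dropped pairwise with a warning.
#'
#' @param empirical,predicted standardized `beta_profile`s on one ZT grid.
#' @param photoperiod_h external photoperiod in hours, delimiting the phases
#'   (ZT0 is counted with the dark phase: it carries the pre-dawn peak).
#' @param exclude_dawn drop the ZT0/ZT24 discontinuity points from the MAE.
#' @return A list: `mae`, `light_decreasing`, `dark_increasing`, `n_used`.
#' @export
compare_profiles <- function(empirical, predicted, photoperiod_h = 16,
                             exclude_dawn = FALSE) {
  stopifnot(inherits(empirical, "beta_profile"),
            inherits(predicted, "beta_profile"))
  if (!isTRUE(attr(empirical, "standardized")) ||
      !isTRUE(attr(predicted, "standardized")))
    stop_("both profiles must be standardized (see standardize_max1)")
  if (length(empirical$zt_hour) != length(predicted$zt_hour) ||
      any(empirical$zt_hour != predicted$zt_hour))
    stop_("profiles are on different ZT grids")
  masked <- is.na(empirical$beta) | is.na(predicted$beta)
  if (any(masked))
    warning("masked points dropped from the comparison", call. = FALSE)
  keep <- !masked
  if (exclude_dawn) keep <- keep & !(empirical$zt_hour %in% c(0, 24))
  if (!any(keep)) stop_("no usable points in common")
  mae <- mean(abs(empirical$beta[keep] - predicted$beta[keep]))
  trend <- function(zt, b) {
    if (length(zt) < 3 || sd(b) == 0) return(NA)
    cor(zt, b, method = "spearman")
  }
  light <- keep & empirical$zt_hour > 0 & empirical$zt_hour < photoperiod_h
  dark <- keep & empirical$zt_hour > photoperiod_h & empirical$zt_hour <= 24
  list(mae = mae,
       light_decreasing = isTRUE(trend(empirical$zt_hour[light],
                                       empirical$beta[light]) < 0),
       dark_increasing = isTRUE(trend(empirical$zt_hour[dark],
                                      empirical$beta[dark]) > 0),
       n_used = sum(keep))
}
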