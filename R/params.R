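#' @keywords internal
"_PACKAGE"

#' @useDynLib dielstarch, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats density rnorm runif rlnorm var sd acf cor quantile
#' @importFrom utils head modifyList packageVersion
NULL

# Canonical ordering of the seven model parameters, and of the full
# 9-dimensional sampling vector (parameters + noise SDs).
PARAM_NAMES <- c("a", "gamma", "H_LD", "tauL_LD", "H_SD", "tauL_SD", "beta_p")
FULL_NAMES <- c(PARAM_NAMES, "sigma_c", "sigma_s")

stop_ <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_("`", name, "` must be a single finite number")
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop_("`", name, "` = ", x, " outside its domain [", lower, ", ", upper, "]")
  invisible(x)
}

#' Core parameters of the carbon-homeostasis model
#'
#' Photosynthesis rate `a` (carbon per day), partitioning fraction to starch
#' `gamma`, degradation potential `beta_p` (sets the dawn peak of the
#' degradation rate; residual starch at dawn on the homeostatic orbit is
#' `1/beta_p`), and the granule-surface exponent `kappa` (2/3 for a spherical
#' granule: degradation acts on the granule surface, which scales as
#' starch amount to the power kappa).
#'
#' @param a photosynthesis rate, > 0 (carbon units per day).
#' @param gamma fraction of fixed carbon partitioned to starch, in \[0, 1\].
#' @param beta_p degradation potential, > 0.
#' @param kappa granule-surface exponent in (0, 1\]; default 2/3.
#' @return An object of class `core_params`.
#' @export
core_params <- function(a, gamma, beta_p, kappa = 2 / 3) {
  check_scalar(a, "a", 0, strict_lower = TRUE)
  check_scalar(gamma, "gamma", 0, 1)
  check_scalar(beta_p, "beta_p", 0, strict_lower = TRUE)
  check_scalar(kappa, "kappa", 0, 1, strict_lower = TRUE)
  structure(list(a = a, gamma = gamma, beta_p = beta_p, kappa = kappa),
            class = "core_params")
}

#' Photoperiod-condition parameters
#'
#' One light condition (long day or short day): sucrose consumption/export
#' rate `H`, subjective photoperiod `tau_L` (the photoperiod implied by the
#' plant's internal starch-degradation schedule), and the external light
#' fraction. All times are day fractions internally; multiply by 24 for hours.
#'
#' @param H sucrose consumption rate, > 0 (per day).
#' @param tau_L subjective photoperiod as a fraction of the day, in \[0, 1\].
#' @param photoperiod external light fraction of the day, in (0, 1).
#' @param label `"LD"` or `"SD"`.
#' @return An object of class `condition_params`.
#' @export
condition_params <- function(H, tau_L, photoperiod, label = "LD") {
  check_scalar(H, "H", 0, strict_lower = TRUE)
  check_scalar(tau_L, "tau_L", 0, 1)
  check_scalar(photoperiod, "photoperiod", 0, 1, strict_lower = TRUE)
  if (photoperiod >= 1) stop_("`photoperiod` must be < 1")
  if (!label %in% c("LD", "SD")) stop_("`label` must be \"LD\" or \"SD\"")
  structure(list(H = H, tau_L = tau_L, photoperiod = photoperiod,
                 label = label),
            class = "condition_params")
}

#' Full parameter set for a paired LD + SD fit
#'
#' The seven-parameter vector (a, gamma, H_LD, tauL_LD, H_SD, tauL_SD, beta_p)
#' of the carbon-homeostasis model plus the two measurement-noise variances
#' (starch and sucrose), the object of Bayesian inference.
#'
#' @param core a [core_params()] object.
#' @param ld,sd [condition_params()] for the long-day and short-day condition.
#' @param sigma_c2,sigma_s2 measurement-noise variances (> 0) for starch and
#'   sucrose.
#' @return An object of class `theta_full`.
#' @export
theta_full <- function(core, ld, sd, sigma_c2, sigma_s2) {
  stopifnot(inherits(core, "core_params"), inherits(ld, "condition_params"),
            inherits(sd, "condition_params"))
  check_scalar(sigma_c2, "sigma_c2", 0, strict_lower = TRUE)
  check_scalar(sigma_s2, "sigma_s2", 0, strict_lower = TRUE)
  structure(list(core = core, ld = ld, sd = sd, sigma_c2 = sigma_c2,
                 sigma_s2 = sigma_s2),
            class = "theta_full")
}

#' Default generating parameter set for synthetic experiments
#'
#' The stated world of the synthetic-data generator: a wild type close to,
#' but not exactly at, carbon homeostasis — the subjective photoperiods sit
#' at the midpoints of the ranges estimated for real wild-type plants (18 h
#' under a 16 h long day, 8.4 h under an 8 h short day), so sucrose
#' oscillates detectably and the subjective photoperiod is identifiable from
#' the data. Concentrations are in units of daily carbon fixation (a = 1);
#' noise SDs are roughly 10% of the diel signal.
#'
#' @param tauL_LD,tauL_SD subjective photoperiods (day fractions).
#' @param sigma_c,sigma_s measurement-noise SDs for starch and sucrose.
#' @return A `theta_full` object.
#' @export
default_theta <- function(tauL_LD = 18 / 24, tauL_SD = 8.4 / 24,
                          sigma_c = 0.03, sigma_s = 0.015) {
  theta_full(
    core = core_params(a = 1, gamma = 0.7, beta_p = 2),
    ld = condition_params(H = 3, tau_L = tauL_LD, photoperiod = 16 / 24,
                          label = "LD"),
    sd = condition_params(H = 2, tau_L = tauL_SD, photoperiod = 8 / 24,
                          label = "SD"),
    sigma_c2 = sigma_c^2, sigma_s2 = sigma_s^2
  )
}

# 9-vector view (noise as SDs, the sampling scale) of a theta_full.
theta_vec <- function(theta) {
  stopifnot(inherits(theta, "theta_full"))
  c(a = theta$core$a, gamma = theta$core$gamma, H_LD = theta$ld$H,
    tauL_LD = theta$ld$tau_L, H_SD = theta$sd$H, tauL_SD = theta$sd$tau_L,
    beta_p = theta$core$beta_p, sigma_c = sqrt(theta$sigma_c2),
    sigma_s = sqrt(theta$sigma_s2))
}

# Rebuild a theta_full from a named 9-vector, keeping kappa and photoperiods
# from `template`.
theta_from_vec <- function(v, template) {
  theta_full(
    core = core_params(v[["a"]], v[["gamma"]], v[["beta_p"]],
                       kappa = template$core$kappa),
    ld = condition_params(v[["H_LD"]], v[["tauL_LD"]],
                          template$ld$photoperiod, "LD"),
    sd = condition_params(v[["H_SD"]], v[["tauL_SD"]],
                          template$sd$photoperiod, "SD"),
    sigma_c2 = v[["sigma_c"]]^2, sigma_s2 = v[["sigma_s"]]^2
  )
}

cond_of <- function(theta, condition) {
  condition <- match.arg(condition, c("LD", "SD"))
  if (condition == "LD") theta$ld else theta$sd
}

#' @export
print.theta_full <- function(x, ...) {
  v <- theta_vec(x)
  cat("Carbon-homeostasis model parameters\n")
  cat(sprintf("  a = %.4g, gamma = %.4g, beta_p = %.4g, kappa = %.4g\n",
              v["a"], v["gamma"], v["beta_p"], x$core$kappa))
  cat(sprintf("  LD: H = %.4g, tau_L = %.4g d (%.2f h), photoperiod %.1f h\n",
              v["H_LD"], v["tauL_LD"], 24 * v["tauL_LD"],
              24 * x$ld$photoperiod))
  cat(sprintf("  SD: H = %.4g, tau_L = %.4g d (%.2f h), photoperiod %.1f h\n",
              v["H_SD"], v["tauL_SD"], 24 * v["tauL_SD"],
              24 * x$sd$photoperiod))
  cat(sprintf("  noise SD: starch %.4g, sucrose %.4g\n",
              v["sigma_c"], v["sigma_s"]))
  invisible(x)
}
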