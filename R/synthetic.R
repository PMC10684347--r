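#' Study design for synthetic diel datasets
#'
#' Mirrors the harvest design of the motivating experiments: long-day (16 h
#' light) sampling at ZT 0, 1, 2, 4, 8, 12, 15, 16, 20, 23, 24 and short-day
#' (8 h light) sampling at ZT 0, 1, 2, 4, 7, 8, 12, 16, 20, 23, 24, with 13
#' wild-type batches. Batch-to-batch variation is modelled as lognormal
#' multiplicative factors on the photosynthesis rate `a` and the sucrose
#' consumption rates `H`, the parameters to which batch differences were
#' attributed.
#'
#' @param ld_zts,sd_zts ZT sampling grids in hours.
#' @param n_batches number of batches (>= 1).
#' @param batch_dispersion lognormal sdlog of the batch factors on `a`,
#'   `H_LD`, `H_SD` (>= 0; 0 disables batch variation).
#' @param seed optional integer seed making generation reproducible.
#' @return An object of class `study_design`.
#' @export
study_design <- function(ld_zts = c(0, 1, 2, 4, 8, 12, 15, 16, 20, 23, 24),
                         sd_zts = c(0, 1, 2, 4, 7, 8, 12, 16, 20, 23, 24),
                         n_batches = 13, batch_dispersion = 0.1,
                         seed = NULL) {
  if (is.unsorted(ld_zts) || is.unsorted(sd_zts))
    stop_("ZT grids must be sorted")
  if (any(c(ld_zts, sd_zts) < 0 | c(ld_zts, sd_zts) > 24))
    stop_("ZT grids must lie within [0, 24]")
  if (n_batches < 1) stop_("`n_batches` must be >= 1")
  if (!is.numeric(batch_dispersion) || batch_dispersion < 0)
    stop_("`batch_dispersion` must be >= 0")
  structure(list(ld_zts = ld_zts, sd_zts = sd_zts,
                 n_batches = as.integer(n_batches),
                 batch_dispersion = batch_dispersion, seed = seed),
            class = "study_design")
}

#' Construct a diel measurement series
#'
#' One genotype x condition x batch series of starch/sucrose (optionally
#' maltose) measurements, stored as a tidy tibble with identifying columns.
#'
#' @param zt_hours sorted sample times in hours within \[0, 24\].
#' @param starch,sucrose non-negative measurement vectors matching `zt_hours`.
#' @param maltose optional non-negative vector (NA if unmeasured).
#' @param genotype,batch,condition series identifiers; `condition` is `"LD"`
#'   or `"SD"`.
#' @return A tibble of class `diel_series`.
#' @export
diel_series <- function(zt_hours, starch, sucrose, maltose = NULL,
                        genotype = "WT", batch = 1L, condition = "LD") {
  if (is.unsorted(zt_hours)) stop_("`zt_hours` must be sorted")
  if (any(zt_hours < 0 | zt_hours > 24)) stop_("`zt_hours` must be in [0, 24]")
  n <- length(zt_hours)
  if (length(starch) != n || length(sucrose) != n)
    stop_("starch/sucrose lengths must match `zt_hours`")
  if (any(starch < 0, na.rm = TRUE) || any(sucrose < 0, na.rm = TRUE))
    stop_("starch and sucrose must be non-negative")
  if (is.null(maltose)) maltose <- rep(NA_real_, n)
  if (length(maltose) != n) stop_("maltose length must match `zt_hours`")
  if (!condition %in% c("LD", "SD")) stop_("`condition` must be LD or SD")
  out <- tibble::tibble(genotype = genotype, batch = as.character(batch),
                        condition = condition, zt_hour = as.numeric(zt_hours),
                        starch = as.numeric(starch),
                        sucrose = as.numeric(sucrose),
                        maltose = as.numeric(maltose))
  class(out) <- c("diel_series", class(out))
  out
}

draw_batch_theta <- function(theta, dispersion) {
  v <- theta_vec(theta)
  f <- rlnorm(3, meanlog = 0, sdlog = dispersion)
  v["a"] <- v["a"] * f[1]
  v["H_LD"] <- v["H_LD"] * f[2]
  v["H_SD"] <- v["H_SD"] * f[3]
  theta_from_vec(v, theta)
}

#' Generate synthetic wild-type diel datasets
#'
#' For each batch, draws batch-level `(a, H_LD, H_SD)` as the base values
#' times lognormal factors, computes the model-mean trajectories at the design
#' ZT grids via [predicted_profile()], and adds i.i.d. Gaussian measurement
#' noise (variance `sigma_c2` for starch, `sigma_s2` for sucrose). Negative
#' draws are truncated at 0 (with a warning); the fitting likelihood ignores
#' the truncation, matching the plain Normal noise model.
#'
#' @param theta generating [theta_full()]; default [default_theta()].
#' @param design a [study_design()]; its `seed` (if non-NULL) makes the output
#'   reproducible without touching the global RNG stream.
#' @param genotype label attached to the series.
#' @return A list of `diel_series` (LD and SD per batch, LD first), with the
#'   per-batch generating parameters in `attr(, "truth")`.
#' @export
generate_wildtype <- function(theta = default_theta(), design = study_design(),
                              genotype = "WT") {
  stopifnot(inherits(theta, "theta_full"), inherits(design, "study_design"))
  run <- function() {
    out <- list()
    truth <- list()
    n_trunc <- 0L
    for (b in seq_len(design$n_batches)) {
      th_b <- if (design$batch_dispersion > 0) {
        draw_batch_theta(theta, design$batch_dispersion)
      } else {
        theta
      }
      truth[[b]] <- th_b
      for (cond in c("LD", "SD")) {
        zts <- if (cond == "LD") design$ld_zts else design$sd_zts
        mu <- predicted_profile(th_b, cond, zts)
        starch <- mu$starch + rnorm(length(zts), 0, sqrt(theta$sigma_c2))
        sucrose <- mu$sucrose + rnorm(length(zts), 0, sqrt(theta$sigma_s2))
        n_trunc <- n_trunc + sum(starch < 0) + sum(sucrose < 0)
        out[[length(out) + 1L]] <- diel_series(
          zts, pmax(starch, 0), pmax(sucrose, 0),
          genotype = genotype, batch = b, condition = cond
        )
      }
    }
    if (n_trunc > 0)
      warning(n_trunc, " negative noise draws truncated at 0", call. = FALSE)
    structure(out, truth = truth, theta_base = theta, design = design)
  }
  if (!is.null(design$seed)) withr::with_seed(design$seed, run()) else run()
}

validate_theta_vec <- function(v) {
  lims <- rbind(a = c(0, Inf), gamma = c(0, 1), H_LD = c(0, Inf),
                tauL_LD = c(0, 1), H_SD = c(0, Inf), tauL_SD = c(0, 1),
                beta_p = c(0, Inf), sigma_c = c(0, Inf), sigma_s = c(0, Inf))
  strict <- c("a", "H_LD", "H_SD", "beta_p", "sigma_c", "sigma_s")
  bad <- character()
  for (nm in rownames(lims)) {
    x <- v[[nm]]
    lo <- lims[nm, 1]
    if (!is.finite(x) || x < lo || x > lims[nm, 2] ||
        (nm %in% strict && x <= lo))
      bad <- c(bad, nm)
  }
  bad
}

#' Generate a synthetic mutant dataset as a sparse deviation from wild type
#'
#' Builds the mutant parameter vector as `theta_wt + delta` — the wild-type
#' values plus additive deviations on the flagged components — and delegates
#' to [generate_wildtype()]. The true deviation is recorded alongside the
#' data for recovery experiments.
#'
#' @param theta_wt wild-type [theta_full()].
#' @param delta named numeric vector of additive deviations; names must be a
#'   subset of `c("a","gamma","H_LD","tauL_LD","H_SD","tauL_SD","beta_p")`.
#'   Unnamed components are 0.
#' @param design a [study_design()].
#' @param genotype mutant label.
#' @return As [generate_wildtype()], with attributes `delta_true` and
#'   `mask_true`.
#' @export
generate_mutant <- function(theta_wt, delta, design = study_design(),
                            genotype = "mutant") {
  stopifnot(inherits(theta_wt, "theta_full"))
  if (is.null(names(delta)) || !all(names(delta) %in% PARAM_NAMES))
    stop_("`delta` must be named with model parameters: ",
          paste(PARAM_NAMES, collapse = ", "))
  full <- stats::setNames(numeric(7), PARAM_NAMES)
  full[names(delta)] <- delta
  v <- theta_vec(theta_wt)
  v[PARAM_NAMES] <- v[PARAM_NAMES] + full
  bad <- validate_theta_vec(v)
  if (length(bad))
    stop_("mutant parameters outside domain: ", paste(bad, collapse = ", "))
  out <- generate_wildtype(theta_from_vec(v, theta_wt), design,
                           genotype = genotype)
  attr(out, "delta_true") <- full
  attr(out, "mask_true") <- full != 0
  out
}

#' Fill in synthetic maltose measurements
#'
#' Maltose, the immediate product of starch breakdown, is proportional to the
#' degradation flux: `maltose_t = scale * beta_t * starch_t^kappa` plus
#' optional Gaussian noise, truncated at 0. `beta_t` is the closed-form
#' profile of the generating parameters (dawn convention: ZT0/ZT24 take the
#' dark-side peak value).
#'
#' @param series a `diel_series` with model-consistent starch values.
#' @param theta the generating [theta_full()].
#' @param scale positive proportionality factor (maltose is only defined up
#'   to scale; the downstream max-1 standardization removes it).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @return The series with its `maltose` column filled.
#' @export
generate_maltose <- function(series, theta, scale = 1, noise_sd = 0) {
  stopifnot(inherits(series, "diel_series"), inherits(theta, "theta_full"))
  check_scalar(scale, "scale", 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  cond <- cond_of(theta, series$condition[1])
  beta <- beta_at_zt(theta$core, cond, series$zt_hour)
  m <- scale * beta * series$starch^theta$core$kappa
  if (noise_sd > 0) m <- m + rnorm(length(m), 0, noise_sd)
  series$maltose <- pmax(m, 0)
  series
}

#' Example mutant deviation presets (synthetic)
#'
#' Synthetic stand-ins for classes of genetic defects, expressed as additive
#' deviations from a wild-type parameter set: a starch-phosphorylation-like
#' defect collapsing the degradation potential to a quarter of wild type, a
#' clock-like defect shortening the long-day subjective photoperiod by 2 h,
#' and a sucrose-export-like defect cutting both consumption rates.
#'
#' @param theta_wt wild-type [theta_full()] the deviations are relative to.
#' @return Named list of delta vectors usable with [generate_mutant()].
#' @export
mutant_presets <- function(theta_wt = default_theta()) {
  v <- theta_vec(theta_wt)
  list(
    gwd_like = c(beta_p = unname(-0.75 * v["beta_p"])),
    prr7_like = c(tauL_LD = -2 / 24),
    sweet_like = c(H_LD = unname(-0.6 * v["H_LD"]),
                   H_SD = unname(-0.6 * v["H_SD"]))
  )
}
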