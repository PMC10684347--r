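DIEL_COLS <- c("genotype", "batch", "condition", "zt_hour", "variable",
               "value")
DIEL_VARS <- c("starch", "sucrose", "maltose")

split_series <- function(long) {
  keys <- unique(long[, c("genotype", "batch", "condition")])
  lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- long[long$genotype == k$genotype & long$batch == k$batch &
                  long$condition == k$condition, ]
    wide <- tidyr_pivot(sub)
    diel_series(wide$zt_hour, wide$starch, wide$sucrose, wide$maltose,
                genotype = k$genotype, batch = k$batch,
                condition = k$condition)
  })
}

# minimal long -> wide without importing tidyr
tidyr_pivot <- function(sub) {
  zts <- sort(unique(sub$zt_hour))
  out <- tibble::tibble(zt_hour = zts)
  for (v in DIEL_VARS) {
    col <- rep(NA_real_, length(zts))
    rows <- sub[sub$variable == v, ]
    col[match(rows$zt_hour, zts)] <- rows$value
    out[[v]] <- col
  }
  if (anyNA(out$starch) || anyNA(out$sucrose))
    stop_("incomplete series: starch/sucrose missing at some ZT for ",
          sub$genotype[1], "/", sub$batch[1], "/", sub$condition[1])
  out
}

#' Read a tidy diel-measurement CSV
#'
#' Long format with columns `genotype`, `batch`, `condition` (LD/SD),
#' `zt_hour`, `variable` (starch/sucrose/maltose), `value`. Rows are grouped
#' into one `diel_series` per genotype x batch x condition. Unknown
#' conditions or variables, and duplicated (series, ZT, variable) rows, are
#' schema errors naming the offending rows.
#'
#' @param path CSV file path.
#' @return A list of `diel_series`; empty (with a warning) for an empty file.
#' @export
read_diel_csv <- function(path) {
  long <- readr::read_csv(path, col_types = readr::cols(
    genotype = readr::col_character(), batch = readr::col_character(),
    condition = readr::col_character(), zt_hour = readr::col_double(),
    variable = readr::col_character(), value = readr::col_double()
  ))
  if (!identical(sort(names(long)), sort(DIEL_COLS)))
    stop_("expected columns ", paste(DIEL_COLS, collapse = ", "),
          "; found ", paste(names(long), collapse = ", "))
  if (nrow(long) == 0) {
    warning("empty data file: ", path, call. = FALSE)
    return(list())
  }
  bad <- which(!long$condition %in% c("LD", "SD"))
  if (length(bad))
    stop_("unknown condition '", long$condition[bad[1]], "' at row ", bad[1])
  bad <- which(!long$variable %in% DIEL_VARS)
  if (length(bad))
    stop_("unknown variable '", long$variable[bad[1]], "' at row ", bad[1])
  dup <- duplicated(long[, c("genotype", "batch", "condition", "zt_hour",
                             "variable")])
  if (any(dup))
    stop_("duplicate measurement rows (first at row ", which(dup)[1], ")")
  split_series(tibble::as_tibble(long))
}

#' Write diel series to a tidy CSV
#'
#' @param series a `diel_series` or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_diel_csv <- function(series, path) {
  if (inherits(series, "diel_series")) series <- list(series)
  long <- dplyr::bind_rows(lapply(series, function(s) {
    rows <- lapply(DIEL_VARS, function(v) {
      if (all(is.na(s[[v]]))) return(NULL)
      tibble::tibble(genotype = s$genotype, batch = s$batch,
                     condition = s$condition, zt_hour = s$zt_hour,
                     variable = v, value = s[[v]])
    })
    dplyr::bind_rows(rows)
  }))
  readr::write_csv(long, path)
  invisible(path)
}

#' Export a simulated trajectory as tidy CSV
#'
#' @param trajectory a `diel_trajectory` from [simulate_trajectory()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "diel_trajectory"))
  readr::write_csv(trajectory[, c("day", "zt_hour", "C", "S")], path)
  invisible(path)
}

#' Export posterior draws as tidy CSV
#'
#' One row per (chain, iteration, parameter).
#'
#' @param fit a `diel_fit`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  stopifnot(inherits(fit, "diel_fit"))
  pars <- dimnames(fit$draws)[[3]]
  rows <- lapply(seq_len(fit$n_chains), function(ch) {
    d <- fit$draws[, ch, , drop = FALSE]
    tibble::tibble(chain = ch,
                   iteration = rep(seq_len(fit$n_samples), length(pars)),
                   parameter = rep(pars, each = fit$n_samples),
                   value = as.vector(d))
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

read_draws_csv <- function(path) {
  long <- readr::read_csv(path, col_types = readr::cols(
    chain = readr::col_integer(), iteration = readr::col_integer(),
    parameter = readr::col_character(), value = readr::col_double()
  ))
  pars <- unique(long$parameter)
  n_chains <- max(long$chain)
  n_iter <- max(long$iteration)
  draws <- array(NA_real_, c(n_iter, n_chains, length(pars)),
                 dimnames = list(NULL, NULL, pars))
  for (p in pars) for (ch in seq_len(n_chains)) {
    sub <- long[long$parameter == p & long$chain == ch, ]
    draws[sub$iteration, ch, p] <- sub$value
  }
  draws
}

#' Load a pipeline configuration
#'
#' YAML (or JSON) configuration with optional blocks `theta`, `design`,
#' `sampler`, `selection`, `paths`; missing entries fall back to package
#' defaults. See the pipeline vignette for the schema.
#'
#' @param path YAML/JSON file path, or a list already in config shape.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(seed = 1, out_dir = "dielstarch-out", data = NULL,
                   theta = list(), design = list(), sampler = list(),
                   selection = list(), maltose = list(scale = 1, noise_sd = 0))
  cfg <- modifyList(defaults, cfg)
  cfg$config_file <- if (is.character(path)) normalizePath(path) else NA_character_
  class(cfg) <- "run_config"
  cfg
}

config_theta <- function(cfg) {
  do.call(default_theta, cfg$theta[intersect(names(cfg$theta),
                                             names(formals(default_theta)))])
}

config_design <- function(cfg) {
  do.call(study_design, cfg$design[intersect(names(cfg$design),
                                             names(formals(study_design)))])
}

config_sampler <- function(cfg) {
  do.call(sampler_config, cfg$sampler[intersect(names(cfg$sampler),
                                                names(formals(sampler_config)))])
}

config_hash <- function(cfg) {
  if (!is.na(cfg$config_file) && file.exists(cfg$config_file))
    return(unname(tools::md5sum(cfg$config_file)))
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg[setdiff(names(cfg), "config_file")], tmp)
  unname(tools::md5sum(tmp))
}

write_run_log <- function(cfg, subcommand, outputs, out_dir) {
  log <- list(subcommand = subcommand, seed = cfg$seed,
              config_hash = config_hash(cfg),
              package_version = as.character(packageVersion("dielstarch")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), tz = "UTC"),
              outputs = as.list(tools::md5sum(outputs)))
  path <- file.path(out_dir, paste0(subcommand, "_log.json"))
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run one stage of the analysis pipeline
#'
#' Thin orchestration over the package functions, writing each stage's CSV
#' and JSON artifacts plus a log (seed, versions, config hash, output
#' checksums) to `config$out_dir`. Stages: `simulate` (synthetic wild-type
#' and optional mutants), `fit` (per-batch wild-type posteriors), `select`
#' (WAIC model selection for a mutant; requires a prior `fit`), `assess`
#' (effect summaries; requires `fit` and `select`), `beta` (empirical vs
#' predicted degradation-rate profile; requires `fit`), and `verify`
#' (re-check output checksums against the logs).
#'
#' @param config a [read_run_config()] result (or path, or list).
#' @param subcommand one of `"simulate"`, `"fit"`, `"select"`, `"assess"`,
#'   `"beta"`, `"verify"`.
#' @return Invisibly, a list of written file paths (for `verify`, a logical).
#' @export
run_pipeline <- function(config, subcommand = c("simulate", "fit", "select",
                                                "assess", "beta", "verify")) {
  subcommand <- match.arg(subcommand)
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(path, stage) {
    if (!file.exists(path))
      stop_("missing upstream artifact ", path, "; run the '", stage,
            "' stage first")
    path
  }
  outputs <- switch(
    subcommand,
    simulate = {
      theta <- config_theta(cfg)
      design <- config_design(cfg)
      if (is.null(design$seed)) design$seed <- cfg$seed
      wt <- generate_wildtype(theta, design)
      wt <- lapply(wt, function(s)
        withr::with_seed(cfg$seed + 1000L + as.integer(s$batch[1]),
                         generate_maltose(s, theta, cfg$maltose$scale,
                                          cfg$maltose$noise_sd)))
      series <- wt
      for (nm in names(cfg$mutants)) {
        mdesign <- design
        mdesign$seed <- design$seed + length(series)
        mt <- generate_mutant(theta, unlist(cfg$mutants[[nm]]), mdesign,
                              genotype = nm)
        series <- c(series, mt)
      }
      data_path <- file.path(out_dir, "data.csv")
      write_diel_csv(series, data_path)
      truth_path <- file.path(out_dir, "truth.json")
      jsonlite::write_json(list(theta = as.list(theta_vec(theta)),
                                mutants = cfg$mutants),
                           truth_path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      c(data_path, truth_path)
    },
    fit = {
      data_path <- if (!is.null(cfg$data)) cfg$data else
        need(file.path(out_dir, "data.csv"), "simulate")
      series <- read_diel_csv(data_path)
      wt_label <- if (is.null(cfg$selection$wt_genotype)) "WT" else
        cfg$selection$wt_genotype
      wt <- Filter(function(s) s$genotype[1] == wt_label, series)
      fits <- fit_batch_set(wt, config = config_sampler(cfg), seed = cfg$seed)
      outs <- character()
      summaries <- list()
      for (key in names(fits)) {
        f <- fits[[key]]
        if (inherits(f, "error")) {
          summaries[[key]] <- list(error = conditionMessage(f))
          next
        }
        dpath <- file.path(out_dir, paste0("fit_draws_", key, ".csv"))
        write_draws_csv(f, dpath)
        outs <- c(outs, dpath)
        s <- summary(f)
        summaries[[key]] <- list(map = as.list(stats::setNames(s$map, s$parameter)),
                                 summary = s,
                                 diagnostics = f$diagnostics[c("max_rhat",
                                                               "min_ess",
                                                               "status")])
      }
      spath <- file.path(out_dir, "fit_summary.json")
      jsonlite::write_json(summaries, spath, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      c(outs, spath)
    },
    select = {
      data_path <- if (!is.null(cfg$data)) cfg$data else
        need(file.path(out_dir, "data.csv"), "simulate")
      spath <- need(file.path(out_dir, "fit_summary.json"), "fit")
      series <- read_diel_csv(data_path)
      summ <- jsonlite::read_json(spath, simplifyVector = TRUE)
      sel_cfg <- cfg$selection
      mutant <- sel_cfg$mutant
      if (is.null(mutant)) stop_("config$selection$mutant is required")
      wt_key <- if (is.null(sel_cfg$wt_key)) names(summ)[1] else sel_cfg$wt_key
      theta_wt <- unlist(summ[[wt_key]]$map)[PARAM_NAMES]
      batch <- if (is.null(sel_cfg$batch)) NULL else sel_cfg$batch
      pair <- pair_series(series, mutant, batch)
      cand <- if (is.null(sel_cfg$candidate_params)) PARAM_NAMES else
        unlist(sel_cfg$candidate_params)
      res <- select_mutant_model(pair, theta_wt, candidate_params = cand,
                                 config = config_sampler(cfg),
                                 seed = cfg$seed)
      tpath <- file.path(out_dir, paste0("select_", mutant, ".csv"))
      readr::write_csv(res$table, tpath)
      dpath <- file.path(out_dir, paste0("select_draws_", mutant, ".csv"))
      write_draws_csv(res$selected$fit, dpath)
      mpath <- file.path(out_dir, paste0("select_meta_", mutant, ".json"))
      jsonlite::write_json(list(mutant = mutant, wt_key = wt_key,
                                theta_wt = as.list(theta_wt),
                                mask = res$selected$mask_string),
                           mpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(tpath, dpath, mpath)
    },
    assess = {
      sel_cfg <- cfg$selection
      mutant <- sel_cfg$mutant
      if (is.null(mutant)) stop_("config$selection$mutant is required")
      mpath <- need(file.path(out_dir, paste0("select_meta_", mutant,
                                              ".json")), "select")
      meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
      wt_draws_path <- need(file.path(out_dir, paste0("fit_draws_",
                                                      meta$wt_key, ".csv")),
                            "fit")
      sel_draws_path <- need(file.path(out_dir, paste0("select_draws_",
                                                       mutant, ".csv")),
                             "select")
      theta_wt <- unlist(meta$theta_wt)[PARAM_NAMES]
      mask <- full_mask(stats::setNames(
        strsplit(meta$mask, "")[[1]] == "1", PARAM_NAMES))
      sel_draws <- read_draws_csv(sel_draws_path)
      wt_draws <- read_draws_csv(wt_draws_path)
      selected <- structure(
        list(fit = structure(list(draws = sel_draws,
                                  n_chains = dim(sel_draws)[2],
                                  n_samples = dim(sel_draws)[1]),
                             class = "diel_fit"),
             mask = mask, mask_string = meta$mask, theta_wt = theta_wt),
        class = "delta_fit")
      wt_fit <- structure(list(draws = wt_draws,
                               n_chains = dim(wt_draws)[2],
                               n_samples = dim(wt_draws)[1]),
                          class = "diel_fit")
      eff <- withr::with_seed(cfg$seed,
                              assess_mutant(selected, wt_fit, mutant = mutant))
      epath <- file.path(out_dir, paste0("effects_", mutant, ".csv"))
      readr::write_csv(effects_table(eff), epath)
      epath
    },
    beta = {
      data_path <- if (!is.null(cfg$data)) cfg$data else
        need(file.path(out_dir, "data.csv"), "simulate")
      spath <- need(file.path(out_dir, "fit_summary.json"), "fit")
      series <- read_diel_csv(data_path)
      summ <- jsonlite::read_json(spath, simplifyVector = TRUE)
      outs <- character()
      rows <- list()
      for (key in names(summ)) {
        if (!is.null(summ[[key]]$error)) next
        map <- unlist(summ[[key]]$map)
        parts <- strsplit(key, ".", fixed = TRUE)[[1]]
        theta <- theta_from_vec(map[FULL_NAMES], default_theta())
        for (cc in c("LD", "SD")) {
          s <- tryCatch(pair_series(series, parts[1], parts[2])[[tolower(cc)]],
                        error = function(e) NULL)
          if (is.null(s) || all(is.na(s$maltose))) next
          emp <- standardize_max1(estimate_beta(s$maltose, s$starch,
                                                s$zt_hour))
          pred <- standardize_max1(predicted_beta_profile(theta, cc,
                                                          s$zt_hour))
          cmp <- compare_profiles(emp, pred,
                                  photoperiod_h = 24 *
                                    cond_of(theta, cc)$photoperiod)
          rows[[paste(key, cc)]] <- tibble::tibble(
            series = key, condition = cc, zt_hour = s$zt_hour,
            beta_empirical = emp$beta, beta_predicted = pred$beta,
            mae = cmp$mae, light_decreasing = cmp$light_decreasing,
            dark_increasing = cmp$dark_increasing)
        }
      }
      bpath <- file.path(out_dir, "beta_profiles.csv")
      readr::write_csv(dplyr::bind_rows(rows), bpath)
      bpath
    },
    verify = {
      logs <- list.files(out_dir, pattern = "_log\\.json$", full.names = TRUE)
      ok <- TRUE
      for (lg in logs) {
        rec <- jsonlite::read_json(lg, simplifyVector = TRUE)
        for (f in names(rec$outputs)) {
          cur <- unname(tools::md5sum(f))
          if (is.na(cur) || cur != rec$outputs[[f]]) {
            warning("checksum mismatch for ", f, call. = FALSE)
            ok <- FALSE
          }
        }
      }
      return(invisible(ok))
    }
  )
  write_run_log(cfg, subcommand, outputs, out_dir)
  invisible(outputs)
}
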