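# End-to-end orchestration: simulate the motivated SST, fit the DBM per
# subject/block, synthesize and extract ERP features, merge, model, and
# write all artifacts with a run manifest.

#' Run configuration for the end-to-end pipeline
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param n_subjects Number of simulated subjects.
#' @param task,agent,erp Stage configurations ([task_config()],
#'   [agent_config()], [erp_effect_config()]).
#' @param space DBM search space ([dbm_search_space()]; default coarse).
#' @param n_grid Rate-grid resolution for belief filtering and fitting.
#' @param rt_base_sd Between-subject baseline-RT SD, ms.
#' @param render_waveforms If TRUE, trial amplitudes are rendered into
#'   epoched waveforms and re-extracted through the ERP feature chain; if
#'   FALSE the synthesized mean amplitudes feed the models directly
#'   (identical up to sample quantization and extraction noise).
#' @param drop_conditions Optional named list subject -> conditions to omit.
#' @return Object of class \code{"sst_run_config"}.
#' @export
run_config <- function(seed = 1L, n_subjects = 10L, task = task_config(),
                       agent = agent_config(), erp = erp_effect_config(),
                       space = dbm_search_space_coarse(), n_grid = 200L,
                       rt_base_sd = 50, render_waveforms = TRUE,
                       drop_conditions = NULL) {
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 task = task, agent = agent, erp = erp, space = space,
                 n_grid = as.integer(n_grid), rt_base_sd = rt_base_sd,
                 render_waveforms = render_waveforms,
                 drop_conditions = drop_conditions),
            class = "sst_run_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' simulate -> fit DBM per subject/block -> synthesize (and optionally
#' render + re-extract) ERP features -> merge -> mixed models -> artifacts.
#' Identical seeds reproduce identical tables.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes \code{trials.csv},
#'   \code{dbm_fits.csv}, \code{erp_features.csv}, \code{merged.csv},
#'   \code{model_*.csv}, \code{simple_slopes_*.csv} and
#'   \code{manifest.json}.
#' @return (Invisibly) list with \code{trials}, \code{dbm_fits},
#'   \code{features}, \code{merged}, \code{models} (fitted
#'   \code{"sst_model"}s), \code{effects} (tidy tables),
#'   \code{slopes} (per-condition simple slopes), \code{manifest}.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sst_run_config"))

  # --- simulate -----------------------------------------------------------
  trials <- with_seed(config$seed, {
    offsets <- stats::rnorm(config$n_subjects, 0, config$rt_base_sd)
    do.call(rbind, lapply(seq_len(config$n_subjects), function(i) {
      a <- config$agent
      a$rt_base <- a$rt_base + offsets[i]
      drop_i <- config$drop_conditions[[as.character(i)]]
      simulate_subject(config$task, a, subject = i,
                       drop_conditions = drop_i, n_grid = config$n_grid)
    }))
  })

  # --- fit DBM per subject x block ---------------------------------------
  cells <- unique(trials[, c("subject", "condition")])
  trials$pstop_fit <- NA_real_
  fits <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- trials$subject == cells$subject[i] &
      trials$condition == cells$condition[i]
    fit <- dbm_grid_fit(trials[sel, ], config$space, n_grid = config$n_grid)
    trials$pstop_fit[sel] <<- fit$pstop
    data.frame(subject = cells$subject[i], condition = cells$condition[i],
               alpha = fit$params$alpha, prior_mean = fit$params$prior_mean,
               prior_scale = fit$params$prior_scale,
               r_squared = fit$r_squared, slope = fit$slope,
               n_trials_used = fit$n_trials_used, stringsAsFactors = FALSE)
  }))

  # --- ERP features -------------------------------------------------------
  amp <- synthesize_amplitudes(trials, config$erp, seed = config$seed + 1L)
  if (config$render_waveforms) {
    # render and re-extract block-wise to bound memory
    feats <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sel <- amp$subject == cells$subject[i] &
        amp$condition == cells$condition[i]
      ep <- render_epochs(amp[sel, ], config$erp,
                          seed = config$seed + 1000L + i)
      extract_erp_features(ep)
    }))
  } else {
    feats <- amp[, c("subject", "condition", "trial_index")]
    feats$p1_latency <- config$erp$p1_latency
    feats$n1_latency <- config$erp$n1_latency
    feats$p1_amp <- amp$p1_amp
    feats$n1_amp <- amp$n1_amp
    feats$retained <- TRUE
    feats$rejection_reason <- "none"
  }
  feats <- standardize_amplitudes(feats)

  # --- merge --------------------------------------------------------------
  merged <- merge(trials, feats, by = c("subject", "condition",
                                        "trial_index"), all.x = TRUE)
  merged <- merged[order(merged$subject, merged$condition,
                         merged$trial_index), ]
  erp_rows <- filter_short_ssd(merged)

  # --- models -------------------------------------------------------------
  go_rows <- merged[!as.logical(merged$is_stop), ]
  stop_rows <- erp_rows[as.logical(erp_rows$is_stop), ]
  models <- list(
    rt = fit_trial_model(go_rows, "rt", pstop = "pstop_fit"),
    p1 = fit_trial_model(erp_rows[!as.logical(erp_rows$is_stop), ], "p1_z",
                         pstop = "pstop_fit"),
    n1 = fit_trial_model(erp_rows[!as.logical(erp_rows$is_stop), ], "n1_z",
                         pstop = "pstop_fit"),
    stop_error = fit_trial_model(stop_rows, "stop_error",
                                 pstop = "pstop_fit", amplitude = "n1_z")
  )
  effects <- lapply(models, tidy_effects)
  slopes <- list(
    p1 = simple_slopes(models$p1),
    n1 = simple_slopes(models$n1),
    stop_error_n1 = simple_slopes(models$stop_error,
                                  term = c("pstop_fit", "n1_z"))
  )

  manifest <- list(
    seed = config$seed, n_subjects = config$n_subjects,
    n_trials = nrow(trials),
    n_cells = nrow(cells),
    missing_cells = {
      mc <- attr(summarize_conditions(trials), "missing_cells")
      if (is.null(mc)) list() else mc
    },
    n_erp_rows = nrow(erp_rows),
    n_short_ssd_removed = nrow(merged) - nrow(erp_rows),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("sstdbm"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trials, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    utils::write.csv(fits, file.path(out_dir, "dbm_fits.csv"),
                     row.names = FALSE)
    utils::write.csv(feats, file.path(out_dir, "erp_features.csv"),
                     row.names = FALSE)
    utils::write.csv(merged, file.path(out_dir, "merged.csv"),
                     row.names = FALSE)
    for (nm in names(effects))
      utils::write.csv(effects[[nm]],
                       file.path(out_dir, paste0("model_", nm, ".csv")),
                       row.names = FALSE)
    for (nm in names(slopes))
      utils::write.csv(slopes[[nm]],
                       file.path(out_dir,
                                 paste0("simple_slopes_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(trials = trials, dbm_fits = fits, features = feats,
                 merged = merged, models = models, effects = effects,
                 slopes = slopes, manifest = manifest))
}

#' Validate a trial table against the task schema
#'
#' Report-only schema check: required columns, value ranges (RT within the
#' response window, SSD within the staircase bounds and only on stop
#' trials, probabilities in (0, 1)).
#'
#' @param trials Trial table.
#' @param task A [task_config()] supplying the bounds.
#' @return Data frame of violations (\code{check}, \code{n_rows},
#'   \code{detail}); zero rows when the table is well formed.
#' @export
validate_trial_table <- function(trials, task = task_config()) {
  v <- list()
  need <- c("subject", "condition", "trial_index", "is_stop", "rt", "ssd")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    v[[length(v) + 1L]] <- data.frame(
      check = "missing_columns", n_rows = NA_integer_,
      detail = paste(miss, collapse = ", "))
  add <- function(check, bad, detail) {
    if (any(bad, na.rm = TRUE))
      v[[length(v) + 1L]] <<- data.frame(
        check = check, n_rows = sum(bad, na.rm = TRUE), detail = detail)
  }
  if (!length(miss)) {
    add("rt_range", is.finite(trials$rt) &
          (trials$rt <= 0 | trials$rt > task$go_duration),
        sprintf("rt outside (0, %g]", task$go_duration))
    add("ssd_on_go_trial", !as.logical(trials$is_stop) & !is.na(trials$ssd),
        "SSD present on a go trial")
    add("ssd_missing_on_stop", as.logical(trials$is_stop) &
          is.na(trials$ssd), "SSD absent on a stop trial")
    add("ssd_range", is.finite(trials$ssd) &
          (trials$ssd < task$ssd_min | trials$ssd > task$ssd_max),
        sprintf("SSD outside [%g, %g]", task$ssd_min, task$ssd_max))
    add("is_stop_binary", !trials$is_stop %in% c(0, 1, TRUE, FALSE),
        "is_stop not binary")
    if ("pstop_agent" %in% names(trials))
      add("pstop_range", !is.na(trials$pstop_agent) &
            (trials$pstop_agent <= 0 | trials$pstop_agent >= 1),
          "P(stop) outside (0, 1)")
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(check = character(), n_rows = integer(),
                  detail = character())
}
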