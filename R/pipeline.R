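## End-to-end orchestration: simulate -> segment -> extract -> select ->
## classify -> report, plus the survey-side analysis. Every artifact is
## listed in a sidecar metadata JSON together with the config hash and seed
## so that runs are verifiably reproducible.

#' Configure an end-to-end run
#'
#' @param outdir Output directory for all artifacts.
#' @param cohort A [cohort_config()]; its seed drives every stochastic
#'   stage.
#' @param alpha ANOVA selection level.
#' @param grid SVM hyper-parameter grid ([svm_grid()]).
#' @param loo_unit `"subject"` or `"segment"`.
#' @param modalities Modalities to classify.
#' @param by_language Evaluate each stimulus-language set separately (the
#'   study's design); if FALSE a single pooled evaluation is run.
#' @param intersect_languages Require ANOVA significance in both language
#'   strata inside each training fold (common-feature intersection); off by
#'   default.
#' @param n_respondents Survey respondents.
#' @param log Log stage progress via [message()].
#' @return Object of class `emofun_run_config`.
#' @export
run_config <- function(outdir, cohort = cohort_config(), alpha = 0.05,
                       grid = svm_grid(), loo_unit = "subject",
                       modalities = MODALITIES, by_language = TRUE,
                       intersect_languages = FALSE, n_respondents = 345,
                       log = TRUE) {
  if (!inherits(cohort, "emofun_cohort_config"))
    stop("configuration error: cohort must come from cohort_config()")
  if (cohort$n_participants <= 0)
    stop("configuration error: n_participants must be positive for a run")
  modalities <- match.arg(modalities, MODALITIES, several.ok = TRUE)
  loo_unit <- match.arg(loo_unit, c("subject", "segment"))
  structure(list(outdir = outdir, cohort = cohort, alpha = alpha,
                 grid = grid, loo_unit = loo_unit, modalities = modalities,
                 by_language = by_language,
                 intersect_languages = intersect_languages,
                 n_respondents = n_respondents, log = isTRUE(log)),
            class = "emofun_run_config")
}

#' A small end-to-end demonstration configuration
#'
#' Twelve clips x 30 participants with shortened (20 s) clips and a coarse
#' hyper-parameter grid, sized so the full pipeline runs in minutes on one
#' CPU.
#'
#' @param outdir Output directory.
#' @param seed Seed propagated to every stage.
#' @param ... Overrides passed to [run_config()].
#' @return An `emofun_run_config`.
#' @export
demo_config <- function(outdir, seed = 1L, ...) {
  clips <- lapply(default_clips(), function(cl) { cl$duration_s <- 20; cl })
  run_config(outdir,
             cohort = cohort_config(n_participants = 30, clips = clips,
                                    effect_size = 2, seed = seed),
             grid = svm_grid(cost_exp = seq(-1, 7, by = 4),
                             gamma_exp = seq(-9, -1, by = 4)),
             ...)
}

log_stage <- function(cfg, fmt, ...) {
  if (cfg$log) message(sprintf(paste0("[emofun] ", fmt), ...))
}

#' Run the full pipeline
#'
#' Stages: simulate (cohort + survey, written as CSV), extract (segment
#' inclusion, feature matrix, registry), classify (per modality and per
#' stimulus-language set: ANOVA selection + one-vs-one RBF SVM under
#' leave-one-out CV), survey (clip summaries and t-test batteries). A
#' failure halts with a stage-named error; completed stages' artifacts
#' remain valid. All artifacts plus their checksums, the config hash and
#' the seed are listed in `metadata.json`.
#'
#' @param config An [run_config()] object.
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `records`, `features`, `evaluations`, `survey`, `files`).
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "emofun_run_config"))
    stop("config must come from run_config()")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(obj, name, writer = write.csv) {
    path <- file.path(config$outdir, name)
    if (identical(writer, write.csv)) write.csv(obj, path, row.names = FALSE)
    else writer(obj, path)
    files <<- c(files, name)
    path
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## -- simulate ---------------------------------------------------------
  log_stage(config, "simulate: %d participants x %d clips",
            config$cohort$n_participants, length(config$cohort$clips))
  cohort <- stage("simulate", generate_cohort(config$cohort))
  survey <- stage("simulate",
                  generate_survey_table(config$cohort,
                                        n_respondents = config$n_respondents))
  stage("simulate", write_cohort(cohort, config$outdir))
  emit(survey, "survey.csv")

  ## -- extract ----------------------------------------------------------
  log_stage(config, "extract: segment selection and 727 functionals")
  records <- stage("extract", select_segments(cohort))
  emit(records[, setdiff(names(records), "segments")], "segment_records.csv")
  emit(segment_inventory(records), "segment_inventory.csv")
  feats <- stage("extract", {
    kept <- cohort$segments[records$included]
    extract_features(kept)
  })
  emit(feats, "features.csv")
  emit(feature_registry(), "feature_registry.json",
       function(obj, path) jsonlite::write_json(obj, path, dataframe = "rows"))

  ## -- classify ---------------------------------------------------------
  meta <- feats[feature_meta_cols()]
  evaluations <- list()
  sets <- if (config$by_language) LANGUAGES else "all"
  for (m in config$modalities) {
    reg <- feature_registry()
    cols <- reg$name[reg$modality == m]
    for (lang in sets) {
      rows <- if (lang == "all") rep(TRUE, nrow(feats)) else meta$language == lang
      xm <- as.matrix(feats[rows, cols, drop = FALSE])
      rows_ok <- rows
      complete <- stats::complete.cases(xm)
      xm <- xm[complete, , drop = FALSE]
      lab <- meta$emotion[rows][complete]
      sid <- meta$participant_id[rows][complete]
      key <- paste(m, lang, sep = "_")
      if (length(unique(lab)) < 2L || nrow(xm) < 4L) {
        log_stage(config, "classify: %s skipped (too few segments)", key)
        next
      }
      log_stage(config, "classify: %s (%d segments)", key, nrow(xm))
      ev <- stage("classify", loo_evaluate(
        xm, lab, sid, grid = config$grid, alpha = config$alpha,
        strata = if (config$intersect_languages && lang == "all")
          meta$language[rows][complete],
        unit = config$loo_unit, modality = key))
      evaluations[[key]] <- ev
      emit(as.data.frame.matrix(as.matrix(ev$confusion)),
           paste0("confusion_", key, ".csv"),
           function(obj, path) write.csv(obj, path, row.names = TRUE))
      emit(list(modality = m, language = lang, accuracy_pct = ev$accuracy,
                n_segments = ev$n, alpha = ev$alpha, unit = ev$unit,
                folds = ev$folds),
           paste0("evaluation_", key, ".json"),
           function(obj, path) jsonlite::write_json(obj, path,
                                                    auto_unbox = TRUE,
                                                    dataframe = "rows",
                                                    digits = NA))
    }
  }
  ## selected-features report on the full included matrix (per language
  ## intersection, the study's common-feature summary)
  sel_report <- stage("classify", {
    xm <- as.matrix(feats[, feature_registry()$name])
    keep <- colSums(is.na(xm)) < nrow(xm)
    sel <- anova_select(xm[, keep, drop = FALSE], meta$emotion,
                        alpha = config$alpha,
                        strata = if (config$by_language) meta$language)
    as.data.frame(sel)[sel$selected, , drop = FALSE]
  })
  emit(sel_report, "selected_features.csv")

  ## -- survey analysis --------------------------------------------------
  log_stage(config, "survey: summaries and t-test batteries")
  emit(summarize_clips(survey), "survey_summary.csv")
  tnt <- do.call(rbind, lapply(unique(survey$clip_id), function(cid)
    target_vs_nontarget_tests(survey, cid, alpha = config$alpha)))
  emit(tnt, "survey_target_tests.csv")
  xl <- do.call(rbind, lapply(intersect(EMOTIONS, unique(survey$emotion)),
                              function(e) cross_language_test(survey, e)))
  emit(xl, "survey_language_tests.csv")
  gd <- do.call(rbind, lapply(unique(survey$clip_id), function(cid)
    gender_difference_tests(survey, cid, alpha = config$alpha)))
  emit(gd, "survey_gender_tests.csv")

  ## -- metadata ---------------------------------------------------------
  all_files <- sort(unique(c(files, "manifest.csv", "ratings.csv",
                             "schema.yaml",
                             grep("^segments/", list.files(config$outdir,
                                                           recursive = TRUE),
                                  value = TRUE))))
  sums <- tools::md5sum(file.path(config$outdir, all_files))
  meta_json <- list(
    seed = config$cohort$seed,
    config_hash = object_md5(config[setdiff(names(config), "outdir")]),
    files = data.frame(file = all_files, md5 = unname(sums)))
  jsonlite::write_json(meta_json, file.path(config$outdir, "metadata.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
  log_stage(config, "done: %d artifacts in %s", length(all_files),
            config$outdir)
  invisible(list(cohort = cohort, records = records, features = feats,
                 evaluations = evaluations, survey = survey,
                 files = all_files))
}

#' Checksums of a finished run's artifacts
#'
#' Reads `metadata.json` and returns the recorded per-file md5 sums; two
#' runs with the same config and seed must agree file-for-file.
#'
#' @param outdir A directory written by [run_experiment()].
#' @return Named character vector of md5 sums.
#' @export
run_checksums <- function(outdir) {
  meta <- jsonlite::read_json(file.path(outdir, "metadata.json"),
                              simplifyVector = TRUE)
  stats::setNames(meta$files$md5, meta$files$file)
}
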