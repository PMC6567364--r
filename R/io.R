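## CSV dialect for cohorts: one CSV per modality per segment under
## segments/<participant>_<clip>_<modality>.csv, a session manifest, a
## ratings table, and a machine-readable schema file describing every
## column.

stream_schema <- function() {
  list(
    manifest = c("participant_id", "clip_id", "emotion", "language",
                 "duration_s", "start_timestamp_ms",
                 paste0(MODALITIES, "_path")),
    ratings = c("participant_id", "clip_id", EMOTIONS, "seen_before",
                "looked_away"),
    facial = list(rate_hz = RATE_BEHAVIOURAL,
                  columns = paste0("au", 1:6),
                  units = "intensity in [-1, 1]"),
    head = list(rate_hz = RATE_BEHAVIOURAL,
                columns = c("yaw", "pitch", "roll"), units = "degrees"),
    eye = list(rate_hz = RATE_BEHAVIOURAL,
               columns = c("gaze_lx", "gaze_ly", "gaze_rx", "gaze_ry",
                           "dist_l", "dist_r", "pupil_l", "pupil_r",
                           "valid_l", "valid_r"),
               units = "screen units / mm / boolean validity"),
    autonomic = list(rate_hz = RATE_AUTONOMIC,
                     columns = c("timestamp_ms", "scl", "temp"),
                     units = "ms / microsiemens / degrees C"))
}

#' Write a cohort to disk as CSV files
#'
#' Writes `manifest.csv`, `ratings.csv`, one CSV per modality per segment
#' under `segments/`, and a `schema.yaml` documenting every column and
#' sampling rate. All paths in the manifest are relative to `dir`.
#'
#' @param cohort An `emofun_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "emofun_cohort"))
  segdir <- file.path(dir, "segments")
  dir.create(segdir, recursive = TRUE, showWarnings = FALSE)
  man <- list()
  for (s in cohort$segments) {
    stem <- paste(s$participant_id, s$clip_id, sep = "_")
    paths <- stats::setNames(rep(NA_character_, length(MODALITIES)), MODALITIES)
    for (m in MODALITIES) {
      if (!is.null(s[[m]])) {
        p <- file.path("segments", paste0(stem, "_", m, ".csv"))
        write.csv(s[[m]], file.path(dir, p), row.names = FALSE)
        paths[[m]] <- p
      }
    }
    man[[length(man) + 1L]] <- data.frame(
      participant_id = s$participant_id, clip_id = s$clip_id,
      emotion = s$target_emotion, language = s$language,
      duration_s = s$duration_s, start_timestamp_ms = s$start_timestamp_ms,
      facial_path = paths[["facial"]], head_path = paths[["head"]],
      eye_path = paths[["eye"]], autonomic_path = paths[["autonomic"]])
  }
  write.csv(do.call(rbind, man), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  write.csv(cohort$ratings, file.path(dir, "ratings.csv"), row.names = FALSE)
  yaml::write_yaml(stream_schema(), file.path(dir, "schema.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv`, `ratings.csv` and
#'   `segments/`.
#' @return An `emofun_cohort` (without a generator config).
#' @export
read_cohort <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"))
  ratings <- read.csv(file.path(dir, "ratings.csv"))
  segments <- lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    streams <- lapply(MODALITIES, function(m) {
      p <- row[[paste0(m, "_path")]]
      if (is.na(p) || !nzchar(p)) NULL else read.csv(file.path(dir, p))
    })
    names(streams) <- MODALITIES
    if (!is.null(streams$eye)) {
      streams$eye$valid_l <- as.logical(streams$eye$valid_l)
      streams$eye$valid_r <- as.logical(streams$eye$valid_r)
    }
    structure(c(list(participant_id = row$participant_id,
                     clip_id = row$clip_id, target_emotion = row$emotion,
                     language = row$language,
                     start_timestamp_ms = row$start_timestamp_ms,
                     duration_s = row$duration_s),
                streams,
                list(rates = list(facial = RATE_BEHAVIOURAL,
                                  head = RATE_BEHAVIOURAL,
                                  eye = RATE_BEHAVIOURAL,
                                  autonomic = RATE_AUTONOMIC))),
              class = "emofun_segment")
  })
  structure(list(segments = segments, ratings = ratings, config = NULL),
            class = "emofun_cohort")
}
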