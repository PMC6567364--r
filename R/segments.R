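## Segment alignment and inclusion rules: offline timestamp matching for the
## wrist-sensor stream, and the target-emotion filter (a segment is kept only
## if the participant self-rated the clip's target emotion above zero).

#' Align an autonomic stream to a clip interval by timestamps
#'
#' Offline matching: keeps the samples whose timestamps fall in the
#' half-open interval `[clip_start_ms, clip_end_ms)`. If the retained span
#' covers less than `min_coverage` of the clip, the stream is flagged as
#' insufficient (the caller then excludes the segment with reason
#' `missing_stream`); a disjoint stream is never an error.
#'
#' @param stream Data frame with a `timestamp_ms` column (milliseconds since
#'   session start) and value columns.
#' @param clip_start_ms,clip_end_ms Clip interval in milliseconds.
#' @param min_coverage Minimum fraction of the clip that must be covered by
#'   retained samples (default 0.8).
#' @return List with `stream` (the trimmed data frame), `coverage` (fraction
#'   in \[0, 1\]) and `ok` (logical).
#' @export
align_autonomic <- function(stream, clip_start_ms, clip_end_ms,
                            min_coverage = 0.8) {
  if (!is.data.frame(stream) || is.null(stream$timestamp_ms))
    stop("stream must be a data frame with a timestamp_ms column")
  if (clip_end_ms <= clip_start_ms) stop("empty clip interval")
  keep <- stream$timestamp_ms >= clip_start_ms &
    stream$timestamp_ms < clip_end_ms
  trimmed <- stream[keep, , drop = FALSE]
  rownames(trimmed) <- NULL
  cov <- if (nrow(trimmed) < 2L) 0 else
    (max(trimmed$timestamp_ms) - min(trimmed$timestamp_ms)) /
      (clip_end_ms - clip_start_ms)
  list(stream = trimmed, coverage = cov, ok = cov >= min_coverage)
}

#' Apply the segment-inclusion rules
#'
#' A segment is included when (i) the participant's self-rating of the
#' clip's target emotion is at least 1 on the 0-10 scale ("not felt" is 0),
#' (ii) at least one modality stream was recorded, and (iii) optionally the
#' participant had not seen the clip before. Every excluded segment carries
#' exactly one reason; when several apply, precedence is `seen_before`,
#' `not_felt`, `missing_stream`.
#'
#' @param segments List of `emofun_segment` objects or an `emofun_cohort`.
#' @param ratings Self-rating data frame with `participant_id`, `clip_id`
#'   and one 0-10 column per emotion (plus optional `seen_before`); one row
#'   per segment is required.
#' @param exclude_seen_before Drop segments of clips the participant had
#'   seen before (maturation control); default TRUE.
#' @param min_rating Inclusion threshold on the target-emotion rating.
#' @return Data frame of segment records: identifiers, ground-truth `label`
#'   (the target emotion for included segments), per-modality presence
#'   flags, `included` and `exclusion_reason`
#'   (`not_felt`/`missing_stream`/`seen_before`/`other` or NA). The segment
#'   list is attached as attribute `segments`.
#' @export
select_segments <- function(segments, ratings, exclude_seen_before = TRUE,
                            min_rating = 1) {
  if (inherits(segments, "emofun_cohort")) {
    if (missing(ratings)) ratings <- segments$ratings
    segments <- segments$segments
  }
  key <- paste(ratings$participant_id, ratings$clip_id, sep = "\r")
  recs <- lapply(segments, function(s) {
    i <- match(paste(s$participant_id, s$clip_id, sep = "\r"), key)
    if (is.na(i))
      stop(sprintf("no rating row for participant %s, clip %s",
                   s$participant_id, s$clip_id))
    rating <- as.numeric(ratings[[s$target_emotion]][i])
    seen <- isTRUE(as.logical(ratings$seen_before[i]))
    present <- vapply(MODALITIES, function(m) !is.null(s[[m]]), TRUE)
    reason <- NA_character_
    if (exclude_seen_before && seen) reason <- "seen_before"
    else if (is.na(rating) || rating < min_rating) reason <- "not_felt"
    else if (!any(present)) reason <- "missing_stream"
    data.frame(participant_id = s$participant_id, clip_id = s$clip_id,
               emotion = s$target_emotion, language = s$language,
               target_rating = rating,
               facial = present[["facial"]], head = present[["head"]],
               eye = present[["eye"]], autonomic = present[["autonomic"]],
               included = is.na(reason), exclusion_reason = reason)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "segments") <- segments
  out
}

#' Segment availability per modality, emotion and stimulus set
#'
#' Counts the included segments with each modality present, split by
#' language (the layout of the study's segment-availability table: rows =
#' modality, columns = emotion).
#'
#' @param records Output of [select_segments()].
#' @return Data frame with columns `language`, `modality` and one count
#'   column per emotion.
#' @export
segment_inventory <- function(records) {
  inc <- records[records$included, , drop = FALSE]
  rows <- list()
  for (lang in intersect(LANGUAGES, unique(records$language)))
    for (m in MODALITIES) {
      sub <- inc[inc$language == lang & inc[[m]], , drop = FALSE]
      counts <- vapply(EMOTIONS, function(e) sum(sub$emotion == e), 0L)
      rows[[length(rows) + 1L]] <-
        data.frame(language = lang, modality = m, as.list(counts),
                   check.names = FALSE)
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kept segments (and their rows) for one modality
#'
#' The classifier for modality m uses only included segments with modality m
#' present; per-modality availability may differ.
#'
#' @param records Output of [select_segments()].
#' @param modality One of `"facial"`, `"head"`, `"eye"`, `"autonomic"`.
#' @return Logical vector over the rows of `records`.
#' @export
modality_mask <- function(records, modality) {
  modality <- match.arg(modality, MODALITIES)
  records$included & records[[modality]]
}
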