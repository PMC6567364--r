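## Synthetic cohort generator: seeded participants x clips with configurable
## emotion-conditional structure in every sensor stream, plus self-ratings
## and an online-survey analogue. The streams only need the statistical
## structure the downstream pipeline assumes (class-conditional mean shifts,
## within-class noise, subject offsets, eye-absence episodes); no attempt is
## made to model tonic/phasic electrodermal dynamics or facial-muscle
## kinematics.

## per-channel baselines and within-class noise SDs, by modality
CHANNEL_DEFS <- list(
  facial = data.frame(name = paste0("au", 1:6), base = 0, sd = 0.15),
  head = data.frame(name = c("yaw", "pitch", "roll"), base = 0, sd = 4),
  eye = data.frame(
    name = c("gaze_lx", "gaze_ly", "gaze_rx", "gaze_ry",
             "dist_l", "dist_r", "pupil_l", "pupil_r"),
    base = c(0.5, 0.5, 0.5, 0.5, 600, 600, 3, 3),
    sd = c(0.08, 0.08, 0.08, 0.08, 8, 8, 0.3, 0.3)),
  autonomic = data.frame(name = c("scl", "temp"), base = c(5, 33),
                         sd = c(0.5, 0.3))
)

## centred six-class pattern with unit population SD; channel j uses the
## pattern rotated by j-1 so that classes are jointly separable across
## channels even when pairs coincide on a single channel
EMOTION_PATTERN <- local({
  p <- (1:6) - 3.5
  p / sqrt(mean(p^2))
})

pattern_for <- function(channel_index, emotion_index) {
  EMOTION_PATTERN[((emotion_index - 1L + channel_index - 1L) %% 6L) + 1L]
}

#' Describe one elicitation clip
#'
#' @param clip_id Unique clip identifier.
#' @param target_emotion One of [emotion_levels()].
#' @param language `"english"` or `"arabic"` (stimulus set tag).
#' @param duration_s Clip duration in seconds, positive.
#' @param target_intensity Mean self-rating (0-10 scale) of the target
#'   emotion among participants who felt it.
#' @param acceptance Probability that a survey respondent accepts the clip.
#' @return A `clip_spec` list.
#' @export
clip_spec <- function(clip_id, target_emotion, language, duration_s,
                      target_intensity = 6, acceptance = 0.75) {
  target_emotion <- match.arg(target_emotion, EMOTIONS)
  language <- match.arg(language, LANGUAGES)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("configuration error: duration_s must be a positive number")
  if (target_intensity < 0 || target_intensity > 10)
    stop("configuration error: target_intensity must be in [0, 10]")
  if (acceptance < 0 || acceptance > 1)
    stop("configuration error: acceptance must be in [0, 1]")
  structure(list(clip_id = as.character(clip_id),
                 target_emotion = target_emotion, language = language,
                 duration_s = as.numeric(duration_s),
                 target_intensity = target_intensity,
                 acceptance = acceptance),
            class = "emofun_clip")
}

#' The default twelve-clip stimulus set
#'
#' One clip per emotion and per stimulus language. Durations are the study's
#' stimulus durations (30-234 s); target intensities and acceptance
#' probabilities emulate the reported elicitation and acceptance pattern
#' (e.g. sadness/disgust strongest for the English set, amusement/disgust
#' for the Arabic set, low acceptance of the disgust clips).
#'
#' @param duration_scale Multiplier applied to every clip duration; values
#'   below 1 shrink the simulated recordings (useful for demos and quick
#'   runs) without touching the class-conditional structure.
#' @return List of [clip_spec()] objects.
#' @export
default_clips <- function(duration_scale = 1) {
  stopifnot(is.numeric(duration_scale), duration_scale > 0)
  en_dur <- c(amusement = 120, sadness = 164, anger = 234, fear = 82,
              surprise = 44, disgust = 65)
  ar_dur <- c(amusement = 174, sadness = 59, anger = 133, fear = 50,
              surprise = 45, disgust = 30)
  en_int <- c(amusement = 4, sadness = 5.5, anger = 4.5, fear = 4,
              surprise = 4, disgust = 5.5)
  ar_int <- c(amusement = 5.2, sadness = 4.5, anger = 5, fear = 3.5,
              surprise = 3.5, disgust = 5.5)
  en_acc <- c(amusement = 0.58, sadness = 0.85, anger = 0.72, fear = 0.82,
              surprise = 0.82, disgust = 0.45)
  ar_acc <- c(amusement = 0.70, sadness = 0.75, anger = 0.55, fear = 0.54,
              surprise = 0.80, disgust = 0.60)
  clips <- list()
  for (e in EMOTIONS) {
    clips[[paste0(e, "_en")]] <- clip_spec(paste0(e, "_en"), e, "english",
                                           en_dur[[e]] * duration_scale,
                                           en_int[[e]], en_acc[[e]])
    clips[[paste0(e, "_ar")]] <- clip_spec(paste0(e, "_ar"), e, "arabic",
                                           ar_dur[[e]] * duration_scale,
                                           ar_int[[e]], ar_acc[[e]])
  }
  unname(clips)
}

#' Configure a synthetic cohort
#'
#' @param n_participants Number of participants (default 29, the study's
#'   laboratory cohort size).
#' @param clips List of [clip_spec()] objects; default [default_clips()].
#' @param effect_size Class-mean separation per modality, in units of the
#'   within-class (per-sample) channel SD: scalar or vector named by
#'   modality. 0 means no emotion-conditional structure.
#' @param noise_sd Positive multiplier on each modality's per-channel noise
#'   SD; scalar or named vector.
#' @param var_scale Per-modality multiplicative spread of the within-class SD
#'   across emotions (1 = homoscedastic classes).
#' @param felt_probability Probability that a participant self-rates the
#'   clip's target emotion above zero.
#' @param subject_sd Between-participant baseline offset SD, in units of the
#'   channel noise SD (0 gives iid segments).
#' @param drop_prob Per-modality probability that a segment's stream is
#'   missing (device failure analogue); scalar or named vector.
#' @param absence_rate Per-frame probability that an eye-absence episode
#'   starts (validity flags false, pupil/gaze missing).
#' @param absence_mean_frames Mean episode length in frames.
#' @param seen_prob Probability a participant reports having seen a clip
#'   before.
#' @param seed Integer seed fixing every downstream draw.
#' @return An object of class `emofun_cohort_config`.
#' @export
cohort_config <- function(n_participants = 29, clips = default_clips(),
                          effect_size = 1, noise_sd = 1, var_scale = 1,
                          felt_probability = 0.85, subject_sd = 0.5,
                          drop_prob = c(facial = 0.3, head = 0.3,
                                        eye = 0.05, autonomic = 0.15),
                          absence_rate = 0.01, absence_mean_frames = 6,
                          seen_prob = 0.05, seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 0 ||
      n_participants != round(n_participants))
    stop("configuration error: n_participants must be a non-negative integer")
  if (!length(clips) || !all(vapply(clips, inherits, TRUE, "emofun_clip")))
    stop("configuration error: clips must be a non-empty list of clip_spec objects")
  effect_size <- per_modality(effect_size, "effect_size", 1)
  noise_sd <- per_modality(noise_sd, "noise_sd", 1)
  var_scale <- per_modality(var_scale, "var_scale", 1)
  drop_prob <- per_modality(drop_prob, "drop_prob", 0)
  if (any(effect_size < 0)) stop("configuration error: effect_size must be >= 0")
  if (any(noise_sd <= 0)) stop("configuration error: noise_sd must be > 0")
  if (any(var_scale <= 0)) stop("configuration error: var_scale must be > 0")
  for (p in c(felt_probability, subject_sd, absence_rate, seen_prob))
    if (!is.numeric(p) || length(p) != 1L || p < 0)
      stop("configuration error: probabilities and SDs must be non-negative scalars")
  if (felt_probability > 1 || absence_rate > 1 || seen_prob > 1 ||
      any(drop_prob < 0) || any(drop_prob > 1))
    stop("configuration error: probabilities must lie in [0, 1]")
  if (absence_mean_frames < 1)
    stop("configuration error: absence_mean_frames must be >= 1")
  structure(list(n_participants = as.integer(n_participants), clips = clips,
                 effect_size = effect_size, noise_sd = noise_sd,
                 var_scale = var_scale, felt_probability = felt_probability,
                 subject_sd = subject_sd, drop_prob = drop_prob,
                 absence_rate = absence_rate,
                 absence_mean_frames = absence_mean_frames,
                 seen_prob = seen_prob, seed = as.integer(seed)),
            class = "emofun_cohort_config")
}

## absence episodes as a logical flag vector (TRUE = absent)
absence_flags <- function(n, rate, mean_len) {
  if (n == 0L || rate <= 0) return(rep(FALSE, n))
  starts <- which(stats::runif(n) < rate)
  flags <- rep(FALSE, n)
  if (length(starts)) {
    lens <- 1L + stats::rgeom(length(starts), 1 / mean_len)
    idx <- unlist(mapply(function(s, l) s:min(n, s + l - 1L), starts, lens,
                         SIMPLIFY = FALSE))
    flags[idx] <- TRUE
  }
  flags
}

## one modality stream matrix: base + subject offset + emotion shift + noise
sim_channels <- function(n, defs, mod, emotion_index, cfg, subj_offset) {
  out <- matrix(NA_real_, n, nrow(defs), dimnames = list(NULL, defs$name))
  es <- cfg$effect_size[[mod]]
  nm <- cfg$noise_sd[[mod]]
  vs <- cfg$var_scale[[mod]]
  for (j in seq_len(nrow(defs))) {
    sd_j <- defs$sd[j] * nm
    pat <- pattern_for(j, emotion_index)
    sd_class <- sd_j * vs^(pat / max(abs(EMOTION_PATTERN)))
    mu <- defs$base[j] + subj_offset[j] + es * sd_j * pat
    out[, j] <- mu + stats::rnorm(n, 0, sd_class)
  }
  out
}

rating_draw <- function(n, mean10) {
  ## truncated discrete draw on 1..10 peaked at the requested mean
  p <- min(max((mean10 - 1) / 9, 0), 1)
  1L + stats::rbinom(n, 9L, p)
}

#' Generate a synthetic cohort
#'
#' Produces one time-aligned multimodal segment and one self-rating per
#' participant x clip. Streams are drawn from per-emotion baselines plus the
#' configured class-mean shift and Gaussian noise; participants carry random
#' baseline offsets shared across their segments; eye-absence episodes are
#' injected as validity-flag-false runs during which gaze and pupil values
#' are missing. Identical `(config, seed)` give bitwise-identical output.
#'
#' @param config An [cohort_config()] object.
#' @return An `emofun_cohort`: list with `segments` (list of
#'   `emofun_segment`), `ratings` (data frame, one row per participant x
#'   clip with 0-10 integer ratings for all six emotions) and `config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 2,
#'                      clips = default_clips(duration_scale = 0.1))
#' coh <- generate_cohort(cfg)
#' length(coh$segments)
generate_cohort <- function(config) {
  if (!inherits(config, "emofun_cohort_config"))
    stop("config must come from cohort_config()")
  with_seed(config$seed, {
    segments <- list()
    ratings <- list()
    for (pi in seq_len(config$n_participants)) {
      pid <- sprintf("P%02d", pi)
      offsets <- lapply(MODALITIES, function(m) {
        defs <- CHANNEL_DEFS[[m]]
        stats::rnorm(nrow(defs), 0,
                     config$subject_sd * defs$sd * config$noise_sd[[m]])
      })
      names(offsets) <- MODALITIES
      t0 <- 0
      for (cl in config$clips) {
        ei <- match(cl$target_emotion, EMOTIONS)
        nb <- round(cl$duration_s * RATE_BEHAVIOURAL)
        na <- round(cl$duration_s * RATE_AUTONOMIC)
        present <- stats::runif(length(MODALITIES)) >= config$drop_prob
        names(present) <- MODALITIES

        facial <- head_df <- eye <- autonomic <- NULL
        if (present[["facial"]]) {
          m <- sim_channels(nb, CHANNEL_DEFS$facial, "facial", ei, config,
                            offsets$facial)
          facial <- as.data.frame(pmin(pmax(m, -1), 1))
        }
        if (present[["head"]])
          head_df <- as.data.frame(
            sim_channels(nb, CHANNEL_DEFS$head, "head", ei, config,
                         offsets$head))
        if (present[["eye"]]) {
          m <- as.data.frame(
            sim_channels(nb, CHANNEL_DEFS$eye, "eye", ei, config,
                         offsets$eye))
          both <- absence_flags(nb, config$absence_rate,
                                config$absence_mean_frames)
          l_only <- absence_flags(nb, config$absence_rate / 2,
                                  config$absence_mean_frames) & !both
          r_only <- absence_flags(nb, config$absence_rate / 2,
                                  config$absence_mean_frames) & !both & !l_only
          m$valid_l <- !(both | l_only)
          m$valid_r <- !(both | r_only)
          m[!m$valid_l, c("gaze_lx", "gaze_ly", "dist_l", "pupil_l")] <- NA
          m[!m$valid_r, c("gaze_rx", "gaze_ry", "dist_r", "pupil_r")] <- NA
          eye <- m
        }
        if (present[["autonomic"]]) {
          m <- as.data.frame(
            sim_channels(na, CHANNEL_DEFS$autonomic, "autonomic", ei, config,
                         offsets$autonomic))
          m <- cbind(timestamp_ms = t0 + (seq_len(na) - 1) /
                       RATE_AUTONOMIC * 1000, m)
          autonomic <- m
        }

        felt <- stats::runif(1) < config$felt_probability
        r <- stats::setNames(stats::rbinom(6L, 10L, 0.12), EMOTIONS)
        r[[cl$target_emotion]] <-
          if (felt) rating_draw(1L, cl$target_intensity) else 0L
        seen <- stats::runif(1) < config$seen_prob

        seg <- structure(list(
          participant_id = pid, clip_id = cl$clip_id,
          target_emotion = cl$target_emotion, language = cl$language,
          start_timestamp_ms = t0, duration_s = cl$duration_s,
          facial = facial, head = head_df, eye = eye, autonomic = autonomic,
          rates = list(facial = RATE_BEHAVIOURAL, head = RATE_BEHAVIOURAL,
                       eye = RATE_BEHAVIOURAL, autonomic = RATE_AUTONOMIC)),
          class = "emofun_segment")
        segments[[length(segments) + 1L]] <- seg
        ratings[[length(ratings) + 1L]] <- data.frame(
          participant_id = pid, clip_id = cl$clip_id,
          as.list(r), seen_before = seen,
          looked_away = stats::runif(1) < 0.05,
          check.names = FALSE)
        t0 <- t0 + (cl$duration_s + 5) * 1000  # 5 s inter-clip countdown
      }
    }
    structure(list(segments = segments,
                   ratings = do.call(rbind, ratings),
                   config = config),
              class = "emofun_cohort")
  })
}

#' @export
print.emofun_segment <- function(x, ...) {
  have <- MODALITIES[!vapply(x[MODALITIES], is.null, TRUE)]
  cat(sprintf("<segment %s x %s (%s, %s): %gs, streams: %s>\n",
              x$participant_id, x$clip_id, x$target_emotion, x$language,
              x$duration_s, paste(have, collapse = ", ")))
  invisible(x)
}

#' @export
print.emofun_cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d participants x %d clips = %d segments>\n",
              x$config$n_participants, length(x$config$clips),
              length(x$segments)))
  invisible(x)
}

## per-clip respondent counts reported for the online survey, in viewing
## order (per emotion: english then arabic); used to derive the default
## cumulative dropout profile
SURVEY_RESPONSES <- c(345, 289, 258, 242, 226, 208, 196, 190, 182, 175, 171, 166)

#' Default per-clip dropout probabilities for the survey generator
#'
#' Derived from the study's per-clip respondent counts (345 down to 166 over
#' twelve clips in viewing order): the probability of dropping out after
#' clip i is `1 - n[i+1]/n[i]`.
#'
#' @param n_clips Number of clips in viewing order.
#' @return Numeric vector of length `n_clips` (last entry 0).
#' @export
default_dropout <- function(n_clips = 12L) {
  d <- 1 - SURVEY_RESPONSES[-1] / SURVEY_RESPONSES[-length(SURVEY_RESPONSES)]
  out <- rep(mean(d), n_clips)
  out[seq_len(min(n_clips - 1L, length(d)))] <- d[seq_len(min(n_clips - 1L, length(d)))]
  out[n_clips] <- 0
  out
}

#' Generate a synthetic online-survey response table
#'
#' Respondents watch the clips in a fixed viewing order (per emotion:
#' English then Arabic) and may drop out after each clip, so per-clip
#' respondent counts decrease monotonically along the viewing order.
#' Ratings follow the same self-rating model as the laboratory cohort;
#' acceptance is Bernoulli with each clip's acceptance probability.
#'
#' @param config An [cohort_config()]; its clips, felt probability and seed
#'   are used.
#' @param dropout_per_clip Probability of dropping out after each clip, in
#'   viewing order; default [default_dropout()].
#' @param n_respondents Number of respondents starting the survey.
#' @param prop_female Proportion of female respondents.
#' @return Data frame with one row per respondent x watched clip:
#'   respondent id, gender, clip id, target emotion, language, six 0-10
#'   emotion ratings, and `accepted`.
#' @export
generate_survey_table <- function(config, dropout_per_clip = NULL,
                                  n_respondents = 345, prop_female = 0.84) {
  if (!inherits(config, "emofun_cohort_config"))
    stop("config must come from cohort_config()")
  clips <- config$clips
  ord <- order(match(vapply(clips, `[[`, "", "target_emotion"), EMOTIONS),
               match(vapply(clips, `[[`, "", "language"), LANGUAGES))
  clips <- clips[ord]
  if (is.null(dropout_per_clip)) dropout_per_clip <- default_dropout(length(clips))
  if (length(dropout_per_clip) != length(clips))
    stop("dropout_per_clip must have one entry per clip")
  if (any(dropout_per_clip < 0 | dropout_per_clip > 1))
    stop("configuration error: dropout probabilities must be in [0, 1]")
  with_seed(config$seed + 7919L, {
    rows <- list()
    gender <- ifelse(stats::runif(n_respondents) < prop_female, "F", "M")
    active <- rep(TRUE, n_respondents)
    for (ci in seq_along(clips)) {
      cl <- clips[[ci]]
      ids <- which(active)
      n <- length(ids)
      if (n > 0L) {
        felt <- stats::runif(n) < config$felt_probability
        target <- integer(n)
        target[felt] <- rating_draw(sum(felt), cl$target_intensity)
        r <- matrix(stats::rbinom(n * 6L, 10L, 0.12), n, 6L,
                    dimnames = list(NULL, EMOTIONS))
        r[, cl$target_emotion] <- target
        rows[[ci]] <- data.frame(
          respondent_id = sprintf("R%04d", ids), gender = gender[ids],
          clip_id = cl$clip_id, emotion = cl$target_emotion,
          language = cl$language, as.data.frame(r),
          accepted = stats::runif(n) < cl$acceptance,
          check.names = FALSE)
      }
      active <- active & (stats::runif(n_respondents) >= dropout_per_clip[ci])
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
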