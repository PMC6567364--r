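## Per-modality statistical-functional extractors. Each extractor maps one
## segment's raw streams to a fixed-length named feature vector:
##   facial 288, head 184, eye 147, autonomic 108, concatenated 727.
## Block lengths and the name <-> position bijection are asserted when the
## registry is first built.

N_FEATURES <- c(facial = 288L, head = 184L, eye = 147L, autonomic = 108L)

BASIC_STATS <- c("mean", "range", "min", "max", "sd", "var")
DUR6 <- c("dur_max", "dur_min", "dur_range", "dur_mean", "dur_rate", "count")
DUR7 <- c("dur_max", "dur_min", "dur_range", "dur_mean", "dur_var",
          "dur_total", "dur_rate")

stats_names <- function(ch) paste(ch, BASIC_STATS, sep = "_")
dur6_names <- function(prefix) paste(prefix, DUR6, sep = "_")
dur7_names <- function(prefix) paste(prefix, DUR7, sep = "_")

## seven-value duration block used by the head event features: max, min,
## range, mean and variance of run durations (s), total duration (s), and
## run-frame rate
duration_stats7 <- function(rs, rate) {
  if (length(rs$start) == 0L)
    return(stats::setNames(rep(0, 7L), DUR7))
  frames <- rs$end - rs$start
  d <- frames / rate
  v <- if (length(d) == 1L) 0 else stats::var(d)
  stats::setNames(c(max(d), min(d), max(d) - min(d), mean(d), v, sum(d),
                    sum(frames) / rs$total_frames), DUR7)
}

modality_absent <- function(modality) {
  stop(structure(class = c("emofun_modality_absent", "error", "condition"),
                 list(message = sprintf("segment has no %s stream", modality),
                      call = sys.call(-1))))
}

vel_of <- function(x) c(NA_real_, diff(x))
acc_of <- function(x) c(NA_real_, NA_real_, diff(x, differences = 2L))

#' Facial action-unit features (288)
#'
#' Low level: six AU intensity channels in \[-1, 1\] at 30 frames/s plus
#' their framewise velocity and acceleration (18 channels). Functionals: the
#' six basic statistics per channel (108), and the six duration statistics
#' for five run types per AU (180): AU-active occurrence (intensity above
#' its segment mean + SD) and the fast/slow/continuous/steady event runs.
#'
#' @param segment An `emofun_segment`.
#' @return Named numeric vector of length 288 with attribute
#'   `modality = "facial"`.
#' @export
facial_features <- function(segment) {
  df <- segment$facial
  if (is.null(df)) modality_absent("facial")
  rate <- segment$rates$facial %||% RATE_BEHAVIOURAL
  aus <- paste0("au", 1:6)
  x <- lapply(aus, function(a) df[[a]])
  names(x) <- aus
  chans <- c(x,
             stats::setNames(lapply(x, vel_of), paste0(aus, "_vel")),
             stats::setNames(lapply(x, acc_of), paste0(aus, "_acc")))
  out <- numeric(0)
  for (cn in names(chans))
    out <- c(out, stats::setNames(basic_stats(chans[[cn]]), stats_names(cn)))
  for (a in aus) {
    active <- safe_threshold_runs(x[[a]], "above")
    ev <- event_channels(x[[a]], rate = rate)
    rsets <- c(list(active = active), ev)
    for (tp in c("active", "fast", "slow", "continuous", "steady"))
      out <- c(out, stats::setNames(duration_stats(rsets[[tp]], rate),
                                    dur6_names(paste(a, tp, sep = "_"))))
  }
  structure(out, modality = "facial")
}

## head-axis direction states with a frontal dead zone of `deadzone` degrees:
## -1 / 0 / +1 per frame, NA where the angle is missing
axis_state <- function(angle, deadzone) {
  s <- ifelse(angle > deadzone, 1L, ifelse(angle < -deadzone, -1L, 0L))
  s[is.na(angle)] <- NA_integer_
  s
}

#' Head-pose features (184)
#'
#' Low level: yaw, pitch and roll angles (degrees, 30 frames/s) plus
#' velocities and accelerations (9 channels). Functionals: six basic
#' statistics per channel (54); max/min/range/mean duration per head
#' direction left/right/up/down/clockwise/anticlockwise (24); per-direction
#' duration rate and direction-diversity rate (12); per-direction
#' change-in-direction rate (6); direction-change counts for yaw, roll,
#' pitch plus their grand total (4); and seven duration statistics for
#' slow/fast/steady/continuous movement per axis (84). Directions use a
#' dead zone of `deadzone` degrees around frontal.
#'
#' @param segment An `emofun_segment`.
#' @param deadzone Angular dead zone (degrees) defining the frontal state.
#' @return Named numeric vector of length 184 with attribute
#'   `modality = "head"`.
#' @export
head_features <- function(segment, deadzone = 5) {
  df <- segment$head
  if (is.null(df)) modality_absent("head")
  rate <- segment$rates$head %||% RATE_BEHAVIOURAL
  axes <- c("yaw", "pitch", "roll")
  ang <- lapply(axes, function(a) df[[a]])
  names(ang) <- axes
  chans <- c(ang,
             stats::setNames(lapply(ang, vel_of), paste0(axes, "_vel")),
             stats::setNames(lapply(ang, acc_of), paste0(axes, "_acc")))
  out <- numeric(0)
  for (cn in names(chans))
    out <- c(out, stats::setNames(basic_stats(chans[[cn]]), stats_names(cn)))

  states <- lapply(ang, axis_state, deadzone = deadzone)
  n <- length(ang$yaw)
  ## direction -> (axis, sign)
  dirs <- list(left = c("yaw", -1), right = c("yaw", 1),
               up = c("pitch", 1), down = c("pitch", -1),
               clockwise = c("roll", 1), anticlockwise = c("roll", -1))
  dir_ind <- lapply(dirs, function(d) states[[d[1]]] == as.integer(d[2]))
  dir_runs <- lapply(dir_ind, runs_from_logical)
  for (dn in names(dirs))
    out <- c(out, stats::setNames(
      duration_stats(dir_runs[[dn]], rate)[c("dur_max", "dur_min",
                                             "dur_range", "dur_mean")],
      paste(dn, c("dur_max", "dur_min", "dur_range", "dur_mean"), sep = "_")))

  ## framewise direction state per frame across the six directions, for the
  ## diversity rate: which of the six directions are visited during frames
  ## where the direction's own axis is non-frontal
  for (dn in names(dirs)) {
    ax <- dirs[[dn]][1]
    nonfrontal <- !is.na(states[[ax]]) & states[[ax]] != 0L
    visited <- vapply(dir_ind, function(ind) any(ind[nonfrontal], na.rm = TRUE),
                      TRUE)
    out <- c(out, stats::setNames(
      c(duration_stats(dir_runs[[dn]], rate)[["dur_rate"]],
        sum(visited) / 6),
      paste(dn, c("dur_rate", "diversity_rate"), sep = "_")))
  }

  ## change-in-direction rate: transitions of the axis state that land in
  ## this direction, per total frames
  for (dn in names(dirs)) {
    ax <- dirs[[dn]][1]; sg <- as.integer(dirs[[dn]][2])
    s <- states[[ax]]
    chg <- !is.na(s[-1]) & !is.na(s[-n]) & s[-1] != s[-n] & s[-1] == sg
    out <- c(out, stats::setNames(sum(chg) / n, paste0(dn, "_change_rate")))
  }

  ## direction-change counts per axis (order yaw, roll, pitch) + grand total
  counts <- vapply(c("yaw", "roll", "pitch"), function(ax) {
    s <- states[[ax]]
    sum(!is.na(s[-1]) & !is.na(s[-n]) & s[-1] != s[-n])
  }, 0)
  out <- c(out, stats::setNames(c(counts, sum(counts)),
                                c("dirchanges_yaw", "dirchanges_roll",
                                  "dirchanges_pitch", "dirchanges_total")))

  ## slow/fast/steady/continuous movement per axis, seven duration stats
  for (ax in c("yaw", "roll", "pitch")) {
    ev <- event_channels(ang[[ax]], rate = rate)
    for (tp in c("slow", "fast", "steady", "continuous"))
      out <- c(out, stats::setNames(duration_stats7(ev[[tp]], rate),
                                    dur7_names(paste(ax, tp, sep = "_"))))
  }
  structure(out, modality = "head")
}

#' Eye activity and gaze features (147)
#'
#' Low level (9 channels at 30 frames/s, frames with undetected eyes
#' excluded as missing): per-eye gaze-point frame-to-frame displacement with
#' its velocity and acceleration (6); the left-minus-right eye-to-tracker
#' distance difference, an approximate head-rotation cue (1); and per-eye
#' pupil size normalised by its segment mean (2). Functionals: six basic
#' statistics per channel (54); mean/SD/variance of the absence indicators
#' for left-only, right-only and both pupils (9); and six duration
#' statistics for fast/slow gaze change per eye (24), three head-rotation
#' categories from the distance-difference channel (18), large/small pupil
#' per eye (24) and absence of left-only/right-only/both pupils (18).
#'
#' @param segment An `emofun_segment`.
#' @return Named numeric vector of length 147 with attribute
#'   `modality = "eye"`.
#' @export
eye_features <- function(segment) {
  df <- segment$eye
  if (is.null(df)) modality_absent("eye")
  rate <- segment$rates$eye %||% RATE_BEHAVIOURAL

  disp <- function(x, y) {
    d <- sqrt(diff(x)^2 + diff(y)^2)
    c(NA_real_, d)
  }
  disp_l <- disp(df$gaze_lx, df$gaze_ly)
  disp_r <- disp(df$gaze_rx, df$gaze_ry)
  dist_diff <- df$dist_l - df$dist_r
  norm_pupil <- function(p) p / mean(p, na.rm = TRUE)
  pn_l <- norm_pupil(df$pupil_l)
  pn_r <- norm_pupil(df$pupil_r)

  chans <- list(disp_l = disp_l, disp_r = disp_r,
                disp_l_vel = vel_of(disp_l), disp_r_vel = vel_of(disp_r),
                disp_l_acc = acc_of(disp_l), disp_r_acc = acc_of(disp_r),
                dist_diff = dist_diff, pupil_l_norm = pn_l,
                pupil_r_norm = pn_r)
  out <- numeric(0)
  for (cn in names(chans))
    out <- c(out, stats::setNames(basic_stats(chans[[cn]]), stats_names(cn)))

  valid_l <- as.logical(df$valid_l)
  valid_r <- as.logical(df$valid_r)
  absence <- list(absence_left = !valid_l & valid_r,
                  absence_right = valid_l & !valid_r,
                  absence_both = !valid_l & !valid_r)
  for (an in names(absence)) {
    ind <- as.numeric(absence[[an]])
    s <- if (length(ind) > 1L) stats::sd(ind) else 0
    out <- c(out, stats::setNames(c(mean(ind), s, s * s),
                                  paste(an, c("mean", "sd", "var"), sep = "_")))
  }

  ## fast and slow gaze change per eye (from displacement velocity magnitude)
  for (eye in c("l", "r")) {
    ev <- event_channels(chans[[paste0("disp_", eye)]], rate = rate)
    for (tp in c("fast", "slow"))
      out <- c(out, stats::setNames(
        duration_stats(ev[[tp]], rate),
        dur6_names(paste0("gaze_", eye, "_", tp))))
  }

  ## head-rotation categories from the eye-distance difference channel
  ok <- !is.na(dist_diff)
  if (sum(ok) >= 2L) {
    mu <- mean(dist_diff[ok]); s <- stats::sd(dist_diff[ok])
    ind_left <- dist_diff < mu - s
    ind_right <- dist_diff > mu + s
  } else {
    ind_left <- ind_right <- rep(FALSE, length(dist_diff))
  }
  rot <- list(rot_left = runs_from_logical(ind_left),
              rot_right = runs_from_logical(ind_right),
              rot_any = runs_from_logical(ind_left | ind_right))
  for (rn in names(rot))
    out <- c(out, stats::setNames(duration_stats(rot[[rn]], rate),
                                  dur6_names(rn)))

  ## large and small pupil per eye on the normalised series
  for (eye in c("l", "r")) {
    pn <- chans[[paste0("pupil_", eye, "_norm")]]
    out <- c(out, stats::setNames(
      duration_stats(safe_threshold_runs(pn, "above"), rate),
      dur6_names(paste0("pupil_", eye, "_large"))))
    out <- c(out, stats::setNames(
      duration_stats(safe_threshold_runs(pn, "below"), rate),
      dur6_names(paste0("pupil_", eye, "_small"))))
  }

  ## absence runs
  for (an in names(absence))
    out <- c(out, stats::setNames(
      duration_stats(runs_from_logical(absence[[an]]), rate),
      dur6_names(paste0(an, "_run"))))

  structure(out, modality = "eye")
}

#' Skin-conductance and temperature features (108)
#'
#' Low level (32 Hz): skin conductance level (microsiemens) and peripheral
#' temperature (degrees C) plus velocities and accelerations (6 channels).
#' Functionals: six basic statistics per channel (36) and six duration
#' statistics for six run types per signal (72): high/low level (raw signal
#' above/below its segment mean +/- SD) and the fast/slow/continuous/steady
#' event runs.
#'
#' @param segment An `emofun_segment`.
#' @return Named numeric vector of length 108 with attribute
#'   `modality = "autonomic"`.
#' @export
autonomic_features <- function(segment) {
  df <- segment$autonomic
  if (is.null(df)) modality_absent("autonomic")
  rate <- segment$rates$autonomic %||% RATE_AUTONOMIC
  sig <- list(scl = df$scl, temp = df$temp)
  chans <- list(scl = sig$scl, temp = sig$temp,
                scl_vel = vel_of(sig$scl), temp_vel = vel_of(sig$temp),
                scl_acc = acc_of(sig$scl), temp_acc = acc_of(sig$temp))
  out <- numeric(0)
  for (cn in names(chans))
    out <- c(out, stats::setNames(basic_stats(chans[[cn]]), stats_names(cn)))
  rsets <- lapply(sig, function(x) {
    ev <- event_channels(x, rate = rate)
    c(list(high = safe_threshold_runs(x, "above"),
           low = safe_threshold_runs(x, "below")), ev)
  })
  for (tp in c("high", "low", "fast", "slow", "continuous", "steady"))
    for (sn in c("scl", "temp"))
      out <- c(out, stats::setNames(duration_stats(rsets[[sn]][[tp]], rate),
                                    dur6_names(paste(sn, tp, sep = "_"))))
  structure(out, modality = "autonomic")
}

## -- registry -----------------------------------------------------------

.emofun_env <- new.env(parent = emptyenv())

## tiny deterministic segment used only to derive the canonical name order
dummy_segment <- function() {
  nb <- 12L; na <- 13L
  ramp <- seq(0, 0.5, length.out = nb)
  structure(list(
    participant_id = "dummy", clip_id = "dummy", target_emotion = "amusement",
    language = "english", start_timestamp_ms = 0, duration_s = nb / RATE_BEHAVIOURAL,
    facial = as.data.frame(stats::setNames(rep(list(ramp), 6), paste0("au", 1:6))),
    head = data.frame(yaw = ramp, pitch = ramp, roll = ramp),
    eye = data.frame(gaze_lx = ramp, gaze_ly = ramp, gaze_rx = ramp,
                     gaze_ry = ramp, dist_l = 600 + ramp, dist_r = 600 - ramp,
                     pupil_l = 3 + ramp, pupil_r = 3 - ramp,
                     valid_l = TRUE, valid_r = TRUE),
    autonomic = data.frame(timestamp_ms = (seq_len(na) - 1) / RATE_AUTONOMIC * 1000,
                           scl = 5 + seq(0, 0.5, length.out = na),
                           temp = 33 + seq(0, 0.5, length.out = na)),
    rates = list(facial = RATE_BEHAVIOURAL, head = RATE_BEHAVIOURAL,
                 eye = RATE_BEHAVIOURAL, autonomic = RATE_AUTONOMIC)),
    class = "emofun_segment")
}

#' Canonical feature registry
#'
#' The stable bijection between feature names and positions, per modality
#' and for the 727-entry concatenation (order facial, head, eye,
#' autonomic). Feature names are prefixed with their modality. Block
#' lengths (288/184/147/108) are asserted when the registry is first built.
#'
#' @return Data frame with columns `index`, `modality`, `name`.
#' @export
#' @examples
#' nrow(feature_registry())  # 727
feature_registry <- function() {
  if (!is.null(.emofun_env$registry)) return(.emofun_env$registry)
  seg <- dummy_segment()
  fns <- list(facial = facial_features, head = head_features,
              eye = eye_features, autonomic = autonomic_features)
  names_by_mod <- lapply(MODALITIES, function(m) {
    v <- fns[[m]](seg)
    if (length(v) != N_FEATURES[[m]])
      stop(sprintf("internal error: %s extractor yields %d features, expected %d",
                   m, length(v), N_FEATURES[[m]]))
    paste(m, names(v), sep = ".")
  })
  reg <- data.frame(
    index = seq_len(sum(N_FEATURES)),
    modality = rep(MODALITIES, N_FEATURES[MODALITIES]),
    name = unlist(names_by_mod))
  if (anyDuplicated(reg$name))
    stop("internal error: duplicated feature names in registry")
  stopifnot(nrow(reg) == 727L)
  .emofun_env$registry <- reg
  reg
}

#' Extract the full 727-entry feature vector for one segment
#'
#' Concatenates the four modality blocks in fixed order facial, head, eye,
#' autonomic. Absent modalities yield missing-valued blocks of the correct
#' length; if every modality is absent an error is raised.
#'
#' @param segment An `emofun_segment`.
#' @return Named numeric vector of length 727.
#' @export
extract_all <- function(segment) {
  reg <- feature_registry()
  if (all(vapply(MODALITIES, function(m) is.null(segment[[m]]), TRUE)))
    stop("segment has no modality streams at all")
  fns <- list(facial = facial_features, head = head_features,
              eye = eye_features, autonomic = autonomic_features)
  blocks <- lapply(MODALITIES, function(m) {
    v <- tryCatch(fns[[m]](segment),
                  emofun_modality_absent = function(e) NULL)
    if (is.null(v)) rep(NA_real_, N_FEATURES[[m]]) else as.numeric(v)
  })
  stats::setNames(unlist(blocks), reg$name)
}

#' Build the segments x features matrix for a set of segments
#'
#' @param segments A list of `emofun_segment` objects or an `emofun_cohort`.
#' @return Data frame with metadata columns (`participant_id`, `clip_id`,
#'   `emotion`, `language`) followed by the 727 named feature columns.
#' @export
extract_features <- function(segments) {
  if (inherits(segments, "emofun_cohort")) segments <- segments$segments
  reg <- feature_registry()
  mat <- t(vapply(segments, extract_all, numeric(nrow(reg))))
  meta <- data.frame(
    participant_id = vapply(segments, `[[`, "", "participant_id"),
    clip_id = vapply(segments, `[[`, "", "clip_id"),
    emotion = vapply(segments, `[[`, "", "target_emotion"),
    language = vapply(segments, `[[`, "", "language"))
  cbind(meta, as.data.frame(mat))
}

#' Metadata column names of a feature matrix
#' @return Character vector.
#' @export
feature_meta_cols <- function() c("participant_id", "clip_id", "emotion", "language")

#' Low-level (framewise) channel names per modality
#'
#' The per-frame signals each extractor summarises: 18 facial (6 AU
#' intensities with velocities and accelerations), 9 head (three pose
#' angles with derivatives), 9 eye (per-eye gaze displacement with
#' derivatives, the eye-distance difference, per-eye normalised pupil) and
#' 6 autonomic (SCL and temperature with derivatives). Each channel `ch`
#' owns the six `<modality>.<ch>_<stat>` entries of [feature_registry()].
#'
#' @param modality One of `"facial"`, `"head"`, `"eye"`, `"autonomic"`.
#' @return Character vector of channel names.
#' @export
lowlevel_channels <- function(modality) {
  modality <- match.arg(modality, MODALITIES)
  base <- switch(modality,
                 facial = paste0("au", 1:6),
                 head = c("yaw", "pitch", "roll"),
                 eye = c("disp_l", "disp_r"),
                 autonomic = c("scl", "temp"))
  chans <- c(base, paste0(base, "_vel"), paste0(base, "_acc"))
  if (modality == "eye")
    chans <- c("disp_l", "disp_r", "disp_l_vel", "disp_r_vel",
               "disp_l_acc", "disp_r_acc", "dist_diff",
               "pupil_l_norm", "pupil_r_norm")
  chans
}
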