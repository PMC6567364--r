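## Independent brute-force oracles and fixture builders used across tests.

## frame-by-frame scan for maximal runs strictly beyond a threshold;
## independent of the rle-based implementation under test
brute_runs <- function(x, side, floor_at_zero = FALSE) {
  ok <- !is.na(x)
  mu <- mean(x[ok])
  s <- sd(x[ok])
  thr <- if (side == "above") mu + s else {
    t0 <- mu - s
    if (floor_at_zero) max(t0, 0) else t0
  }
  beyond <- if (side == "above") !is.na(x) & x > thr else !is.na(x) & x < thr
  starts <- integer(0); ends <- integer(0)
  in_run <- FALSE
  for (i in seq_along(x)) {
    if (beyond[i] && !in_run) { starts <- c(starts, i); in_run <- TRUE }
    if (!beyond[i] && in_run) { ends <- c(ends, i); in_run <- FALSE }
  }
  if (in_run) ends <- c(ends, length(x) + 1L)
  list(start = starts, end = ends)
}

## arithmetic oracle for the six duration statistics
brute_duration <- function(start, end, total, rate) {
  if (length(start) == 0L) return(c(0, 0, 0, 0, 0, 0))
  d <- (end - start) / rate
  c(max(d), min(d), max(d) - min(d), mean(d), sum(end - start) / total,
    length(d))
}

## closed-form Welch statistic (textbook formula)
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  c(t = t, df = df, p = p)
}

## random channel with optional missing frames, for oracle-equivalence loops
random_channel <- function(n, na_frac = 0) {
  x <- rnorm(n)
  if (na_frac > 0) x[sample(n, max(1, round(na_frac * n)))] <- NA
  x
}

## hand-built segment with full control over every stream
make_segment <- function(nb = 90L, na = 96L,
                         facial = NULL, head = NULL, eye = NULL,
                         autonomic = NULL, participant = "P01",
                         clip = "amusement_en", emotion = "amusement",
                         language = "english") {
  if (is.null(facial))
    facial <- as.data.frame(setNames(rep(list(rep(0.1, nb)), 6),
                                     paste0("au", 1:6)))
  if (is.null(head))
    head <- data.frame(yaw = rep(0, nb), pitch = rep(0, nb),
                       roll = rep(0, nb))
  if (is.null(eye))
    eye <- data.frame(gaze_lx = rep(0.5, nb), gaze_ly = rep(0.5, nb),
                      gaze_rx = rep(0.5, nb), gaze_ry = rep(0.5, nb),
                      dist_l = rep(600, nb), dist_r = rep(600, nb),
                      pupil_l = rep(3, nb), pupil_r = rep(3, nb),
                      valid_l = rep(TRUE, nb), valid_r = rep(TRUE, nb))
  if (is.null(autonomic))
    autonomic <- data.frame(timestamp_ms = (seq_len(na) - 1) / 32 * 1000,
                            scl = rep(5, na), temp = rep(33, na))
  structure(list(participant_id = participant, clip_id = clip,
                 target_emotion = emotion, language = language,
                 start_timestamp_ms = 0, duration_s = nb / 30,
                 facial = facial, head = head, eye = eye,
                 autonomic = autonomic,
                 rates = list(facial = 30, head = 30, eye = 30,
                              autonomic = 32)),
            class = "emofun_segment")
}

## small fast cohort configurations for tests
tiny_clips <- function(duration_s = 6) {
  clips <- list()
  for (e in emotion_levels())
    for (lg in c("english", "arabic"))
      clips[[paste0(e, "_", substr(lg, 1, 2))]] <-
        clip_spec(paste0(e, "_", substr(lg, 1, 2)), e, lg, duration_s)
  unname(clips)
}

expect_runs_equal <- function(rs, oracle) {
  expect_equal(as.integer(rs$start), as.integer(oracle$start))
  expect_equal(as.integer(rs$end), as.integer(oracle$end))
}
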