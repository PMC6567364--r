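test_that("feature blocks have the canonical lengths and a stable name bijection", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 727)
  expect_equal(unname(table(reg$modality)[c("facial", "head", "eye", "autonomic")]),
               c(288L, 184L, 147L, 108L), ignore_attr = TRUE)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_identical(reg$name, feature_registry()$name)  # cached and stable
  ## order is facial, head, eye, autonomic
  expect_equal(unique(reg$modality), c("facial", "head", "eye", "autonomic"))
})

test_that("constant streams yield zero duration and zero spread features", {
  seg <- make_segment()                 # all-constant streams
  f <- facial_features(seg)
  expect_length(f, 288)
  expect_true(all(f[grepl("_(dur_|count)", names(f))] == 0))
  expect_true(all(f[grepl("_var$|_sd$|_range$", names(f))] == 0))

  h <- head_features(seg)               # motionless, frontal head
  expect_length(h, 184)
  expect_true(all(h[grepl("^(left|right|up|down|clockwise|anticlockwise)_dur",
                          names(h))] == 0))
  expect_true(all(h[grepl("^dirchanges_", names(h))] == 0))

  e <- eye_features(seg)                # both eyes valid every frame
  expect_length(e, 147)
  expect_true(all(e[grepl("^absence_", names(e))] == 0))

  a <- autonomic_features(seg)          # constant SCL and temperature
  expect_length(a, 108)
  dur <- a[grepl("_(high|low|fast|slow|continuous|steady)_", names(a))]
  expect_length(dur, 72)
  expect_true(all(dur == 0))
})

test_that("head direction features respond to sustained rotations", {
  nb <- 120L
  yaw <- c(rep(0, 40), rep(-12, 40), rep(12, 40))   # frontal, left, right
  seg <- make_segment(nb = nb,
                      head = data.frame(yaw = yaw, pitch = rep(0, nb),
                                        roll = rep(0, nb)))
  h <- head_features(seg)
  expect_equal(h[["left_dur_max"]], 40 / 30)
  expect_equal(h[["right_dur_max"]], 40 / 30)
  expect_equal(h[["up_dur_max"]], 0)
  expect_equal(h[["left_dur_rate"]], 40 / 120)
  expect_equal(h[["dirchanges_yaw"]], 2)
  expect_equal(h[["dirchanges_total"]], 2)
})

test_that("eye absence indicators count validity-flag patterns", {
  nb <- 60L
  eye <- data.frame(gaze_lx = runif(nb), gaze_ly = runif(nb),
                    gaze_rx = runif(nb), gaze_ry = runif(nb),
                    dist_l = rnorm(nb, 600), dist_r = rnorm(nb, 600),
                    pupil_l = rnorm(nb, 3, 0.1), pupil_r = rnorm(nb, 3, 0.1),
                    valid_l = rep(TRUE, nb), valid_r = rep(TRUE, nb))
  eye$valid_l[11:16] <- FALSE                       # left-only absence
  eye$valid_l[31:34] <- FALSE; eye$valid_r[31:34] <- FALSE  # both
  eye[!eye$valid_l, c("gaze_lx", "gaze_ly", "dist_l", "pupil_l")] <- NA
  eye[!eye$valid_r, c("gaze_rx", "gaze_ry", "dist_r", "pupil_r")] <- NA
  f <- eye_features(make_segment(nb = nb, eye = eye))
  expect_equal(f[["absence_left_mean"]], 6 / 60)
  expect_equal(f[["absence_both_mean"]], 4 / 60)
  expect_equal(f[["absence_right_mean"]], 0)
  expect_equal(f[["absence_left_run_count"]], 1)
  expect_equal(f[["absence_left_run_dur_max"]], 6 / 30)
  expect_equal(f[["absence_both_run_dur_rate"]], 4 / 60)
})

test_that("the concatenated vector is 727 long with missing blocks for absent modalities", {
  seg <- make_segment()
  v <- extract_all(seg)
  expect_length(v, 727)
  expect_identical(names(v), feature_registry()$name)
  expect_identical(v, extract_all(seg))              # deterministic

  only_aut <- make_segment()
  only_aut$facial <- only_aut$head <- only_aut$eye <- NULL
  v2 <- extract_all(only_aut)
  expect_equal(sum(is.na(v2)), 727 - 108)
  expect_true(all(!is.na(v2[feature_registry()$modality == "autonomic"])))

  none <- make_segment()
  none$facial <- none$head <- none$eye <- none$autonomic <- NULL
  expect_error(extract_all(none), "no modality")

  expect_error(facial_features(only_aut), class = "emofun_modality_absent")
})

test_that("duration rates, counts and variance pairs satisfy their invariants", {
  set.seed(55)
  cfg <- cohort_config(n_participants = 1, clips = tiny_clips(8), seed = 56,
                       drop_prob = 0)
  coh <- generate_cohort(cfg)
  feats <- extract_features(coh$segments[1:4])
  reg <- feature_registry()
  x <- as.matrix(feats[, reg$name])
  rates <- x[, grepl("dur_rate$", colnames(x)), drop = FALSE]
  expect_true(all(rates >= 0 & rates <= 1, na.rm = TRUE))
  counts <- x[, grepl("(count|dirchanges_.*)$", colnames(x)), drop = FALSE]
  expect_true(all(counts >= 0 & counts == round(counts), na.rm = TRUE))
  sds <- x[, grepl("_sd$", colnames(x)), drop = FALSE]
  vars <- x[, sub("_sd$", "_var", colnames(sds)), drop = FALSE]
  expect_equal(unname(vars), unname(sds^2), tolerance = 1e-10)
})

test_that("run-derived features are invariant to per-segment min-max rescaling", {
  ## mean +/- SD thresholds are affine-equivariant, so light-normalisation
  ## (a positive affine map) cannot change any run set
  set.seed(77)
  x <- rnorm(200, 5, 2)
  xr <- (x - min(x)) / (max(x) - min(x))
  expect_runs_equal(threshold_runs(x, "above"), threshold_runs(xr, "above"))
  expect_runs_equal(threshold_runs(x, "below"), threshold_runs(xr, "below"))

  nb <- 150L
  au <- 0.4 * sin(seq(0, 6 * pi, length.out = nb)) + rnorm(nb, 0, 0.05)
  au_r <- (au - min(au)) / (max(au) - min(au))
  f1 <- facial_features(make_segment(
    nb = nb, facial = as.data.frame(setNames(rep(list(au), 6), paste0("au", 1:6)))))
  f2 <- facial_features(make_segment(
    nb = nb, facial = as.data.frame(setNames(rep(list(au_r), 6), paste0("au", 1:6)))))
  dur <- grepl("_active_|_fast_|_slow_|_continuous_|_steady_", names(f1))
  expect_equal(f1[dur], f2[dur])
})
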