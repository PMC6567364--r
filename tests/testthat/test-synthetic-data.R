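test_that("identical config and seed give bitwise-identical cohorts", {
  cfg <- cohort_config(n_participants = 2, clips = tiny_clips(), seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_identical(generate_survey_table(cfg, n_respondents = 40),
                   generate_survey_table(cfg, n_respondents = 40))
  ## and a different seed changes the draws
  cfg2 <- cohort_config(n_participants = 2, clips = tiny_clips(), seed = 12)
  expect_false(identical(generate_cohort(cfg2)$segments[[1]]$autonomic,
                         a$segments[[1]]$autonomic))
})

test_that("stream lengths, ranges and rating scales respect the recording model", {
  cfg <- cohort_config(n_participants = 2, clips = tiny_clips(7), seed = 3,
                       drop_prob = 0)
  coh <- generate_cohort(cfg)
  for (s in coh$segments) {
    expect_equal(nrow(s$facial), round(7 * 30))
    expect_equal(nrow(s$eye), round(7 * 30))
    expect_equal(nrow(s$autonomic), round(7 * 32))
    expect_true(all(abs(as.matrix(s$facial)) <= 1))
    expect_type(s$eye$valid_l, "logical")
    ## pupil values during absence episodes are missing, never zero-filled
    expect_true(all(is.na(s$eye$pupil_l[!s$eye$valid_l])))
  }
  r <- coh$ratings
  vals <- unlist(r[emotion_levels()])
  expect_true(all(vals == round(vals) & vals >= 0 & vals <= 10))
})

test_that("segment means obey the configured channel baseline (law of large numbers)", {
  cfg <- cohort_config(n_participants = 1,
                       clips = list(clip_spec("c1", "amusement", "english", 60)),
                       effect_size = 0, subject_sd = 0, drop_prob = 0,
                       seed = 5)
  coh <- generate_cohort(cfg)
  scl <- coh$segments[[1]]$autonomic$scl
  se <- 0.5 / sqrt(length(scl))          # noise_sd 0.5 microsiemens
  expect_lt(abs(mean(scl) - 5), 3 * se)
})

test_that("a null effect leaves class-conditional stream distributions exchangeable", {
  cfg <- cohort_config(n_participants = 10, clips = tiny_clips(4),
                       effect_size = 0, subject_sd = 0, drop_prob = 0,
                       seed = 21)
  coh <- generate_cohort(cfg)
  seg_mean <- vapply(coh$segments, function(s) mean(s$autonomic$scl), 0)
  emo <- vapply(coh$segments, `[[`, "", "target_emotion")
  p <- oneway.test(seg_mean ~ emo, var.equal = TRUE)$p.value
  expect_gt(p, 0.001)                    # null accepted at nominal level
})

test_that("invalid configurations are rejected before any draw", {
  expect_error(cohort_config(n_participants = -1), "configuration error")
  expect_error(cohort_config(noise_sd = 0), "configuration error")
  expect_error(clip_spec("c", "sadness", "english", duration_s = 0),
               "configuration error")
  expect_error(cohort_config(felt_probability = 1.3), "configuration error")
  expect_error(cohort_config(effect_size = c(bogus = 1)), "unknown modality")
})

test_that("survey dropout shapes per-clip respondent counts monotonically", {
  cfg <- cohort_config(n_participants = 1, clips = tiny_clips(), seed = 9)
  ## no dropout: every respondent rates every clip
  sv <- generate_survey_table(cfg, dropout_per_clip = rep(0, 12),
                              n_respondents = 25)
  expect_equal(unname(table(sv$clip_id)[unique(sv$clip_id)]),
               rep(25L, 12), ignore_attr = TRUE)
  ## certain dropout after the first clip: clips 2..12 empty
  sv1 <- generate_survey_table(cfg, dropout_per_clip = c(1, rep(0, 11)),
                               n_respondents = 25)
  expect_equal(length(unique(sv1$clip_id)), 1L)
  ## default profile: counts non-increasing along the viewing order
  sv2 <- generate_survey_table(cfg, n_respondents = 200)
  counts <- vapply(unique(sv2$clip_id), function(cid) sum(sv2$clip_id == cid), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("survey acceptance matches its configured probability (binomial oracle)", {
  clips <- list(clip_spec("only", "fear", "english", 5, acceptance = 0.7))
  cfg <- cohort_config(n_participants = 1, clips = clips, seed = 13)
  sv <- generate_survey_table(cfg, dropout_per_clip = 0, n_respondents = 1000)
  phat <- mean(sv$accepted)
  ci <- qnorm(0.995) * sqrt(0.7 * 0.3 / 1000)
  expect_lt(abs(phat - 0.7), ci)
})
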