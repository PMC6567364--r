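test_that("autonomic alignment keeps samples inside the clip interval", {
  ts <- seq(0, 60000 - 1, by = 1000 / 32)
  stream <- data.frame(timestamp_ms = ts, scl = seq_along(ts))

  exact <- align_autonomic(stream, 0, 60000)
  expect_equal(nrow(exact$stream), length(ts))
  expect_true(exact$ok)

  ## stream starting 5 s late: first 5 s absent, remainder retained
  late <- align_autonomic(stream[stream$timestamp_ms >= 5000, ], 0, 60000)
  expect_equal(min(late$stream$timestamp_ms), 5000)
  expect_equal(nrow(late$stream), sum(ts >= 5000))
  expect_lt(late$coverage, 0.95)
  expect_true(late$ok)                       # 55/60 >= default 0.8
  expect_false(align_autonomic(stream[stream$timestamp_ms >= 20000, ],
                               0, 60000)$ok)  # 40/60 < 0.8

  disjoint <- align_autonomic(stream, 100000, 160000)
  expect_equal(nrow(disjoint$stream), 0)
  expect_false(disjoint$ok)
  expect_equal(disjoint$coverage, 0)
})

test_that("segments are kept only when the target emotion was felt", {
  cfg <- cohort_config(n_participants = 3, clips = tiny_clips(), seed = 31,
                       drop_prob = 0, seen_prob = 0)
  coh <- generate_cohort(cfg)
  recs <- select_segments(coh)

  expect_equal(nrow(recs), length(coh$segments))
  ## partition: excluded + included = total, exactly one reason each
  expect_equal(sum(recs$included) + sum(!recs$included), nrow(recs))
  expect_true(all(is.na(recs$exclusion_reason[recs$included])))
  expect_true(all(!is.na(recs$exclusion_reason[!recs$included])))

  ## included iff the target rating is at least 1
  key <- paste(coh$ratings$participant_id, coh$ratings$clip_id)
  for (i in seq_len(nrow(recs))) {
    j <- match(paste(recs$participant_id[i], recs$clip_id[i]), key)
    expect_equal(recs$included[i], coh$ratings[[recs$emotion[i]]][j] >= 1)
  }

  ## filtering is idempotent
  recs2 <- select_segments(attr(recs, "segments")[recs$included],
                           coh$ratings)
  expect_true(all(recs2$included))
})

test_that("seen-before and stream-less segments are excluded with the right reason", {
  seg_ok <- make_segment()
  seg_none <- make_segment(clip = "sadness_en", emotion = "sadness")
  seg_none$facial <- seg_none$head <- seg_none$eye <- seg_none$autonomic <- NULL
  seg_seen <- make_segment(clip = "anger_en", emotion = "anger")
  ratings <- data.frame(participant_id = "P01",
                        clip_id = c("amusement_en", "sadness_en", "anger_en"),
                        amusement = c(5L, 1L, 1L), sadness = c(0L, 5L, 0L),
                        anger = c(0L, 0L, 6L), fear = 0L, surprise = 0L,
                        disgust = 0L,
                        seen_before = c(FALSE, FALSE, TRUE))
  recs <- select_segments(list(seg_ok, seg_none, seg_seen), ratings)
  expect_equal(recs$included, c(TRUE, FALSE, FALSE))
  expect_equal(recs$exclusion_reason, c(NA, "missing_stream", "seen_before"))
  ## the maturation toggle restores seen-before segments
  recs2 <- select_segments(list(seg_seen), ratings,
                           exclude_seen_before = FALSE)
  expect_true(recs2$included)
  ## a rating of zero excludes with reason not_felt
  ratings0 <- ratings; ratings0$amusement[1] <- 0L
  expect_equal(select_segments(list(seg_ok), ratings0)$exclusion_reason,
               "not_felt")
  ## a missing rating row is an error naming the record
  expect_error(select_segments(list(make_segment(clip = "fear_en")), ratings),
               "fear_en")
})

test_that("kept-segment counts follow the felt probability (binomial oracle)", {
  cfg <- cohort_config(n_participants = 10, clips = tiny_clips(3),
                       felt_probability = 0.8, drop_prob = 0, seen_prob = 0,
                       seed = 37)
  coh <- generate_cohort(cfg)          # 120 segments
  recs <- select_segments(coh)
  n <- nrow(recs)
  ci <- qnorm(0.995) * sqrt(0.8 * 0.2 * n)
  expect_lt(abs(sum(recs$included) - 0.8 * n), ci)
})

test_that("the segment inventory counts per modality, emotion and language", {
  cfg <- cohort_config(n_participants = 4, clips = tiny_clips(), seed = 41)
  coh <- generate_cohort(cfg)
  recs <- select_segments(coh)
  inv <- segment_inventory(recs)
  expect_equal(nrow(inv), 8)           # 2 languages x 4 modalities
  kept <- recs[recs$included & recs$language == "english" & recs$eye, ]
  row <- inv[inv$language == "english" & inv$modality == "eye", ]
  expect_equal(unname(unlist(row[emotion_levels()])),
               unname(vapply(emotion_levels(),
                             function(e) sum(kept$emotion == e), 0L)))
  ## the classifier mask only admits included segments with the modality
  m <- modality_mask(recs, "autonomic")
  expect_true(all(recs$included[m] & recs$autonomic[m]))
})
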