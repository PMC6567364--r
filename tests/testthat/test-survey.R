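## minimal survey-table builder in the generate_survey_table dialect
survey_fixture <- function(ratings_by_emotion, clip_id = "fear_en",
                           emotion = "fear", language = "english",
                           accepted = NULL, gender = NULL) {
  n <- length(ratings_by_emotion[[1]])
  df <- data.frame(respondent_id = sprintf("R%04d", seq_len(n)),
                   gender = gender %||% rep("F", n),
                   clip_id = clip_id, emotion = emotion, language = language)
  for (e in emotion_levels())
    df[[e]] <- ratings_by_emotion[[e]] %||% rep(0L, n)
  df$accepted <- accepted %||% rep(TRUE, n)
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("clip summaries compute plain means, SEs and acceptance percentages", {
  sv <- survey_fixture(list(fear = c(2, 4, 6)))
  s <- summarize_clip(sv, "fear_en")
  expect_equal(s$mean[["fear"]], 4)
  expect_equal(s$se[["fear"]], sd(c(2, 4, 6)) / sqrt(3))

  all10 <- summarize_clip(survey_fixture(list(fear = rep(10, 12))), "fear_en")
  expect_equal(all10$mean[["fear"]], 10)
  expect_equal(all10$se[["fear"]], 0)

  acc <- summarize_clip(survey_fixture(list(fear = rep(5, 100)),
                                       accepted = rep(c(TRUE, FALSE),
                                                      c(70, 30))), "fear_en")
  expect_equal(acc$acceptance_pct, 70)

  empty <- summarize_clip(sv, "nonexistent")
  expect_equal(empty$n, 0)
  expect_true(all(is.na(empty$mean)))
})

test_that("Welch statistics match the closed-form oracle", {
  set.seed(81)
  a <- rnorm(25, 5, 2); b <- rnorm(40, 3, 1)
  ## direct check through the internal row builder used by all batteries
  r <- emofun:::welch_row(a, b)
  o <- welch_oracle(a, b)
  expect_equal(r$t, unname(o["t"]), tolerance = 1e-12)
  expect_equal(r$df, unname(o["df"]), tolerance = 1e-12)
  expect_equal(r$p, unname(o["p"]), tolerance = 1e-12)
})

test_that("target vs non-target tests detect strong elicitation and handle degeneracy", {
  set.seed(82)
  n <- 200
  sv <- survey_fixture(list(
    fear = pmin(pmax(round(rnorm(n, 7, 1)), 0), 10),
    amusement = pmin(pmax(round(rnorm(n, 2, 1)), 0), 10),
    sadness = pmin(pmax(round(rnorm(n, 2, 1)), 0), 10),
    anger = pmin(pmax(round(rnorm(n, 2, 1)), 0), 10),
    surprise = pmin(pmax(round(rnorm(n, 2, 1)), 0), 10),
    disgust = pmin(pmax(round(rnorm(n, 2, 1)), 0), 10)))
  tt <- target_vs_nontarget_tests(sv, "fear_en")
  expect_equal(nrow(tt), 5)                       # Bonferroni family of five
  expect_true(all(tt$significant))
  expect_true(all(tt$p_bonferroni >= tt$p))
  ## corrected significant set is a subset of the uncorrected one
  expect_true(all(tt$p[tt$significant] < 0.05))

  ## identical samples: t = 0, p = 1
  same <- survey_fixture(list(fear = rep(4, 10), sadness = rep(4, 10)))
  t0 <- target_vs_nontarget_tests(same, "fear_en")
  expect_equal(t0$p[t0$emotion == "sadness"], 1)
  expect_false(any(t0$significant[t0$emotion == "sadness"]))

  ## n = 1 is untestable, not an error
  one <- survey_fixture(list(fear = 5))
  expect_false(any(target_vs_nontarget_tests(one, "fear_en")$testable))
})

test_that("cross-language tests are calibrated under the null and powered under shift", {
  set.seed(83)
  pvals <- replicate(200, {
    sv <- rbind(
      survey_fixture(list(fear = round(runif(30, 2, 8))), clip_id = "fear_en",
                     language = "english"),
      survey_fixture(list(fear = round(runif(30, 2, 8))), clip_id = "fear_ar",
                     language = "arabic"))
    cross_language_test(sv, "fear")$p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))

  sv <- rbind(
    survey_fixture(list(fear = rnorm(200, 5, 1.5)), clip_id = "fear_en",
                   language = "english"),
    survey_fixture(list(fear = rnorm(200, 4, 1.5)), clip_id = "fear_ar",
                   language = "arabic"))
  res <- cross_language_test(sv, "fear")
  expect_true(res$significant)

  empty <- survey_fixture(list(fear = rnorm(10, 5)))
  expect_false(cross_language_test(empty, "fear")$testable)  # no arabic arm
})

test_that("gender comparisons reuse the Welch + Bonferroni machinery", {
  set.seed(84)
  n <- 120
  gender <- rep(c("F", "M"), each = n / 2)
  sad <- c(rnorm(n / 2, 6, 1), rnorm(n / 2, 3, 1))  # women rate sadness higher
  sv <- survey_fixture(list(sadness = round(pmin(pmax(sad, 0), 10)),
                            fear = round(runif(n, 0, 8))),
                       clip_id = "sadness_en", emotion = "sadness",
                       gender = gender)
  g <- gender_difference_tests(sv, "sadness_en")
  expect_equal(nrow(g), 6)
  expect_true(g$significant[g$emotion == "sadness"])
  expect_false(g$significant[g$emotion == "fear"])
})
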