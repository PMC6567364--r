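## Survey-side statistics: per-clip rating summaries with unequal respondent
## counts, acceptance percentages, and the Welch t-test batteries
## (target vs non-target with Bonferroni correction; English vs Arabic
## target; gender differences).

#' Summarise one clip's ratings and acceptance
#'
#' Means are taken over whoever responded to the clip ("weighted" only in
#' the sense that respondent counts differ between clips); SE = sd/sqrt(n).
#'
#' @param survey Survey table from [generate_survey_table()] (or the same
#'   dialect).
#' @param clip_id Clip to summarise.
#' @return List of class `emofun_clip_summary`: `clip_id`, `n`, per-emotion
#'   `mean` and `se` (0-10 scale), `acceptance_pct`. Zero responses give an
#'   explicit empty summary (`n = 0`, `NA` statistics).
#' @export
summarize_clip <- function(survey, clip_id) {
  sub <- survey[survey$clip_id == clip_id, , drop = FALSE]
  n <- nrow(sub)
  if (n == 0L)
    return(structure(list(clip_id = clip_id, n = 0L,
                          mean = stats::setNames(rep(NA_real_, 6), EMOTIONS),
                          se = stats::setNames(rep(NA_real_, 6), EMOTIONS),
                          acceptance_pct = NA_real_),
                     class = "emofun_clip_summary"))
  m <- vapply(EMOTIONS, function(e) mean(sub[[e]]), 0)
  se <- vapply(EMOTIONS, function(e)
    if (n > 1L) stats::sd(sub[[e]]) / sqrt(n) else 0, 0)
  acc <- if (!is.null(sub$accepted)) 100 * mean(sub$accepted) else NA_real_
  structure(list(clip_id = clip_id, n = n, mean = m, se = se,
                 acceptance_pct = acc),
            class = "emofun_clip_summary")
}

#' @export
print.emofun_clip_summary <- function(x, ...) {
  cat(sprintf("Clip %s: n = %d, acceptance %.1f%%\n", x$clip_id, x$n,
              x$acceptance_pct))
  print(round(rbind(mean = x$mean, se = x$se), 2))
  invisible(x)
}

#' Summarise every clip in a survey table
#'
#' @param survey Survey table.
#' @return Data frame, one row per clip: `clip_id`, `emotion`, `language`,
#'   `n`, `acceptance_pct`, and per-emotion mean columns `mean_<emotion>`.
#' @export
summarize_clips <- function(survey) {
  clips <- unique(survey$clip_id)
  rows <- lapply(clips, function(cid) {
    s <- summarize_clip(survey, cid)
    sub <- survey[survey$clip_id == cid, ][1, ]
    out <- data.frame(clip_id = cid, emotion = sub$emotion,
                      language = sub$language, n = s$n,
                      acceptance_pct = s$acceptance_pct)
    for (e in EMOTIONS) out[[paste0("mean_", e)]] <- s$mean[[e]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

welch_row <- function(a, b) {
  if (sum(!is.na(a)) < 2L || sum(!is.na(b)) < 2L)
    return(data.frame(t = NA_real_, df = NA_real_, p = NA_real_,
                      testable = FALSE))
  if (stats::sd(a, na.rm = TRUE) == 0 && stats::sd(b, na.rm = TRUE) == 0) {
    ## degenerate: identical constants are trivially non-significant,
    ## unequal constants trivially different; t.test would error
    eq <- isTRUE(all.equal(mean(a, na.rm = TRUE), mean(b, na.rm = TRUE)))
    return(data.frame(t = if (eq) 0 else Inf, df = NA_real_,
                      p = if (eq) 1 else 0, testable = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, testable = TRUE)
}

#' Target vs non-target emotion tests for one clip
#'
#' Two-sample two-tailed Welch (unequal-variance) t-tests of the target
#' emotion's ratings against each of the five non-target emotions, with
#' Bonferroni correction over the five comparisons (the per-clip family).
#'
#' @param survey Survey table.
#' @param clip_id Clip to test.
#' @param alpha Family significance level (default 0.05).
#' @return Data frame, one row per non-target emotion: `clip_id`, `target`,
#'   `emotion`, `t`, `df`, `p`, `p_bonferroni`, `significant`, `testable`.
#' @export
target_vs_nontarget_tests <- function(survey, clip_id, alpha = 0.05) {
  sub <- survey[survey$clip_id == clip_id, , drop = FALSE]
  if (nrow(sub) == 0L) stop(sprintf("no responses for clip %s", clip_id))
  target <- as.character(sub$emotion[1])
  nontargets <- setdiff(EMOTIONS, target)
  rows <- lapply(nontargets, function(e) {
    r <- welch_row(sub[[target]], sub[[e]])
    cbind(data.frame(clip_id = clip_id, target = target, emotion = e), r)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * length(nontargets), 1)
  out$significant <- out$testable & !is.na(out$p_bonferroni) &
    out$p_bonferroni < alpha
  rownames(out) <- NULL
  out
}

#' English vs Arabic target-emotion test per emotion
#'
#' Two-sample two-tailed Welch t-test of the target-emotion ratings of the
#' English clip against those of the Arabic clip eliciting the same
#' emotion; a single uncorrected comparison per emotion.
#'
#' @param survey Survey table containing both language sets.
#' @param emotion Target emotion to compare.
#' @param alpha Significance level.
#' @return One-row data frame: `emotion`, group means, `t`, `df`, `p`,
#'   `significant`, `testable`.
#' @export
cross_language_test <- function(survey, emotion, alpha = 0.05) {
  emotion <- match.arg(emotion, EMOTIONS)
  en <- survey[survey$emotion == emotion & survey$language == "english",
               emotion]
  ar <- survey[survey$emotion == emotion & survey$language == "arabic",
               emotion]
  r <- welch_row(en, ar)
  out <- cbind(data.frame(emotion = emotion,
                          mean_english = if (length(en)) mean(en) else NA_real_,
                          mean_arabic = if (length(ar)) mean(ar) else NA_real_),
               r)
  out$significant <- out$testable & !is.na(out$p) & out$p < alpha
  out
}

#' Gender differences in self-rated emotions for one clip
#'
#' Welch t-tests of each emotion's ratings between female and male
#' respondents, Bonferroni-corrected over the six emotions tested per clip.
#'
#' @param survey Survey table with a `gender` column (`"F"`/`"M"`).
#' @param clip_id Clip to test.
#' @param alpha Family significance level.
#' @return Data frame, one row per emotion, with Welch statistics and
#'   corrected significance.
#' @export
gender_difference_tests <- function(survey, clip_id, alpha = 0.05) {
  sub <- survey[survey$clip_id == clip_id, , drop = FALSE]
  if (nrow(sub) == 0L) stop(sprintf("no responses for clip %s", clip_id))
  rows <- lapply(EMOTIONS, function(e) {
    r <- welch_row(sub[[e]][sub$gender == "F"], sub[[e]][sub$gender == "M"])
    cbind(data.frame(clip_id = clip_id, emotion = e), r)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * length(EMOTIONS), 1)
  out$significant <- out$testable & !is.na(out$p_bonferroni) &
    out$p_bonferroni < alpha
  rownames(out) <- NULL
  out
}
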