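## One-way ANOVA feature selection and min-max normalisation. The F test is
## the classical equal-variance one-way ANOVA, vectorised over features so
## that per-fold selection over 727 features stays cheap inside
## cross-validation; it is cross-checked against stats::oneway.test in the
## test suite.

#' Vectorised one-way ANOVA F test over feature columns
#'
#' Classical (equal-variance) one-way F test of each feature against the
#' grouping factor, with missing values dropped per feature. Features whose
#' between- and within-group sums of squares are both (numerically) zero, or
#' with insufficient degrees of freedom, are degenerate: their F and p are
#' `NA`.
#'
#' @param x Numeric matrix or data frame, observations x features.
#' @param groups Grouping factor (one entry per row of `x`).
#' @return Data frame with one row per feature: `feature`, `F`, `p`, `df1`,
#'   `df2`, `degenerate`.
#' @export
anova_f <- function(x, groups) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  g <- factor(groups)
  if (nrow(x) != length(g)) stop("groups must have one entry per row of x")
  obs <- !is.na(x)
  xz <- ifelse(obs, x, 0)
  n_jc <- rowsum(obs + 0, g)          # groups x features counts
  s_jc <- rowsum(xz, g)               # group sums
  n <- colSums(n_jc)
  k <- colSums(n_jc > 0)
  grand <- colSums(s_jc) / n
  m_jc <- s_jc / ifelse(n_jc > 0, n_jc, NA)
  ssb <- colSums(n_jc * sweep(m_jc, 2, grand, "-")^2, na.rm = TRUE)
  sstot <- colSums(xz^2) - n * grand^2
  ssw <- pmax(sstot - ssb, 0)
  df1 <- k - 1
  df2 <- n - k
  ## scale-aware zero tolerance for constant features
  tiny <- (sstot <= 1e-12 * pmax(colSums(xz^2), 1))
  degen <- df1 < 1 | df2 < 1 | tiny | n < 2
  f <- ifelse(degen, NA_real_, (ssb / df1) / (ssw / df2))
  p <- ifelse(is.na(f), NA_real_, stats::pf(f, df1, df2, lower.tail = FALSE))
  feat <- colnames(x)
  if (is.null(feat)) feat <- paste0("V", seq_len(ncol(x)))
  data.frame(feature = feat, F = unname(f), p = unname(p),
             df1 = unname(df1), df2 = unname(df2),
             degenerate = unname(degen))
}

#' ANOVA feature selection at level alpha
#'
#' Runs the one-way F test per feature and selects features with p <= alpha.
#' With a `strata` factor (the two stimulus-language sets), the test is run
#' within each stratum and a feature is selected only if it is significant
#' in every stratum -- the common-feature intersection across stimulus sets.
#' Degenerate features (undefined F) are never selected.
#'
#' @param x Observations x features matrix or data frame.
#' @param groups Emotion labels, one per row.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param strata Optional stratification factor (e.g. language).
#' @return Object of class `emofun_selection`: data frame with per-stratum
#'   `F_*`/`p_*` columns, `degenerate` and `selected`; `alpha` and the
#'   strata names are attached as attributes.
#' @export
anova_select <- function(x, groups, alpha = 0.05, strata = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  g <- factor(groups)
  tab <- table(g)
  if (sum(tab >= 2) < 2)
    stop("need at least 2 groups with at least 2 observations each")
  x <- as.matrix(x)
  if (is.null(strata)) {
    res <- anova_f(x, g)
    out <- data.frame(feature = res$feature, F_all = res$F, p_all = res$p,
                      degenerate = res$degenerate,
                      selected = !res$degenerate & !is.na(res$p) & res$p <= alpha)
    strata_names <- "all"
  } else {
    st <- factor(strata)
    if (length(st) != nrow(x)) stop("strata must have one entry per row")
    strata_names <- levels(st)
    out <- NULL
    sel <- rep(TRUE, ncol(x))
    degen <- rep(FALSE, ncol(x))
    for (lv in strata_names) {
      res <- anova_f(x[st == lv, , drop = FALSE], g[st == lv])
      if (is.null(out)) out <- data.frame(feature = res$feature)
      out[[paste0("F_", lv)]] <- res$F
      out[[paste0("p_", lv)]] <- res$p
      sel <- sel & !res$degenerate & !is.na(res$p) & res$p <= alpha
      degen <- degen | res$degenerate
    }
    out$degenerate <- degen
    out$selected <- sel
  }
  structure(out, class = c("emofun_selection", "data.frame"),
            alpha = alpha, strata = strata_names)
}

#' @export
print.emofun_selection <- function(x, ...) {
  cat(sprintf("ANOVA feature selection (alpha = %g, strata: %s)\n",
              attr(x, "alpha"), paste(attr(x, "strata"), collapse = ", ")))
  cat(sprintf("  %d / %d features selected (%d degenerate)\n",
              sum(x$selected), nrow(x), sum(x$degenerate)))
  invisible(x)
}

#' Min-max normalisation fitted on training data
#'
#' Per-feature affine map taking the training minimum and maximum to
#' \[0, 1\]; the identical map is applied to the test matrix, whose values
#' may legitimately fall outside \[0, 1\]. Zero-range (constant) training
#' features map to 0 everywhere.
#'
#' @param train Numeric matrix or data frame, non-empty.
#' @param test Optional matrix with the same columns.
#' @return List with `train`, `test` (or NULL), and the fitted `min` and
#'   `range` vectors.
#' @export
minmax_fit_apply <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop("training matrix is empty")
  mins <- suppressWarnings(apply(train, 2, min, na.rm = TRUE))
  maxs <- suppressWarnings(apply(train, 2, max, na.rm = TRUE))
  rng <- maxs - mins
  ## all-missing training columns behave like zero-range columns
  mins[!is.finite(mins)] <- 0
  rng[!is.finite(rng)] <- 0
  scale1 <- function(m) {
    m <- as.matrix(m)
    out <- sweep(m, 2, mins, "-")
    out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
    out[, rng <= 0] <- 0
    out
  }
  list(train = scale1(train),
       test = if (!is.null(test)) scale1(test),
       min = mins, range = rng)
}
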