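## One-vs-one multiclass RBF SVM with leave-one-out cross-validation.
## The binary machines are libSVM C-classifiers (via e1071); the one-vs-one
## decoding, majority vote, tie-breaking and the cross-validation discipline
## (per-fold ANOVA selection and min-max scaling fitted on training folds
## only) are implemented here.

#' Default hyper-parameter grid for the RBF SVM
#'
#' Powers of two: cost 2^-5 .. 2^15, gamma 2^-15 .. 2^3.
#'
#' @param cost_exp,gamma_exp Exponent sequences.
#' @return Data frame with columns `cost` and `gamma`, ordered by ascending
#'   cost then gamma (the tie-break order of the grid search).
#' @export
svm_grid <- function(cost_exp = seq(-5, 15, by = 2),
                     gamma_exp = seq(-15, 3, by = 2)) {
  g <- expand.grid(gamma = 2^gamma_exp, cost = 2^cost_exp)[, c("cost", "gamma")]
  g[order(g$cost, g$gamma), , drop = FALSE]
}

#' Fit a one-vs-one multiclass RBF SVM
#'
#' Trains one binary libSVM C-classifier per unordered class pair (15 for
#' six classes). Inputs are assumed already normalised; no further scaling
#' is applied.
#'
#' @param x Numeric training matrix.
#' @param y Class labels (coerced to factor; level order fixes class
#'   indices for tie-breaking).
#' @param cost,gamma RBF SVM hyper-parameters.
#' @return Object of class `emofun_ovo`.
#' @export
ovo_fit <- function(x, y, cost = 1, gamma = 1 / ncol(x)) {
  y <- droplevels(factor(y))
  lv <- levels(y)
  if (length(lv) < 2L) stop("need at least 2 classes to fit a classifier")
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    e1071::svm(x = x[sel, , drop = FALSE],
               y = factor(y[sel], levels = pr),
               type = "C-classification", kernel = "radial",
               cost = cost, gamma = gamma, scale = FALSE)
  })
  structure(list(models = models, pairs = pairs, levels = lv,
                 cost = cost, gamma = gamma),
            class = "emofun_ovo")
}

#' Predict from a one-vs-one SVM by majority vote
#'
#' Each pairwise machine votes for one class; the final class is the
#' majority. Ties are broken by the summed signed pairwise decision values
#' in each class's favour, then by the lowest class index.
#'
#' @param object An `emofun_ovo` model.
#' @param newdata Numeric matrix of observations to classify.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.emofun_ovo <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  k <- length(object$levels)
  votes <- matrix(0L, n, k, dimnames = list(NULL, object$levels))
  score <- matrix(0, n, k, dimnames = list(NULL, object$levels))
  for (i in seq_along(object$models)) {
    pr <- object$pairs[[i]]
    p <- predict(object$models[[i]], newdata, decision.values = TRUE)
    dv <- attr(p, "decision.values")[, 1]
    ## decision value is oriented toward the first level of the pair
    first_is_a <- colnames(attr(p, "decision.values"))[1] ==
      paste(pr[1], pr[2], sep = "/")
    dva <- if (first_is_a) dv else -dv
    winner <- ifelse(dva > 0, pr[1], pr[2])
    for (cl in pr) {
      w <- winner == cl
      votes[w, cl] <- votes[w, cl] + 1L
    }
    score[, pr[1]] <- score[, pr[1]] + dva
    score[, pr[2]] <- score[, pr[2]] - dva
  }
  pred <- vapply(seq_len(n), function(i) {
    best <- which(votes[i, ] == max(votes[i, ]))
    if (length(best) > 1L) {
      s <- score[i, best]
      best <- best[s == max(s)]
    }
    object$levels[min(best)]
  }, "")
  factor(pred, levels = object$levels)
}

## deterministic stratified fold assignment: within each class, observations
## are dealt round-robin to folds in row order (no RNG)
inner_fold_ids <- function(y, k) {
  y <- factor(y)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
  }
  fold
}

## inner grid search: accuracy of each (cost, gamma) under a deterministic
## stratified k-fold CV on the training matrix; returns the best row
grid_search <- function(x, y, grid, inner_folds = 3L) {
  fold <- inner_fold_ids(y, inner_folds)
  acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    correct <- 0L; total <- 0L
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || !any(!tr)) next
      fit <- ovo_fit(x[tr, , drop = FALSE], y[tr],
                     cost = grid$cost[gi], gamma = grid$gamma[gi])
      pred <- predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
      total <- total + sum(!tr)
    }
    acc[gi] <- if (total > 0L) correct / total else 0
  }
  best <- which.max(acc)  # first maximum: lowest cost, then lowest gamma
  list(cost = grid$cost[best], gamma = grid$gamma[best], acc = acc[best])
}

#' Leave-one-out evaluation of the selection + SVM pipeline
#'
#' For each held-out unit (a participant by default, so all of a subject's
#' segments leave together), ANOVA feature selection and min-max scaling
#' are fitted on the training folds only and applied unchanged to the test
#' fold; the RBF one-vs-one SVM is tuned by an inner deterministic
#' stratified cross-validation over the hyper-parameter grid and refitted
#' on the full training fold. Folds whose training part loses a class
#' entirely are skipped with a warning and recorded.
#'
#' @param x Observations x features matrix (rows complete for the chosen
#'   modality).
#' @param labels Emotion labels, one per row.
#' @param subject_ids Participant identifier per row (the leave-one-out
#'   unit when `unit = "subject"`).
#' @param grid Hyper-parameter grid from [svm_grid()].
#' @param alpha ANOVA selection level.
#' @param strata Optional per-row stratum (language) for common-feature
#'   intersection inside each training fold; NULL (default) selects on the
#'   pooled training fold.
#' @param unit `"subject"` (default) or `"segment"`.
#' @param inner_folds Folds of the inner grid-search CV.
#' @param modality Optional label stored in the report.
#' @return Object of class `emofun_cv`: overall accuracy (%), 6x6
#'   confusion matrix (rows = true), per-fold log with chosen
#'   hyper-parameters and selected-feature counts, per-row predictions, and
#'   the selection mask of each fold.
#' @export
loo_evaluate <- function(x, labels, subject_ids, grid = svm_grid(),
                         alpha = 0.05, strata = NULL,
                         unit = c("subject", "segment"), inner_folds = 3L,
                         modality = NA_character_) {
  unit <- match.arg(unit)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(labels, levels = intersect(EMOTIONS, unique(as.character(labels))))
  if (nlevels(y) < 2L) stop("need at least 2 classes present")
  if (!nrow(grid)) stop("empty hyper-parameter grid")
  units <- if (unit == "subject") as.character(subject_ids)
           else as.character(seq_len(nrow(x)))
  fold_log <- list()
  pred <- rep(NA_character_, nrow(x))
  masks <- list()
  for (u in unique(units)) {
    test <- units == u
    tr_y <- droplevels(y[!test])
    if (nlevels(tr_y) < nlevels(droplevels(y))) {
      warning(sprintf("fold '%s' skipped: training fold lost a class", u))
      fold_log[[u]] <- data.frame(unit = u, n_test = sum(test),
                                  n_selected = NA, cost = NA, gamma = NA,
                                  skipped = TRUE)
      next
    }
    sel <- anova_select(x[!test, , drop = FALSE], y[!test], alpha = alpha,
                        strata = if (!is.null(strata)) strata[!test])
    mask <- sel$selected
    if (!any(mask)) mask <- !sel$degenerate  # fall back to all usable features
    masks[[u]] <- sel$selected
    sc <- minmax_fit_apply(x[!test, mask, drop = FALSE],
                           x[test, mask, drop = FALSE])
    gs <- grid_search(sc$train, y[!test], grid, inner_folds)
    fit <- ovo_fit(sc$train, y[!test], cost = gs$cost, gamma = gs$gamma)
    pred[test] <- as.character(predict(fit, sc$test))
    fold_log[[u]] <- data.frame(unit = u, n_test = sum(test),
                                n_selected = sum(sel$selected),
                                cost = gs$cost, gamma = gs$gamma,
                                skipped = FALSE)
  }
  evaluated <- !is.na(pred)
  lv <- levels(y)
  confusion <- table(true = factor(as.character(y[evaluated]), levels = lv),
                     predicted = factor(pred[evaluated], levels = lv))
  accuracy <- if (any(evaluated))
    100 * sum(diag(confusion)) / sum(confusion) else NA_real_
  structure(list(modality = modality, accuracy = accuracy,
                 confusion = confusion,
                 folds = do.call(rbind, c(fold_log, list(make.row.names = FALSE))),
                 predictions = data.frame(unit = units,
                                          true = as.character(y),
                                          predicted = pred),
                 selection_masks = masks,
                 alpha = alpha, unit = unit, n = nrow(x)),
            class = "emofun_cv")
}

#' @export
print.emofun_cv <- function(x, ...) {
  cat(sprintf("Leave-one-%s-out evaluation%s\n", x$unit,
              if (!is.na(x$modality)) paste0(" [", x$modality, "]") else ""))
  cat(sprintf("  %d segments, %d folds (%d skipped)\n", x$n,
              nrow(x$folds), sum(x$folds$skipped)))
  cat(sprintf("  accuracy: %.1f%%\n", x$accuracy))
  invisible(x)
}

#' @export
summary.emofun_cv <- function(object, ...) {
  print(object)
  cat("\nConfusion matrix (rows = true):\n")
  print(object$confusion)
  sel <- object$folds$n_selected[!object$folds$skipped]
  if (length(sel))
    cat(sprintf("\nSelected features per fold: median %g (range %g-%g)\n",
                stats::median(sel), min(sel), max(sel)))
  invisible(object)
}

#' Plot a cross-validation confusion matrix as a shaded grid
#'
#' @param x An `emofun_cv` object.
#' @param ... Passed to [graphics::image()].
#' @export
plot.emofun_cv <- function(x, ...) {
  cm <- as.matrix(x$confusion)
  prop <- cm / pmax(rowSums(cm), 1)
  k <- nrow(cm)
  graphics::image(seq_len(k), seq_len(k), t(prop[k:1, , drop = FALSE]),
                  col = grDevices::gray(seq(1, 0.2, length.out = 64)),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  main = sprintf("accuracy %.1f%%", x$accuracy), ...)
  graphics::axis(1, seq_len(k), colnames(cm), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(k), rev(rownames(cm)), las = 2, cex.axis = 0.8)
  for (i in seq_len(k)) for (j in seq_len(k))
    graphics::text(j, k - i + 1, cm[i, j],
                   col = if (prop[i, j] > 0.5) "white" else "black")
  invisible(x)
}
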