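#' Confusion-matrix metrics for one evaluation fold
#'
#' Sensitivity and specificity are percentages of true cases and true
#' controls recovered; the overall accuracy reported by this pipeline is
#' their mean, (SN + SP) / 2 (balanced accuracy) — the arithmetic the study
#' tables use (e.g. SN 72.5 and SP 78.5 print as accuracy 75.5). The raw
#' proportion correct is kept as a secondary field.
#'
#' @param y_true,y_pred Binary 0/1 vectors of equal length; both classes
#'   must be present in `y_true`.
#' @param fold Optional fold label (e.g. `"1a"`).
#' @return Object of class `fold_metrics`: one-row data frame with `fold`,
#'   `tp`, `fn`, `tn`, `fp`, `sn`, `sp`, `accuracy`, `raw_accuracy`.
#' @export
confusion_metrics <- function(y_true, y_pred, fold = NA_character_) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    stop("labels and predictions must be binary 0/1", call. = FALSE)
  }
  if (length(unique(y_true)) < 2L) {
    stop("undefined metric: both classes must be present in y_true",
         call. = FALSE)
  }
  tp <- sum(y_true == 1 & y_pred == 1); fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0); fp <- sum(y_true == 0 & y_pred == 1)
  sn <- 100 * tp / (tp + fn)
  sp <- 100 * tn / (tn + fp)
  out <- data.frame(fold = fold, tp = tp, fn = fn, tn = tn, fp = fp,
                    sn = sn, sp = sp, accuracy = (sn + sp) / 2,
                    raw_accuracy = 100 * (tp + tn) / length(y_true))
  class(out) <- c("fold_metrics", "data.frame")
  out
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Non-parametric ROC over all distinct score thresholds; the area is
#' computed by the trapezoid rule and equals the Mann-Whitney pair-count
#' probability that a random case outscores a random control, with ties
#' counting one half.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return Object of class `roc_curve`: list with `points` (data frame
#'   `threshold`, `fpr`, `tpr` from (0,0) to (1,1)), `auc`, `n_cases`,
#'   `n_controls`, and the input `scores`/`labels` (needed for paired AUC
#'   comparison).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels) || !all(labels %in% c(0L, 1L))) {
    stop("scores and 0/1 labels of equal length required", call. = FALSE)
  }
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  if (length(unique(scores)) == 1L) {
    warning("constant scores: ROC is the diagonal, AUC = 0.5")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # collapse tied scores into single thresholds
  last <- rev(!duplicated(rev(s)))
  tpr <- cumsum(l == 1L)[last] / n1
  fpr <- cumsum(l == 0L)[last] / n0
  points <- data.frame(threshold = c(Inf, s[last]),
                       fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                 utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc, n_cases = n1, n_controls = n0,
                 scores = scores, labels = labels),
            class = "roc_curve")
}

# Hanley-McNeil standard error of an empirical AUC.
auc_se_hanley <- function(auc, n_cases, n_controls) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_cases - 1) * (q1 - auc^2) +
        (n_controls - 1) * (q2 - auc^2)) / (n_cases * n_controls))
}

#' Compare two ROC areas (Hanley-McNeil)
#'
#' Standard errors follow Hanley-McNeil (Q1 = A/(2-A), Q2 = 2A^2/(1+A)). In
#' paired mode (both classifiers scored the same sample) the correlation
#' between the two areas is estimated as the mean of the Pearson
#' correlations of the two score vectors within cases and within controls;
#' z = (A1 - A2) / sqrt(SE1^2 + SE2^2 - 2 r SE1 SE2), two-sided p. With
#' r = 0 this reduces to the unpaired two-AUC z-test.
#'
#' @param roc1,roc2 `roc_curve` objects from [roc_auc()].
#' @param paired Were both score vectors obtained on the identical sample?
#' @return List with `auc1`, `auc2`, `se1`, `se2`, `r`, `z`, `p`.
#' @export
compare_auc <- function(roc1, roc2, paired = TRUE) {
  stopifnot(inherits(roc1, "roc_curve"), inherits(roc2, "roc_curve"))
  se1 <- auc_se_hanley(roc1$auc, roc1$n_cases, roc1$n_controls)
  se2 <- auc_se_hanley(roc2$auc, roc2$n_cases, roc2$n_controls)
  if (paired) {
    if (length(roc1$labels) != length(roc2$labels) ||
        !all(roc1$labels == roc2$labels)) {
      stop("paired comparison requires the two ROC curves to be built on ",
           "the identical sample (same labels, same order)", call. = FALSE)
    }
    r_cases <- suppressWarnings(
      stats::cor(roc1$scores[roc1$labels == 1], roc2$scores[roc2$labels == 1]))
    r_controls <- suppressWarnings(
      stats::cor(roc1$scores[roc1$labels == 0], roc2$scores[roc2$labels == 0]))
    r <- mean(c(r_cases, r_controls), na.rm = TRUE)
    if (!is.finite(r)) r <- 0
  } else {
    r <- 0
  }
  denom <- sqrt(max(se1^2 + se2^2 - 2 * r * se1 * se2, 0))
  diff <- roc1$auc - roc2$auc
  z <- if (denom < .Machine$double.eps) {
    if (abs(diff) < .Machine$double.eps) 0 else sign(diff) * Inf
  } else diff / denom
  list(auc1 = roc1$auc, auc2 = roc2$auc, se1 = se1, se2 = se2,
       r = r, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Stratified random halvings for the 5x2 protocol
#'
#' Five seeded random splits of the sample into halves `a` and `b`,
#' stratified by class so each half holds (as near as possible) half the
#' cases and half the controls.
#'
#' @param labels Binary 0/1 labels.
#' @param seed Integer seed.
#' @param repeats Number of halvings (default 5).
#' @return List of `repeats` logical vectors (`TRUE` = half `a`), with the
#'   seed attached as attribute `"seed"`.
#' @export
make_partitions <- function(labels, seed, repeats = 5L) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  n <- length(labels)
  parts <- with_seed(substream_seed(seed, "partitions"), {
    lapply(seq_len(repeats), function(r) {
      in_a <- logical(n)
      for (cl in c(0L, 1L)) {
        idx <- which(labels == cl)
        k <- length(idx)
        size <- floor(k / 2) + stats::rbinom(1, 1, (k %% 2) / 2)
        in_a[idx[sample.int(k, size)]] <- TRUE
      }
      in_a
    })
  })
  attr(parts, "seed") <- as.integer(seed)
  parts
}

#' 5x2 cross-validation of an arbitrary fit/predict pair
#'
#' The validation protocol: the sample is randomly halved five times
#' (stratified by class); for each halving a fresh model is trained on half
#' `a`, its weights frozen, and scored on half `b`, then the roles are
#' reversed — ten independent evaluation experiments. Fold metrics use the
#' frozen models' test predictions only; the report's averages row is the
#' arithmetic mean of the ten folds, and a pooled empirical ROC is built
#' from all out-of-sample scores.
#'
#' @param X Numeric matrix of model inputs.
#' @param labels Binary 0/1 labels (n >= 20).
#' @param trainer List with `fit = function(X, y, seed)` returning a model
#'   and `predict = function(model, X)` returning scores in \[0, 1\].
#' @param seed Integer seed (drives the halvings and per-fold fit seeds).
#' @param partitions Optional precomputed [make_partitions()] result so two
#'   arms can share identical splits.
#' @param threshold Classification threshold passed to [mlp_classify()].
#' @return Object of class `crossval_report`: `folds` (10-row data frame),
#'   `averages`, `roc` (pooled out-of-sample ROC), `pooled` (scores/labels/
#'   fold of every test prediction), `partitions`, `seed`.
#' @export
five_by_two_cv <- function(X, labels, trainer, seed = 1L, partitions = NULL,
                           threshold = 0.5) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  if (length(labels) < 20L) stop("need n >= 20 for the 5x2 protocol", call. = FALSE)
  if (is.null(partitions)) partitions <- make_partitions(labels, seed)
  folds <- list(); pooled_scores <- numeric(0); pooled_labels <- integer(0)
  pooled_fold <- character(0); pooled_index <- integer(0)
  for (r in seq_along(partitions)) {
    in_a <- partitions[[r]]
    for (half in c("a", "b")) {
      train_idx <- if (half == "a") in_a else !in_a
      test_idx <- !train_idx
      fold_id <- paste0(r, half)
      model <- trainer$fit(X[train_idx, , drop = FALSE], labels[train_idx],
                           substream_seed(seed, paste0("fit", fold_id)))
      sc <- trainer$predict(model, X[test_idx, , drop = FALSE])
      fm <- confusion_metrics(labels[test_idx], mlp_classify(sc, threshold),
                              fold = fold_id)
      folds[[fold_id]] <- fm
      pooled_scores <- c(pooled_scores, sc)
      pooled_labels <- c(pooled_labels, labels[test_idx])
      pooled_fold <- c(pooled_fold, rep(fold_id, sum(test_idx)))
      pooled_index <- c(pooled_index, which(test_idx))
    }
  }
  folds <- do.call(rbind, folds)
  averages <- data.frame(sn = mean(folds$sn), sp = mean(folds$sp),
                         accuracy = mean(folds$accuracy),
                         raw_accuracy = mean(folds$raw_accuracy))
  roc <- roc_auc(pooled_scores, pooled_labels)
  structure(list(folds = folds, averages = averages, roc = roc,
                 pooled = data.frame(index = pooled_index,
                                     fold = pooled_fold,
                                     score = pooled_scores,
                                     label = pooled_labels),
                 partitions = partitions, seed = as.integer(seed)),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat("5x2 cross-validation report\n")
  print(data.frame(fold = x$folds$fold,
                   sn = round_half_up(x$folds$sn, 1),
                   sp = round_half_up(x$folds$sp, 1),
                   accuracy = round_half_up(x$folds$accuracy, 1)),
        row.names = FALSE)
  cat(sprintf("Average  SN %.1f  SP %.1f  accuracy %.1f  AUC %.3f\n",
              round_half_up(x$averages$sn, 1), round_half_up(x$averages$sp, 1),
              round_half_up(x$averages$accuracy, 1), x$roc$auc))
  invisible(x)
}

#' Chi-square homogeneity of fold error rates
#'
#' Goodness-of-fit chi-square of the per-fold correct/incorrect counts
#' against the pooled correct rate (df = folds - 1): a small statistic says
#' the ten evaluation experiments behave like draws from one underlying
#' accuracy.
#'
#' @param folds A `fold_metrics`-style data frame with columns `tp`, `fn`,
#'   `tn`, `fp` (e.g. `report$folds`).
#' @param alpha Significance level for the `ns` flag.
#' @return List with `chi2`, `df`, `p`, `ns` (not significant at `alpha`).
#' @export
fold_homogeneity_chi2 <- function(folds, alpha = 0.05) {
  stopifnot(is.data.frame(folds), all(c("tp", "fn", "tn", "fp") %in% names(folds)))
  if (nrow(folds) < 2L) stop("need at least two folds", call. = FALSE)
  correct <- folds$tp + folds$tn
  total <- folds$tp + folds$fn + folds$tn + folds$fp
  rate <- sum(correct) / sum(total)
  e_c <- total * rate; e_i <- total * (1 - rate)
  if (any(e_c < 1e-12) || any(e_i < 1e-12)) {
    stop("zero expected count; pool folds before testing", call. = FALSE)
  }
  chi2 <- sum((correct - e_c)^2 / e_c + ((total - correct) - e_i)^2 / e_i)
  df <- nrow(folds) - 1L
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p, ns = p > alpha)
}

# Kolmogorov-Smirnov normality gate (parameters estimated from the sample),
# as the study's software applied it.
ks_normal <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 4L || stats::sd(x) == 0) return(FALSE)
  p <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  p >= alpha
}

# Bivariate two-group p-value used by the screen and the Table 2 analogue.
bivariate_p <- function(x, group, kind, correct = TRUE) {
  g0 <- x[group == 0]; g1 <- x[group == 1]
  if (kind == "binary") {
    tab <- rbind(c(sum(g0 == 1), sum(g0 == 0)), c(sum(g1 == 1), sum(g1 == 0)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
    suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
  } else {
    if (stats::sd(x) == 0) return(NA_real_)
    if (ks_normal(g0) && ks_normal(g1)) {
      stats::t.test(g0, g1)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(g0, g1)$p.value)
    }
  }
}

#' Two-group clinical characteristics comparison
#'
#' The cohort-description analysis: per continuous variable a
#' Kolmogorov-Smirnov normality gate (at `alpha_normal`, each group) chooses
#' Student's t-test (both normal, summarised mean +/- SD) or Mann-Whitney
#' (otherwise, summarised median (range)); binary variables are compared by
#' chi-square, Yates-corrected by default.
#'
#' @param data Data frame of variables to compare.
#' @param group Binary 0/1 group membership, one per row of `data`.
#' @param kinds Optional named `"binary"`/`"continuous"` per column
#'   (guessed from the values otherwise).
#' @param correct Apply the continuity correction to 2x2 chi-squares.
#' @param alpha_normal Normality-gate level.
#' @return Data frame: `variable`, `kind`, `test`, `summary_g0`,
#'   `summary_g1`, `p`.
#' @export
group_compare <- function(data, group, kinds = NULL, correct = TRUE,
                          alpha_normal = 0.05) {
  stopifnot(is.data.frame(data), nrow(data) == length(group))
  group <- as.integer(group)
  if (length(unique(group)) != 2L) stop("need two non-empty groups", call. = FALSE)
  rows <- lapply(colnames(data), function(v) {
    x <- data[[v]]
    kind <- if (!is.null(kinds)) kinds[[v]] else {
      if (all(x %in% c(0, 1))) "binary" else "continuous"
    }
    g0 <- x[group == 0]; g1 <- x[group == 1]
    if (kind == "binary") {
      test <- "chi-square"
      s0 <- sprintf("%d (%.1f)", sum(g0 == 1), 100 * mean(g0 == 1))
      s1 <- sprintf("%d (%.1f)", sum(g1 == 1), 100 * mean(g1 == 1))
    } else if (stats::sd(x) == 0) {
      test <- "skipped (zero variance)"
      s0 <- s1 <- sprintf("%.1f (constant)", x[1])
    } else if (ks_normal(g0, alpha_normal) && ks_normal(g1, alpha_normal)) {
      test <- "t-test"
      s0 <- sprintf("%.1f±%.1f", mean(g0), stats::sd(g0))
      s1 <- sprintf("%.1f±%.1f", mean(g1), stats::sd(g1))
    } else {
      test <- "Mann-Whitney"
      s0 <- sprintf("%.1f (%.0f-%.0f)", stats::median(g0), min(g0), max(g0))
      s1 <- sprintf("%.1f (%.0f-%.0f)", stats::median(g1), min(g1), max(g1))
    }
    p <- if (startsWith(test, "skipped")) NA_real_ else {
      bivariate_p(x, group, if (kind == "binary") "binary" else "continuous",
                  correct = correct)
    }
    data.frame(variable = v, kind = kind, test = test,
               summary_g0 = s0, summary_g1 = s1, p = p)
  })
  do.call(rbind, rows)
}

#' Normality-gated correlation
#'
#' Pearson product-moment correlation when both vectors pass the
#' Kolmogorov-Smirnov normality gate, Spearman rank correlation otherwise;
#' two-sided p-value.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"auto"` (the gate), `"pearson"`, or `"spearman"`.
#' @return List with `r`, `p`, `method`.
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  if (method == "auto") {
    method <- if (ks_normal(x) && ks_normal(y)) "pearson" else "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, method = method)
}
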