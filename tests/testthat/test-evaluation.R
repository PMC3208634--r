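test_that("confusion metrics use (SN+SP)/2 as overall accuracy", {
  perfect <- confusion_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(perfect$sn, perfect$sp, perfect$accuracy), c(100, 100, 100))

  # 1000 cases at SN 72.5%, 1000 controls at SP 78.5% -> accuracy 75.5%
  y <- rep(c(1, 0), each = 1000)
  pred <- c(rep(1, 725), rep(0, 275), rep(0, 785), rep(1, 215))
  m <- confusion_metrics(y, pred)
  expect_equal(c(m$sn, m$sp, m$accuracy), c(72.5, 78.5, 75.5))
  expect_equal(m$raw_accuracy, 75.5)  # equal group sizes: raw == balanced

  allpos <- confusion_metrics(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(c(allpos$sn, allpos$sp, allpos$accuracy), c(100, 0, 50))

  expect_error(confusion_metrics(c(1, 1), c(1, 0)), "both classes")
})

test_that("stored confusion counts reproduce the stored percentages", {
  set.seed(3)
  for (i in 1:20) {
    y <- rbinom(50, 1, 0.5); p <- rbinom(50, 1, 0.5)
    if (length(unique(y)) < 2) next
    m <- confusion_metrics(y, p)
    expect_equal(100 * m$tp / (m$tp + m$fn), m$sn, tolerance = 0.1)
    expect_equal(100 * m$tn / (m$tn + m$fp), m$sp, tolerance = 0.1)
  }
})

test_that("trapezoidal AUC equals exhaustive pair counting on random instances", {
  set.seed(2024)
  for (i in 1:500) {
    n1 <- sample(2:8, 1); n0 <- sample(2:8, 1)
    scores <- sample(seq(0, 1, by = 0.1), n1 + n0, replace = TRUE)  # many ties
    labels <- c(rep(1, n1), rep(0, n0))
    expect_equal(roc_auc(scores, labels)$auc, pair_count_auc(scores, labels))
  }
})

test_that("ROC endpoints, perfect separation, and the null behave as required", {
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))

  set.seed(5)
  null <- roc_auc(runif(4000), rbinom(4000, 1, 0.5))
  expect_lt(abs(null$auc - 0.5), 0.03)

  expect_warning(flat <- roc_auc(rep(0.3, 10), rep(c(0, 1), 5)), "constant")
  expect_equal(flat$auc, 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("empirical AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  scores <- runif(200)
  labels <- rbinom(200, 1, plogis(3 * (scores - 0.5)))
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs)
})

test_that("correlated AUC comparison has the documented limits", {
  set.seed(8)
  scores <- runif(120)
  labels <- rbinom(120, 1, plogis(2 * (scores - 0.5)))
  r1 <- roc_auc(scores, labels)
  same <- compare_auc(r1, r1, paired = TRUE)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  scores2 <- runif(120)
  r2 <- roc_auc(scores2, labels)
  unpaired <- compare_auc(r1, r2, paired = FALSE)
  manual_z <- (r1$auc - r2$auc) / sqrt(unpaired$se1^2 + unpaired$se2^2)
  expect_equal(unpaired$z, manual_z)  # r = 0 reduces to the unpaired test
  expect_equal(unpaired$r, 0)

  r3 <- roc_auc(scores2, rbinom(120, 1, 0.5))
  expect_error(compare_auc(r1, r3, paired = TRUE), "identical sample")
})

test_that("the paired AUC test rejects a real difference at reasonable power", {
  set.seed(9)
  reject <- 0L
  for (i in 1:200) {
    n <- 400
    truth <- rbinom(n, 1, 0.5)
    good <- truth + rnorm(n, sd = 1.15)   # AUC ~ 0.73
    weak <- truth + rnorm(n, sd = 2.6)    # AUC ~ 0.61
    cmp <- compare_auc(roc_auc(good, truth), roc_auc(weak, truth))
    reject <- reject + (cmp$p < 0.05)
  }
  expect_gt(reject / 200, 0.5)
})

test_that("5x2 partitions are disjoint, covering, stratified and reproducible", {
  set.seed(10)
  labels <- rbinom(120, 1, 0.4)
  parts <- make_partitions(labels, seed = 99)
  expect_length(parts, 5L)
  for (p in parts) {
    expect_true(any(p) && any(!p))                  # both halves non-empty
    expect_lte(abs(sum(p) - 60), 2)                 # near-half
    expect_lte(abs(sum(labels[p]) - sum(labels) / 2), 1)  # stratified
  }
  expect_identical(parts, make_partitions(labels, seed = 99))
  expect_false(identical(parts, make_partitions(labels, seed = 100)))
})

test_that("the 5x2 protocol reports ten folds whose mean is the averages row", {
  d <- separable_clouds(n = 80, margin = 3, seed = 11)
  rep1 <- five_by_two_cv(d$X, d$y, mlp_trainer(mlp_config(max_epochs = 60)),
                         seed = 4)
  expect_identical(nrow(rep1$folds), 10L)
  expect_identical(rep1$folds$fold,
                   paste0(rep(1:5, each = 2), rep(c("a", "b"), 5)))
  expect_equal(rep1$averages$sn, mean(rep1$folds$sn))
  expect_equal(rep1$averages$accuracy, mean(rep1$folds$accuracy))
  # every record is tested exactly once per repeat
  per_repeat <- table(sub("[ab]$", "", rep1$pooled$fold), rep1$pooled$index)
  expect_true(all(per_repeat == 1L))

  rep2 <- five_by_two_cv(d$X, d$y, mlp_trainer(mlp_config(max_epochs = 60)),
                         seed = 4)
  expect_identical(rep1$folds, rep2$folds)
})

test_that("fold homogeneity chi-square matches hand arithmetic", {
  same <- data.frame(tp = rep(40, 4), fn = rep(10, 4),
                     tn = rep(35, 4), fp = rep(15, 4))
  h <- fold_homogeneity_chi2(same)
  expect_equal(h$chi2, 0)
  expect_equal(h$p, 1)
  expect_true(h$ns)

  # three folds of 100 with 80/70/75 correct, checked against direct
  # evaluation of sum (O-E)^2/E
  toy <- data.frame(tp = c(40, 35, 40), fn = c(10, 15, 10),
                    tn = c(40, 35, 35), fp = c(10, 15, 15))
  correct <- toy$tp + toy$tn; total <- rowSums(toy)
  rate <- sum(correct) / sum(total)
  hand <- sum((correct - total * rate)^2 / (total * rate) +
              (total - correct - total * (1 - rate))^2 / (total * (1 - rate)))
  h2 <- fold_homogeneity_chi2(toy)
  expect_equal(h2$chi2, hand)
  expect_identical(h2$df, 2L)

  deviant <- data.frame(tp = c(45, 45, 45, 10), fn = c(5, 5, 5, 40),
                        tn = c(45, 45, 45, 10), fp = c(5, 5, 5, 40))
  expect_lt(fold_homogeneity_chi2(deviant)$p, 0.05)
  expect_error(fold_homogeneity_chi2(same[1, ]), "two folds")
})

test_that("continuity-corrected chi-square equals the closed form on a grid of tables", {
  for (a in c(1, 3, 6)) for (b in c(2, 5, 8)) for (cc in c(1, 4, 7)) for (d in c(2, 6, 9)) {
    ours <- suppressWarnings(
      stats::chisq.test(matrix(c(a, b, cc, d), 2, 2), correct = TRUE))
    expect_equal(unname(ours$statistic), yates_closed_form(a, cc, b, d),
                 tolerance = 1e-10)
  }
})

test_that("group comparison picks tests by normality and matches printed contingency p", {
  # hypertension 47/196 vs 63/176 with continuity correction -> p 0.017
  grp <- rep(c(0, 1), c(196, 176))
  hyp <- c(rep(1, 47), rep(0, 149), rep(1, 63), rep(0, 113))
  tab <- group_compare(data.frame(hypertension = hyp), grp)
  expect_equal(round(tab$p, 3), 0.017)
  expect_identical(tab$test, "chi-square")

  set.seed(12)
  d <- data.frame(shifted = c(rnorm(200, 0), rnorm(200, 1)))
  g <- rep(c(0, 1), each = 200)
  row <- group_compare(d, g)
  expect_identical(row$test, "t-test")
  expect_lt(row$p, 0.001)

  skewed <- data.frame(x = exp(c(rnorm(150), rnorm(150))))
  row2 <- group_compare(skewed, rep(c(0, 1), each = 150))
  expect_identical(row2$test, "Mann-Whitney")

  const <- group_compare(data.frame(x = rep(3.2, 40)), rep(c(0, 1), 20))
  expect_true(startsWith(const$test, "skipped"))
  expect_true(is.na(const$p))
})

test_that("correlation picks Pearson/Spearman by the normality gate", {
  set.seed(13)
  x <- rnorm(300)
  expect_equal(correlate(x, x)$r, 1)

  y <- rnorm(10000); z <- rnorm(10000)
  expect_lt(abs(correlate(y, z)$r), 0.05)

  toy <- correlate(1:5, c(2, 1, 4, 3, 5), method = "spearman")
  expect_equal(toy$r, 0.8)  # 1 - 6*4/(5*24)

  skew <- exp(rnorm(300))
  expect_identical(correlate(skew, x)$method, "spearman")
  expect_error(correlate(rep(1, 10), rnorm(10)), "constant")
})
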