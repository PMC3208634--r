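test_that("distribution penalty is zero on mirrored halves and order-invariant", {
  set.seed(1)
  half <- data.frame(x = rnorm(30), b = rbinom(30, 1, 0.4))
  doubled <- rbind(half, half)
  split <- rep(c(TRUE, FALSE), each = 30)
  expect_equal(distribution_similarity(doubled, split), 0)

  # brute-force KS on a label-sorted toy split of a single variable
  x <- c(1, 2, 3, 4, 5, 6)
  split2 <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  grid <- sort(unique(x))
  f_a <- sapply(grid, function(g) mean(x[split2] <= g))
  f_b <- sapply(grid, function(g) mean(x[!split2] <= g))
  expect_equal(distribution_similarity(data.frame(x = x), split2),
               max(abs(f_a - f_b)))

  perm <- sample(nrow(doubled))
  expect_equal(distribution_similarity(doubled[perm, ], split[perm]),
               distribution_similarity(doubled, split))
  expect_error(distribution_similarity(half, rep(TRUE, 30)), "non-empty")
})

test_that("fitness is mean crossover accuracy minus the weighted penalty", {
  d <- separable_clouds(n = 60, margin = 5, seed = 2)
  X <- cbind(d$X, noise = runif(60))
  chrom <- list(split = rep(c(TRUE, FALSE), 30), mask = c(TRUE, TRUE, FALSE))
  cfg0 <- twist_config(lambda = 0, mlp = mlp_config(max_epochs = 150), seed = 3)
  f0 <- chromosome_fitness(chrom, X, d$y, cfg0, mlp_seed = 5)
  # on a widely separable set the twin accuracies are essentially perfect
  expect_gt(f0, 0.95)

  cfg1 <- twist_config(lambda = 0.7, mlp = mlp_config(max_epochs = 150), seed = 3)
  f1 <- chromosome_fitness(chrom, X, d$y, cfg1, mlp_seed = 5)
  pen <- distribution_similarity(X, chrom$split)
  expect_equal(f1, f0 - 0.7 * pen)

  none <- list(split = chrom$split, mask = c(FALSE, FALSE, FALSE))
  expect_identical(chromosome_fitness(none, X, d$y, cfg0), -Inf)
})

test_that("the genetic search is elitist, seeded and constraint-respecting", {
  d <- planted_signal_data(n = 120, p = 6, k = 1, logodds = 2, seed = 4)
  cfg <- twist_config(population_size = 10, generations = 6, patience = 6,
                      lambda = 0.1, mlp = mlp_config(max_epochs = 40), seed = 9)
  res <- run_twist(d$X, d$y, cfg)
  expect_true(all(diff(res$trajectory$best) >= 0))
  expect_gte(length(res$selected), 1L)
  # split respects the stratified near-half constraint
  for (cl in c(0, 1)) {
    k <- sum(d$y == cl)
    na <- sum(res$split[d$y == cl])
    expect_gte(na, floor(k / 2 * 0.9) - 1)
    expect_lte(na, ceiling(k / 2 * 1.1) + 1)
  }
  res2 <- run_twist(d$X, d$y, cfg)
  expect_identical(res, res2)

  seq_cfg <- twist_config(population_size = 8, generations = 4, patience = 4,
                          lambda = 0.1, mlp = mlp_config(max_epochs = 30),
                          mode = "sequential", seed = 9)
  seq_res <- run_twist(d$X, d$y, seq_cfg)
  expect_s3_class(seq_res, "twist_result")
  expect_true(all(c("split", "mask") %in% names(seq_res$chromosome)))
})

test_that("informative variables are recovered from a small planted design", {
  hits <- 0L
  for (s in 1:3) {
    d <- planted_signal_data(n = 400, p = 10, k = 2, logodds = 1.8, seed = s)
    res <- run_twist(d$X, d$y, twist_config(
      population_size = 14, generations = 12, patience = 6, lambda = 0.1,
      mlp = mlp_config(max_epochs = 60), seed = s))
    hits <- hits + all(d$informative %in% res$selected)
  }
  expect_gte(hits, 2L)
})

test_that("degenerate inputs are refused", {
  d <- planted_signal_data(n = 30, p = 3, seed = 5)
  expect_error(run_twist(d$X, rep(1L, 30), twist_config()), "both classes")
  Xna <- d$X; Xna[1, 1] <- NA
  expect_error(run_twist(Xna, d$y, twist_config()), "complete-case")
  expect_error(twist_config(population_size = 1), "population_size")
  expect_error(twist_config(crossover_rate = 1.2), "rates")
})
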