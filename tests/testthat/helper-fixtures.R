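# Fixtures are built in code; no stored data.

# Rectangle landmark set: anterior/middle/posterior pairs of a given height,
# spaced 10 mm apart horizontally.
rect_landmarks <- function(h_a = 30, h_m = 30, h_p = 30) {
  matrix(c(0, h_a,   # anterior-superior
           0, 0,     # anterior-inferior
           10, h_m,  # middle-superior
           10, 0,    # middle-inferior
           20, h_p,  # posterior-superior
           20, 0),   # posterior-inferior
         ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
}

# Two labelled Gaussian clouds separated by `margin` standard deviations.
separable_clouds <- function(n = 60, margin = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n, 0.25, 0.25 / margin), n / 2, 2),
             matrix(rnorm(n, 0.75, 0.25 / margin), n / 2, 2))
  X <- pmin(pmax(X, 0), 1)
  list(X = X, y = rep(c(0, 1), each = n / 2))
}

# Tabular set with an XOR interaction of two binaries that no main-effects
# logistic model can see, plus pure-noise columns.
xor_interaction_data <- function(n = 1000, n_noise = 3, seed = 1) {
  set.seed(seed)
  b1 <- rbinom(n, 1, 0.5)
  b2 <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, ifelse(xor(b1, b2), 0.85, 0.15))
  X <- cbind(b1 = b1, b2 = b2,
             matrix(runif(n * n_noise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(n_noise)))))
  list(X = X, y = y)
}

# Planted-signal design: p variables, the first `k` informative with the
# given per-SD log-odds.
planted_signal_data <- function(n = 600, p = 20, k = 3, logodds = 1.5,
                                seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("v", seq_len(p))))
  eta <- rowSums(scale(X[, seq_len(k), drop = FALSE])) * logodds
  y <- rbinom(n, 1, plogis(eta))
  list(X = X, y = y, informative = paste0("v", seq_len(k)))
}

# Brute-force AUC by case/control pair counting (ties count one half).
pair_count_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Closed-form continuity-corrected chi-square for a 2x2 table.
yates_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- n * max(0, abs(a * d - b * c) - n / 2)^2
  num / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Small TWIST configuration used by recovery-style tests.
fast_twist_config <- function(seed, ...) {
  twist_config(population_size = 20, generations = 20, patience = 10,
               lambda = 0.1, mlp = mlp_config(max_epochs = 80),
               seed = seed, ...)
}
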