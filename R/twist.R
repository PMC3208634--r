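#' Configuration of the evolutionary wrapper
#'
#' The wrapper co-optimises a train/test split (distribution-balanced
#' halves) and an input-variable mask with a generational genetic algorithm:
#' tournament selection, uniform crossover, bit-flip mutation, elitism, and
#' a "doping" step that replaces the worst few individuals with random
#' immigrants each generation to keep the gene pool diverse. Fitness of a
#' chromosome is the mean test accuracy of twin, independently initialised
#' perceptrons trained crosswise on the two halves (a-b and b-a), minus
#' `lambda` times the distribution penalty of the split.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param generations Maximum generations.
#' @param tournament_size Tournament size for parent selection.
#' @param crossover_rate Probability a child is formed by uniform crossover.
#' @param mutation_rate Per-bit flip probability; default `NULL` means
#'   1 / chromosome length.
#' @param elite_count Best individuals copied unchanged each generation.
#' @param immigrant_fraction Fraction of the (non-elite) population replaced
#'   by random chromosomes each generation (the doping injection).
#' @param lambda Weight coupling the distribution penalty into the fitness.
#' @param patience Stop after this many generations without best-fitness
#'   improvement.
#' @param split_tolerance Halves must each hold within +/- this fraction of
#'   half the records of every class.
#' @param mlp An [mlp_config()] for the inner twin networks.
#' @param n_hidden Hidden units of the inner networks.
#' @param mode `"joint"` evolves split and mask in one chromosome;
#'   `"sequential"` first optimises the split under the full mask, then the
#'   mask under the frozen split.
#' @param seed Master seed.
#' @return Object of class `twist_config`.
#' @export
twist_config <- function(population_size = 50L, generations = 100L,
                         tournament_size = 3L, crossover_rate = 0.9,
                         mutation_rate = NULL, elite_count = 2L,
                         immigrant_fraction = 0.05, lambda = 0.5,
                         patience = 20L, split_tolerance = 0.10,
                         mlp = mlp_config(max_epochs = 100L),
                         n_hidden = 4L,
                         mode = c("joint", "sequential"), seed = 1L) {
  mode <- match.arg(mode)
  if (population_size < 2L) stop("population_size must be >= 2", call. = FALSE)
  for (r in c(crossover_rate, immigrant_fraction)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 tournament_size = as.integer(tournament_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elite_count = as.integer(elite_count),
                 immigrant_fraction = immigrant_fraction,
                 lambda = lambda, patience = as.integer(patience),
                 split_tolerance = split_tolerance, mlp = mlp,
                 n_hidden = as.integer(n_hidden), mode = mode,
                 seed = as.integer(seed)),
            class = "twist_config")
}

#' Distribution dissimilarity of a candidate split
#'
#' How far apart the two halves' empirical distributions are, averaged over
#' variables: the two-sample Kolmogorov-Smirnov statistic for continuous
#' columns and the absolute prevalence difference for binary columns. Zero
#' if and only if every variable's empirical distribution coincides across
#' halves; invariant to record order.
#'
#' @param table Numeric data frame or matrix of the analysis variables.
#' @param split_bits Logical (or 0/1) vector, `TRUE` = half `a`.
#' @return Non-negative penalty.
#' @export
distribution_similarity <- function(table, split_bits) {
  table <- as.data.frame(table)
  split_bits <- as.logical(split_bits)
  if (nrow(table) != length(split_bits)) stop("length mismatch", call. = FALSE)
  if (!any(split_bits) || all(split_bits)) {
    stop("both halves must be non-empty", call. = FALSE)
  }
  pen <- vapply(table, function(x) {
    a <- x[split_bits]; b <- x[!split_bits]
    if (all(x %in% c(0, 1))) abs(mean(a) - mean(b)) else ks_statistic(a, b)
  }, numeric(1))
  mean(pen)
}

# --- chromosome helpers ------------------------------------------------

random_split <- function(labels, tol) {
  n <- length(labels)
  in_a <- logical(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    k <- length(idx)
    in_a[idx[sample.int(k, floor(k / 2) + stats::rbinom(1, 1, (k %% 2) / 2))]] <- TRUE
  }
  in_a
}

repair_split <- function(split, labels, tol) {
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    k <- length(idx)
    lo <- max(1L, floor(k / 2 * (1 - tol)))
    hi <- min(k - 1L, ceiling(k / 2 * (1 + tol)))
    na <- sum(split[idx])
    if (na < lo) {
      pool <- idx[!split[idx]]
      split[pool[sample.int(length(pool), lo - na)]] <- TRUE
    } else if (na > hi) {
      pool <- idx[split[idx]]
      split[pool[sample.int(length(pool), na - hi)]] <- FALSE
    }
  }
  split
}

repair_mask <- function(mask) {
  if (!any(mask)) mask[sample.int(length(mask), 1L)] <- TRUE
  mask
}

#' Fitness of one chromosome
#'
#' Trains twin freshly-initialised perceptrons crosswise on the chromosome's
#' split (train on `a` / test on `b`, and the reverse), using only the
#' masked variables, and returns the mean of the two balanced test
#' accuracies (as a fraction) minus `lambda` times the split's
#' [distribution_similarity()] penalty. A chromosome selecting no variables
#' scores `-Inf`.
#'
#' @param chromosome List with `split` (logical per record) and `mask`
#'   (logical per variable).
#' @param X Numeric input matrix (scaled to \[0, 1\]).
#' @param y Binary 0/1 labels.
#' @param config A [twist_config()].
#' @param mlp_seed Seed for the twin networks' initialisation (the twins use
#'   `mlp_seed` and `mlp_seed + 1`).
#' @return Numeric fitness.
#' @export
chromosome_fitness <- function(chromosome, X, y, config, mlp_seed = 1L) {
  mask <- as.logical(chromosome$mask)
  split <- as.logical(chromosome$split)
  if (!any(mask)) return(-Inf)
  Xm <- as.matrix(X)[, mask, drop = FALSE]
  acc <- numeric(2)
  for (k in 1:2) {
    tr <- if (k == 1) split else !split
    cfg <- config$mlp
    cfg$seed <- as.integer(mlp_seed + k - 1L)
    model <- mlp_train(Xm[tr, , drop = FALSE], y[tr], cfg,
                       n_hidden = config$n_hidden)
    pred <- mlp_classify(predict(model, Xm[!tr, , drop = FALSE]))
    acc[k] <- confusion_metrics(y[!tr], pred)$accuracy / 100
  }
  penalty <- if (config$lambda == 0) 0 else distribution_similarity(X, split)
  mean(acc) - config$lambda * penalty
}

ga_engine <- function(X, y, config, evolve, fixed_split = NULL,
                      fixed_mask = NULL, phase = "joint") {
  n <- nrow(X); L <- ncol(X)
  pop_size <- config$population_size
  # one expected flip per chromosome part: split bits at 1/n, mask bits at 1/L
  mut_split <- config$mutation_rate %||% (1 / n)
  mut_mask <- config$mutation_rate %||% (1 / L)
  new_individual <- function() {
    list(split = fixed_split %||% random_split(y, config$split_tolerance),
         mask = fixed_mask %||% repair_mask(stats::runif(L) < 0.5))
  }
  pop <- replicate(pop_size, new_individual(), simplify = FALSE)
  fitness <- rep(NA_real_, pop_size)
  best <- list(fitness = -Inf)
  trajectory <- data.frame(generation = integer(), best = numeric(),
                           mean = numeric())
  stall <- 0L
  for (gen in seq_len(config$generations)) {
    gen_seed <- substream_seed(config$seed, paste0(phase, "-fit-", gen))
    fitness <- vapply(pop, function(ind) {
      chromosome_fitness(ind, X, y, config, mlp_seed = gen_seed)
    }, numeric(1))
    improved <- max(fitness) > best$fitness
    if (improved) {
      i <- which.max(fitness)
      best <- list(chromosome = pop[[i]], fitness = fitness[i],
                   mlp_seed = gen_seed)
      stall <- 0L
    } else stall <- stall + 1L
    trajectory <- rbind(trajectory, data.frame(
      generation = gen, best = best$fitness,
      mean = mean(fitness[is.finite(fitness)])))
    if (stall >= config$patience || gen == config$generations) break

    ord <- order(fitness, decreasing = TRUE)
    elites <- pop[ord[seq_len(min(config$elite_count, pop_size))]]
    tournament <- function() {
      cand <- sample.int(pop_size, config$tournament_size, replace = TRUE)
      pop[[cand[which.max(fitness[cand])]]]
    }
    children <- lapply(seq_len(pop_size - length(elites)), function(j) {
      p1 <- tournament(); p2 <- tournament()
      child <- p1
      if (stats::runif(1) < config$crossover_rate) {
        if ("split" %in% evolve) {
          take <- stats::runif(n) < 0.5
          child$split <- ifelse(take, p1$split, p2$split)
        }
        if ("mask" %in% evolve) {
          take <- stats::runif(L) < 0.5
          child$mask <- ifelse(take, p1$mask, p2$mask)
        }
      }
      if ("split" %in% evolve) {
        flip <- stats::runif(n) < mut_split
        child$split <- xor(child$split, flip)
        child$split <- repair_split(child$split, y, config$split_tolerance)
      }
      if ("mask" %in% evolve) {
        flip <- stats::runif(L) < mut_mask
        child$mask <- repair_mask(xor(child$mask, flip))
      }
      child
    })
    # doping: random immigrants replace the tail of the new generation
    n_imm <- floor(config$immigrant_fraction * pop_size)
    if (n_imm > 0 && length(children) >= n_imm) {
      for (j in seq(length(children) - n_imm + 1L, length(children))) {
        children[[j]] <- new_individual()
      }
    }
    pop <- c(elites, children)
  }
  list(best = best, trajectory = trajectory)
}

#' Run the evolutionary split-and-mask optimisation
#'
#' Evolves, under one seeded genetic algorithm, a distribution-balanced
#' train/test halving of the sample and a mask over the input variables,
#' scoring each candidate by twin crosswise perceptrons
#' ([chromosome_fitness()]). In `"sequential"` mode the split is optimised
#' first (all variables on), then the mask under the frozen split.
#'
#' @param X Numeric input matrix (scaled to \[0, 1\]) with named columns.
#' @param y Binary 0/1 labels.
#' @param config A [twist_config()].
#' @return Object of class `twist_result`: `chromosome` (best split + mask),
#'   `selected` (chosen variable names), `fitness`, `split` (logical, `TRUE`
#'   = half `a`), `trajectory` (per-generation best/mean fitness), `config`.
#' @export
run_twist <- function(X, y, config = twist_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (anyNA(X)) stop("inputs must be complete-case", call. = FALSE)
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2L) {
    stop("labels must be binary 0/1 with both classes present", call. = FALSE)
  }
  if (min(table(y)) < 4L) {
    stop("too few records per class for a stratified halving", call. = FALSE)
  }
  res <- with_seed(substream_seed(config$seed, "twist"), {
    if (config$mode == "joint") {
      ga_engine(X, y, config, evolve = c("split", "mask"), phase = "joint")
    } else {
      all_mask <- rep(TRUE, ncol(X))
      ph1 <- ga_engine(X, y, config, evolve = "split",
                       fixed_mask = all_mask, phase = "tt")
      ph2 <- ga_engine(X, y, config, evolve = "mask",
                       fixed_split = ph1$best$chromosome$split, phase = "is")
      ph2$trajectory <- rbind(
        cbind(ph1$trajectory, phase = "split"),
        cbind(ph2$trajectory, phase = "mask"))
      ph2
    }
  })
  chrom <- res$best$chromosome
  structure(list(chromosome = chrom,
                 selected = colnames(X)[chrom$mask],
                 fitness = res$best$fitness,
                 split = chrom$split,
                 trajectory = res$trajectory,
                 config = config),
            class = "twist_result")
}

#' @export
print.twist_result <- function(x, ...) {
  cat("TWIST result: ", length(x$selected), "/",
      length(x$chromosome$mask), " variables selected, fitness ",
      round(x$fitness, 4), "\n", sep = "")
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a TWIST result to JSON
#'
#' Writes the selected-variable list (mirroring the published
#' selected-variable table), the split assignment and the fitness
#' trajectory.
#'
#' @param result A `twist_result`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
twist_to_json <- function(result, path) {
  stopifnot(inherits(result, "twist_result"))
  jsonlite::write_json(list(
    selected = result$selected,
    n_selected = length(result$selected),
    fitness = result$fitness,
    split_half_a = which(result$split),
    trajectory = result$trajectory,
    seed = result$config$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
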