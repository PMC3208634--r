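#' @keywords internal
"_PACKAGE"

# Derive a reproducible integer sub-seed from a master seed and a stage name.
# Keeps every source of randomness tied to one master seed while stages stay
# independent (a change in one stage's draw count does not shift another's).
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(as.numeric(master)) * 69069 + h * 9973) %% (2^31 - 1))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Truncated normal via inverse-CDF so draws are a deterministic function of
# the uniform stream (one draw per value).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (!is.finite(mean) || !is.finite(sd) || sd <= 0) {
    stop("truncated normal requires finite mean and sd > 0", call. = FALSE)
  }
  if (lower >= upper) stop("truncation bounds must satisfy lower < upper", call. = FALSE)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Two-sample Kolmogorov-Smirnov statistic, computed directly from the two
# ECDFs (no p-value machinery, no tie warnings).
ks_statistic <- function(x, y) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  grid <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(grid)
  fy <- stats::ecdf(y)(grid)
  max(abs(fx - fy))
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
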