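#' Maximum-likelihood logistic regression
#'
#' Fits a binary logistic model by iteratively reweighted least squares with
#' step-halving (the log-likelihood is non-decreasing across iterations, and
#' the trace is returned so this can be asserted). Reports Wald standard
#' errors, odds ratios with 95\% confidence intervals `exp(coef +/- 1.96 SE)`
#' and two-sided Wald p-values.
#'
#' @param X Numeric matrix or data frame of predictors.
#' @param y Binary 0/1 response.
#' @param terms Columns of `X` to include (default all).
#' @return Object of class `logistic_fit` with `coefficients`, `se`, `or`,
#'   `ci_low`, `ci_high`, `p`, `loglik`, `loglik_trace`, `converged`,
#'   `separation`, `n`.
#' @export
fit_logistic <- function(X, y, terms = colnames(X)) {
  X <- as.data.frame(X)
  if (is.null(terms)) stop("`X` must have named columns", call. = FALSE)
  missing_terms <- setdiff(terms, colnames(X))
  if (length(missing_terms)) {
    stop("terms not present in X: ", paste(missing_terms, collapse = ", "),
         call. = FALSE)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  M <- cbind(`(Intercept)` = 1, as.matrix(X[, terms, drop = FALSE]))
  if (nrow(M) != length(y)) stop("X and y lengths differ", call. = FALSE)

  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    dropped <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop("singular design: collinear term(s) ", paste(dropped, collapse = ", "),
         call. = FALSE)
  }

  loglik <- function(beta) {
    eta <- drop(M %*% beta)
    sum(y * eta - log1p(exp(eta)))
  }

  beta <- numeric(ncol(M))
  ll <- loglik(beta)
  trace <- ll
  converged <- FALSE
  for (iter in seq_len(50L)) {
    eta <- drop(M %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(M, z, w)
    beta_new <- fit$coefficients
    # step-halve until the likelihood does not decrease
    step <- beta_new - beta
    ll_new <- loglik(beta + step)
    halvings <- 0L
    while (ll_new < ll && halvings < 20L) {
      step <- step / 2
      ll_new <- loglik(beta + step)
      halvings <- halvings + 1L
    }
    beta <- beta + step
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < 1e-10 * (abs(ll) + 1)) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }

  mu <- stats::plogis(drop(M %*% beta))
  separation <- all(abs(mu - y) < 1e-6) || max(abs(beta)) > 15

  W <- mu * (1 - mu)
  info <- crossprod(M, M * W)
  cov <- tryCatch(solve(info), error = function(e) {
    # near-singular information (typically quasi-separation at small n):
    # report Moore-Penrose-based SEs and flag the fit
    separation <<- TRUE
    ev <- eigen(info, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    ev$vectors[, pos, drop = FALSE] %*%
      ((1 / ev$values[pos]) * t(ev$vectors[, pos, drop = FALSE]))
  })
  se <- sqrt(pmax(diag(cov), 0))
  names(beta) <- names(se) <- colnames(M)
  if (separation) converged <- FALSE

  structure(list(
    coefficients = beta, se = se,
    or = exp(beta), ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    loglik = ll, loglik_trace = trace,
    converged = converged, separation = separation,
    n = length(y), terms = terms
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit (n =", x$n, ", logLik =", round(x$loglik, 2), ")\n")
  print(or_table(x), row.names = FALSE)
  if (x$separation) cat("warning: separation detected; estimates unreliable\n")
  invisible(x)
}

#' Odds-ratio report table
#'
#' Term, OR, 95\% CI and p-value for each non-intercept term, the layout of
#' a multivariable risk-factor table.
#'
#' @param fit A `logistic_fit`.
#' @return Data frame with columns `term`, `or`, `ci_low`, `ci_high`, `p`.
#' @export
or_table <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  keep <- names(fit$coefficients) != "(Intercept)"
  data.frame(term = names(fit$coefficients)[keep],
             or = unname(fit$or[keep]),
             ci_low = unname(fit$ci_low[keep]),
             ci_high = unname(fit$ci_high[keep]),
             p = unname(fit$p[keep]))
}

lrt_p <- function(fit_big, fit_small, df = 1L) {
  stat <- 2 * (fit_big$loglik - fit_small$loglik)
  stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

#' Forward stepwise logistic regression
#'
#' SPSS-style forward selection with likelihood-ratio tests: at each step the
#' candidate with the smallest entry p-value joins the model if
#' `p < alpha_enter`; any included variable whose removal p-value exceeds
#' `alpha_stay` is then removed. Exact p ties are broken lexicographically.
#' The published protocol's unusual pairing (enter 0.3 / stay 0.35) is the
#' default.
#'
#' @param X Predictor matrix or data frame.
#' @param y Binary 0/1 response.
#' @param alpha_enter Significance level to enter (default 0.3).
#' @param alpha_stay Significance level to stay (default 0.35).
#' @param max_steps Safety cap on enter/remove cycles.
#' @return List with `fit` (the final [fit_logistic()]) and `trace` (data
#'   frame of `step`, `action`, `variable`, `p`).
#' @export
forward_stepwise <- function(X, y, alpha_enter = 0.3, alpha_stay = 0.35,
                             max_steps = 100L) {
  X <- as.data.frame(X)
  candidates <- colnames(X)
  if (length(candidates) < 1L) stop("need at least one candidate variable", call. = FALSE)
  included <- character(0)
  trace <- data.frame(step = integer(), action = character(),
                      variable = character(), p = numeric())
  step_no <- 0L
  fit_terms <- function(terms) {
    if (length(terms) == 0L) {
      # intercept-only fit
      fit_logistic(data.frame(.null = rep(0, length(y)))[, 0, drop = FALSE],
                   y, terms = character(0))
    } else fit_logistic(X, y, terms)
  }
  current <- fit_terms(included)
  repeat {
    step_no <- step_no + 1L
    if (step_no > max_steps) break
    changed <- FALSE

    pool <- sort(setdiff(candidates, included))
    if (length(pool)) {
      entry_p <- vapply(pool, function(v) {
        fit_v <- try(fit_terms(c(included, v)), silent = TRUE)
        if (inherits(fit_v, "try-error")) return(NA_real_)
        lrt_p(fit_v, current)
      }, numeric(1))
      ok <- which(!is.na(entry_p))
      if (length(ok)) {
        best <- ok[which.min(entry_p[ok])]  # ties: first in sorted order
        if (entry_p[best] < alpha_enter) {
          included <- c(included, pool[best])
          current <- fit_terms(included)
          trace <- rbind(trace, data.frame(step = step_no, action = "enter",
                                           variable = pool[best],
                                           p = entry_p[best]))
          changed <- TRUE
        }
      }
    }

    repeat {
      if (length(included) == 0L) break
      removal_p <- vapply(sort(included), function(v) {
        fit_v <- try(fit_terms(setdiff(included, v)), silent = TRUE)
        if (inherits(fit_v, "try-error")) return(NA_real_)
        lrt_p(current, fit_v)
      }, numeric(1))
      if (all(is.na(removal_p))) break
      worst <- which.max(removal_p)
      if (removal_p[worst] > alpha_stay) {
        v <- names(removal_p)[worst]
        included <- setdiff(included, v)
        current <- fit_terms(included)
        trace <- rbind(trace, data.frame(step = step_no, action = "remove",
                                         variable = v, p = removal_p[worst]))
        changed <- TRUE
      } else break
    }

    if (!changed) break
  }
  list(fit = current, trace = trace, included = included)
}

#' Bivariate p-value screen
#'
#' Keeps the variables whose two-group bivariate comparison (chi-square for
#' binaries, normality-gated t / Mann-Whitney for continuous variables, as
#' in [group_compare()]) has `p < alpha` — the published alternative to
#' stepwise selection.
#'
#' @param X Predictor matrix or data frame.
#' @param y Binary 0/1 group labels.
#' @param alpha Screening level (default 0.25).
#' @param kinds Optional named character vector `"binary"`/`"continuous"`
#'   per column; guessed from the values otherwise.
#' @return Character vector of retained variable names.
#' @export
bivariate_screen <- function(X, y, alpha = 0.25, kinds = NULL) {
  X <- as.data.frame(X)
  p <- vapply(colnames(X), function(v) {
    kind <- if (!is.null(kinds)) kinds[[v]] else {
      if (all(X[[v]] %in% c(0, 1))) "binary" else "continuous"
    }
    bivariate_p(X[[v]], y, kind)
  }, numeric(1))
  names(p)[!is.na(p) & p < alpha]
}
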