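#' Training configuration for the multilayer perceptron
#'
#' @param learning_rate Positive gradient-descent step size.
#' @param momentum Momentum coefficient in \[0, 1).
#' @param max_epochs Maximum training epochs (>= 1).
#' @param batch `"full"` (one gradient step per epoch over all records) or
#'   `"online"` (per-record updates in a seeded random order each epoch).
#' @param patience Early-stop patience: training halts when the epoch error
#'   has not improved by more than `tol` for this many epochs.
#' @param tol Minimum error improvement that resets the patience counter.
#' @param init_scale Weights initialised uniform(-`init_scale`, `init_scale`).
#' @param loss `"sse"` (sum of squared errors, the classical backpropagation
#'   target) or `"cross_entropy"`.
#' @param seed Integer seed for weight initialisation (and online ordering).
#' @return Object of class `mlp_config`.
#' @export
mlp_config <- function(learning_rate = 0.1, momentum = 0.9, max_epochs = 500L,
                       batch = c("full", "online"), patience = 25L,
                       tol = 1e-6, init_scale = 0.5,
                       loss = c("sse", "cross_entropy"), seed = 1L) {
  batch <- match.arg(batch)
  loss <- match.arg(loss)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (max_epochs < 1) stop("max_epochs must be >= 1", call. = FALSE)
  if (momentum < 0 || momentum >= 1) stop("momentum must lie in [0, 1)", call. = FALSE)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs), batch = batch,
                 patience = as.integer(patience), tol = tol,
                 init_scale = init_scale, loss = loss,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train a feed-forward network with four hidden units
#'
#' A fully connected perceptron (n_inputs -> n_hidden -> 1) with sigmoid
#' units throughout, trained by backpropagation (gradient descent with
#' momentum) on the configured loss. The single sigmoid output lies in
#' (0, 1) and is read as the probability-like score of the positive class.
#'
#' @param X Numeric matrix of scaled inputs in \[0, 1\].
#' @param y Binary 0/1 labels, `length(y) == nrow(X)`.
#' @param config An [mlp_config()].
#' @param n_hidden Number of hidden units (default 4, the study
#'   architecture).
#' @return Object of class `mlp_model`: weights (`W1`, `b1`, `w2`, `b2`),
#'   `n_inputs`, `n_hidden`, the config, and `errors` (per-epoch training
#'   loss).
#' @export
mlp_train <- function(X, y, config = mlp_config(), n_hidden = 4L) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X))) {
    stop("data error: inputs must be finite numeric", call. = FALSE)
  }
  y <- as.numeric(y)
  if (nrow(X) != length(y) || !all(y %in% c(0, 1))) {
    stop("data error: y must be 0/1 with one label per row of X", call. = FALSE)
  }
  d <- ncol(X); n <- nrow(X); h <- as.integer(n_hidden)

  with_seed(config$seed, {
    W1 <- matrix(stats::runif(d * h, -config$init_scale, config$init_scale), d, h)
    b1 <- stats::runif(h, -config$init_scale, config$init_scale)
    w2 <- stats::runif(h, -config$init_scale, config$init_scale)
    b2 <- stats::runif(1, -config$init_scale, config$init_scale)
    vW1 <- matrix(0, d, h); vb1 <- numeric(h); vw2 <- numeric(h); vb2 <- 0

    errors <- numeric(0)
    best <- Inf; stall <- 0L
    lr <- config$learning_rate; mom <- config$momentum

    epoch_loss <- function() {
      H <- sigmoid(sweep(X %*% W1, 2, b1, "+"))
      o <- sigmoid(drop(H %*% w2) + b2)
      if (config$loss == "sse") sum((o - y)^2)
      else -sum(y * log(pmax(o, 1e-12)) + (1 - y) * log(pmax(1 - o, 1e-12)))
    }

    for (epoch in seq_len(config$max_epochs)) {
      if (config$batch == "full") {
        H <- sigmoid(sweep(X %*% W1, 2, b1, "+"))
        o <- sigmoid(drop(H %*% w2) + b2)
        delta_o <- if (config$loss == "sse") (o - y) * o * (1 - o) else (o - y)
        grad_w2 <- drop(crossprod(H, delta_o))
        grad_b2 <- sum(delta_o)
        delta_h <- (delta_o %o% w2) * H * (1 - H)
        grad_W1 <- crossprod(X, delta_h)
        grad_b1 <- colSums(delta_h)
        vW1 <- mom * vW1 - lr * grad_W1; W1 <- W1 + vW1
        vb1 <- mom * vb1 - lr * grad_b1; b1 <- b1 + vb1
        vw2 <- mom * vw2 - lr * grad_w2; w2 <- w2 + vw2
        vb2 <- mom * vb2 - lr * grad_b2; b2 <- b2 + vb2
      } else {
        for (i in sample.int(n)) {
          x_i <- X[i, ]
          hh <- sigmoid(drop(x_i %*% W1) + b1)
          o <- sigmoid(sum(hh * w2) + b2)
          delta_o <- if (config$loss == "sse") (o - y[i]) * o * (1 - o) else o - y[i]
          delta_h <- delta_o * w2 * hh * (1 - hh)
          vw2 <- mom * vw2 - lr * delta_o * hh; w2 <- w2 + vw2
          vb2 <- mom * vb2 - lr * delta_o; b2 <- b2 + vb2
          vW1 <- mom * vW1 - lr * outer(x_i, delta_h); W1 <- W1 + vW1
          vb1 <- mom * vb1 - lr * delta_h; b1 <- b1 + vb1
        }
      }
      err <- epoch_loss()
      if (!is.finite(err)) {
        stop("training diverged at epoch ", epoch,
             " (non-finite error); reduce the learning rate", call. = FALSE)
      }
      errors <- c(errors, err)
      if (err < best - config$tol) { best <- err; stall <- 0L } else stall <- stall + 1L
      if (stall >= config$patience) break
    }

    structure(list(W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                   n_inputs = d, n_hidden = h,
                   input_names = colnames(X),
                   config = config, errors = errors),
              class = "mlp_model")
  })
}

#' Score new records with a trained network
#'
#' Deterministic forward pass; returns the sigmoid output in (0, 1).
#'
#' @param object An `mlp_model`.
#' @param newdata Numeric matrix (or vector for a single record) with
#'   `n_inputs` columns.
#' @param ... Unused.
#' @return Numeric score vector in (0, 1).
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != object$n_inputs) {
    stop("dimension mismatch: model expects ", object$n_inputs,
         " inputs, got ", ncol(X), call. = FALSE)
  }
  H <- sigmoid(sweep(X %*% object$W1, 2, object$b1, "+"))
  drop(sigmoid(drop(H %*% object$w2) + object$b2))
}

#' Threshold a network score into a class
#'
#' Scores from 0 to 0.5 are read as class 0; scores strictly above 0.5 as
#' class 1 (0.5 itself belongs to class 0).
#'
#' @param score Scores in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return Integer 0/1 vector.
#' @export
mlp_classify <- function(score, threshold = 0.5) {
  if (any(score < 0 | score > 1)) stop("scores must lie in [0, 1]", call. = FALSE)
  as.integer(score > threshold)
}

#' Serialise / restore a trained network
#'
#' JSON round trip of the weights and training configuration for exact
#' reload.
#'
#' @param model An `mlp_model`.
#' @param path Output (input) JSON path.
#' @return `mlp_to_json()` the path invisibly; `mlp_from_json()` the model.
#' @export
mlp_to_json <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(W1 = model$W1, b1 = model$b1, w2 = model$w2, b2 = model$b2,
              n_inputs = model$n_inputs, n_hidden = model$n_hidden,
              input_names = model$input_names,
              config = unclass(model$config), errors = model$errors)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname mlp_to_json
#' @export
mlp_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$W1 <- matrix(obj$W1, nrow = obj$n_inputs)
  obj$config <- structure(obj$config, class = "mlp_config")
  structure(obj, class = "mlp_model")
}
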