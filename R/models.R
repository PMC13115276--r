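# Small analytic models with exact, vectorized per-sample gradients.
# Both models minimize the multinomial cross-entropy; gradients are
# hand-derived so per-sample clipping is exact (no autodiff dependency).

#' Initialize model parameters
#'
#' Softmax regression starts at zero (the loss is convex, the origin is a
#' neutral point); the one-hidden-layer perceptron uses a scaled-uniform
#' initialization driven by `seed`.
#'
#' @param model_kind `"softmax_regression"` or `"mlp_1hidden"`.
#' @param n_features input dimension (a bias column is appended internally).
#' @param n_classes number of classes.
#' @param hidden hidden-layer width (perceptron only).
#' @param seed integer seed used for the perceptron initialization.
#' @return An object of class `model_params`: list with the flat weight
#'   vector `w` and the shape metadata needed to unflatten it.
#' @export
init_params <- function(model_kind = c("softmax_regression", "mlp_1hidden"),
                        n_features, n_classes, hidden = 16, seed = 1) {
  model_kind <- match.arg(model_kind)
  stopifnot(n_features >= 1, n_classes >= 2)
  if (model_kind == "softmax_regression") {
    w <- numeric(n_classes * (n_features + 1))
  } else {
    stopifnot(hidden >= 1)
    n1 <- hidden * (n_features + 1)
    n2 <- n_classes * (hidden + 1)
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed)
    lim1 <- sqrt(6 / (n_features + 1 + hidden))
    lim2 <- sqrt(6 / (hidden + 1 + n_classes))
    w <- c(
      stats::runif(n1, -lim1, lim1),
      stats::runif(n2, -lim2, lim2)
    )
  }
  structure(
    list(
      w = w, model_kind = model_kind, n_features = as.integer(n_features),
      n_classes = as.integer(n_classes),
      hidden = if (model_kind == "mlp_1hidden") as.integer(hidden) else NA_integer_,
      init_seed = as.integer(seed)
    ),
    class = "model_params"
  )
}

add_bias <- function(x) cbind(x, 1)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

unflatten <- function(params) {
  d1 <- params$n_features + 1L
  k <- params$n_classes
  if (params$model_kind == "softmax_regression") {
    list(W = matrix(params$w, k, d1))
  } else {
    h <- params$hidden
    n1 <- h * d1
    list(
      W1 = matrix(params$w[seq_len(n1)], h, d1),
      W2 = matrix(params$w[-seq_len(n1)], k, h + 1L)
    )
  }
}

# Forward pass returning the class-probability matrix (m x K).
forward_probs <- function(params, x) {
  xb <- add_bias(x)
  wl <- unflatten(params)
  if (params$model_kind == "softmax_regression") {
    softmax_rows(xb %*% t(wl$W))
  } else {
    a <- tanh(xb %*% t(wl$W1))
    softmax_rows(add_bias(a) %*% t(wl$W2))
  }
}

#' Predicted class labels
#'
#' @param params a `model_params`.
#' @param x feature matrix (n x d, without bias column).
#' @return 0-based integer labels (ties broken toward the lower class).
#' @export
predict_labels <- function(params, x) {
  p <- forward_probs(params, x)
  max.col(p, ties.method = "first") - 1L
}

#' Mean multinomial cross-entropy loss
#'
#' @param params a `model_params`.
#' @param x feature matrix.
#' @param y 0-based integer labels.
#' @return Scalar mean negative log-likelihood.
#' @export
model_loss <- function(params, x, y) {
  p <- forward_probs(params, x)
  -mean(log(pmax(p[cbind(seq_along(y), y + 1L)], 1e-300)))
}

#' Exact per-sample gradients of the cross-entropy loss
#'
#' Row `i` is the flattened gradient of the per-example loss at example
#' `i`. Softmax regression: `(p - onehot(y)) %o% [x, 1]`. Perceptron:
#' one-hidden-layer tanh backpropagation, vectorized over the batch.
#'
#' @param params a `model_params`.
#' @param x feature matrix (batch x d).
#' @param y 0-based integer labels (length = batch).
#' @return Matrix (batch x length(w)) of per-sample gradients.
#' @export
per_sample_gradients <- function(params, x, y) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (nrow(x) == 0L) stop("empty batch")
  if (ncol(x) != params$n_features) stop("feature dimension mismatch")
  if (length(y) != nrow(x)) stop("label/feature length mismatch")
  if (any(y < 0 | y >= params$n_classes)) stop("label out of range")
  m <- nrow(x)
  k <- params$n_classes
  xb <- add_bias(x)
  d1 <- ncol(xb)
  wl <- unflatten(params)
  if (params$model_kind == "softmax_regression") {
    p <- softmax_rows(xb %*% t(wl$W))
    dz <- p
    dz[cbind(seq_len(m), y + 1L)] <- dz[cbind(seq_len(m), y + 1L)] - 1
    # grad for row i is dz_i %o% xb_i flattened column-major as matrix(k, d1)
    g <- dz[, rep(seq_len(k), d1), drop = FALSE] *
      xb[, rep(seq_len(d1), each = k), drop = FALSE]
    g
  } else {
    h <- params$hidden
    a <- tanh(xb %*% t(wl$W1)) # m x h
    ab <- add_bias(a)
    p <- softmax_rows(ab %*% t(wl$W2))
    dz2 <- p
    dz2[cbind(seq_len(m), y + 1L)] <- dz2[cbind(seq_len(m), y + 1L)] - 1
    g2 <- dz2[, rep(seq_len(k), h + 1L), drop = FALSE] *
      ab[, rep(seq_len(h + 1L), each = k), drop = FALSE]
    da <- (dz2 %*% wl$W2[, seq_len(h), drop = FALSE]) * (1 - a^2) # m x h
    g1 <- da[, rep(seq_len(h), d1), drop = FALSE] *
      xb[, rep(seq_len(d1), each = h), drop = FALSE]
    cbind(g1, g2)
  }
}
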