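# Independent oracles used across the suite. Each reimplements the quantity
# under test from its definition, by a different route than the package.

# Central finite-difference gradient of the mean cross-entropy at one example.
fd_gradient <- function(params, x_row, y_scalar, h = 1e-6) {
  vapply(seq_along(params$w), function(j) {
    pp <- params
    pm <- params
    pp$w[j] <- pp$w[j] + h
    pm$w[j] <- pm$w[j] - h
    (model_loss(pp, x_row, y_scalar) - model_loss(pm, x_row, y_scalar)) / (2 * h)
  }, numeric(1))
}

# Order-2 Renyi divergence of the Poisson-subsampled Gaussian mixture
# (1-q) N(0, s^2) + q N(1, s^2) against N(0, s^2), by quadrature.
subsampled_rdp2_quadrature <- function(sigma, q) {
  ratio_sq <- function(x) {
    # dnorm(x, 1, s) / dnorm(x, 0, s) = exp((2 x - 1) / (2 s^2)), stable in the tails
    lr <- (1 - q) + q * exp((2 * x - 1) / (2 * sigma^2))
    lr^2 * stats::dnorm(x, 0, sigma)
  }
  val <- stats::integrate(ratio_sq, -40 * sigma, 1 + 40 * sigma,
    rel.tol = 1e-10, subdivisions = 1000L
  )$value
  log(val) # alpha - 1 = 1
}

# Naive per-step RDP composition: expand the ledger to single steps and sum.
compose_rdp_naive <- function(ledger, alpha_grid) {
  rdp <- numeric(length(alpha_grid))
  for (i in seq_len(nrow(ledger))) {
    for (rep in seq_len(ledger$count[i])) {
      rdp <- rdp + alpha_grid / (2 * ledger$sigma[i]^2)
    }
  }
  rdp
}

# Textbook multiclass MCC via the correlation between one-hot encodings.
mcc_correlation_oracle <- function(cm) {
  k <- nrow(cm)
  # rebuild paired labels from the matrix: entry (i, j) has true i, pred j
  yt <- integer(0)
  yp <- integer(0)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      yt <- c(yt, rep(i, cm[i, j]))
      yp <- c(yp, rep(j, cm[i, j]))
    }
  }
  t_oh <- outer(yt, seq_len(k), "==") * 1
  p_oh <- outer(yp, seq_len(k), "==") * 1
  num <- sum(diag(stats::cov(t_oh, p_oh)))
  den <- sqrt(sum(diag(stats::cov(t_oh, t_oh))) * sum(diag(stats::cov(p_oh, p_oh))))
  if (den == 0) {
    return(0)
  }
  num / den
}

# Default dual dynamic shape used by several trainer/evaluation tests.
desk_schedule <- function(total = 200, sigma0 = 1, c0 = 5) {
  schedule_config(total,
    lambda = 1.1, beta = 0.8, a = 0.6, rho = 0.3,
    sigma0 = sigma0, c0 = c0
  )
}

desk_dataset <- function(n = 700, seed = 3) {
  generate_gaussian_mixture(ham10000_like_preset(n_samples = n, seed = seed))
}
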