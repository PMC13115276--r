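#' Renyi-DP cost of one Gaussian-mechanism step
#'
#' A Gaussian mechanism whose noise standard deviation is `sigma` times the
#' step's L2 sensitivity satisfies `(alpha, alpha / (2 sigma^2))`-RDP. The
#' clipping threshold is the sensitivity of the clipped gradient sum and is
#' normalized out, so the accountant only ever sees the multiplier.
#'
#' @param alpha Renyi order, greater than 1 (vectorized).
#' @param sigma noise multiplier, positive.
#' @return RDP cost at each order.
#' @export
gaussian_rdp <- function(alpha, sigma) {
  if (any(alpha <= 1)) stop("`alpha` must be greater than 1")
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be positive")
  alpha / (2 * sigma^2)
}

#' Renyi-DP cost of one Poisson-subsampled Gaussian step
#'
#' Integer-order upper bound on the RDP of the Poisson-subsampled Gaussian
#' mechanism, via the binomial expansion of the order-`alpha` moment of the
#' mixture likelihood ratio:
#' `(1/(alpha-1)) log( sum_k C(alpha,k) (1-q)^(alpha-k) q^k exp(k(k-1)/(2 sigma^2)) )`.
#' At `q = 1` this reduces to [gaussian_rdp()]. Computed in log space.
#'
#' This is an optional accounting mode: the default per-step cost used by
#' the schedule design ignores subsampling amplification and is therefore
#' conservative; this mode is provided for comparability with mainstream
#' subsampled-Gaussian accountants.
#'
#' @param alpha integer Renyi order, at least 2 (vectorized).
#' @param sigma noise multiplier, positive.
#' @param q Poisson sampling rate in (0, 1].
#' @return RDP cost at each order.
#' @export
subsampled_gaussian_rdp <- function(alpha, sigma, q) {
  if (any(alpha < 2) || any(alpha != floor(alpha))) {
    stop("subsampled mode requires integer alpha >= 2; use plain mode for fractional orders")
  }
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be positive")
  if (!is.numeric(q) || q <= 0 || q > 1) stop("`q` must lie in (0, 1]")
  vapply(alpha, function(a) {
    k <- 0:a
    logterms <- lchoose(a, k) + (a - k) * log1p(-q) + k * log(q) +
      k * (k - 1) / (2 * sigma^2)
    # (1-q)^0 terms with q = 1: log1p(-1) = -Inf handled by 0 * -Inf guard
    if (q == 1) logterms <- ifelse(k == a, k * (k - 1) / (2 * sigma^2), -Inf)
    max(0, logsumexp(logterms) / (a - 1))
  }, numeric(1))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(x - m)))
}

#' Default Renyi order grid
#'
#' Fine fractional orders near 1, all integers up to 64, plus 128 and 256.
#'
#' @return Numeric vector of orders, all greater than 1.
#' @export
default_alpha_grid <- function() {
  sort(unique(c(1 + (1:99) / 10, 2:64, 128, 256)))
}

#' Privacy ledger of heterogeneous Gaussian steps
#'
#' One row per group of identical steps: noise multiplier, Poisson sampling
#' rate and repetition count. Sensitivity is normalized into the multiplier,
#' so a training run under the dual schedule has one row per stage.
#'
#' @param sigma positive noise multipliers.
#' @param q sampling rates in (0, 1], recycled.
#' @param count positive integer step counts, recycled.
#' @return An object of class `privacy_ledger` (a data frame).
#' @export
privacy_ledger <- function(sigma, q = 1, count = 1) {
  led <- data.frame(sigma = sigma, q = q, count = count)
  if (any(led$sigma <= 0)) stop("all `sigma` must be positive")
  if (any(led$q <= 0 | led$q > 1)) stop("all `q` must lie in (0, 1]")
  if (any(led$count < 1 | led$count != floor(led$count))) {
    stop("all `count` must be positive integers")
  }
  led$count <- as.integer(led$count)
  structure(led, class = c("privacy_ledger", "data.frame"))
}

#' Ledger of a full training run under a stage table
#'
#' @param table a [stage_table()].
#' @param q Poisson sampling rate of each step.
#' @return A [privacy_ledger()] with one row per stage.
#' @export
ledger_from_schedule <- function(table, q = 1) {
  stopifnot(inherits(table, "stage_table"))
  privacy_ledger(sigma = table$sigma, q = q, count = table$duration)
}

#' Write / read a privacy ledger as CSV
#'
#' @param ledger a `privacy_ledger`.
#' @param path CSV file with columns `sigma`, `q`, `count`.
#' @return `write_ledger` returns `path` invisibly; `read_ledger` a ledger.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "privacy_ledger"))
  utils::write.csv(as.data.frame(ledger), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("sigma", "q", "count")
  if (!all(need %in% names(tab))) {
    stop("ledger file lacks required columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  }
  privacy_ledger(tab$sigma, tab$q, tab$count)
}

#' Compose per-step RDP costs over a ledger
#'
#' Sequential composition of RDP guarantees is additive at each order, so
#' the total curve is `sum(count * per-step cost)` over the ledger rows.
#'
#' @param ledger a [privacy_ledger()].
#' @param alpha_grid Renyi orders; defaults to [default_alpha_grid()]
#'   (restricted to integers in subsampled mode).
#' @param mode `"plain"` (default; per-step cost `alpha / (2 sigma^2)`, no
#'   subsampling amplification — conservative) or `"subsampled"`
#'   (Poisson-amplified integer-order bound).
#' @return An object of class `rdp_curve`: list with `alpha` and `rdp`.
#' @export
compose_rdp <- function(ledger, alpha_grid = default_alpha_grid(),
                        mode = c("plain", "subsampled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ledger, "privacy_ledger"))
  if (nrow(ledger) == 0L) stop("empty ledger")
  if (mode == "subsampled") {
    alpha_grid <- alpha_grid[alpha_grid >= 2 & alpha_grid == floor(alpha_grid)]
    if (length(alpha_grid) == 0L) stop("subsampled mode needs integer orders >= 2")
  }
  rdp <- numeric(length(alpha_grid))
  for (i in seq_len(nrow(ledger))) {
    step <- if (mode == "plain") {
      gaussian_rdp(alpha_grid, ledger$sigma[i])
    } else {
      subsampled_gaussian_rdp(alpha_grid, ledger$sigma[i], ledger$q[i])
    }
    rdp <- rdp + ledger$count[i] * step
  }
  structure(list(alpha = alpha_grid, rdp = rdp), class = "rdp_curve")
}

#' Convert an RDP curve to an (epsilon, delta) guarantee
#'
#' A mechanism that is `(alpha, R)`-RDP satisfies
#' `(R + log(1/delta) / (alpha - 1), delta)`-DP; the conversion minimizes
#' this bound over the order grid.
#'
#' @param curve an [compose_rdp()] result.
#' @param delta target failure probability in (0, 1).
#' @return An object of class `dp_guarantee`: list with `epsilon`, `delta`,
#'   `optimal_alpha`.
#' @export
rdp_to_dp <- function(curve, delta) {
  stopifnot(inherits(curve, "rdp_curve"))
  if (!is.numeric(delta) || delta <= 0 || delta >= 1) {
    stop("`delta` must lie in (0, 1)")
  }
  eps <- curve$rdp + log(1 / delta) / (curve$alpha - 1)
  i <- which.min(eps)
  structure(
    list(epsilon = eps[i], delta = delta, optimal_alpha = curve$alpha[i]),
    class = "dp_guarantee"
  )
}

#' @export
print.dp_guarantee <- function(x, ...) {
  cat(sprintf(
    "(epsilon = %.6g, delta = %.3g)-DP at Renyi order alpha = %g\n",
    x$epsilon, x$delta, x$optimal_alpha
  ))
  invisible(x)
}

#' Epsilon consumed by a full run of a schedule configuration
#'
#' Convenience wrapper: realizes the stage table, builds the ledger,
#' composes and converts.
#'
#' @param config a [schedule_config()].
#' @param delta failure probability.
#' @param q Poisson sampling rate.
#' @param mode accounting mode, see [compose_rdp()].
#' @param alpha_grid Renyi orders.
#' @return A `dp_guarantee`.
#' @export
schedule_epsilon <- function(config, delta, q = 1, mode = c("plain", "subsampled"),
                             alpha_grid = default_alpha_grid()) {
  mode <- match.arg(mode)
  led <- ledger_from_schedule(stage_table(config), q = q)
  rdp_to_dp(compose_rdp(led, alpha_grid, mode), delta)
}

#' Calibrate the initial noise multiplier to a privacy budget
#'
#' Bisection on `sigma0` over `[1e-2, 1e4]`: the epsilon consumed by a fixed
#' schedule shape is strictly decreasing in `sigma0`, so the multiplier that
#' meets a target budget is unique. Iterates until the achieved epsilon is
#' within `tol_epsilon` of the target or the bracket is narrower than
#' `tol_sigma`.
#'
#' @param target_epsilon positive privacy budget to hit.
#' @param delta failure probability in (0, 1).
#' @param config a [schedule_config()]; its `sigma0` is ignored and replaced
#'   by the calibrated value.
#' @param q Poisson sampling rate.
#' @param mode accounting mode, see [compose_rdp()].
#' @param alpha_grid Renyi orders.
#' @param tol_epsilon,tol_sigma stopping tolerances.
#' @return List with `sigma0`, `epsilon_achieved`, `config` (the input
#'   config with the calibrated `sigma0`).
#' @export
calibrate_sigma0 <- function(target_epsilon, delta, config, q = 1,
                             mode = c("plain", "subsampled"),
                             alpha_grid = default_alpha_grid(),
                             tol_epsilon = 1e-3, tol_sigma = 1e-9) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "schedule_config"))
  if (!is.numeric(target_epsilon) || target_epsilon <= 0) {
    stop("`target_epsilon` must be positive")
  }
  eps_at <- function(s0) {
    cfg <- config
    cfg$sigma0 <- s0
    schedule_epsilon(cfg, delta, q, mode, alpha_grid)$epsilon
  }
  lo <- 1e-2
  hi <- 1e4
  eps_lo <- eps_at(lo) # large epsilon (little noise)
  eps_hi <- eps_at(hi)
  if (target_epsilon > eps_lo || target_epsilon < eps_hi) {
    stop(sprintf(
      "target epsilon %.4g unreachable: achievable range [%.4g, %.4g] for sigma0 in [1e-2, 1e4]",
      target_epsilon, eps_hi, eps_lo
    ))
  }
  repeat {
    mid <- (lo + hi) / 2
    eps_mid <- eps_at(mid)
    if (abs(eps_mid - target_epsilon) <= tol_epsilon || (hi - lo) < tol_sigma) {
      cfg <- config
      cfg$sigma0 <- mid
      return(list(sigma0 = mid, epsilon_achieved = eps_mid, config = cfg))
    }
    if (eps_mid > target_epsilon) lo <- mid else hi <- mid
  }
}
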