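#' Clip a gradient to an L2 norm bound
#'
#' Returns `g * min(1, C / ||g||_2)`: the direction is preserved, the norm
#' never exceeds `C`, and gradients already inside the ball — the intended
#' regime for minority-class gradients during the high-threshold initial
#' stage — pass through unchanged. The zero vector passes through.
#'
#' @param g numeric gradient vector.
#' @param clip positive L2 bound.
#' @return The clipped vector.
#' @export
clip_gradient <- function(g, clip) {
  if (!is.numeric(clip) || clip <= 0) stop("`clip` must be positive")
  nrm <- sqrt(sum(g^2))
  if (nrm <= clip) g else g * (clip / nrm)
}

# Row-wise clipping of a per-sample gradient matrix.
clip_rows <- function(gmat, clip) {
  if (clip <= 0) stop("`clip` must be positive")
  nrms <- sqrt(rowSums(gmat^2))
  scale <- pmin(1, clip / pmax(nrms, .Machine$double.xmin))
  gmat * scale
}

#' Privatize a batch of clipped per-sample gradients
#'
#' Under the default `"noise_on_sum"` convention the Gaussian noise (per
#' coordinate standard deviation `sigma * clip`, matching the sensitivity
#' of the clipped sum) is added to the summed rows and the result divided
#' by `divisor` (the expected batch size under Poisson sampling, or the
#' fixed batch size). `"literal_mean"` adds the same noise to the row mean
#' instead; it is kept for fidelity experiments but its effective noise is
#' `batch`-fold larger than the sum-based sensitivity argument requires.
#'
#' @param clipped matrix of clipped per-sample gradients (possibly 0 rows:
#'   an empty Poisson batch contributes pure noise).
#' @param clip clipping threshold used (the per-step sensitivity).
#' @param sigma noise multiplier; 0 gives the exact clipped mean.
#' @param noise_stream an RNG stream (see internals); required so no draw
#'   touches hidden global state.
#' @param divisor denominator of the aggregate (ignored for
#'   `"literal_mean"`, which divides by the realized batch size).
#' @param convention `"noise_on_sum"` (default) or `"literal_mean"`.
#' @return Noisy aggregate gradient vector.
#' @export
privatize_batch <- function(clipped, clip, sigma, noise_stream, divisor,
                            convention = c("noise_on_sum", "literal_mean")) {
  convention <- match.arg(convention)
  if (missing(noise_stream) || is.null(noise_stream)) {
    stop("`noise_stream` is required: privatization must not use hidden global randomness")
  }
  if (!is.matrix(clipped)) clipped <- matrix(clipped, nrow = 1)
  dim_w <- ncol(clipped)
  noise <- if (sigma > 0) {
    with_stream(noise_stream, function() stats::rnorm(dim_w, sd = sigma * clip))
  } else {
    numeric(dim_w)
  }
  if (convention == "noise_on_sum") {
    if (divisor <= 0) stop("`divisor` must be positive")
    unname((colSums(clipped) + noise) / divisor)
  } else {
    m <- nrow(clipped)
    if (m == 0L) stop("literal_mean convention is undefined for an empty batch")
    unname(colMeans(clipped) + noise)
  }
}

#' One SGD update
#'
#' @param w weight vector.
#' @param g noisy aggregate gradient.
#' @param eta learning rate.
#' @return `w - eta * g`.
#' @export
sgd_step <- function(w, g, eta) {
  if (length(w) != length(g)) stop("shape mismatch between weights and gradient")
  w - eta * g
}

#' Training configuration
#'
#' @param schedule a [schedule_config()] whose `total_iterations` is the
#'   number of optimizer steps to run.
#' @param learning_rate positive step size.
#' @param batch_size expected (Poisson) or exact (fixed-size) batch size.
#' @param sampling `"poisson"` (default; each example enters the batch
#'   independently with probability `batch_size / n`, the regime the
#'   accountant's sampling rate refers to) or `"fixed_size"` (uniform
#'   subsets of exactly `batch_size`).
#' @param model_kind,hidden model choice, see [init_params()].
#' @param noise_convention see [privatize_batch()].
#' @param seed integer run seed; split internally into independent sampling
#'   and noise streams.
#' @return An object of class `train_config`.
#' @export
train_config <- function(schedule, learning_rate = 0.1, batch_size = 128,
                         sampling = c("poisson", "fixed_size"),
                         model_kind = c("softmax_regression", "mlp_1hidden"),
                         hidden = 16,
                         noise_convention = c("noise_on_sum", "literal_mean"),
                         seed = 1) {
  sampling <- match.arg(sampling)
  model_kind <- match.arg(model_kind)
  noise_convention <- match.arg(noise_convention)
  stopifnot(inherits(schedule, "schedule_config"))
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  if (batch_size < 1) stop("`batch_size` must be at least 1")
  structure(
    list(
      schedule = schedule, learning_rate = learning_rate,
      batch_size = as.integer(batch_size), sampling = sampling,
      model_kind = model_kind, hidden = as.integer(hidden),
      noise_convention = noise_convention, seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' Train with the step-wise dual dynamic schedule
#'
#' Runs `total_iterations` DP-SGD steps. Each iteration looks up the
#' current stage's noise multiplier and clipping threshold, samples a
#' batch, computes exact per-sample gradients, clips each row, adds
#' calibrated Gaussian noise, and applies the update. The run is fully
#' reproducible from the configuration seed, and the returned ledger feeds
#' the accountant directly.
#'
#' @param dataset a `labelled_dataset` with at least two classes.
#' @param config a [train_config()].
#' @return An object of class `train_result`: list with `params` (final
#'   model), `loss_trace` (per-iteration mean batch loss; `NA` for empty
#'   Poisson batches), `ledger` (a [privacy_ledger()]), `stage_log`
#'   (0-based iteration indices where a new stage begins), `table` (the
#'   realized [stage_table()]) and `config`.
#' @export
train_sdd <- function(dataset, config) {
  stopifnot(inherits(dataset, "labelled_dataset"), inherits(config, "train_config"))
  k <- length(dataset$class_counts)
  if (k < 2) stop("training needs at least two classes")
  n <- nrow(dataset$features)
  if (config$batch_size > n) stop("batch_size exceeds the dataset size")
  table <- stage_table(config$schedule)
  run_dp_loop(dataset, config, table)
}

#' Static DPSGD ablation baseline
#'
#' Standard DPSGD with a constant noise multiplier and clipping threshold:
#' the degenerate single-stage schedule (`beta = 1`, `a = 1`). Matched to a
#' dual dynamic run via the accountant, it isolates the contribution of the
#' dynamic budget allocation.
#'
#' @param dataset a `labelled_dataset`.
#' @param config a [train_config()]; its schedule's `sigma0` and `c0` are
#'   used as the constant noise multiplier and clipping threshold.
#' @return A `train_result`, see [train_sdd()].
#' @export
train_dpsgd_static <- function(dataset, config) {
  stopifnot(inherits(dataset, "labelled_dataset"), inherits(config, "train_config"))
  sched <- config$schedule
  static <- schedule_config(
    total_iterations = sched$total_iterations, gamma = 1, beta = 1, a = 1,
    rho = sched$rho, n = 1, sigma0 = sched$sigma0, c0 = sched$c0,
    convention = "n_stages"
  )
  cfg <- config
  cfg$schedule <- static
  run_dp_loop(dataset, cfg, stage_table(static))
}

run_dp_loop <- function(dataset, config, table) {
  x <- dataset$features
  y <- dataset$labels
  n <- nrow(x)
  k <- length(dataset$class_counts)
  total <- sum(table$duration)
  q <- config$batch_size / n
  seeds <- derive_seeds(config$seed, 3L)
  sample_stream <- rng_stream(seeds[1])
  noise_stream <- rng_stream(seeds[2])
  params <- init_params(config$model_kind,
    n_features = ncol(x), n_classes = k,
    hidden = config$hidden, seed = seeds[3]
  )
  w <- params$w
  loss_trace <- rep(NA_real_, total)
  stage_log <- table$cumulative_start
  divisor <- config$batch_size
  for (t in seq_len(total) - 1L) {
    sc <- schedule_lookup(table, t)
    idx <- if (config$sampling == "poisson") {
      with_stream(sample_stream, function() which(stats::runif(n) < q))
    } else {
      with_stream(sample_stream, function() sample.int(n, config$batch_size))
    }
    params$w <- w
    if (length(idx) > 0L) {
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      g <- per_sample_gradients(params, xb, yb)
      loss_trace[t + 1L] <- model_loss(params, xb, yb)
      gc_ <- clip_rows(g, sc$clip)
    } else {
      gc_ <- matrix(numeric(0), 0L, length(w))
    }
    gt <- privatize_batch(gc_, sc$clip, sc$sigma, noise_stream,
      divisor = divisor, convention = config$noise_convention
    )
    w <- sgd_step(w, gt, config$learning_rate)
    if (anyNA(w) || any(!is.finite(w))) {
      stop(sprintf("non-finite weights at iteration %d: diverged (reduce the learning rate?)", t))
    }
  }
  params$w <- w
  structure(
    list(
      params = params,
      loss_trace = loss_trace,
      # a zero noise multiplier has no finite privacy cost: no ledger
      ledger = if (all(table$sigma > 0)) {
        privacy_ledger(table$sigma, q = q, count = table$duration)
      } else {
        NULL
      },
      stage_log = stage_log,
      table = table,
      config = config
    ),
    class = "train_result"
  )
}

#' @export
print.train_result <- function(x, ...) {
  fin <- x$loss_trace[!is.na(x$loss_trace)]
  cat(sprintf(
    "DP-SGD run: %d iterations, %d stage(s); final batch loss %.4f\n",
    length(x$loss_trace), nrow(x$table),
    if (length(fin)) fin[length(fin)] else NA_real_
  ))
  invisible(x)
}

#' Serialize a training result
#'
#' Writes the result as JSON (weights, loss trace, stage log, configuration
#' scalars) plus the privacy ledger as a CSV sidecar.
#'
#' @param result a `train_result`.
#' @param path output JSON path; the ledger goes to `<path>.ledger.csv`.
#' @return `path`, invisibly.
#' @export
write_train_result <- function(result, path) {
  stopifnot(inherits(result, "train_result"))
  obj <- list(
    model_kind = result$params$model_kind,
    weights = result$params$w,
    loss_trace = result$loss_trace,
    stage_log = result$stage_log,
    schedule = unclass(result$config$schedule),
    learning_rate = result$config$learning_rate,
    batch_size = result$config$batch_size,
    sampling = result$config$sampling,
    seed = result$config$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  write_ledger(result$ledger, paste0(path, ".ledger.csv"))
  invisible(path)
}
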