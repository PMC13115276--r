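#' Schedule configuration for dual dynamic DP-SGD
#'
#' Collects and validates every hyperparameter of the step-wise dual dynamic
#' schedule: total iteration budget, stage dynamics (`gamma` / `lambda`),
#' noise step ratio `beta`, clipping decay `a`, protection constant `rho`,
#' the stage-count parameter `n` (derived from `lambda` and `rho` when not
#' supplied), and the initial noise multiplier / clipping threshold.
#'
#' The dynamics factor `lambda` and step increment `gamma` are two names for
#' one dial (`lambda = 1/gamma`); supply either, or both if they agree to
#' 1e-9. `beta` defaults to `gamma`, the coupling under which stage durations
#' and noise growth are driven by a single parameter; `beta = sqrt(gamma)`
#' gives exactly uniform per-stage privacy expenditure, and smaller values
#' (e.g. 0.8 at `gamma = 0.9`) are a conservative margin that suppresses
#' late-stage noise variance.
#'
#' @param total_iterations positive integer, total optimizer iterations T.
#' @param gamma step increment in (0, 1]; stage durations satisfy
#'   `D[i] = D[i+1] * gamma`.
#' @param lambda dynamics factor `1/gamma` (alternative parameterization).
#' @param beta noise step ratio in (0, 1]; the stage noise multiplier grows
#'   by `1/beta` per stage. Defaults to `gamma`.
#' @param a clipping decay in (0, 1]; the stage clipping threshold shrinks
#'   by `a` per stage.
#' @param rho protection constant in (0, 1]: minimum fraction of the budget
#'   the first (low-noise, high-threshold) stage must occupy.
#' @param n stage-count parameter; derived via [derive_num_steps()] when
#'   `NULL` and `lambda > 1`.
#' @param sigma0 initial (stage-0) noise multiplier, positive.
#' @param c0 initial (stage-0) clipping threshold, positive.
#' @param convention `"n_stages"` (default; `n` stages, consistent with the
#'   protection horizon under the floor stage-count rule) or
#'   `"n_plus_1_stages"` (stages `D0..Dn` read literally).
#' @param variant stage-count formula variant passed to [derive_num_steps()].
#'
#' @return An object of class `schedule_config`.
#' @seealso [stage_table()], [derive_num_steps()]
#' @export
schedule_config <- function(total_iterations,
                            gamma = NULL,
                            lambda = NULL,
                            beta = NULL,
                            a = 1,
                            rho = 0.3,
                            n = NULL,
                            sigma0 = 1,
                            c0 = 1,
                            convention = c("n_stages", "n_plus_1_stages"),
                            variant = c("floor", "floor_minus_1")) {
  convention <- match.arg(convention)
  variant <- match.arg(variant)
  if (is.null(gamma) && is.null(lambda)) {
    stop("one of `gamma` or `lambda` must be supplied")
  }
  if (!is.null(gamma) && !is.null(lambda)) {
    if (abs(lambda - 1 / gamma) > 1e-9) {
      stop("`gamma` and `lambda` disagree: lambda must equal 1/gamma")
    }
  }
  if (is.null(gamma)) gamma <- 1 / lambda
  if (is.null(lambda)) lambda <- 1 / gamma
  stopifnot(
    is.numeric(total_iterations), length(total_iterations) == 1L,
    total_iterations >= 1, total_iterations == floor(total_iterations)
  )
  check_unit_interval(gamma, "gamma")
  if (is.null(beta)) beta <- gamma
  check_unit_interval(beta, "beta")
  check_unit_interval(a, "a")
  check_unit_interval(rho, "rho")
  # sigma0 = 0 is the no-privacy limit: valid for training, not for accounting
  if (!is.numeric(sigma0) || sigma0 < 0) stop("`sigma0` must be non-negative")
  if (!is.numeric(c0) || c0 <= 0) stop("`c0` must be positive")
  if (is.null(n)) {
    if (lambda <= 1) {
      stop("`n` must be given explicitly when lambda = 1 (no geometric growth)")
    }
    n <- derive_num_steps(lambda, rho, variant)
  }
  if (n < 1 || n != floor(n)) stop("`n` must be a positive integer")
  stages <- if (convention == "n_stages") n else n + 1L
  if (total_iterations < stages) {
    stop("total_iterations is smaller than the number of stages")
  }
  structure(
    list(
      total_iterations = as.integer(total_iterations),
      gamma = gamma, lambda = lambda, beta = beta, a = a, rho = rho,
      n = as.integer(n), sigma0 = sigma0, c0 = c0,
      convention = convention, variant = variant
    ),
    class = "schedule_config"
  )
}

check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x > 1) {
    stop(sprintf("`%s` must lie in (0, 1]", name))
  }
  invisible(x)
}

#' Stage count from the protection-horizon constraint
#'
#' The first stage must cover at least a fraction `rho` of the iteration
#' budget. Under geometric stage growth `D[i] = D[0] * lambda^i` this bounds
#' the usable number of stages, giving
#' `n = floor(log_lambda(1 + (lambda - 1) / rho))`.
#'
#' @param lambda dynamics factor, strictly greater than 1.
#' @param rho protection constant in (0, 1].
#' @param variant `"floor"` (default) applies the floor directly;
#'   `"floor_minus_1"` subtracts one more (never below 1), the stricter
#'   reading under which the schedule has `n + 1` stages.
#' @return A positive integer stage-count parameter.
#' @examples
#' derive_num_steps(1.1, 0.3) # 3
#' @export
derive_num_steps <- function(lambda, rho, variant = c("floor", "floor_minus_1")) {
  variant <- match.arg(variant)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 1) {
    stop("`lambda` must be strictly greater than 1")
  }
  check_unit_interval(rho, "rho")
  n <- floor(log(1 + (lambda - 1) / rho, base = lambda))
  if (variant == "floor_minus_1") n <- max(1, n - 1)
  as.integer(max(1, n))
}

#' Geometric stage durations summing exactly to the iteration budget
#'
#' Divides `total_iterations` into `n` (or `n + 1`) stages with
#' `D[i] = D[0] * lambda^i`. The real-valued first stage is
#' `T (lambda - 1) / (lambda^stages - 1)` (equal division when
#' `lambda = 1`). Integerization rounds the cumulative stage boundaries
#' half-up and differences them, so the integer durations always sum to
#' `total_iterations` and remain non-decreasing when `lambda > 1`.
#'
#' @param total_iterations iteration budget T.
#' @param lambda dynamics factor, at least 1.
#' @param n stage-count parameter.
#' @param convention stage-count convention, see [schedule_config()].
#' @param integerize if `FALSE`, return the real-valued durations (used for
#'   analytic checks such as exact uniform expenditure).
#' @return Numeric vector of stage durations.
#' @export
stage_durations <- function(total_iterations, lambda, n,
                            convention = c("n_stages", "n_plus_1_stages"),
                            integerize = TRUE) {
  convention <- match.arg(convention)
  if (lambda < 1) stop("`lambda` must be at least 1")
  if (n < 1 || n != floor(n)) stop("`n` must be a positive integer")
  stages <- if (convention == "n_stages") n else n + 1
  if (integerize && total_iterations < stages) {
    stop("total_iterations is smaller than the number of stages")
  }
  if (lambda == 1) {
    real <- rep(total_iterations / stages, stages)
  } else {
    d0 <- total_iterations * (lambda - 1) / (lambda^stages - 1)
    real <- d0 * lambda^(seq_len(stages) - 1)
  }
  if (!integerize) {
    return(real)
  }
  bounds <- round_half_up(cumsum(real))
  bounds[stages] <- total_iterations # guard the last boundary against fp drift
  durations <- diff(c(0, bounds))
  if (any(durations < 1)) {
    stop("integerized schedule has an empty stage; increase total_iterations")
  }
  # rounding can dent monotonicity by one unit when real increments are
  # tiny; rebalance so growth is preserved without breaking conservation
  repeat {
    bad <- which(diff(durations) < 0)
    if (length(bad) == 0L) break
    i <- bad[1]
    move <- ceiling((durations[i] - durations[i + 1]) / 2)
    durations[i] <- durations[i] - move
    durations[i + 1] <- durations[i + 1] + move
    if (durations[i] < 1) stop("integerized schedule has an empty stage; increase total_iterations")
  }
  as.integer(durations)
}

# round-half-up, unlike base round()'s banker's rounding
round_half_up <- function(x) floor(x + 0.5)

#' Per-stage noise multipliers and clipping thresholds
#'
#' Closed-form dual schedules: `sigma[i] = sigma0 * beta^-i` (noise grows
#' when `beta < 1`) and `C[i] = c0 * a^i` (threshold decays when `a < 1`),
#' for stages `i = 0, ..., stages - 1`.
#'
#' @param sigma0,c0 initial noise multiplier and clipping threshold.
#' @param beta,a per-stage noise step ratio and clipping decay in (0, 1].
#' @param stages number of stages.
#' @return List with components `sigmas` and `clips`.
#' @export
stage_parameters <- function(sigma0, c0, beta, a, stages) {
  if (sigma0 < 0 || c0 <= 0) stop("`sigma0` must be non-negative and `c0` positive")
  check_unit_interval(beta, "beta")
  check_unit_interval(a, "a")
  if (stages < 1 || stages != floor(stages)) stop("`stages` must be a positive integer")
  i <- seq_len(stages) - 1
  list(sigmas = sigma0 * beta^(-i), clips = c0 * a^i)
}

#' Build the realized stage table
#'
#' Materializes a [schedule_config()] into per-stage durations, noise
#' multipliers, clipping thresholds and cumulative (0-based, half-open)
#' stage boundaries.
#'
#' @param config a `schedule_config`.
#' @return An object of class `stage_table`: a data frame with columns
#'   `stage`, `duration`, `sigma`, `clip`, `cumulative_start`, carrying the
#'   config as an attribute.
#' @export
stage_table <- function(config) {
  stopifnot(inherits(config, "schedule_config"))
  durations <- stage_durations(config$total_iterations, config$lambda,
    config$n,
    convention = config$convention
  )
  pars <- stage_parameters(
    config$sigma0, config$c0, config$beta, config$a,
    length(durations)
  )
  tab <- data.frame(
    stage = seq_along(durations) - 1L,
    duration = durations,
    sigma = pars$sigmas,
    clip = pars$clips,
    cumulative_start = cumsum(c(0L, durations[-length(durations)]))
  )
  structure(tab, class = c("stage_table", "data.frame"), config = config)
}

#' @export
print.stage_table <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Dual dynamic schedule: T = %d iterations, %d stages (lambda = %.4g, beta = %.4g, a = %.4g)\n",
    cfg$total_iterations, nrow(x), cfg$lambda, cfg$beta, cfg$a
  ))
  print.data.frame(x, ...)
  invisible(x)
}

#' Look up the noise multiplier and clipping threshold of an iteration
#'
#' Stages partition iterations `0..T-1` into half-open intervals; iteration
#' `t` belongs to the unique stage whose interval contains it.
#'
#' @param table a `stage_table`.
#' @param t 0-based iteration index (vectorized).
#' @return List with `sigma` and `clip`, each the length of `t`.
#' @export
schedule_lookup <- function(table, t) {
  stopifnot(inherits(table, "stage_table"))
  total <- sum(table$duration)
  if (any(t < 0 | t >= total | t != floor(t))) {
    stop(sprintf("iteration index out of range [0, %d)", total))
  }
  idx <- findInterval(t, table$cumulative_start)
  list(sigma = table$sigma[idx], clip = table$clip[idx])
}

#' Effective injected noise variance per stage
#'
#' The per-coordinate variance of the noise added to the clipped gradient
#' sum at stage `i` is `V[i] = (sigma[i] * clip[i])^2`. Under the dual
#' schedule this equals `(sigma0 * c0)^2 * (a / beta)^(2 i)`: when `a < beta`
#' the absolute noise power decays geometrically even though the noise
#' multiplier grows.
#'
#' @param table a `stage_table`.
#' @return Numeric vector of per-stage noise variances.
#' @export
noise_variance_trajectory <- function(table) {
  stopifnot(inherits(table, "stage_table"))
  (table$sigma * table$clip)^2
}

#' Per-stage privacy expenditure profile
#'
#' Returns the RDP-cost proxy `D[i] / sigma[i]^2` for each stage. With
#' real-valued durations the profile is exactly constant when
#' `beta = sqrt(gamma)` (uniform privacy expenditure); `beta` below that
#' neutral point makes later stages cheaper.
#'
#' @param table a `stage_table`, or a list with `duration` and `sigma`
#'   vectors (e.g. real-valued durations for analytic checks).
#' @return Numeric vector of per-stage expenditure proxies.
#' @export
expenditure_profile <- function(table) {
  table$duration / table$sigma^2
}

#' Summary statistics of a realized schedule
#'
#' Duration-weighted moments of the per-iteration noise multiplier, the
#' fraction of the budget spent in the first (protected) stage, and the
#' effective noise variance trajectory.
#'
#' @param table a `stage_table`.
#' @return An object of class `schedule_stats`: list with `sigma_initial`,
#'   `weighted_mean`, `weighted_variance`, `d0_fraction`, `noise_variance`.
#' @export
schedule_stats <- function(table) {
  stopifnot(inherits(table, "stage_table"))
  total <- sum(table$duration)
  mu <- sum(table$duration * table$sigma) / total
  wvar <- sum(table$duration * (table$sigma - mu)^2) / total
  structure(
    list(
      sigma_initial = table$sigma[1],
      weighted_mean = mu,
      weighted_variance = wvar,
      d0_fraction = table$duration[1] / total,
      noise_variance = noise_variance_trajectory(table)
    ),
    class = "schedule_stats"
  )
}

#' @export
print.schedule_stats <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Schedule statistics:\n  sigma0            %.6g\n  weighted mean     %.6g\n",
      "  weighted variance %.6g\n  D0 fraction       %.6g\n"
    ),
    x$sigma_initial, x$weighted_mean, x$weighted_variance, x$d0_fraction
  ))
  invisible(x)
}

#' Write / read a stage table
#'
#' The CSV holds columns `stage`, `duration`, `sigma`, `clip`, `v`
#' (noise variance) and `cumulative_start`; the JSON mirror embeds the full
#' configuration so a schedule file is self-describing.
#'
#' @param table a `stage_table`.
#' @param path output file; `write_stage_table` picks CSV or JSON from the
#'   extension.
#' @return `write_stage_table` returns `path` invisibly; `read_stage_table`
#'   returns a `stage_table` (CSV input yields a table without config
#'   attribute; JSON input restores the config).
#' @export
write_stage_table <- function(table, path) {
  stopifnot(inherits(table, "stage_table"))
  out <- data.frame(
    stage = table$stage, duration = table$duration,
    sigma = table$sigma, clip = table$clip,
    v = noise_variance_trajectory(table),
    cumulative_start = table$cumulative_start
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    cfg <- attr(table, "config")
    jsonlite::write_json(
      list(config = unclass(cfg), table = out),
      path,
      auto_unbox = TRUE, digits = NA
    )
  } else {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_stage_table
#' @export
read_stage_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    tab <- obj$table
    cfg <- obj$config
    config <- schedule_config(
      total_iterations = cfg$total_iterations, gamma = cfg$gamma,
      beta = cfg$beta, a = cfg$a, rho = cfg$rho, n = cfg$n,
      sigma0 = cfg$sigma0, c0 = cfg$c0, convention = cfg$convention,
      variant = cfg$variant
    )
  } else {
    tab <- utils::read.csv(path)
    config <- NULL
  }
  need <- c("stage", "duration", "sigma", "clip", "cumulative_start")
  if (!all(need %in% names(tab))) {
    stop("schedule file lacks required columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  }
  out <- data.frame(
    stage = as.integer(tab$stage), duration = as.integer(tab$duration),
    sigma = tab$sigma, clip = tab$clip,
    cumulative_start = as.integer(tab$cumulative_start)
  )
  structure(out, class = c("stage_table", "data.frame"), config = config)
}

#' Convert an epoch budget to an iteration budget
#'
#' The privacy accountant charges per sampled batch, so schedules are
#' expressed in optimizer iterations; this helper converts an epoch count
#' into `epochs * ceiling(n_samples / batch_size)` iterations.
#'
#' @param epochs number of passes over the data.
#' @param n_samples training-set size.
#' @param batch_size expected batch size.
#' @return Integer iteration count.
#' @export
epochs_to_iterations <- function(epochs, n_samples, batch_size) {
  stopifnot(epochs >= 1, n_samples >= 1, batch_size >= 1)
  as.integer(epochs * ceiling(n_samples / batch_size))
}
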