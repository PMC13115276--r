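#' Confusion matrix
#'
#' @param y_true,y_pred 0-based integer labels in `[0, n_classes)`.
#' @param n_classes number of classes K.
#' @return A K x K integer matrix of class `confusion_matrix`; rows are the
#'   true class, columns the predicted class.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (any(y_true < 0 | y_true >= n_classes | y_pred < 0 | y_pred >= n_classes)) {
    stop(sprintf("labels must lie in [0, %d)", n_classes))
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  structure(cm, class = c("confusion_matrix", class(cm)))
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (sum(cm) == 0) stop("confusion matrix is empty")
  invisible(cm)
}

#' Overall accuracy
#' @param cm a confusion matrix (rows true, columns predicted).
#' @return Fraction of correct predictions.
#' @export
accuracy <- function(cm) {
  check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' Multiclass Matthews correlation coefficient
#'
#' Covariance form of the multiclass MCC:
#' `(c s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`
#' with `c` the number of correct predictions, `s` the total, `t_k` the
#' true and `p_k` the predicted class totals. Returns 0 by convention when
#' a marginal is degenerate (all-one-class truth or predictions), where the
#' denominator vanishes.
#'
#' @param cm a confusion matrix (rows true, columns predicted).
#' @return MCC in `[-1, 1]`.
#' @export
mcc_multiclass <- function(cm) {
  check_cm(cm)
  s <- sum(cm)
  c_ <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  num <- c_ * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) {
    return(0)
  }
  num / den
}

per_class_prf <- function(cm) {
  check_cm(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  data.frame(class = seq_len(nrow(cm)) - 1L, precision = precision, recall = recall, f1 = f1)
}

#' Macro-averaged F1 and recall
#'
#' One-vs-rest per-class precision/recall/F1, averaged unweighted over all
#' classes. A class with neither true nor predicted positives contributes
#' zero (deterministic convention for degenerate classifiers).
#'
#' @param cm a confusion matrix.
#' @return Scalar in `[0, 1]`.
#' @export
macro_f1 <- function(cm) mean(per_class_prf(cm)$f1)

#' @rdname macro_f1
#' @export
macro_recall <- function(cm) mean(per_class_prf(cm)$recall)

#' Group accuracy for few-shot and large-shot classes
#'
#' Per-group value is the unweighted mean of the member classes'
#' class-conditional accuracy (per-class recall), so a majority-only
#' classifier scores 1 on the dominant group and 0 on the few-shot group.
#'
#' @param cm a confusion matrix.
#' @param group_map character vector labelling each class `"large_shot"` or
#'   `"few_shot"`.
#' @return Named list with `large_shot` and `few_shot` means.
#' @export
group_accuracy <- function(cm, group_map) {
  check_cm(cm)
  if (length(group_map) != nrow(cm)) stop("`group_map` must label every class")
  if (!all(c("large_shot", "few_shot") %in% group_map)) {
    stop("both groups must be non-empty")
  }
  rec <- per_class_prf(cm)$recall
  list(
    large_shot = mean(rec[group_map == "large_shot"]),
    few_shot = mean(rec[group_map == "few_shot"])
  )
}

#' Full imbalance-aware metrics report
#'
#' @param cm a confusion matrix.
#' @param group_map optional group labels; group accuracies are reported
#'   only when given.
#' @return An object of class `metrics_report`: list with `accuracy`,
#'   `mcc`, `macro_f1`, `macro_recall`, `per_class` (precision/recall/F1
#'   data frame) and, when applicable, `group_accuracy`.
#' @export
metrics_report <- function(cm, group_map = NULL) {
  check_cm(cm)
  rep_ <- list(
    accuracy = accuracy(cm),
    mcc = mcc_multiclass(cm),
    macro_f1 = macro_f1(cm),
    macro_recall = macro_recall(cm),
    per_class = per_class_prf(cm)
  )
  if (!is.null(group_map)) rep_$group_accuracy <- group_accuracy(cm, group_map)
  structure(rep_, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | MCC %.4f | macro F1 %.4f | macro recall %.4f\n",
    x$accuracy, x$mcc, x$macro_f1, x$macro_recall
  ))
  if (!is.null(x$group_accuracy)) {
    cat(sprintf(
      "group accuracy: large-shot %.4f, few-shot %.4f\n",
      x$group_accuracy$large_shot, x$group_accuracy$few_shot
    ))
  }
  invisible(x)
}

#' Seed-replicated comparison of schedules at matched privacy
#'
#' For each algorithm and privacy budget, calibrates the initial noise
#' multiplier so a full run consumes the target epsilon, trains once per
#' seed on the shared train/validation split, evaluates on validation, and
#' aggregates means over seeds. All runs see the same data; only the
#' algorithm and the run seed differ.
#'
#' @param dataset_config a [synthetic_config()] (e.g. a preset) describing
#'   the shared dataset.
#' @param algorithms character subset of `c("sdd", "static")`. The static
#'   baseline keeps the dual schedule's initial clipping threshold as its
#'   constant threshold.
#' @param eps_targets positive privacy budgets.
#' @param seeds integer run seeds.
#' @param schedule a [schedule_config()] giving the dual dynamic shape
#'   (its `sigma0` is recalibrated per budget).
#' @param delta failure probability for the accountant.
#' @param learning_rate,batch_size,model_kind,hidden,sampling,noise_convention
#'   passed to [train_config()].
#' @param split_fraction,split_seed train/validation split control.
#' @param mode accounting mode, see [compose_rdp()].
#' @return An object of class `comparison_table`: list with `runs` (one row
#'   per algorithm x budget x seed) and `aggregate` (means over seeds),
#'   both data frames.
#' @export
run_comparison <- function(dataset_config, algorithms = c("sdd", "static"),
                           eps_targets = 3, seeds = 1:5, schedule,
                           delta = 1e-3, learning_rate = 0.1, batch_size = 128,
                           model_kind = "softmax_regression", hidden = 16,
                           sampling = "poisson",
                           noise_convention = "noise_on_sum",
                           split_fraction = 0.8, split_seed = 1,
                           mode = "plain") {
  stopifnot(inherits(dataset_config, "synthetic_config"), inherits(schedule, "schedule_config"))
  algorithms <- match.arg(algorithms, c("sdd", "static"), several.ok = TRUE)
  if (length(seeds) < 1) stop("at least one seed is required")
  dataset <- generate_gaussian_mixture(dataset_config)
  split <- train_val_split(dataset, split_fraction, seed = split_seed, stratified = TRUE)
  n_train <- nrow(split$train$features)
  q <- batch_size / n_train
  k <- length(dataset$class_counts)
  runs <- list()
  for (algo in algorithms) {
    shape <- if (algo == "sdd") {
      schedule
    } else {
      schedule_config(
        total_iterations = schedule$total_iterations, gamma = 1, beta = 1,
        a = 1, rho = schedule$rho, n = 1, sigma0 = schedule$sigma0,
        c0 = schedule$c0, convention = "n_stages"
      )
    }
    for (eps in eps_targets) {
      cal <- tryCatch(
        calibrate_sigma0(eps, delta, shape, q = q, mode = mode),
        error = function(e) {
          stop(sprintf(
            "calibration failed for algorithm '%s' at epsilon %.3g: %s",
            algo, eps, conditionMessage(e)
          ))
        }
      )
      for (seed in seeds) {
        tc <- train_config(cal$config,
          learning_rate = learning_rate,
          batch_size = batch_size, sampling = sampling,
          model_kind = model_kind, hidden = hidden,
          noise_convention = noise_convention, seed = seed
        )
        fit <- if (algo == "sdd") {
          train_sdd(split$train, tc)
        } else {
          train_dpsgd_static(split$train, tc)
        }
        pred <- predict_labels(fit$params, split$val$features)
        cm <- confusion_matrix(split$val$labels, pred, k)
        rep_ <- metrics_report(cm, dataset$group_map)
        runs[[length(runs) + 1L]] <- data.frame(
          algo = algo, eps_target = eps,
          eps_achieved = cal$epsilon_achieved, sigma0 = cal$sigma0,
          seed = seed,
          accuracy = rep_$accuracy, mcc = rep_$mcc,
          macro_f1 = rep_$macro_f1, macro_recall = rep_$macro_recall,
          large_shot_accuracy = rep_$group_accuracy$large_shot,
          few_shot_accuracy = rep_$group_accuracy$few_shot
        )
      }
    }
  }
  runs <- do.call(rbind, runs)
  metric_cols <- c(
    "accuracy", "mcc", "macro_f1", "macro_recall",
    "large_shot_accuracy", "few_shot_accuracy"
  )
  agg <- stats::aggregate(runs[metric_cols],
    by = list(algo = runs$algo, eps_target = runs$eps_target), FUN = mean
  )
  sds <- stats::aggregate(runs[metric_cols],
    by = list(algo = runs$algo, eps_target = runs$eps_target), FUN = stats::sd
  )
  names(sds)[-(1:2)] <- paste0(metric_cols, "_sd")
  agg <- merge(agg, sds, by = c("algo", "eps_target"), sort = FALSE)
  structure(
    list(runs = runs, aggregate = agg, seeds = seeds),
    class = "comparison_table"
  )
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf(
    "Matched-privacy comparison over %d seed(s)\n", length(x$seeds)
  ))
  print.data.frame(x$aggregate, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Serialize a comparison table as JSON
#'
#' Stable schema: `runs` (one object per run with algorithm, budget,
#' achieved epsilon, seed and metrics) followed by `aggregate`.
#'
#' @param table a `comparison_table`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(table, path) {
  stopifnot(inherits(table, "comparison_table"))
  jsonlite::write_json(
    list(runs = table$runs, aggregate = table$aggregate),
    path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
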