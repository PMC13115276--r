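#' Configuration for the synthetic imbalanced-classification generator
#'
#' Describes a Gaussian-mixture classification problem with controllable
#' class imbalance and separability: each class draws isotropic Gaussian
#' features around a centroid, centroids are placed at pairwise distance
#' `class_mean_separation`, and class sizes follow `class_proportions`.
#'
#' @param n_samples total number of samples.
#' @param class_proportions positive proportions summing to 1 (one per class).
#' @param n_features feature dimension.
#' @param class_mean_separation pairwise distance between class centroids,
#'   in units of the within-class standard deviation when `noise_sd = 1`.
#' @param noise_sd within-class (isotropic) standard deviation.
#' @param seed integer seed; the dataset is a deterministic function of the
#'   configuration.
#' @param group_map optional integer/character vector naming each class
#'   `"large_shot"` or `"few_shot"`; defaults to marking the single most
#'   frequent class large-shot and all others few-shot.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples, class_proportions, n_features,
                             class_mean_separation = 3, noise_sd = 1,
                             seed = 1, group_map = NULL) {
  stopifnot(n_samples >= 1, n_features >= 1, class_mean_separation > 0, noise_sd > 0)
  p <- class_proportions
  if (any(p <= 0)) stop("all class proportions must be positive")
  if (abs(sum(p) - 1) > 1e-9) stop("class proportions must sum to 1")
  k <- length(p)
  if (k < 2) stop("need at least two classes")
  if (is.null(group_map)) {
    group_map <- rep("few_shot", k)
    group_map[which.max(p)] <- "large_shot"
  }
  if (length(group_map) != k || !all(group_map %in% c("large_shot", "few_shot"))) {
    stop("`group_map` must label every class 'large_shot' or 'few_shot'")
  }
  structure(
    list(
      n_samples = as.integer(n_samples), class_proportions = p,
      n_features = as.integer(n_features),
      class_mean_separation = class_mean_separation, noise_sd = noise_sd,
      seed = as.integer(seed), group_map = group_map
    ),
    class = "synthetic_config"
  )
}

# Largest-remainder apportionment of n among proportions p; conserves n
# exactly, ties broken toward lower class index.
apportion_counts <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- raw - counts
    give <- order(frac, seq_along(p), decreasing = c(TRUE, FALSE), method = "radix")[seq_len(rem)]
    counts[give] <- counts[give] + 1
  }
  as.integer(counts)
}

#' Generate a class-imbalanced Gaussian-mixture dataset
#'
#' Realized class counts are the largest-remainder apportionment of
#' `n_samples * class_proportions`. Class centroids are mutually equidistant
#' (scaled regular-simplex arrangement, requiring `n_features >= K - 1`),
#' features are isotropic Gaussians around the centroid, and rows are
#' shuffled deterministically under the configured seed.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `labelled_dataset`: list with `features`
#'   (n x d matrix), `labels` (0-based integer classes), `class_counts`,
#'   `group_map`, and the generating `config`.
#' @export
generate_gaussian_mixture <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  k <- length(config$class_proportions)
  d <- config$n_features
  if (d < k - 1) {
    stop("equidistant centroids need n_features >= number of classes - 1")
  }
  counts <- apportion_counts(config$n_samples, config$class_proportions)
  if (any(counts == 0)) {
    stop("a class received zero samples under apportionment; increase n_samples")
  }
  centroids <- simplex_centroids(k, d) * config$class_mean_separation
  n <- sum(counts)
  labels <- rep(seq_len(k) - 1L, counts)
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(config$seed)
  feats <- centroids[labels + 1L, , drop = FALSE] +
    matrix(stats::rnorm(n * d, sd = config$noise_sd), n, d)
  ord <- sample.int(n)
  feats <- feats[ord, , drop = FALSE]
  labels <- labels[ord]
  colnames(feats) <- paste0("f", seq_len(d) - 1L)
  structure(
    list(
      features = feats, labels = labels, class_counts = counts,
      group_map = config$group_map, config = config
    ),
    class = "labelled_dataset"
  )
}

# K mutually equidistant unit-distance points (regular simplex) embedded in
# d >= K-1 dimensions, centered at the origin.
simplex_centroids <- function(k, d) {
  v <- diag(1, k, k) # vertices of the standard simplex in R^k
  v <- sweep(v, 2, colMeans(v)) # center
  # orthonormal basis of the (k-1)-dim affine hull
  b <- qr.Q(qr(t(v)))[, seq_len(k - 1), drop = FALSE]
  coords <- v %*% b # k x (k-1), pairwise distance sqrt(2)
  coords <- coords / sqrt(2) # unit pairwise distance
  out <- matrix(0, k, d)
  out[, seq_len(k - 1)] <- coords
  out
}

#' @export
print.labelled_dataset <- function(x, ...) {
  cat(sprintf(
    "Labelled dataset: %d samples, %d features, %d classes\n",
    nrow(x$features), ncol(x$features), length(x$class_counts)
  ))
  cat(
    "  class counts:",
    paste(sprintf("%d (%s)", x$class_counts, substr(x$group_map, 1, 1)), collapse = ", "), "\n"
  )
  invisible(x)
}

#' Imbalanced dataset presets
#'
#' Approximate emulations of two dermoscopic lesion benchmarks' class
#' structure: a dominant melanocytic-nevus-like class holding roughly two
#' thirds of the samples and several few-shot classes at or below 5%. The
#' 7-class preset defaults to 10015 samples, the 8-class preset to 25331.
#' Exactly one class is marked large-shot. Per-class proportions are
#' approximate by design and freely overridable through
#' [synthetic_config()].
#'
#' @param n_samples total samples.
#' @param n_features feature dimension.
#' @param class_mean_separation,noise_sd,seed passed to [synthetic_config()].
#' @return A [synthetic_config()].
#' @export
ham10000_like_preset <- function(n_samples = 10015, n_features = 10,
                                 class_mean_separation = 3, noise_sd = 1,
                                 seed = 1) {
  # AK, BCC, BKL, DF, NV, VASC, MEL; NV dominates at ~0.67
  p <- c(0.033, 0.051, 0.110, 0.011, 0.670, 0.014, 0.111)
  synthetic_config(
    n_samples, p / sum(p), n_features,
    class_mean_separation, noise_sd, seed,
    group_map = c(
      "few_shot", "few_shot", "few_shot", "few_shot",
      "large_shot", "few_shot", "few_shot"
    )
  )
}

#' @rdname ham10000_like_preset
#' @export
isic2019_like_preset <- function(n_samples = 25331, n_features = 10,
                                 class_mean_separation = 3, noise_sd = 1,
                                 seed = 1) {
  # adds an SCC-like eighth few-shot class; NV still dominant
  p <- c(0.034, 0.131, 0.104, 0.009, 0.509, 0.010, 0.178, 0.025)
  synthetic_config(
    n_samples, p / sum(p), n_features,
    class_mean_separation, noise_sd, seed,
    group_map = c(
      "few_shot", "few_shot", "few_shot", "few_shot",
      "large_shot", "few_shot", "few_shot", "few_shot"
    )
  )
}

#' Train/validation split
#'
#' @param dataset a `labelled_dataset`.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed for the permutation.
#' @param stratified if `TRUE` (default) split each class separately so the
#'   class proportions are preserved within rounding; requires at least one
#'   sample per class on each side.
#' @return List with `train` and `val`, each a `labelled_dataset`.
#' @export
train_val_split <- function(dataset, fraction = 0.8, seed = 1, stratified = TRUE) {
  stopifnot(inherits(dataset, "labelled_dataset"))
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must lie in (0, 1)")
  n <- nrow(dataset$features)
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(seed)
  if (stratified) {
    train_idx <- integer(0)
    for (cls in seq_along(dataset$class_counts) - 1L) {
      rows <- which(dataset$labels == cls)
      n_tr <- round_half_up(length(rows) * fraction)
      if (n_tr < 1 || n_tr >= length(rows)) {
        stop(sprintf("class %d too small for a stratified %.0f/%.0f split", cls, 100 * fraction, 100 * (1 - fraction)))
      }
      train_idx <- c(train_idx, sample(rows, n_tr))
    }
  } else {
    train_idx <- sample.int(n, round_half_up(n * fraction))
  }
  train_idx <- sort(train_idx)
  val_idx <- setdiff(seq_len(n), train_idx)
  list(
    train = subset_dataset(dataset, train_idx),
    val = subset_dataset(dataset, val_idx)
  )
}

subset_dataset <- function(dataset, idx) {
  k <- length(dataset$class_counts)
  labels <- dataset$labels[idx]
  structure(
    list(
      features = dataset$features[idx, , drop = FALSE],
      labels = labels,
      class_counts = as.integer(tabulate(labels + 1L, nbins = k)),
      group_map = dataset$group_map,
      config = dataset$config
    ),
    class = "labelled_dataset"
  )
}

#' Write / read a labelled dataset as CSV
#'
#' Header row with feature columns `f0..f{d-1}` followed by a `label`
#' column. Decimal points are written with "." regardless of locale, and
#' numeric values round-trip exactly (17 significant digits).
#'
#' @param dataset a `labelled_dataset`.
#' @param path CSV file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` a
#'   `labelled_dataset` (without generator config).
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "labelled_dataset"))
  df <- as.data.frame(format(dataset$features, digits = 17, trim = TRUE, scientific = TRUE))
  names(df) <- colnames(dataset$features)
  df$label <- dataset$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @param group_map optional group labels to attach on read (the CSV itself
#'   carries only features and labels).
#' @export
read_dataset <- function(path, group_map = NULL) {
  tab <- tryCatch(
    utils::read.csv(path, colClasses = NA),
    error = function(e) stop("failed to parse dataset CSV: ", conditionMessage(e))
  )
  if (!"label" %in% names(tab)) {
    stop(sprintf("dataset CSV '%s' has no 'label' column (line 1)", path))
  }
  feat_cols <- setdiff(names(tab), "label")
  if (length(feat_cols) == 0L) stop("dataset CSV has no feature columns")
  bad <- which(!vapply(tab[feat_cols], is.numeric, logical(1)))
  if (length(bad)) {
    stop(sprintf("non-numeric feature column '%s' in dataset CSV", feat_cols[bad[1]]))
  }
  if (any(tab$label != floor(tab$label)) || any(tab$label < 0)) {
    stop("labels must be non-negative integers")
  }
  labels <- as.integer(tab$label)
  k <- max(labels) + 1L
  feats <- as.matrix(tab[feat_cols])
  if (is.null(group_map)) {
    counts <- tabulate(labels + 1L, nbins = k)
    group_map <- rep("few_shot", k)
    group_map[which.max(counts)] <- "large_shot"
  }
  structure(
    list(
      features = feats, labels = labels,
      class_counts = as.integer(tabulate(labels + 1L, nbins = k)),
      group_map = group_map, config = NULL
    ),
    class = "labelled_dataset"
  )
}
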