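#' SVM hyperparameters
#'
#' Radial-basis-function SVM configuration, parameterized by the
#' regularization weight `C` and the kernel width `sigma` in
#' `k(x, y) = exp(-||x - y||^2 / (2 sigma^2))`. libsvm's `gamma` convention
#' is converted internally as `gamma = 1 / (2 sigma^2)`. The defaults are
#' the empirically selected values of the published classifier pair:
#' `C = 0.03` with `sigma = 3` for the low-load detector and `sigma = 0.3`
#' for the high-load detector.
#'
#' @param C regularization weight (> 0).
#' @param sigma RBF kernel width (> 0).
#' @return object of class `svm_config`.
#' @export
svm_config <- function(C = 0.03, sigma = 3) {
  if (!(C > 0) || !(sigma > 0)) stop("C and sigma must be positive")
  structure(list(C = C, sigma = sigma, gamma = 1 / (2 * sigma^2)),
            class = "svm_config")
}

#' @rdname svm_config
#' @export
svm_config_low <- function() svm_config(C = 0.03, sigma = 3)

#' @rdname svm_config
#' @export
svm_config_high <- function() svm_config(C = 0.03, sigma = 0.3)

# Coerce a labeled DFHM set (list of labeled dfhm, or a dfhm_table data
# frame) to a feature matrix + label vector.
labeled_set_matrix <- function(labeled) {
  if (is.data.frame(labeled)) {
    meta <- c("subject_id", "task_id", "start_s", "label", "training")
    X <- as.matrix(labeled[setdiff(names(labeled), meta)])
    y <- labeled$label
  } else {
    X <- do.call(rbind, lapply(labeled, dfhm_to_vector))
    y <- vapply(labeled, function(m) m$label %||% NA_character_, "")
  }
  if (anyNA(X)) stop("labeled set contains NaN/NA features")
  if (anyNA(y) || any(y == "")) stop("labeled set contains unlabeled maps")
  if (!all(y %in% c("low", "moderate", "high")))
    stop("labels must be low/moderate/high")
  list(X = X, y = y)
}

train_binary <- function(X, y_bin, cfg, positive) {
  if (length(unique(y_bin)) < 2L)
    stop("cannot train ", positive,
         "-vs-rest SVM: training labels contain a single class")
  e1071::svm(X, factor(y_bin, levels = c("rest", positive)),
             type = "C-classification", kernel = "radial",
             cost = cfg$C, gamma = cfg$gamma, scale = FALSE)
}

#' Train the low-load / high-load SVM pair
#'
#' Trains two binary RBF SVMs on the same labeled DFHM set: the low-load
#' model separates `low` from `{moderate, high}`, the high-load model
#' separates `high` from `{low, moderate}`.
#'
#' @param labeled labeled maps: a list of `dfhm` with `label` set, or a
#'   [dfhm_table()] data frame.
#' @param cfg_low,cfg_high [svm_config()] for the two detectors.
#' @param seed integer seed recorded in the metadata (training itself is
#'   deterministic given the data).
#' @param montage montage the maps were built against (recorded; checked on
#'   [load_model_pair()]).
#' @return object of class `model_pair` with elements `low_model`,
#'   `high_model` and `meta` (sizes, configs, seed, montage labels,
#'   training-set hash).
#' @export
train_pair <- function(labeled, cfg_low = svm_config_low(),
                       cfg_high = svm_config_high(), seed = 1L,
                       montage = default_montage()) {
  d <- labeled_set_matrix(labeled)
  y_low <- ifelse(d$y == "low", "low", "rest")
  y_high <- ifelse(d$y == "high", "high", "rest")
  low_model <- train_binary(d$X, y_low, cfg_low, "low")
  high_model <- train_binary(d$X, y_high, cfg_high, "high")
  meta <- list(n = nrow(d$X), p = ncol(d$X),
               class_counts = as.list(table(d$y)),
               cfg_low = unclass(cfg_low), cfg_high = unclass(cfg_high),
               seed = seed, montage = montage$labels,
               training_hash = sum(d$X) + length(d$y),
               version = as.character(utils::packageVersion("dfhm")))
  structure(list(low_model = low_model, high_model = high_model,
                 meta = meta),
            class = "model_pair")
}

#' Apply the SVM pair to one DFHM
#'
#' @param m a `dfhm` or a feature vector of the training dimension.
#' @param models a `model_pair`.
#' @return logical vector `c(is_low = ..., is_high = ...)`.
#' @export
classify_map <- function(m, models) {
  stopifnot(inherits(models, "model_pair"))
  x <- if (inherits(m, "dfhm")) dfhm_to_vector(m) else as.numeric(m)
  if (length(x) != models$meta$p)
    stop("feature length ", length(x), " does not match training dimension ",
         models$meta$p)
  X <- matrix(x, nrow = 1)
  c(is_low = unname(predict(models$low_model, X) == "low"),
    is_high = unname(predict(models$high_model, X) == "high"))
}

# vectorized prediction over a matrix of maps (rows)
classify_matrix <- function(X, models) {
  stopifnot(inherits(models, "model_pair"))
  if (ncol(X) != models$meta$p) stop("feature dimension mismatch")
  data.frame(is_low = predict(models$low_model, X) == "low",
             is_high = predict(models$high_model, X) == "high")
}

#' Monte Carlo cross-validation of the SVM pair
#'
#' Random sub-sampling validation: the labeled set is split at random into
#' training and test parts (default 60/40), both models are retrained from
#' scratch on the training part, held-out accuracy is measured on the test
#' part, and the procedure is repeated (default 10 times). Splits are
#' stratified by label by default; `stratify = FALSE` gives plain random
#' sub-sampling.
#'
#' @param labeled labeled maps (see [train_pair()]).
#' @param train_frac fraction of maps used for training, in (0, 1).
#' @param reps number of random splits (>= 1).
#' @param cfg_low,cfg_high [svm_config()] for the two detectors.
#' @param seed RNG seed; results are bit-reproducible for a fixed seed.
#' @param stratify stratify splits by label.
#' @return list with `mean_acc_low`, `mean_acc_high` (percent) and
#'   `per_split` (data frame of per-split accuracies in percent).
#' @export
monte_carlo_cv <- function(labeled, train_frac = 0.60, reps = 10,
                           cfg_low = svm_config_low(),
                           cfg_high = svm_config_high(),
                           seed = 1L, stratify = TRUE) {
  if (reps < 1) stop("reps must be >= 1")
  if (!(train_frac > 0 && train_frac < 1))
    stop("train_frac must lie in (0, 1)")
  d <- labeled_set_matrix(labeled)
  n <- nrow(d$X)
  set.seed(seed)
  acc <- matrix(NA_real_, reps, 2, dimnames = list(NULL, c("low", "high")))
  for (r in seq_len(reps)) {
    tr <- if (stratify) {
      unlist(lapply(split(seq_len(n), d$y), function(idx)
        sample(idx, max(1L, round(train_frac * length(idx))))))
    } else sample(n, round(train_frac * n))
    te <- setdiff(seq_len(n), tr)
    y_low <- ifelse(d$y == "low", "low", "rest")
    y_high <- ifelse(d$y == "high", "high", "rest")
    m_low <- train_binary(d$X[tr, , drop = FALSE], y_low[tr], cfg_low, "low")
    m_high <- train_binary(d$X[tr, , drop = FALSE], y_high[tr], cfg_high,
                           "high")
    acc[r, "low"] <- mean(predict(m_low, d$X[te, , drop = FALSE]) == y_low[te])
    acc[r, "high"] <- mean(predict(m_high, d$X[te, , drop = FALSE]) ==
                             y_high[te])
  }
  list(mean_acc_low = mean(acc[, "low"]) * 100,
       mean_acc_high = mean(acc[, "high"]) * 100,
       per_split = data.frame(split = seq_len(reps),
                              acc_low = acc[, "low"] * 100,
                              acc_high = acc[, "high"] * 100))
}

#' Save / load a trained model pair
#'
#' The serialized file carries the montage and training metadata; loading
#' refuses a montage mismatch.
#'
#' @param models a `model_pair`.
#' @param path output file.
#' @param montage montage expected at load time.
#' @return `path` (save) or the `model_pair` (load).
#' @export
save_model_pair <- function(models, path) {
  stopifnot(inherits(models, "model_pair"))
  saveRDS(models, path)
  invisible(path)
}

#' @rdname save_model_pair
#' @export
load_model_pair <- function(path, montage = default_montage()) {
  models <- readRDS(path)
  if (!inherits(models, "model_pair")) stop("not a model_pair file: ", path)
  if (!identical(models$meta$montage, montage$labels))
    stop("model was trained on a different montage")
  models
}
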