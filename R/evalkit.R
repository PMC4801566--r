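#' Stratified K-fold assignment
#'
#' Assigns every segment to exactly one of `K` folds.  With
#' `stratified = TRUE` (default) samples are dealt to folds class by
#' class in seeded random order, keeping both the overall and the
#' per-class fold sizes within one of each other.
#'
#' @param labels Class label per segment (factor or coercible).
#' @param K Number of folds (>= 2).
#' @param seed Optional integer seed.
#' @param stratified Stratify by class (default `TRUE`).
#' @return An object of class `fold_plan` with the per-segment
#'   `assignment` (1..K), `K`, `seed` and `stratified`.
#' @export
kfold_split <- function(labels, K, seed = NULL, stratified = TRUE) {
  labels <- as.factor(labels)
  n <- length(labels)
  stopifnot(K >= 2, n >= K)
  assignment <- integer(n)
  with_seed(seed, {
    if (stratified) {
      counts <- table(labels)
      if (any(counts < K))
        stop(sprintf("class '%s' has fewer samples than K = %d",
                     names(counts)[which.min(counts)], K),
             call. = FALSE)
      pos <- 0L
      for (cl in levels(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        assignment[idx] <- ((pos + seq_along(idx) - 1L) %% K) + 1L
        pos <- pos + length(idx)
      }
    } else {
      assignment <- ((sample.int(n) - 1L) %% K) + 1L
    }
  })
  structure(list(assignment = assignment, K = as.integer(K), seed = seed,
                 stratified = isTRUE(stratified)),
            class = "fold_plan")
}

#' Confusion matrix
#'
#' Counts of (true, predicted) label pairs: rows are true classes,
#' columns predictions.  Confusion need not be symmetric -- class A being
#' mistaken for B says nothing about B being mistaken for A.
#'
#' @param true_labels,pred_labels Equal-length label vectors.
#' @param levels Optional common class levels; defaults to the union of
#'   levels seen.
#' @return An object of class `confusion_matrix` wrapping the integer
#'   count matrix.
#' @export
confusion <- function(true_labels, pred_labels, levels = NULL) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors differ in length", call. = FALSE)
  if (is.null(levels))
    levels <- union(base::levels(as.factor(true_labels)),
                    base::levels(as.factor(pred_labels)))
  t_f <- factor(true_labels, levels = levels)
  p_f <- factor(pred_labels, levels = levels)
  if (any(is.na(t_f)) || any(is.na(p_f)))
    stop("label outside the declared levels", call. = FALSE)
  counts <- unclass(table(true = t_f, predicted = p_f))
  structure(list(counts = counts, levels = levels),
            class = "confusion_matrix")
}

#' @rdname confusion
#' @param cm A `confusion_matrix`.
#' @return `accuracy()` returns the correct differentiation rate,
#'   trace/total.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  sum(diag(cm$counts)) / sum(cm$counts)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion_matrix: %d classes, %d samples, accuracy %.4f\n",
              length(x$levels), sum(x$counts), accuracy(x)))
  print(x$counts)
  invisible(x)
}

#' Write a confusion matrix as labelled CSV
#'
#' @param cm A [confusion()] matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  df <- as.data.frame.matrix(cm$counts)
  write.table(cbind(true = rownames(cm$counts), df), path, sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a segment to selected sensors and positions
#'
#' Keeps the columns whose metadata matches the requested sensor types
#' and body positions; downstream feature width scales as
#' `14 * kept channels`.
#'
#' @param seg A [sensor_segment()].
#' @param sensors Character subset of `c("acc", "gyro", "mag")`, or
#'   `NULL` for all.
#' @param positions Character subset of `c("T", "RA", "LA", "RL", "LL")`,
#'   or `NULL` for all.
#' @return A reduced [sensor_segment()].
#' @export
channel_subset <- function(seg, sensors = NULL, positions = NULL) {
  stopifnot(inherits(seg, "sensor_segment"))
  keep <- rep(TRUE, nrow(seg$channel_meta))
  if (!is.null(sensors)) keep <- keep & seg$channel_meta$sensor %in% sensors
  if (!is.null(positions))
    keep <- keep & seg$channel_meta$position %in% positions
  if (!any(keep)) stop("empty channel selection", call. = FALSE)
  sensor_segment(seg$data[, keep, drop = FALSE], seg$label, seg$subject,
                 seg$channel_meta[keep, , drop = FALSE])
}

#' @rdname channel_subset
#' @param dataset A `har_dataset`.
#' @export
dataset_subset <- function(dataset, sensors = NULL, positions = NULL) {
  stopifnot(inherits(dataset, "har_dataset"))
  dataset$segments <- lapply(dataset$segments, channel_subset,
                             sensors = sensors, positions = positions)
  dataset
}

# Adapt a dbn_spec to the feature width and class count at hand, keeping
# the hidden sizes.
adapt_spec <- function(spec, n_features, n_classes) {
  ls <- spec$layer_sizes
  ls[c(1L, 3L, 5L)] <- n_features
  ls[6L] <- n_classes
  spec$layer_sizes <- as.integer(ls)
  spec
}

#' K-fold evaluation of the full pipeline
#'
#' For each fold: extract features from the training segments, fit the
#' PCA basis on the training fold only (leakage guard), project both
#' folds, train the classifier on the training fold, and evaluate on the
#' held-out fold.  Feature extraction itself is per-segment and
#' leakage-free, so it is computed once.
#'
#' @param dataset A `har_dataset`.
#' @param spec A [dbn_spec()]; input/output sizes are adapted to the
#'   feature width and class count automatically.
#' @param K Number of folds (default 6).
#' @param seed Integer seed driving the fold plan and every training
#'   stage.
#' @param n_keep Principal components kept per feature type (default 3).
#' @param features Optional precomputed feature matrix (one row per
#'   segment) to skip re-extraction.
#' @return List with `mean_accuracy` (mean of the per-fold accuracies),
#'   `fold_accuracies`, `per_fold` confusion matrices, the `aggregate`
#'   confusion matrix over all held-out predictions, and the `fold_plan`.
#' @export
train_eval <- function(dataset, spec = dbn_spec(), K = 6L, seed = 1L,
                       n_keep = 3L, features = NULL) {
  stopifnot(inherits(dataset, "har_dataset"))
  labels <- dataset$labels
  if (is.null(features)) features <- extract_feature_matrix(dataset$segments)
  plan <- kfold_split(labels, K, seed = derive_seed(seed, "folds"))
  lvls <- levels(labels)
  per_fold <- vector("list", K)
  fold_acc <- numeric(K)
  agg_true <- agg_pred <- character(0)
  for (f in seq_len(K)) {
    te <- plan$assignment == f
    basis <- fit_pca(features[!te, , drop = FALSE], n_keep = n_keep)
    Ztr <- project(features[!te, , drop = FALSE], basis)
    Zte <- project(features[te, , drop = FALSE], basis)
    spec_f <- adapt_spec(spec, ncol(Ztr), length(lvls))
    model <- train_dbn(Ztr, labels[!te], spec_f,
                       seed = derive_seed(seed, paste0("fold", f)))
    pred <- predict(model, Zte)$labels
    per_fold[[f]] <- confusion(labels[te], pred, levels = lvls)
    fold_acc[f] <- accuracy(per_fold[[f]])
    agg_true <- c(agg_true, as.character(labels[te]))
    agg_pred <- c(agg_pred, as.character(pred))
  }
  list(mean_accuracy = mean(fold_acc), fold_accuracies = fold_acc,
       per_fold = per_fold,
       aggregate = confusion(agg_true, agg_pred, levels = lvls),
       fold_plan = plan)
}

#' Train/predict holdout evaluation
#'
#' Trains on a fixed number of segments per activity-subject pair and
#' predicts the remainder (e.g. 50 train / 10 predict per pair for the
#' full-size dataset), mirroring a train-then-deploy split rather than
#' full cross-validation.
#'
#' @param dataset A `har_dataset`.
#' @param spec A [dbn_spec()].
#' @param train_per_pair Training segments per activity-subject pair.
#' @param seed Integer seed.
#' @param n_keep Principal components kept per feature type.
#' @return List with `accuracy`, the predicting `confusion` matrix, and
#'   the trained `model`.
#' @export
holdout_eval <- function(dataset, spec = dbn_spec(), train_per_pair = 50L,
                         seed = 1L, n_keep = 3L) {
  stopifnot(inherits(dataset, "har_dataset"))
  labels <- dataset$labels
  pair <- interaction(labels, dataset$subjects, drop = TRUE)
  tr <- logical(length(labels))
  with_seed(derive_seed(seed, "holdout"), {
    for (p in levels(pair)) {
      idx <- which(pair == p)
      if (length(idx) <= train_per_pair)
        stop("not enough segments per pair to hold any out",
             call. = FALSE)
      tr[idx[sample.int(length(idx), train_per_pair)]] <- TRUE
    }
  })
  features <- extract_feature_matrix(dataset$segments)
  basis <- fit_pca(features[tr, , drop = FALSE], n_keep = n_keep)
  Ztr <- project(features[tr, , drop = FALSE], basis)
  Zte <- project(features[!tr, , drop = FALSE], basis)
  spec_h <- adapt_spec(spec, ncol(Ztr), nlevels(labels))
  model <- train_dbn(Ztr, labels[tr], spec_h,
                     seed = derive_seed(seed, "holdout-train"))
  pred <- predict(model, Zte)$labels
  cm <- confusion(labels[!tr], pred, levels = levels(labels))
  list(accuracy = accuracy(cm), confusion = cm, model = model)
}
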