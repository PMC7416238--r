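#' Confusion counts for seizure detection
#'
#' Seizure (label 1) is the positive class: `tp` counts seizure segments
#' predicted as seizures, `fn` seizures predicted non-seizure, `fp`
#' non-seizures predicted seizure, and `tn` non-seizures predicted
#' non-seizure.
#'
#' @param truth,predicted Equal-length vectors of 0/1 labels.
#' @return A list of class `"confusion_counts"` with integer fields
#'   `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' must have equal length", call. = FALSE)
  if (!all(truth %in% c(0L, 1L)) || !all(predicted %in% c(0L, 1L)))
    stop("labels must be 0 (non-seizure) or 1 (seizure)", call. = FALSE)
  structure(list(tp = sum(truth == 1L & predicted == 1L),
                 fn = sum(truth == 1L & predicted == 0L),
                 fp = sum(truth == 0L & predicted == 1L),
                 tn = sum(truth == 0L & predicted == 0L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("tp=%d fn=%d fp=%d tn=%d\n", x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Classification accuracy
#'
#' `(TN + TP) / (TP + TN + FP + FN)`.
#'
#' @param counts A [confusion_counts()] object.
#' @return A number in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop("accuracy is undefined on zero samples", call. = FALSE)
  (counts$tn + counts$tp) / total
}

#' Seizure sensitivity (recall of the positive class)
#'
#' `TP / (TP + FN)`: the fraction of true seizure segments detected.
#'
#' @param counts A [confusion_counts()] object.
#' @return A number in `[0, 1]`.
#' @export
sensitivity <- function(counts) {
  pos <- counts$tp + counts$fn
  if (pos == 0)
    stop("sensitivity is undefined without positive samples", call. = FALSE)
  counts$tp / pos
}

#' Stratified train/test split
#'
#' Samples a seeded split preserving the label proportions per class.
#'
#' @param labels Label vector.
#' @param train_fraction Fraction of each class assigned to training,
#'   default 0.7.
#' @return A list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7) {
  idx_by_class <- split(seq_along(labels), labels)
  train <- sort(unlist(lapply(idx_by_class, function(idx) {
    sample(idx, round(train_fraction * length(idx)))
  }), use.names = FALSE))
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Run a seeded end-to-end synthetic experiment
#'
#' Generates a multiview Gaussian dataset (or builds the three EEG views
#' from synthetic segments), splits it 70/30 stratified by label, fits an
#' [mvfcm_classifier()] on the training part, predicts the held-out part,
#' and reports accuracy and sensitivity.
#'
#' @param config A list with elements `data` (either an
#'   [mv_gaussian_scenario()] or an [eeg_scenario()]), `model` (arguments
#'   for [mvfcm_classifier()]: `n_clusters`, `m`, `temperature`, `nstart`,
#'   ...), and `train_fraction` (default 0.7). Missing parts take defaults.
#' @param seed Integer seed driving the data generation, the split and the
#'   fit. Default 1.
#' @return A list of class `"mvfcm_report"`: the configuration echoes, view
#'   weights, confusion counts and both metrics.
#' @examples
#' rep <- run_experiment(list(data = mv_gaussian_scenario(n_per_class = 30)),
#'                       seed = 1)
#' rep$accuracy
#' @export
run_experiment <- function(config = list(), seed = 1L) {
  seed <- as.integer(seed)
  data_cfg <- config$data
  if (is.null(data_cfg)) data_cfg <- mv_gaussian_scenario()
  model_cfg <- config$model
  if (is.null(model_cfg)) model_cfg <- list()
  train_fraction <- if (is.null(config$train_fraction)) 0.7
                    else config$train_fraction

  if (inherits(data_cfg, "eeg_scenario")) {
    data_cfg$seed <- seed
    segs <- gen_synthetic_eeg(data_cfg)
    dataset <- build_views(segs)
    labels <- attr(dataset, "labels")
  } else {
    data_cfg$seed <- seed
    sim <- gen_multiview_gaussian(data_cfg)
    dataset <- sim$dataset
    labels <- sim$labels
  }

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  split <- stratified_split(labels, train_fraction)

  args <- c(list(x = subset_samples(dataset, split$train),
                 labels = labels[split$train],
                 centers = if (is.null(model_cfg$n_clusters)) 2L
                           else model_cfg$n_clusters,
                 seed = seed),
            model_cfg[setdiff(names(model_cfg), "n_clusters")])
  clf <- do.call(mvfcm_classifier, args)

  pred <- predict(clf, subset_samples(dataset, split$test))
  cc <- confusion_counts(labels[split$test], pred)
  structure(list(seed = seed,
                 n_train = length(split$train),
                 n_test = length(split$test),
                 view_weights = clf$weights,
                 label_map = clf$label_map,
                 confusion = cc,
                 accuracy = accuracy(cc),
                 sensitivity = sensitivity(cc)),
            class = "mvfcm_report")
}

#' @export
print.mvfcm_report <- function(x, ...) {
  cat("Multiview FCM experiment report\n")
  cat(sprintf("  seed %d, %d train / %d test samples\n",
              x$seed, x$n_train, x$n_test))
  cat("  view weights:", paste(signif(x$view_weights, 4), collapse = " "), "\n")
  cat("  confusion: "); print(x$confusion)
  cat(sprintf("  accuracy    %.4f\n  sensitivity %.4f\n",
              x$accuracy, x$sensitivity))
  invisible(x)
}

#' Write an experiment report as JSON
#'
#' @param report An `"mvfcm_report"` from [run_experiment()].
#' @param path Output file path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "mvfcm_report"))
  doc <- unclass(report)
  doc$confusion <- unclass(doc$confusion)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}
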