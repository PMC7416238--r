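#' Per-view memberships of a single sample
#'
#' At prediction time each view votes on its own: the membership of a sample
#' to cluster c in view i uses only that view's squared Euclidean distances,
#' `u_c^(i) = [ sum_e (d_i(x, o_c) / d_i(x, o_e))^{1/(m-1)} ]^{-1}`, so the
#' view weights are applied exactly once when the votes are combined.
#' Zero distances follow the same analytic limit as in training.
#'
#' @param sample_views A list of length-N numeric vectors (or 1-row
#'   matrices), the sample's coordinates in each view.
#' @param centers Per-view `C x n_i` center matrices.
#' @param m Fuzzifier, > 1.
#' @return An `N x C` matrix; every row sums to 1.
#' @export
per_view_membership <- function(sample_views, centers, m) {
  check_fuzzifier(m)
  if (!is.list(sample_views) || length(sample_views) != length(centers))
    stop("'sample_views' must be a list with one vector per view", call. = FALSE)
  C <- nrow(centers[[1L]])
  out <- matrix(0, length(centers), C)
  for (i in seq_along(centers)) {
    xi <- as.numeric(sample_views[[i]])
    if (length(xi) != ncol(centers[[i]]))
      stop(sprintf("view %d: sample has %d features, centers have %d",
                   i, length(xi), ncol(centers[[i]])), call. = FALSE)
    d <- colSums((t(centers[[i]]) - xi)^2)
    out[i, ] <- memberships_from_distances(matrix(d, ncol = 1L), m)[, 1L]
  }
  out
}

## Batch version: list of N per-view C x K membership matrices.
per_view_membership_batch <- function(dataset, centers, m) {
  dataset <- multiview_dataset(dataset)
  dists <- pairwise_sq_distances(dataset, centers)
  lapply(dists, memberships_from_distances, m = m)
}

#' Combine per-view memberships into class scores
#'
#' The view-weighted membership `s_c = sum_i w_i u_c^(i)` per cluster, then
#' clusters pooled into class labels through `label_map` by summation. With
#' a bijective cluster-to-class map the scores of each sample sum to 1.
#'
#' @param per_view_u An `N x C` matrix as returned by
#'   [per_view_membership()], or a list of `C x K` per-view membership
#'   matrices for a batch.
#' @param weights Simplex vector of fitted view weights.
#' @param label_map Integer vector of length C giving the class label of
#'   each cluster.
#' @param class_labels Ordered vector of class labels to score (defaults to
#'   the sorted unique mapped labels).
#' @return For a single sample, a named score vector over `class_labels`;
#'   for a batch, a `K x length(class_labels)` matrix.
#' @export
class_scores <- function(per_view_u, weights, label_map,
                         class_labels = sort(unique(label_map))) {
  if (is.matrix(per_view_u)) {
    check_weights(weights, nrow(per_view_u))
    s <- drop(crossprod(per_view_u, weights))          # per-cluster scores
    out <- vapply(class_labels, function(lab) sum(s[label_map == lab]), 0)
    names(out) <- as.character(class_labels)
    return(out)
  }
  check_weights(weights, length(per_view_u))
  S <- Reduce(`+`, Map(`*`, as.list(weights), per_view_u)) # C x K
  M <- vapply(class_labels,
              function(lab) colSums(S[label_map == lab, , drop = FALSE]),
              numeric(ncol(S)))
  matrix(M, ncol = length(class_labels),
         dimnames = list(NULL, as.character(class_labels)))
}

#' Map clusters to class labels by majority vote
#'
#' Each training sample is hard-assigned to its maximal-membership cluster
#' (ties to the lowest cluster index); each cluster then takes the majority
#' label among its samples (ties to the lowest label). Clusters that attract
#' no sample inherit the globally most frequent label.
#'
#' @param partition `C x K` membership matrix from training.
#' @param labels Vector of training labels, one per sample.
#' @return Integer (or same-type) vector of length C: label of each cluster.
#' @export
map_clusters_to_labels <- function(partition, labels) {
  K <- ncol(partition)
  if (length(labels) != K)
    stop("need one label per training sample", call. = FALSE)
  ulab <- sort(unique(labels))
  if (length(ulab) < 2L)
    warning("training labels contain a single class; the map is degenerate")
  global_major <- ulab[which.max(vapply(ulab, function(l) sum(labels == l), 0L))]
  hard <- apply(partition, 2L, which.max)
  vapply(seq_len(nrow(partition)), function(cc) {
    members <- labels[hard == cc]
    if (!length(members)) return(global_major)
    votes <- vapply(ulab, function(l) sum(members == l), 0L)
    ulab[which.max(votes)]                     # ties resolve to lowest label
  }, labels[1L])
}

#' Fit a multiview FCM seizure classifier
#'
#' Unsupervised training followed by a supervised cluster-to-label map:
#' [mvfcm()] learns per-view centers and view weights from the training
#' features alone, then each cluster is labelled by majority vote over the
#' training labels. Prediction combines per-view memberships with the
#' learned view weights and returns the highest-scoring class.
#'
#' @inheritParams mvfcm
#' @param labels Vector of training labels aligned with the rows of `x`
#'   (for seizure detection, 0 = non-seizure, 1 = seizure).
#' @param scale Standardize every view on training statistics before
#'   clustering (default `TRUE`): the entropy-regularized view weights
#'   compare within-cluster scatter across views, which is only meaningful
#'   on a common scale. The stored transform is re-applied at prediction.
#' @param ... Further arguments passed to [mvfcm()].
#' @return An object of class `"mvfcm_classifier"`: the underlying `fit`,
#'   `centers`, `weights`, `label_map`, `class_labels` and configuration.
#' @examples
#' sim <- gen_multiview_gaussian(mv_gaussian_scenario(n_per_class = 30, seed = 1))
#' clf <- mvfcm_classifier(sim$dataset, sim$labels, seed = 1)
#' table(predict(clf, sim$dataset), sim$labels)
#' @export
mvfcm_classifier <- function(x, labels, centers = 2, scale = TRUE, ...) {
  x <- multiview_dataset(x)
  if (length(labels) != n_samples(x))
    stop("need one label per sample", call. = FALSE)
  fit <- mvfcm(x, centers = centers, scale = scale, ...)
  label_map <- map_clusters_to_labels(fit$membership, labels)
  structure(list(fit = fit,
                 centers = fit$centers,
                 weights = fit$weights,
                 config = fit$config,
                 label_map = label_map,
                 class_labels = sort(unique(labels))),
            class = "mvfcm_classifier")
}

#' @export
print.mvfcm_classifier <- function(x, ...) {
  cat("Multiview FCM classifier\n")
  cat("  cluster -> label map:", paste(x$label_map, collapse = " "), "\n")
  print(x$fit)
  invisible(x)
}

#' Predict class labels from a multiview FCM classifier
#'
#' @param object A fitted [mvfcm_classifier()].
#' @param newdata A [multiview_dataset] (or list of matrices) with matching
#'   view dimensions.
#' @param type `"class"` for labels, `"scores"` for the per-class
#'   view-weighted membership scores, `"both"` for a data frame with both.
#' @param ... Unused.
#' @return Labels, a score matrix, or a data frame, per `type`. Score ties
#'   resolve to the lowest class label.
#' @export
predict.mvfcm_classifier <- function(object, newdata,
                                     type = c("class", "scores", "both"),
                                     ...) {
  type <- match.arg(type)
  newdata <- multiview_dataset(newdata)
  if (!identical(unname(view_dims(newdata)), unname(object$fit$view_dims)))
    stop("'newdata' view dimensions do not match the fitted model",
         call. = FALSE)
  newdata <- apply_view_scaling(newdata, object$fit$scaling)
  pvu <- per_view_membership_batch(newdata, object$centers, object$config$m)
  S <- class_scores(pvu, object$weights, object$label_map,
                    object$class_labels)
  cls <- object$class_labels[apply(S, 1L, which.max)]   # ties -> lowest label
  switch(type,
         class = cls,
         scores = S,
         both = {
           ids <- attr(newdata, "sample_ids")
           df <- data.frame(sample_id = if (is.null(ids))
                              paste0("s", seq_len(nrow(S))) else ids,
                            predicted_label = cls)
           sc <- as.data.frame(S)
           names(sc) <- paste0("score_", colnames(S))
           cbind(df, sc)
         })
}

#' Save or load a trained multiview FCM classifier as JSON
#'
#' The model is serialized at full double precision (17 significant digits),
#' so a load/save round trip reproduces predictions bit-identically.
#'
#' @param model A fitted [mvfcm_classifier()].
#' @param path File path of the JSON document.
#' @return `write_mvfcm_model()` returns `path` invisibly;
#'   `read_mvfcm_model()` returns the reconstructed classifier.
#' @export
write_mvfcm_model <- function(model, path) {
  stopifnot(inherits(model, "mvfcm_classifier"))
  cfg <- model$config
  cfg$seed <- if (is.null(cfg$seed)) NA_integer_ else cfg$seed
  doc <- list(
    format = "mvfcm_classifier",
    version = 1L,
    config = cfg,
    centers = model$centers,
    weights = model$weights,
    label_map = model$label_map,
    class_labels = model$class_labels,
    scaling = model$fit$scaling,
    objective_trace = model$fit$objective_trace
  )
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_mvfcm_model
#' @export
read_mvfcm_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "mvfcm_classifier"))
    stop("not an mvfcm classifier model file", call. = FALSE)
  centers <- lapply(doc$centers, function(mm)
    do.call(rbind, lapply(mm, function(r) as.numeric(unlist(r)))))
  cfg <- lapply(doc$config, function(x) unlist(x))
  if (!is.null(cfg$seed) && is.na(cfg$seed)) cfg$seed <- NULL
  scaling <- if (is.null(doc$scaling)) NULL else
    lapply(doc$scaling, function(s) list(center = as.numeric(unlist(s$center)),
                                         scale = as.numeric(unlist(s$scale))))
  fit <- list(centers = centers,
              weights = as.numeric(unlist(doc$weights)),
              config = cfg,
              scaling = scaling,
              view_dims = vapply(centers, ncol, 0L),
              objective_trace = as.numeric(unlist(doc$objective_trace)))
  class(fit) <- "mvfcm"
  structure(list(fit = fit,
                 centers = centers,
                 weights = fit$weights,
                 config = cfg,
                 label_map = unlist(doc$label_map),
                 class_labels = unlist(doc$class_labels)),
            class = "mvfcm_classifier")
}
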