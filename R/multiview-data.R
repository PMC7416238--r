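#' Multiview dataset
#'
#' Bundle K samples observed through N feature views into a validated
#' container. View `i` is a numeric `K x n_i` matrix; all views share the
#' same rows (samples), but each view may have its own dimensionality.
#'
#' @param views A list of numeric matrices (or vectors, coerced to one-column
#'   matrices), one per view, each with the same number of rows.
#' @param sample_ids Optional character vector of length K identifying the
#'   rows. Defaults to the row names of the first view, if any.
#' @return An object of class `"multiview_dataset"`: the list of views with
#'   attributes `K` (samples), `N` (views) and `dims` (per-view widths).
#' @examples
#' d <- multiview_dataset(list(matrix(rnorm(20), 10), matrix(rnorm(30), 10)))
#' d
#' @export
multiview_dataset <- function(views, sample_ids = NULL) {
  if (inherits(views, "multiview_dataset")) return(views)
  if (!is.list(views) || length(views) < 1L)
    stop("'views' must be a non-empty list of numeric matrices", call. = FALSE)
  views <- lapply(views, function(v) {
    if (is.vector(v) && is.numeric(v)) v <- matrix(v, ncol = 1L)
    if (!is.matrix(v) || !is.numeric(v))
      stop("each view must be a numeric matrix", call. = FALSE)
    storage.mode(v) <- "double"
    v
  })
  K <- nrow(views[[1L]])
  if (K < 1L) stop("views must contain at least one sample", call. = FALSE)
  if (!all(vapply(views, nrow, 0L) == K))
    stop("all views must have the same number of rows (samples)", call. = FALSE)
  if (any(vapply(views, ncol, 0L) < 1L))
    stop("every view needs at least one feature column", call. = FALSE)
  for (i in seq_along(views))
    if (!all(is.finite(views[[i]])))
      stop(sprintf("view %d contains non-finite values", i), call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- rownames(views[[1L]])
  if (!is.null(sample_ids)) {
    sample_ids <- as.character(sample_ids)
    if (length(sample_ids) != K)
      stop("'sample_ids' length must equal the number of samples", call. = FALSE)
  }
  structure(views,
            class = "multiview_dataset",
            K = K, N = length(views),
            dims = vapply(views, ncol, 0L),
            sample_ids = sample_ids)
}

#' @export
print.multiview_dataset <- function(x, ...) {
  cat(sprintf("Multiview dataset: %d samples, %d view%s (dims: %s)\n",
              attr(x, "K"), attr(x, "N"),
              if (attr(x, "N") == 1L) "" else "s",
              paste(attr(x, "dims"), collapse = ", ")))
  invisible(x)
}

#' @export
dim.multiview_dataset <- function(x) c(attr(x, "K"), attr(x, "N"))

n_samples <- function(x) attr(x, "K")
n_views   <- function(x) attr(x, "N")
view_dims <- function(x) attr(x, "dims")

## Subset samples (rows) across all views, keeping ids aligned.
subset_samples <- function(x, idx) {
  x <- multiview_dataset(x)
  ids <- attr(x, "sample_ids")
  multiview_dataset(lapply(unclass(x), function(v) v[idx, , drop = FALSE]),
                    sample_ids = if (!is.null(ids)) ids[idx])
}

#' Read and write multiview feature tables
#'
#' One delimited text table per view: samples as rows, a header row of
#' feature names, and an optional leading `sample_id` column. Labels live in
#' a separate two-column CSV (`sample_id,label`, label 0 = non-seizure,
#' 1 = seizure).
#'
#' @param paths Character vector of file paths, one per view, in view order.
#' @param sep Field separator, default comma.
#' @return `read_views()` returns a [multiview_dataset]; `read_labels()`
#'   returns an integer vector named by sample id.
#' @export
read_views <- function(paths, sep = ",") {
  tabs <- lapply(paths, utils::read.csv, sep = sep, check.names = FALSE)
  ids <- NULL
  views <- lapply(tabs, function(tb) {
    if (names(tb)[1L] == "sample_id") {
      ids <<- as.character(tb[[1L]])
      tb <- tb[-1L]
    }
    as.matrix(tb)
  })
  multiview_dataset(views, sample_ids = ids)
}

#' @rdname read_views
#' @param dataset A [multiview_dataset].
#' @param labels Optional labels to write alongside (`write_labels`).
#' @export
write_views <- function(dataset, paths) {
  dataset <- multiview_dataset(dataset)
  stopifnot(length(paths) == n_views(dataset))
  ids <- attr(dataset, "sample_ids")
  for (i in seq_len(n_views(dataset))) {
    v <- dataset[[i]]
    if (is.null(colnames(v)))
      colnames(v) <- paste0("f", seq_len(ncol(v)))
    df <- as.data.frame(v)
    if (!is.null(ids)) df <- cbind(sample_id = ids, df)
    utils::write.csv(df, paths[i], row.names = FALSE)
  }
  invisible(paths)
}

#' @rdname read_views
#' @param path Path of the labels CSV.
#' @param sample_ids Optional ids written alongside the labels (defaults to
#'   the names of `labels`, then to `s1, s2, ...`).
#' @export
read_labels <- function(path) {
  tb <- utils::read.csv(path)
  if (!all(c("sample_id", "label") %in% names(tb)))
    stop("labels file must have columns 'sample_id' and 'label'", call. = FALSE)
  lab <- as.integer(tb$label)
  if (!all(lab %in% c(0L, 1L)))
    stop("labels must be 0 (non-seizure) or 1 (seizure)", call. = FALSE)
  names(lab) <- as.character(tb$sample_id)
  lab
}

#' @rdname read_views
#' @export
write_labels <- function(labels, path, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- names(labels)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(labels))
  }
  utils::write.csv(data.frame(sample_id = sample_ids,
                              label = as.integer(labels)),
                   path, row.names = FALSE)
  invisible(path)
}
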