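## Closed-form coordinate updates of the entropy-regularized multiview
## fuzzy c-means objective
##
##   P(U, O, W) = sum_i w_i sum_c sum_mu u_cmu^m ||x_mu^(i) - o_c^(i)||^2
##                + T_w sum_i w_i log w_i
##
## subject to column-stochastic memberships U (C x K) and simplex view
## weights W (length N). Each update below is the exact minimizer of P in
## its own block with the others held fixed, so alternating them can never
## increase P.

#' Per-view squared Euclidean distances
#'
#' For every view, the `C x K` matrix of squared Euclidean distances between
#' each cluster center and each sample in that view's feature space.
#'
#' @param dataset A [multiview_dataset] (or list of `K x n_i` matrices).
#' @param centers A list of `C x n_i` center matrices, one per view.
#' @return A list of `C x K` nonnegative matrices, one per view.
#' @export
pairwise_sq_distances <- function(dataset, centers) {
  dataset <- multiview_dataset(dataset)
  check_centers(dataset, centers)
  lapply(seq_len(n_views(dataset)), function(i) {
    X <- dataset[[i]]                       # K x n
    O <- centers[[i]]                       # C x n
    tX <- t(X)
    D <- matrix(0, nrow(O), nrow(X))
    for (cc in seq_len(nrow(O)))            # direct form: no cancellation
      D[cc, ] <- colSums((tX - O[cc, ])^2)
    D
  })
}

check_centers <- function(dataset, centers) {
  if (!is.list(centers) || length(centers) != n_views(dataset))
    stop("'centers' must be a list with one matrix per view", call. = FALSE)
  C <- nrow(centers[[1L]])
  for (i in seq_along(centers)) {
    if (!is.matrix(centers[[i]]) || nrow(centers[[i]]) != C)
      stop("all center matrices must have the same number of rows", call. = FALSE)
    if (ncol(centers[[i]]) != view_dims(dataset)[i])
      stop(sprintf("view %d: center dimension %d does not match data dimension %d",
                   i, ncol(centers[[i]]), view_dims(dataset)[i]), call. = FALSE)
    if (!all(is.finite(centers[[i]])))
      stop(sprintf("view %d centers contain non-finite values", i), call. = FALSE)
  }
  invisible(TRUE)
}

check_partition <- function(U, K, tol = 1e-9) {
  if (!is.matrix(U) || ncol(U) != K)
    stop("membership matrix must be C x K", call. = FALSE)
  if (any(U < -tol) || any(U > 1 + tol))
    stop("memberships must lie in [0, 1]", call. = FALSE)
  if (any(abs(colSums(U) - 1) > tol))
    stop("membership columns must sum to 1", call. = FALSE)
  invisible(TRUE)
}

check_weights <- function(w, N, tol = 1e-9) {
  if (length(w) != N || any(!is.finite(w)))
    stop("weights must be a finite vector of length N", call. = FALSE)
  if (any(w <= 0) || abs(sum(w) - 1) > tol)
    stop("weights must be strictly positive and sum to 1", call. = FALSE)
  invisible(TRUE)
}

#' Update cluster centers
#'
#' Membership-weighted means, computed independently per view and
#' coordinate: `o_cp = sum_mu u_cmu^m x_mup / sum_mu u_cmu^m`. A cluster
#' whose total fuzzified membership underflows (below 1e-12) is re-seeded
#' from a randomly drawn sample rather than producing NaN centers.
#'
#' @param dataset A [multiview_dataset].
#' @param partition `C x K` membership matrix with columns summing to 1.
#' @param m Fuzzifier, must exceed 1.
#' @return A list of `C x n_i` center matrices.
#' @export
update_centers <- function(dataset, partition, m) {
  dataset <- multiview_dataset(dataset)
  check_fuzzifier(m)
  check_partition(partition, n_samples(dataset))
  Um <- partition^m
  denom <- rowSums(Um)
  empty <- which(denom < 1e-12)
  centers <- lapply(unclass(dataset), function(X) (Um %*% X) / denom)
  if (length(empty)) {
    reseed <- sample.int(n_samples(dataset), length(empty), replace = TRUE)
    for (i in seq_along(centers))
      centers[[i]][empty, ] <- dataset[[i]][reseed, , drop = FALSE]
  }
  centers
}

check_fuzzifier <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 1 + 1e-6)
    stop("fuzzifier 'm' must be a single number > 1", call. = FALSE)
  invisible(TRUE)
}

## Shared membership columns from an aggregated C x K distance matrix.
## Computed in log space: u_c = softmax_c( -log(A_c) / (m - 1) ), which is
## algebraically the classical ratio form but immune to under/overflow.
## Columns containing exact zeros follow the analytic limit: membership is
## split uniformly over the zero-distance clusters.
memberships_from_distances <- function(A, m) {
  C <- nrow(A); K <- ncol(A)
  U <- matrix(0, C, K)
  zero_col <- colSums(A == 0) > 0L
  if (any(!zero_col)) {
    L <- -log(A[, !zero_col, drop = FALSE]) / (m - 1)
    L <- sweep(L, 2L, apply(L, 2L, max))
    E <- exp(L)
    U[, !zero_col] <- sweep(E, 2L, colSums(E), "/")
  }
  if (any(zero_col)) {
    Z <- A[, zero_col, drop = FALSE] == 0
    U[, zero_col] <- sweep(Z + 0, 2L, colSums(Z), "/")
  }
  U
}

#' Update the shared fuzzy partition
#'
#' Memberships from view-weight-aggregated squared distances: with
#' `A_cmu = sum_i w_i ||x_mu^(i) - o_c^(i)||^2`, the minimizing column is
#' `u_cmu = [ sum_e (A_cmu / A_emu)^{1/(m-1)} ]^{-1}`. Samples at zero
#' aggregated distance from one or more centers take the analytic limit:
#' membership uniform over exactly those clusters.
#'
#' @inheritParams update_centers
#' @param centers List of per-view `C x n_i` center matrices.
#' @param weights Simplex vector of view weights.
#' @return `C x K` membership matrix; every column sums to 1.
#' @export
update_memberships <- function(dataset, centers, weights, m) {
  dataset <- multiview_dataset(dataset)
  check_fuzzifier(m)
  check_weights(weights, n_views(dataset))
  dists <- pairwise_sq_distances(dataset, centers)
  A <- Reduce(`+`, Map(`*`, as.list(weights), dists))
  memberships_from_distances(A, m)
}

#' Per-view dispersions
#'
#' `D_l = sum_c sum_mu u_cmu^m ||x_mu^(l) - o_c^(l)||^2`: the fuzzified
#' within-cluster scatter of view `l`. Small dispersion marks a view in
#' which the current partition is compact, i.e. an informative view.
#'
#' @inheritParams update_memberships
#' @param partition `C x K` membership matrix.
#' @return Nonnegative numeric vector of length N.
#' @export
compute_dispersions <- function(dataset, partition, centers, m) {
  dataset <- multiview_dataset(dataset)
  check_fuzzifier(m)
  check_partition(partition, n_samples(dataset))
  dists <- pairwise_sq_distances(dataset, centers)
  Um <- partition^m
  vapply(dists, function(D) sum(Um * D), 0)
}

#' Update view weights
#'
#' Entropy-regularized softmax of negative dispersion,
#' `w_i = exp(-D_i / T_w) / sum_l exp(-D_l / T_w)`, evaluated with the
#' max-shift trick so arbitrarily large dispersions cannot overflow.
#' Lower dispersion (a tighter view) always earns a larger weight; the
#' temperature controls how sharply the weights concentrate.
#'
#' @param dispersions Nonnegative numeric vector of per-view dispersions.
#' @param temperature Positive regularization temperature `T_w`.
#' @return Simplex vector of strictly positive view weights.
#' @export
update_weights <- function(dispersions, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("'temperature' must be a single positive number", call. = FALSE)
  if (any(!is.finite(dispersions)) || any(dispersions < 0))
    stop("dispersions must be finite and nonnegative", call. = FALSE)
  z <- -dispersions / temperature
  e <- exp(z - max(z))
  w <- e / sum(e)
  # the softmax is strictly positive analytically; keep it so numerically
  w <- pmax(w, 1e-300)
  w / sum(w)
}

#' Multiview fuzzy c-means objective
#'
#' The weighted fuzzified scatter plus the weight-entropy penalty:
#' `P = sum_i w_i D_i + T_w sum_i w_i log w_i`. The first term is
#' nonnegative; the entropy term lies in `[-T_w log N, 0]`, minimized at
#' uniform weights.
#'
#' @inheritParams compute_dispersions
#' @inheritParams update_weights
#' @param weights Strictly positive simplex vector of view weights.
#' @param m Fuzzifier (> 1).
#' @return A single finite number.
#' @export
mvfcm_objective <- function(dataset, partition, centers, weights, m,
                            temperature) {
  dataset <- multiview_dataset(dataset)
  if (any(weights <= 0))
    stop("all view weights must be strictly positive", call. = FALSE)
  D <- compute_dispersions(dataset, partition, centers, m)
  sum(weights * D) + temperature * sum(weights * log(weights))
}
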