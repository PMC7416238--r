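#' Fit entropy-regularized multiview fuzzy c-means
#'
#' Alternating optimization of the multiview FCM objective: one shared fuzzy
#' partition over all views, per-view cluster centers, and a simplex of view
#' weights set by an entropy-regularized softmax of the per-view dispersions.
#' Views whose clusters are compact receive large weights; uninformative
#' (high-dispersion) views are down-weighted automatically.
#'
#' Each sweep performs, in order: center update, membership update,
#' dispersion computation, weight update, objective evaluation. Every step
#' is the exact coordinate-wise minimizer, so the objective trace is
#' non-increasing; iteration stops when the absolute objective change drops
#' below `tol` or after `max_iter` sweeps.
#'
#' @param x A [multiview_dataset] or a list of `K x n_i` numeric matrices
#'   (one per view, shared rows).
#' @param centers Number of clusters C (>= 2), or a list of per-view initial
#'   center matrices (implies `init = "given"`).
#' @param m Fuzzifier, > 1. Values near 1 give nearly crisp partitions;
#'   large values flatten the memberships. Default 2.
#' @param temperature Weight-entropy temperature `T_w` > 0. Large values pull
#'   the view weights toward uniform; small values concentrate weight on the
#'   lowest-dispersion view. Default 1.
#' @param max_iter Maximum number of alternation sweeps. Default 300.
#' @param tol Stop when the objective changes by less than this. Default 1e-6.
#' @param nstart Number of random restarts; the fit with the lowest final
#'   objective is kept. Default 1.
#' @param init Initialization: `"random_membership"` draws each membership
#'   column from a flat Dirichlet; `"sample_centers"` picks C distinct samples
#'   as initial centers. Ignored when `centers` is a list.
#' @param scale If `TRUE`, z-score every feature column per view before
#'   clustering (the transform is stored and re-applied to new data by
#'   `predict`). Dispersion-based view weighting compares views by their
#'   within-cluster scatter, so views on arbitrary scales should be
#'   standardized for the weights to reflect informativeness rather than
#'   units. Default `FALSE`: the objective is optimized on the features as
#'   given.
#' @param seed Optional integer seed making the fit (and restarts) fully
#'   reproducible; the caller's RNG state is restored on exit.
#' @return An object of class `"mvfcm"` with components `membership`
#'   (`C x K`), `centers` (per-view list), `weights`, `cluster` (hard
#'   assignment by maximal membership, ties to the lowest index),
#'   `objective`, `objective_trace`, `diagnostics` (per-iteration constraint
#'   deviations), `n_iter`, `converged`, and the call/configuration.
#' @seealso [update_centers()], [update_memberships()], [update_weights()],
#'   [compute_dispersions()], [mvfcm_objective()], [mvfcm_classifier()]
#' @examples
#' sim <- gen_multiview_gaussian(mv_gaussian_scenario(n_per_class = 30, seed = 1))
#' fit <- mvfcm(sim$dataset, centers = 2, seed = 1)
#' fit
#' fit$weights
#' @export
mvfcm <- function(x, centers = 2, m = 2, temperature = 1,
                  max_iter = 300L, tol = 1e-6, nstart = 1L,
                  init = c("random_membership", "sample_centers"),
                  scale = FALSE, seed = NULL) {
  cl <- match.call()
  x <- multiview_dataset(x)
  scaling <- NULL
  if (isTRUE(scale)) {
    scaling <- lapply(unclass(x), function(v)
      list(center = colMeans(v),
           scale = pmax(apply(v, 2L, stats::sd), 1e-12)))
    x <- apply_view_scaling(x, scaling)
  }
  check_fuzzifier(m)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("'temperature' must be positive", call. = FALSE)
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be positive", call. = FALSE)
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("'max_iter' must be at least 1", call. = FALSE)

  given_centers <- NULL
  if (is.list(centers)) {
    given_centers <- centers
    check_centers(x, given_centers)
    C <- nrow(given_centers[[1L]])
    init <- "given"
  } else {
    C <- as.integer(centers)
    if (C < 2L) stop("'centers' must be at least 2", call. = FALSE)
    init <- match.arg(init)
  }
  K <- n_samples(x)
  if (K < C)
    stop(sprintf("need at least as many samples (%d) as clusters (%d)", K, C),
         call. = FALSE)

  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(restore_rng(old_seed), add = TRUE)
    set.seed(as.integer(seed))
  }

  best <- NULL
  for (r in seq_len(max(1L, as.integer(nstart)))) {
    res <- mvfcm_once(x, C, m, temperature, max_iter, tol, init, given_centers)
    if (is.null(best) || res$objective < best$objective) best <- res
  }

  best$call <- cl
  best$scaling <- scaling
  best$config <- list(n_clusters = C, m = m, temperature = temperature,
                      max_iter = max_iter, tol = tol, nstart = nstart,
                      init = init, scale = isTRUE(scale), seed = seed)
  best$view_dims <- view_dims(x)
  best$K <- K
  class(best) <- "mvfcm"
  best
}

## Apply stored per-view z-scoring (no-op when scaling is NULL).
apply_view_scaling <- function(x, scaling) {
  if (is.null(scaling)) return(x)
  x <- multiview_dataset(x)
  multiview_dataset(lapply(seq_along(scaling), function(i)
    sweep(sweep(x[[i]], 2L, scaling[[i]]$center), 2L,
          scaling[[i]]$scale, "/")),
    sample_ids = attr(x, "sample_ids"))
}

restore_rng <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old_seed, envir = globalenv())
}

## One alternating-optimization run from a fresh initialization.
mvfcm_once <- function(x, C, m, temperature, max_iter, tol, init,
                       given_centers) {
  K <- n_samples(x); N <- n_views(x)
  W <- rep(1 / N, N)
  if (init == "random_membership") {
    G <- matrix(stats::rexp(C * K), C, K)     # flat Dirichlet columns
    U <- sweep(G, 2L, colSums(G), "/")
  } else {
    O0 <- if (init == "given") given_centers else {
      idx <- sample.int(K, C)
      lapply(unclass(x), function(V) V[idx, , drop = FALSE])
    }
    U <- update_memberships(x, O0, W, m)
  }

  trace <- numeric(0)
  diag_col <- numeric(0); diag_w <- numeric(0)
  converged <- FALSE
  P_prev <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    O <- update_centers(x, U, m)
    U <- update_memberships(x, O, W, m)
    D <- compute_dispersions(x, U, O, m)
    W <- update_weights(D, temperature)
    P <- sum(W * D) + temperature * sum(W * log(W))
    trace <- c(trace, P)
    diag_col <- c(diag_col, max(abs(colSums(U) - 1)))
    diag_w <- c(diag_w, abs(sum(W) - 1))
    if (is.finite(P_prev) && abs(P_prev - P) < tol) { converged <- TRUE; break }
    P_prev <- P
  }

  hard <- apply(U, 2L, which.max)             # which.max breaks ties low
  list(membership = U, centers = O, weights = W,
       dispersions = D, cluster = hard,
       objective = P, objective_trace = trace,
       diagnostics = data.frame(iter = seq_along(trace),
                                objective = trace,
                                max_membership_col_dev = diag_col,
                                weight_sum_dev = diag_w),
       n_iter = iter, converged = converged)
}

#' @export
print.mvfcm <- function(x, ...) {
  cat("Entropy-regularized multiview fuzzy c-means\n")
  cat(sprintf("  %d samples, %d view%s, %d clusters (m = %g, T_w = %g)\n",
              x$K, length(x$weights),
              if (length(x$weights) == 1L) "" else "s",
              x$config$n_clusters, x$config$m, x$config$temperature))
  cat(sprintf("  objective %.6g after %d iteration%s (%sconverged)\n",
              x$objective, x$n_iter, if (x$n_iter == 1L) "" else "s",
              if (x$converged) "" else "not "))
  cat("  view weights:", paste(signif(x$weights, 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.mvfcm <- function(object, ...) {
  structure(list(fit = object,
                 cluster_sizes = tabulate(object$cluster,
                                          object$config$n_clusters),
                 mean_max_membership = mean(apply(object$membership, 2L, max))),
            class = "summary.mvfcm")
}

#' @export
print.summary.mvfcm <- function(x, ...) {
  print(x$fit)
  cat("  hard cluster sizes:", paste(x$cluster_sizes, collapse = " "), "\n")
  cat(sprintf("  mean maximal membership: %.3f\n", x$mean_max_membership))
  cat(sprintf("  per-view dispersions: %s\n",
              paste(signif(x$fit$dispersions, 4), collapse = " ")))
  invisible(x)
}

#' @export
coef.mvfcm <- function(object, ...) object$centers

#' @export
fitted.mvfcm <- function(object, ...) t(object$membership)

#' Membership of new samples under a fitted multiview partition
#'
#' Computes the shared (view-weight-aggregated) memberships of new samples
#' with respect to the fitted centers and weights, plus the hard assignment.
#'
#' @param object A fitted [mvfcm] object.
#' @param newdata A [multiview_dataset] (or list of matrices) with the same
#'   view dimensions as the training data.
#' @param ... Unused.
#' @return A list with `membership` (`K_new x C`) and `cluster` (argmax,
#'   ties to the lowest index).
#' @export
predict.mvfcm <- function(object, newdata, ...) {
  newdata <- multiview_dataset(newdata)
  if (!identical(unname(view_dims(newdata)), unname(object$view_dims)))
    stop("'newdata' view dimensions do not match the fitted model",
         call. = FALSE)
  newdata <- apply_view_scaling(newdata, object$scaling)
  U <- update_memberships(newdata, object$centers, object$weights,
                          object$config$m)
  list(membership = t(U), cluster = apply(U, 2L, which.max))
}

#' Plot the objective trace of a multiview FCM fit
#'
#' @param x A fitted [mvfcm] object.
#' @param ... Passed to [plot.default()].
#' @export
plot.mvfcm <- function(x, ...) {
  plot(seq_along(x$objective_trace), x$objective_trace, type = "b",
       xlab = "iteration", ylab = "objective",
       main = "Multiview FCM objective trace", ...)
  invisible(x)
}
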