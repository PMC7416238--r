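# Naive nested-loop oracles for the closed-form updates, kept deliberately
# independent of the package's vectorized implementations.

oracle_distances <- function(views, centers) {
  lapply(seq_along(views), function(i) {
    X <- views[[i]]; O <- centers[[i]]
    D <- matrix(0, nrow(O), nrow(X))
    for (cc in seq_len(nrow(O)))
      for (mu in seq_len(nrow(X)))
        for (p in seq_len(ncol(X)))
          D[cc, mu] <- D[cc, mu] + (X[mu, p] - O[cc, p])^2
    D
  })
}

oracle_centers <- function(views, U, m) {
  C <- nrow(U); K <- ncol(U)
  lapply(views, function(X) {
    O <- matrix(0, C, ncol(X))
    for (cc in seq_len(C)) {
      den <- 0
      for (mu in seq_len(K)) den <- den + U[cc, mu]^m
      for (p in seq_len(ncol(X))) {
        num <- 0
        for (mu in seq_len(K)) num <- num + U[cc, mu]^m * X[mu, p]
        O[cc, p] <- num / den
      }
    }
    O
  })
}

oracle_memberships <- function(views, centers, weights, m) {
  d <- oracle_distances(views, centers)
  C <- nrow(centers[[1L]]); K <- nrow(views[[1L]])
  A <- matrix(0, C, K)
  for (i in seq_along(views)) A <- A + weights[i] * d[[i]]
  U <- matrix(0, C, K)
  for (mu in seq_len(K)) {
    for (cc in seq_len(C)) {
      s <- 0
      for (ee in seq_len(C)) s <- s + (A[cc, mu] / A[ee, mu])^(1 / (m - 1))
      U[cc, mu] <- 1 / s
    }
  }
  U
}

oracle_dispersions <- function(views, U, centers, m) {
  d <- oracle_distances(views, centers)
  vapply(seq_along(views), function(l) {
    tot <- 0
    for (cc in seq_len(nrow(U)))
      for (mu in seq_len(ncol(U)))
        tot <- tot + U[cc, mu]^m * d[[l]][cc, mu]
    tot
  }, 0)
}

oracle_weights <- function(D, Tw) {
  e <- exp(-D / Tw)
  e / sum(e)
}

oracle_objective <- function(views, U, centers, weights, m, Tw) {
  D <- oracle_dispersions(views, U, centers, m)
  sum(weights * D) + Tw * sum(weights * log(weights))
}

# A random small instance with a valid partition, weights and centers.
rand_instance <- function(seed, K = NULL, N = NULL, C = NULL) {
  set.seed(seed)
  if (is.null(K)) K <- sample(4:12, 1)
  if (is.null(N)) N <- sample(1:3, 1)
  if (is.null(C)) C <- sample(2:3, 1)
  dims <- sample(1:4, N, replace = TRUE)
  views <- lapply(dims, function(p) matrix(rnorm(K * p), K, p))
  G <- matrix(rexp(C * K), C, K)
  U <- sweep(G, 2, colSums(G), "/")
  w <- rexp(N); w <- w / sum(w)
  centers <- lapply(dims, function(p) matrix(rnorm(C * p), C, p))
  list(views = views, U = U, weights = w, centers = centers,
       K = K, N = N, C = C, m = runif(1, 1.3, 3), Tw = runif(1, 0.5, 3))
}

# Exhaustive grid minimizer for the small fixture: every membership column
# walks a discretized 2-cluster simplex; at each grid point the centers and
# weights take their closed forms given U and the objective is evaluated
# directly. Independent of the package's alternating optimizer: no
# iteration, just a dense scan of the partition space.
brute_force_min_objective <- function(fixture, m, Tw, step = 0.125) {
  views <- unclass(fixture$dataset)
  tviews <- lapply(views, t)
  K <- fixture$K
  grid <- seq(0, 1, by = step)
  nG <- length(grid)
  idx <- rep(1L, K)
  best <- Inf
  repeat {
    u1 <- grid[idx]
    Um <- rbind(u1^m, (1 - u1)^m)
    den <- rowSums(Um)
    if (any(den < 1e-12)) den <- NULL       # empty cluster: no valid centers
    D <- if (is.null(den)) NULL else vapply(seq_along(views), function(i) {
      O <- (Um %*% views[[i]]) / den
      d1 <- colSums((tviews[[i]] - O[1L, ])^2)
      d2 <- colSums((tviews[[i]] - O[2L, ])^2)
      sum(Um[1L, ] * d1 + Um[2L, ] * d2)
    }, 0)
    if (!is.null(D)) {
      e <- exp(-D / Tw); W <- e / sum(e)
      P <- sum(W * D) + Tw * sum(W * log(W))
      if (P < best) best <- P
    }
    d <- 1L
    while (d <= K && idx[d] == nG) { idx[d] <- 1L; d <- d + 1L }
    if (d > K) break
    idx[d] <- idx[d] + 1L
  }
  best
}
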