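test_that("pairwise squared distances match geometry and the loop oracle", {
  d <- multiview_dataset(list(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)))
  ctr <- list(matrix(c(0, 0), 1))
  D <- pairwise_sq_distances(d, ctr)
  expect_equal(D[[1]][1, 1], 0)        # coincident point
  expect_equal(D[[1]][1, 2], 25)       # 3-4-5 triangle, squared

  inst <- rand_instance(101, N = 2)
  got <- pairwise_sq_distances(multiview_dataset(inst$views), inst$centers)
  want <- oracle_distances(inst$views, inst$centers)
  for (i in seq_along(got)) expect_equal(got[[i]], want[[i]], tolerance = 1e-12)
  expect_true(all(vapply(got, function(M) all(M >= 0), TRUE)))

  bad <- list(matrix(0, 1, 3))
  expect_error(pairwise_sq_distances(d, bad), "dimension")
})

test_that("center update equals fuzzified means and the loop oracle", {
  X <- matrix(rnorm(12), 4, 3)
  d <- multiview_dataset(list(X))
  # C = 1, all memberships 1: per-coordinate mean
  O <- update_centers(d, matrix(1, 1, 4), m = 2)
  expect_equal(drop(O[[1]]), colMeans(X))
  # crisp memberships: within-cluster means regardless of m
  U <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  for (m in c(1.5, 2, 3)) {
    Oc <- update_centers(d, U, m)
    expect_equal(Oc[[1]][1, ], colMeans(X[1:2, ]))
    expect_equal(Oc[[1]][2, ], colMeans(X[3:4, ]))
  }
  # hand-set soft partition vs the loop oracle
  set.seed(7)
  views <- list(matrix(rnorm(8), 4, 2), matrix(rnorm(4), 4, 1))
  U <- rbind(c(0.7, 0.2, 0.9, 0.4), c(0.3, 0.8, 0.1, 0.6))
  got <- update_centers(multiview_dataset(views), U, m = 2)
  want <- oracle_centers(views, U, m = 2)
  for (i in 1:2) expect_equal(got[[i]], want[[i]], tolerance = 1e-12)
})

test_that("membership update matches the closed ratio form", {
  # aggregated distances (1, 4), m = 2 -> (0.8, 0.2)
  u <- mvfcm:::memberships_from_distances(matrix(c(1, 4), 2, 1), m = 2)
  expect_equal(drop(u), c(0.8, 0.2))
  # symmetric distances -> (0.5, 0.5)
  u <- mvfcm:::memberships_from_distances(matrix(c(3, 3), 2, 1), m = 2)
  expect_equal(drop(u), c(0.5, 0.5))
  # zero distance to a unique center -> hard assignment
  u <- mvfcm:::memberships_from_distances(matrix(c(0, 2, 5), 3, 1), m = 2)
  expect_equal(drop(u), c(1, 0, 0))
  # zero distance to two centers -> split between exactly those
  u <- mvfcm:::memberships_from_distances(matrix(c(0, 0, 5), 3, 1), m = 2)
  expect_equal(drop(u), c(0.5, 0.5, 0))

  for (seed in 1:20) {
    inst <- rand_instance(seed)
    got <- update_memberships(multiview_dataset(inst$views), inst$centers,
                              inst$weights, inst$m)
    want <- oracle_memberships(inst$views, inst$centers, inst$weights, inst$m)
    expect_equal(got, want, tolerance = 1e-10)
    expect_equal(colSums(got), rep(1, inst$K), tolerance = 1e-12)
  }
})

test_that("memberships survive extreme distance scales via log-space", {
  A <- matrix(c(1e-310, 4e-310, 2e300, 8e300), 2, 2)
  u <- mvfcm:::memberships_from_distances(A, m = 2)
  expect_equal(u[, 1], c(0.8, 0.2))
  expect_equal(u[, 2], c(0.8, 0.2))
})

test_that("dispersions match the loop oracle and degenerate cases", {
  # all samples at their crisp centers -> zero dispersion in every view
  X <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  dat <- multiview_dataset(list(X[c(1, 2, 2), ], 3 * X[c(1, 2, 2), ]))
  U <- rbind(c(1, 0, 0), c(0, 1, 1))
  ctr <- list(X, 3 * X)
  expect_equal(compute_dispersions(dat, U, ctr, 2), c(0, 0))
  # duplicated view gives identical dispersion
  inst <- rand_instance(55, N = 1)
  dd <- multiview_dataset(list(inst$views[[1]], inst$views[[1]]))
  ctr <- list(inst$centers[[1]], inst$centers[[1]])
  D <- compute_dispersions(dd, inst$U, ctr, inst$m)
  expect_equal(D[1], D[2])
  # loop oracle on random instances
  for (seed in 21:35) {
    inst <- rand_instance(seed)
    got <- compute_dispersions(multiview_dataset(inst$views), inst$U,
                               inst$centers, inst$m)
    want <- oracle_dispersions(inst$views, inst$U, inst$centers, inst$m)
    expect_equal(got, want, tolerance = 1e-10)
    expect_true(all(got >= 0))
  }
})

test_that("weight update is the entropy-regularized softmax", {
  expect_equal(update_weights(c(2, 2, 2), 1), rep(1 / 3, 3))
  expect_equal(update_weights(5, 2), 1)
  w <- update_weights(c(1, 2), 1)
  expect_equal(w, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))))
  expect_equal(w[1], 0.73106, tolerance = 1e-5)
  # overflow safety: huge dispersions
  w <- update_weights(c(1e6, 2e6), temperature = 1)
  expect_equal(w, c(1, 0))
  expect_equal(sum(w), 1)
  # monotone: lower dispersion, higher weight
  for (seed in 36:45) {
    set.seed(seed)
    D <- sort(rexp(4, 0.1)); Tw <- runif(1, 0.5, 5)
    got <- update_weights(D, Tw)
    expect_equal(got, oracle_weights(D, Tw), tolerance = 1e-10)
    expect_true(all(diff(got) < 0))
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
})

test_that("objective combines weighted dispersion and weight entropy", {
  # samples at crisp centers, uniform weights -> P = -Tw log N
  X <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  d <- multiview_dataset(list(X, 2 * X))
  U <- diag(2)
  O <- list(X, 2 * X)
  expect_equal(mvfcm_objective(d, U, O, c(0.5, 0.5), 2, temperature = 3),
               -3 * log(2))
  # single view: classical FCM objective, entropy term vanishes
  inst <- rand_instance(77, N = 1)
  P <- mvfcm_objective(multiview_dataset(inst$views), inst$U, inst$centers,
                       1, inst$m, inst$Tw)
  expect_equal(P, oracle_dispersions(inst$views, inst$U, inst$centers,
                                     inst$m))
  # loop-oracle agreement on random instances
  for (seed in 46:55) {
    inst <- rand_instance(seed)
    got <- mvfcm_objective(multiview_dataset(inst$views), inst$U,
                           inst$centers, inst$weights, inst$m, inst$Tw)
    want <- oracle_objective(inst$views, inst$U, inst$centers, inst$weights,
                             inst$m, inst$Tw)
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(mvfcm_objective(multiview_dataset(inst$views), inst$U,
                               inst$centers, c(0, 1), inst$m, inst$Tw),
               "positive")
})
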