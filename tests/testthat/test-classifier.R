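make_crisp_instance <- function() {
  # two tight, distant clusters seen in two views
  v1 <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 8, 0.1), 10))
  v2 <- rbind(matrix(rnorm(10, -3, 0.1), 10), matrix(rnorm(10, 3, 0.1), 10))
  list(dataset = multiview_dataset(list(v1, v2)),
       labels = rep(c(0L, 1L), each = 10))
}

test_that("per-view memberships follow the ratio form per view", {
  ctr <- list(rbind(c(0, 0), c(2, 0)), rbind(c(0, 1), c(0, -1)))
  # equidistant in a view -> uniform row
  u <- per_view_membership(list(c(1, 5), c(9, 0)), ctr, m = 2)
  expect_equal(u[1, ], c(0.5, 0.5))
  expect_equal(u[2, ], c(0.5, 0.5))
  expect_equal(rowSums(u), c(1, 1))
  # at a center in every view -> hard membership everywhere
  u <- per_view_membership(list(c(2, 0), c(0, -1)), ctr, m = 2)
  expect_equal(u[1, ], c(0, 1))
  expect_equal(u[2, ], c(0, 1))
  # one view, distances (1, 4), m = 2 -> (0.8, 0.2)
  u <- per_view_membership(list(c(1, 0)), list(rbind(c(0, 0), c(3, 0))), 2)
  expect_equal(drop(u), c(0.8, 0.2))
  expect_error(per_view_membership(list(c(1, 2, 3)), list(ctr[[1]]), m = 2),
               "features")
})

test_that("class scores combine views by weight and pool clusters by label", {
  pv <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  s <- class_scores(pv, c(0.7, 0.3), label_map = c(0L, 1L))
  expect_equal(unname(s), c(0.69, 0.31))
  expect_equal(sum(s), 1)
  # single view: scores are that view's memberships
  expect_equal(unname(class_scores(pv[1, , drop = FALSE], 1, c(0L, 1L))),
               c(0.9, 0.1))
  # identical rows: any convex combination returns the row
  pv2 <- rbind(c(0.6, 0.4), c(0.6, 0.4))
  for (w1 in c(0.1, 0.5, 0.9))
    expect_equal(unname(class_scores(pv2, c(w1, 1 - w1), c(0L, 1L))),
                 c(0.6, 0.4))
  # clusters pooling onto one label sum their scores
  s3 <- class_scores(rbind(c(0.5, 0.3, 0.2)), 1, label_map = c(0L, 0L, 1L))
  expect_equal(unname(s3), c(0.8, 0.2))
})

test_that("cluster-to-label mapping is a majority vote with documented ties", {
  U <- rbind(c(0.9, 0.8, 0.1, 0.2), c(0.1, 0.2, 0.9, 0.8))
  expect_equal(map_clusters_to_labels(U, c(0, 0, 1, 1)), c(0, 1))
  # cluster with votes {1: 3, 0: 1} -> 1
  U2 <- rbind(c(0.9, 0.9, 0.9, 0.9, 0.1), c(0.1, 0.1, 0.1, 0.1, 0.9))
  expect_equal(map_clusters_to_labels(U2, c(1, 1, 1, 0, 0)), c(1, 0))
  # tie in a cluster resolves to the lowest label
  U3 <- rbind(c(0.9, 0.9, 0.1), c(0.1, 0.1, 0.9))
  expect_equal(map_clusters_to_labels(U3, c(0, 1, 1)), c(0, 1))
  # empty cluster inherits the global majority
  U4 <- rbind(c(0.9, 0.9, 0.9), c(0.1, 0.1, 0.1))
  expect_equal(map_clusters_to_labels(U4, c(1, 1, 0)), c(1, 1))
  # exhaustive vote-counting oracle on random instances
  for (seed in 1:10) {
    set.seed(seed)
    C <- sample(2:4, 1); K <- 30
    G <- matrix(rexp(C * K), C, K)
    U <- sweep(G, 2, colSums(G), "/")
    labels <- sample(0:1, K, replace = TRUE)
    got <- map_clusters_to_labels(U, labels)
    hard <- apply(U, 2, which.max)
    for (cc in seq_len(C)) {
      in_c <- labels[hard == cc]
      if (length(in_c)) {
        n0 <- sum(in_c == 0); n1 <- sum(in_c == 1)
        expect_equal(got[cc], if (n1 > n0) 1L else 0L)
      }
    }
  }
  expect_warning(map_clusters_to_labels(U4, c(1, 1, 1)), "single class")
})

test_that("the classifier recovers tight, distant, labelled clusters", {
  set.seed(20)
  inst <- make_crisp_instance()
  clf <- mvfcm_classifier(inst$dataset, inst$labels, seed = 1)
  expect_equal(mean(predict(clf, inst$dataset) == inst$labels), 1)
  # label symmetry: flipping the labels flips the map, not the accuracy
  clf2 <- mvfcm_classifier(inst$dataset, 1L - inst$labels, seed = 1)
  expect_equal(mean(predict(clf2, inst$dataset) == (1L - inst$labels)), 1)
})

test_that("prediction ties resolve to the lowest class label", {
  ctr <- list(rbind(-1, 1))
  fit <- mvfcm(list(matrix(c(-1, 1, -0.9, 0.9), 4)), centers = ctr, m = 2)
  model <- structure(list(fit = fit, centers = fit$centers,
                          weights = fit$weights, config = fit$config,
                          label_map = c(0L, 1L), class_labels = c(0L, 1L)),
                     class = "mvfcm_classifier")
  # the origin is equidistant from both centers -> scores tie -> label 0
  pred <- predict(model, list(matrix(0, 1, 1)))
  expect_identical(pred, 0L)
  sc <- predict(model, list(matrix(0, 1, 1)), type = "scores")
  expect_equal(unname(sc[1, ]), c(0.5, 0.5))
})

test_that("JSON round trip reproduces predictions bit-identically", {
  set.seed(33)
  inst <- make_crisp_instance()
  clf <- mvfcm_classifier(inst$dataset, inst$labels, seed = 7, nstart = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_mvfcm_model(clf, path)
  back <- read_mvfcm_model(path)
  expect_identical(back$centers, lapply(clf$centers, unname))
  expect_identical(back$weights, clf$weights)
  expect_identical(back$label_map, clf$label_map)
  newd <- multiview_dataset(list(matrix(rnorm(12), 6), matrix(rnorm(6), 6)))
  expect_identical(predict(back, newd, type = "scores"),
                   predict(clf, newd, type = "scores"))
  expect_identical(predict(back, newd), predict(clf, newd))
})

test_that("with one view and crisp data prediction is nearest-center", {
  set.seed(44)
  X <- rbind(matrix(rnorm(30, 0, 0.2), 15), matrix(rnorm(30, 10, 0.2), 15))
  labels <- rep(c(0L, 1L), each = 15)
  clf <- mvfcm_classifier(list(X), labels, scale = FALSE, seed = 2)
  newX <- matrix(rnorm(40, 5 + 3 * rep(c(-1, 1), 10)), 20)
  pred <- predict(clf, list(newX))
  ctr <- clf$centers[[1]]
  nearest <- apply(newX, 1, function(r)
    which.min(c(sum((r - ctr[1, ])^2), sum((r - ctr[2, ])^2))))
  expect_equal(pred, clf$label_map[nearest])
})

test_that("view CSV and label round trips preserve the dataset", {
  d <- multiview_dataset(list(matrix(rnorm(12), 4), matrix(rnorm(8), 4)),
                         sample_ids = paste0("seg", 1:4))
  paths <- c(withr::local_tempfile(fileext = ".csv"),
             withr::local_tempfile(fileext = ".csv"))
  write_views(d, paths)
  back <- read_views(paths)
  expect_equal(unclass(back)[[1]], d[[1]], ignore_attr = TRUE)
  expect_equal(unclass(back)[[2]], d[[2]], ignore_attr = TRUE)
  expect_identical(attr(back, "sample_ids"), paste0("seg", 1:4))
  lp <- withr::local_tempfile(fileext = ".csv")
  write_labels(c(0L, 1L, 1L, 0L), lp, sample_ids = paste0("seg", 1:4))
  lab <- read_labels(lp)
  expect_identical(unname(lab), c(0L, 1L, 1L, 0L))
})
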