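test_that("co-clustering similarity matches the hand-counted example", {
  ## two runs over samples A, B, C: {AB|C} and {A|BC}
  runs <- fake_runs(list(c(1L, 1L, 2L), c(1L, 2L, 2L)),
                    ids = c("A", "B", "C"))
  S <- co_clustering_matrix(runs)
  expect_equal(S["A", "B"], 0.5)
  expect_equal(S["B", "C"], 0.5)
  expect_equal(S["A", "C"], 0)
  expect_true(isSymmetric(S))
  expect_equal(unname(diag(S)), rep(1, 3))
})

test_that("identical partitions give a 0/1 similarity matrix", {
  runs <- fake_runs(rep(list(c(1L, 1L, 2L, 2L)), 5),
                    ids = paste0("s", 1:4))
  S <- co_clustering_matrix(runs)
  expect_true(all(S %in% c(0, 1)))
  expect_error(co_clustering_matrix(fake_runs(list())), "no retained")
})

test_that("threshold components keep edges at exactly the threshold", {
  S <- diag(3)
  dimnames(S) <- list(c("a", "b", "c"), c("a", "b", "c"))
  S["a", "b"] <- S["b", "a"] <- 0.5    # edge weight 0.5 is retained
  S["b", "c"] <- S["c", "b"] <- 0.49   # strictly below -> removed
  comp <- threshold_graph_components(S, threshold = 0.5)
  expect_equal(comp[["a"]], comp[["b"]])
  expect_false(comp[["c"]] == comp[["a"]])
  ## all-ones: one component; all-zero off-diagonal: singletons
  S1 <- matrix(1, 3, 3, dimnames = dimnames(S))
  expect_equal(length(unique(threshold_graph_components(S1))), 1L)
  expect_equal(length(unique(threshold_graph_components(diag(3)))), 3L)
})

test_that("components are labeled by decreasing size", {
  S <- diag(5)
  S[1:2, 1:2] <- 1      # component of 2
  S[3:5, 3:5] <- 1      # component of 3
  dimnames(S) <- list(paste0("s", 1:5), paste0("s", 1:5))
  comp <- threshold_graph_components(S)
  expect_equal(unname(comp), c(2L, 2L, 1L, 1L, 1L))
})

test_that("raising the edge threshold never merges components", {
  set.seed(3)
  n <- 12
  S <- matrix(runif(n * n), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(paste0("s", 1:n), paste0("s", 1:n))
  prev <- threshold_graph_components(S, 0.2)
  for (thr in c(0.4, 0.6, 0.8)) {
    cur <- threshold_graph_components(S, thr)
    ## refinement: samples split at a lower threshold stay split
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (prev[i] != prev[j]) expect_true(cur[i] != cur[j])
    }
    prev <- cur
  }
})

test_that("silhouette filter retains only strictly positive silhouettes", {
  runs <- fake_runs(rep(list(c(1L, 1L, 2L, 2L)), 3))
  runs[[1]]$silhouette <- -0.1
  runs[[2]]$silhouette <- 0
  runs[[3]]$silhouette <- 0.2
  kept <- silhouette_filter(runs)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$silhouette, 0.2)
  expect_length(silhouette_filter(fake_runs(list())), 0L)
})

test_that("the ensemble is deterministic and fails runs softly", {
  toy <- toy_discrete()
  grid <- clustering_grid(algorithms = c("kmeans", "agglomerative", "dbscan"),
                          preprocessing = c("none", "pca2"), k = 2:4)
  e1 <- build_ensemble(toy$d, grid, seed = 5)
  e2 <- build_ensemble(toy$d, grid, seed = 5)
  expect_identical(lapply(e1, `[[`, "labels"), lapply(e2, `[[`, "labels"))
  expect_equal(length(e1), nrow(grid))
  ## every successful run labels every sample
  for (r in e1) {
    if (r$success) expect_length(r$labels, ncol(toy$d$states))
  }
  expect_error(build_ensemble(toy$d, grid[0, ], seed = 1), "empty")
})

test_that("consensus recovers well-separated planted groups exactly", {
  toy <- toy_discrete()
  grid <- clustering_grid(algorithms = c("kmeans", "agglomerative"),
                          preprocessing = c("none", "robust_scaling", "pca2"),
                          k = 2:5)
  cg <- consensus_cluster(toy$d, grid = grid, seed = 2)
  expect_equal(length(unique(cg$components)), 3L)
  expect_equal(adjusted_rand_index(cg$components, toy$groups), 1.0)
  ## the manifest reports the run count, retained count is consistent
  expect_equal(cg$n_runs, nrow(grid))
  expect_lte(cg$n_retained, cg$n_runs)
})

test_that("density-based runs treat noise points as singletons", {
  set.seed(8)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2),
             c(30, 30))  # one far outlier -> DBSCAN noise
  labs <- rbsubtype:::dbscan_cluster(X, min_pts = 4)
  expect_true(any(labs == -1L))
  ## via the ensemble wrapper the noise sample becomes its own cluster
  d <- structure(list(states = matrix("U", 2, nrow(X),
                                      dimnames = list(c("p1", "p2"),
                                                      paste0("s", seq_len(nrow(X)))))),
                 class = "DiscreteMatrix")
  grid <- clustering_grid(algorithms = "dbscan", preprocessing = "none")
  ens <- build_ensemble(X, grid, seed = 1)
  r <- ens[[1]]
  expect_true(r$success)
  ## the far outlier ends up in its own singleton cluster
  expect_equal(sum(r$labels == r$labels[nrow(X)]), 1L)
})
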