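#' Default clustering-ensemble grid
#'
#' The ensemble sweeps a Cartesian grid of clustering algorithm,
#' preprocessing and requested cluster number. Algorithms: k-means;
#' agglomerative clustering with single/average/complete linkage and
#' cosine/Euclidean/Manhattan distance; spectral clustering; affinity
#' propagation; DBSCAN; mean-shift. Preprocessings: none, robust scaling,
#' L2 normalization, linear projection (PCA, 1-4 dims) and, optionally,
#' manifold embedding (non-metric MDS, 1-4 dims). k runs over 2..6 for the
#' algorithms that take a cluster number; affinity propagation, DBSCAN and
#' mean-shift choose their own.
#'
#' @param algorithms,preprocessing,k character/integer vectors selecting a
#'   subset of the grid.
#' @param manifold include the manifold-embedding preprocessings.
#' @return A data.frame with one row per requested run.
#' @export
clustering_grid <- function(algorithms = c("kmeans", "agglomerative",
                                           "spectral", "affinity_propagation",
                                           "dbscan", "meanshift"),
                            preprocessing = NULL,
                            k = 2:6,
                            manifold = TRUE) {
  if (is.null(preprocessing)) {
    preprocessing <- c("none", "robust_scaling", "normalization",
                       paste0("pca", 1:4),
                       if (manifold) paste0("mds", 1:4))
  }
  rows <- list()
  for (prep in preprocessing) {
    for (alg in algorithms) {
      if (alg == "agglomerative") {
        for (link in c("single", "average", "complete")) {
          for (metric in c("cosine", "euclidean", "manhattan")) {
            for (kk in k) {
              rows[[length(rows) + 1L]] <- data.frame(
                algorithm = alg, linkage = link, metric = metric,
                preprocessing = prep, k = kk, stringsAsFactors = FALSE)
            }
          }
        }
      } else if (alg %in% c("kmeans", "spectral")) {
        for (kk in k) {
          rows[[length(rows) + 1L]] <- data.frame(
            algorithm = alg, linkage = NA_character_, metric = NA_character_,
            preprocessing = prep, k = kk, stringsAsFactors = FALSE)
        }
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = alg, linkage = NA_character_, metric = NA_character_,
          preprocessing = prep, k = NA_integer_, stringsAsFactors = FALSE)
      }
    }
  }
  grid <- do.call(rbind, rows)
  if (nrow(grid) == 0) stop("empty clustering grid", call. = FALSE)
  grid
}

## ---- preprocessing -------------------------------------------------------

preprocess_features <- function(X, method) {
  switch(sub("[0-9]$", "", method),
    none = X,
    robust_scaling = {
      med <- apply(X, 2, stats::median)
      iqr <- apply(X, 2, stats::IQR)
      iqr[iqr == 0] <- 1
      sweep(sweep(X, 2, med), 2, iqr, "/")
    },
    normalization = {
      nrm <- sqrt(rowSums(X^2))
      nrm[nrm == 0] <- 1
      X / nrm
    },
    pca = {
      d <- as.integer(sub("^pca", "", method))
      p <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 4L)
      p$x[, seq_len(min(d, ncol(p$x))), drop = FALSE]
    },
    mds = {
      d <- as.integer(sub("^mds", "", method))
      manifold_embed(X, d)
    },
    stop("unknown preprocessing: ", method, call. = FALSE)
  )
}

## Non-metric MDS embedding (classical-MDS initialised); falls back to the
## classical solution if the stress optimisation cannot run (e.g. exactly
## duplicated samples).
manifold_embed <- function(X, d) {
  dst <- stats::dist(X)
  init <- stats::cmdscale(dst, k = d)
  if (ncol(init) < d) {
    init <- cbind(init, matrix(0, nrow(init), d - ncol(init)))
  }
  if (any(dst <= 0)) {
    dst[dst <= 0] <- min(dst[dst > 0], 1e-8) * 1e-3
  }
  out <- try(MASS::isoMDS(dst, y = init, k = d, trace = FALSE),
             silent = TRUE)
  if (inherits(out, "try-error")) init else out$points
}

cosine_dist <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  sim <- tcrossprod(X / nrm)
  sim[sim > 1] <- 1; sim[sim < -1] <- -1
  stats::as.dist(1 - sim)
}

feature_dist <- function(X, metric) {
  switch(metric,
    euclidean = stats::dist(X),
    manhattan = stats::dist(X, method = "manhattan"),
    cosine = cosine_dist(X),
    stop("unknown metric: ", metric, call. = FALSE))
}

## ---- the individual algorithms ------------------------------------------

## Affinity propagation (Frey & Dueck) on similarity = -squared Euclidean
## distance, preference = median similarity; deterministic.
affinity_propagation <- function(X, damping = 0.9, max_iter = 200L,
                                 conv_iter = 25L) {
  n <- nrow(X)
  S <- -as.matrix(stats::dist(X))^2
  pref <- stats::median(S[upper.tri(S)])
  diag(S) <- pref
  R <- A <- matrix(0, n, n)
  stable <- 0L
  ex_old <- rep(-1L, n)
  for (it in seq_len(max_iter)) {
    ## responsibilities: r(i,k) = s(i,k) - max_{k' != k} (a + s)(i,k')
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew

    ## availabilities: a(i,k) = min(0, r(k,k) + sum_{i' != i,k} r+(i',k));
    ## a(k,k) = sum_{i' != k} r+(i',k)
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- pmin(0, matrix(cs, n, n, byrow = TRUE) - Rp)
    diag(Anew) <- cs - diag(R)
    A <- damping * A + (1 - damping) * Anew

    ex <- which(diag(A + R) > 0)
    if (identical(ex, ex_old)) stable <- stable + 1L else stable <- 0L
    ex_old <- ex
    if (stable >= conv_iter && length(ex) > 0) break
  }
  ex <- which(diag(A + R) > 0)
  if (length(ex) == 0) ex <- which.max(diag(A + R))
  labels <- max.col(S[, ex, drop = FALSE], ties.method = "first")
  labels[ex] <- seq_along(ex)
  as.integer(factor(labels))
}

## DBSCAN with eps set from the upper knee of the k-nearest-neighbour
## distance profile (the median shatters small sample sets into
## micro-clusters).
dbscan_cluster <- function(X, min_pts = 4L, eps = NULL) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  if (is.null(eps)) {
    knn <- apply(D, 1, function(r) sort(r)[min_pts + 1L])
    eps <- stats::quantile(knn, 0.9, names = FALSE)
  }
  labels <- integer(n)   # 0 = unvisited, -1 = noise
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- which(D[i, ] <= eps)
    if (length(nb) < min_pts) {
      labels[i] <- -1L
      next
    }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      if (!visited[j]) {
        visited[j] <- TRUE
        nb_j <- which(D[j, ] <= eps)
        if (length(nb_j) >= min_pts) queue <- union(queue, nb_j)
      }
      if (labels[j] <= 0L) labels[j] <- cl
    }
  }
  labels
}

## Mean-shift with a Gaussian kernel; bandwidth defaults to the median
## pairwise distance over 2. Modes closer than bandwidth/2 merge.
meanshift_cluster <- function(X, bandwidth = NULL, max_iter = 50L,
                              tol = 1e-5) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  if (is.null(bandwidth)) {
    bandwidth <- stats::median(D[upper.tri(D)]) / 2
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  modes <- X
  for (it in seq_len(max_iter)) {
    shift_max <- 0
    for (i in seq_len(n)) {
      d2 <- colSums((t(X) - modes[i, ])^2)
      wgt <- exp(-d2 / (2 * bandwidth^2))
      new <- colSums(X * wgt) / sum(wgt)
      shift_max <- max(shift_max, sqrt(sum((new - modes[i, ])^2)))
      modes[i, ] <- new
    }
    if (shift_max < tol * bandwidth) break
  }
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] > 0L) next
    cl <- cl + 1L
    d <- sqrt(colSums((t(modes) - modes[i, ])^2))
    labels[d <= bandwidth / 2 & labels == 0L] <- cl
  }
  as.integer(factor(labels))
}

run_one_clustering <- function(X, spec, dist_cache = NULL) {
  n <- nrow(X)
  labels <- switch(spec$algorithm,
    kmeans = suppressWarnings(
      stats::kmeans(X, centers = spec$k, nstart = 10L,
                    iter.max = 100L)$cluster),
    agglomerative = {
      dst <- if (!is.null(dist_cache)) dist_cache else
        feature_dist(X, spec$metric)
      stats::cutree(stats::hclust(dst, method = spec$linkage), k = spec$k)
    },
    spectral = {
      sc <- kernlab::specc(as.matrix(X), centers = spec$k)
      as.integer(sc)
    },
    affinity_propagation = affinity_propagation(X),
    dbscan = dbscan_cluster(X),
    meanshift = meanshift_cluster(X),
    stop("unknown algorithm: ", spec$algorithm, call. = FALSE)
  )
  labels
}

#' Build the clustering ensemble over a discretized methylation matrix
#'
#' Executes every run of the grid on the numerically encoded discrete
#' matrix (U=0, S=0.5, M=1; samples as observations). A run fails softly:
#' exceptions, fewer than 2 non-empty clusters, or density-based runs
#' labelling more than half the samples as noise mark the run
#' unsuccessful without aborting the ensemble. Noise labels from
#' density-based runs become singleton clusters. Each run's seed derives
#' deterministically from the master seed and its grid position, and the
#' silhouette score is computed in the run's own preprocessed feature
#' space with Euclidean distance.
#'
#' @param d a `DiscreteMatrix` (or a numeric samples-by-features matrix).
#' @param grid a data.frame from [clustering_grid()].
#' @param seed master seed.
#' @return A list of runs (class `ClusteringEnsemble`); each run carries
#'   algorithm, preprocessing, k, seed, labels, silhouette and success
#'   flag.
#' @export
build_ensemble <- function(d, grid = clustering_grid(), seed = 1L) {
  X0 <- if (inherits(d, "DiscreteMatrix")) discrete_to_numeric(d) else d
  if (nrow(X0) < 3) stop("need at least 3 samples", call. = FALSE)
  if (nrow(grid) == 0) stop("empty clustering grid", call. = FALSE)

  preps <- unique(grid$preprocessing)
  feats <- lapply(preps, function(p) preprocess_features(X0, p))
  names(feats) <- preps
  ## cache distances per (preprocessing, metric) and the Euclidean
  ## distance per preprocessing for silhouettes
  sil_dist <- lapply(feats, stats::dist)
  dist_cache <- list()

  runs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- as.list(grid[i, ])
    run_seed <- (as.integer(seed) * 10007L + i) %% .Machine$integer.max
    X <- feats[[spec$preprocessing]]
    dc <- NULL
    if (identical(spec$algorithm, "agglomerative")) {
      key <- paste(spec$preprocessing, spec$metric)
      if (is.null(dist_cache[[key]])) {
        dist_cache[[key]] <- if (spec$metric == "euclidean")
          sil_dist[[spec$preprocessing]] else feature_dist(X, spec$metric)
      }
      dc <- dist_cache[[key]]
    }
    set.seed(run_seed)
    ## individual algorithms may warn about their own convergence; the
    ## ensemble treats runs atomically (success + labels or soft failure)
    labels <- try(suppressWarnings(run_one_clustering(X, spec, dc)),
                  silent = TRUE)
    run <- c(spec, list(seed = run_seed, labels = NULL,
                        silhouette = NA_real_, success = FALSE,
                        message = ""))
    if (inherits(labels, "try-error")) {
      run$message <- conditionMessage(attr(labels, "condition"))
    } else if (length(labels) != nrow(X0) || anyNA(labels)) {
      run$message <- "incomplete labeling"
    } else {
      noise <- labels < 0L
      if (mean(noise) > 0.5) {
        run$message <- "more than 50% noise"
      } else {
        if (any(noise)) {  # noise samples become singleton clusters
          labels[noise] <- max(labels, 0L) + seq_len(sum(noise))
        }
        labels <- as.integer(factor(labels))
        if (length(unique(labels)) >= 2) {
          run$labels <- labels
          run$success <- TRUE
          sw <- cluster::silhouette(labels, sil_dist[[spec$preprocessing]])
          run$silhouette <- mean(sw[, "sil_width"])
        } else {
          run$message <- "fewer than 2 clusters"
        }
      }
    }
    runs[[i]] <- run
  }
  structure(runs, class = "ClusteringEnsemble",
            sample_ids = rownames(X0), master_seed = seed)
}

#' Discard clusterings with non-positive silhouette
#'
#' @param runs a `ClusteringEnsemble`.
#' @param cutoff runs with silhouette less than or equal to this are
#'   dropped (default 0); unsuccessful runs are always dropped.
#' @return The retained runs, same class.
#' @export
silhouette_filter <- function(runs, cutoff = 0) {
  keep <- vapply(runs, function(r) {
    isTRUE(r$success) && is.finite(r$silhouette) && r$silhouette > cutoff
  }, logical(1))
  structure(runs[keep], class = "ClusteringEnsemble",
            sample_ids = attr(runs, "sample_ids"),
            master_seed = attr(runs, "master_seed"))
}

#' Co-clustering similarity matrix
#'
#' S[i,j] is the fraction of retained clusterings in which samples i and j
#' share a cluster; the diagonal is 1.
#'
#' @param runs retained runs ([silhouette_filter()] output).
#' @return Symmetric sample-by-sample matrix in [0,1].
#' @export
co_clustering_matrix <- function(runs) {
  ids <- attr(runs, "sample_ids")
  runs <- Filter(function(r) isTRUE(r$success), runs)
  if (length(runs) == 0) stop("no retained clustering runs", call. = FALSE)
  n <- length(runs[[1]]$labels)
  S <- matrix(0, n, n)
  for (r in runs) {
    S <- S + outer(r$labels, r$labels, "==")
  }
  S <- S / length(runs)
  diag(S) <- 1
  if (!is.null(ids)) dimnames(S) <- list(ids, ids)
  S
}

#' Final clusters as components of the thresholded similarity graph
#'
#' Edges with weight strictly below the threshold are removed; the
#' connected components of what remains are the final clusters, labeled in
#' decreasing size (ties broken by the smallest member sample ID).
#'
#' @param S co-clustering similarity matrix.
#' @param threshold edge threshold (default 0.5); an edge of exactly the
#'   threshold weight is retained.
#' @return Integer vector of component labels named by sample.
#' @export
threshold_graph_components <- function(S, threshold = 0.5) {
  if (!isSymmetric(unname(S)) || any(S < 0 | S > 1)) {
    stop("S must be a symmetric similarity matrix in [0,1]", call. = FALSE)
  }
  adj <- S >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  ids <- if (!is.null(rownames(S))) rownames(S) else as.character(seq_len(nrow(S)))
  ## relabel: decreasing size, ties by smallest member sample ID
  sizes <- table(memb)
  first_member <- vapply(names(sizes), function(m) {
    min(ids[memb == as.integer(m)])
  }, character(1))
  ord <- order(-as.integer(sizes), first_member)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  out <- relabel[memb]
  names(out) <- ids
  out
}

#' Consensus clustering of a discretized methylation matrix
#'
#' Convenience wrapper: ensemble, silhouette filter, co-clustering
#' similarity, thresholded-graph components.
#'
#' @inheritParams build_ensemble
#' @param threshold edge threshold for [threshold_graph_components()].
#' @param silhouette_cutoff cutoff for [silhouette_filter()].
#' @return A list of class `ConsensusGraph`: `similarity`, `components`,
#'   `n_runs`, `n_retained`, `edge_threshold`, `runs` (manifest
#'   data.frame).
#' @export
consensus_cluster <- function(d, grid = clustering_grid(), threshold = 0.5,
                              silhouette_cutoff = 0, seed = 1L) {
  ens <- build_ensemble(d, grid, seed)
  kept <- silhouette_filter(ens, silhouette_cutoff)
  S <- co_clustering_matrix(kept)
  comp <- threshold_graph_components(S, threshold)
  manifest <- do.call(rbind, lapply(ens, function(r) {
    data.frame(algorithm = r$algorithm, linkage = r$linkage,
               metric = r$metric, preprocessing = r$preprocessing,
               k = r$k, seed = r$seed, silhouette = r$silhouette,
               success = r$success,
               n_clusters = if (r$success) length(unique(r$labels)) else NA,
               stringsAsFactors = FALSE)
  }))
  structure(list(similarity = S, components = comp,
                 n_runs = length(ens), n_retained = length(kept),
                 edge_threshold = threshold, runs = manifest),
            class = "ConsensusGraph")
}

#' @export
print.ConsensusGraph <- function(x, ...) {
  cat("ConsensusGraph:", nrow(x$similarity), "samples;",
      x$n_retained, "of", x$n_runs, "clusterings retained\n")
  cat("  components (threshold ", x$edge_threshold, "): ",
      paste(table(x$components), collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b two label vectors over the same samples.
#' @return The Hubert-Arabie adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length", call. = FALSE)
  mclust::adjustedRandIndex(a, b)
}
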