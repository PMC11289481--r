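#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Satterthwaite degrees of freedom. Unlike
#' `stats::t.test()` this follows the convention needed for mass-testing
#' near-constant methylation probes: two groups with zero variance and
#' equal means give t = 0, p = 1 (and infinite t, p = 0 when the means
#' differ).
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return A list with `t`, `df`, `p`.
#' @export
welch_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  res <- row_welch(matrix(group_a, nrow = 1), matrix(group_b, nrow = 1))
  list(t = res$t[1], df = res$df[1], p = res$p[1])
}

## Vectorised Welch test over matrix rows (features x samples per group).
row_welch <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  ## zero variance in both groups: equal means -> t = 0, p = 1;
  ## different means -> infinitely strong evidence
  degen <- se2 == 0
  t[degen & ma == mb] <- 0
  t[degen & ma != mb] <- Inf * sign(ma - mb)[degen & ma != mb]
  df[degen] <- na + nb - 2
  p <- 2 * stats::pt(-abs(t), df)
  p[degen & ma == mb] <- 1
  p[degen & ma != mb] <- 0
  list(t = t, df = df, p = p, mean_a = ma, mean_b = mb)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (order-preserving, monotonicity enforced).
#'
#' @param pvals numeric vector of p-values in [0,1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' One-vs-rest differential methylation
#'
#' Per-probe Welch test of one cluster against all remaining samples, BH
#' adjustment across all tested probes, and the effect/significance call:
#' a probe passes iff |delta beta| >= `min_delta` and adjusted p <
#' `max_adj_p`. Direction is "hyper" when the target-cluster mean exceeds
#' the rest. Probes with missing values in more than 20% of either group
#' are skipped and reported via the `skipped` attribute.
#'
#' @param beta a [beta_matrix()].
#' @param labels cluster labels named by (or ordered as) the samples.
#' @param target_cluster the cluster tested against the rest.
#' @param min_delta minimum absolute beta-value mean difference.
#' @param max_adj_p adjusted-p cut-off (strict inequality).
#' @return A data.frame of class `DifferentialResult` with columns probe,
#'   mean_group, mean_rest, delta, t, df, p, p_adj, direction, island (if
#'   annotated), pass.
#' @export
call_dm_probes <- function(beta, labels, target_cluster,
                           min_delta = 0.2, max_adj_p = 0.001) {
  stopifnot(inherits(beta, "BetaMatrix"))
  v <- beta$values
  if (!is.null(names(labels))) labels <- labels[colnames(v)]
  if (length(labels) != ncol(v) || anyNA(labels)) {
    stop("labels must cover every sample", call. = FALSE)
  }
  if (!target_cluster %in% labels) {
    stop("unknown cluster label: ", target_cluster, call. = FALSE)
  }
  in_grp <- labels == target_cluster
  if (sum(in_grp) < 2 || sum(!in_grp) < 2) {
    stop("both the target cluster and the rest need >= 2 samples",
         call. = FALSE)
  }
  A <- v[, in_grp, drop = FALSE]
  B <- v[, !in_grp, drop = FALSE]
  na_frac_a <- rowMeans(is.na(A))
  na_frac_b <- rowMeans(is.na(B))
  tested <- na_frac_a <= 0.2 & na_frac_b <= 0.2
  skipped <- rownames(v)[!tested]

  res <- row_welch(A[tested, , drop = FALSE], B[tested, , drop = FALSE])
  p_adj <- bh_adjust(res$p)
  delta <- res$mean_a - res$mean_b
  out <- data.frame(
    probe = rownames(v)[tested],
    mean_group = res$mean_a,
    mean_rest = res$mean_b,
    delta = delta,
    t = res$t,
    df = res$df,
    p = res$p,
    p_adj = p_adj,
    direction = ifelse(delta > 0, "hyper", "hypo"),
    ## small epsilon so a planted effect of exactly min_delta is not lost
    ## to floating-point rounding of the group means
    pass = abs(delta) >= min_delta - 1e-9 & p_adj < max_adj_p,
    stringsAsFactors = FALSE
  )
  if (!is.null(beta$annotation)) {
    out$island <- beta$annotation$island[match(out$probe,
                                               beta$annotation$probe_id)]
  }
  attr(out, "skipped") <- skipped
  attr(out, "target_cluster") <- target_cluster
  class(out) <- c("DifferentialResult", "data.frame")
  out
}

#' CpG-island partition of differentially methylated probes
#'
#' Counts passing probes inside and outside CpG islands, overall and per
#' direction. Unannotated probes count as outside with a warning (or an
#' error in strict mode).
#'
#' @param results a `DifferentialResult` from [call_dm_probes()].
#' @param annotation probe annotation with `probe_id` and `island`; can be
#'   omitted when the results already carry an island column.
#' @param strict error (rather than warn) on unannotated passing probes.
#' @return A list with `n_in_islands`, `n_outside`, `fraction_in` (NA when
#'   nothing passes) and `by_direction` (data.frame).
#' @export
island_partition <- function(results, annotation = NULL, strict = FALSE) {
  pass <- results[results$pass, , drop = FALSE]
  if (!is.null(annotation)) {
    island <- annotation$island[match(pass$probe, annotation$probe_id)]
  } else {
    island <- pass$island
  }
  if (nrow(pass) > 0 && (is.null(island) || anyNA(island))) {
    n_missing <- if (is.null(island)) nrow(pass) else sum(is.na(island))
    msg <- paste(n_missing, "passing probes lack island annotation")
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; counted as outside islands")
    if (is.null(island)) island <- rep(FALSE, nrow(pass))
    island[is.na(island)] <- FALSE
  }
  if (nrow(pass) == 0) {
    return(list(n_in_islands = 0L, n_outside = 0L, fraction_in = NA_real_,
                by_direction = data.frame(direction = character(0),
                                          n_in_islands = integer(0),
                                          n_outside = integer(0),
                                          fraction_in = numeric(0))))
  }
  by_dir <- do.call(rbind, lapply(split(island, pass$direction), function(z) {
    data.frame(n_in_islands = sum(z), n_outside = sum(!z),
               fraction_in = mean(z))
  }))
  by_dir <- cbind(direction = rownames(by_dir), by_dir)
  rownames(by_dir) <- NULL
  list(n_in_islands = sum(island),
       n_outside = sum(!island),
       fraction_in = mean(island),
       by_direction = by_dir)
}
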