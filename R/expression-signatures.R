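#' Differential expression between two sample groups
#'
#' Transparent stand-in for a transcript-level differential test: the
#' effect b is the difference of group means of log1p(tpm) and the p-value
#' comes from a Welch test on the same scale. Genes with all-zero tpm in
#' both groups are flagged and given b = 0, p = 1.
#'
#' @param expr an [expression_matrix()].
#' @param group_a,group_b sample-ID vectors (each >= 2 samples).
#' @return A data.frame with gene, b, t, df, p, all_zero.
#' @export
de_test <- function(expr, group_a, group_b) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  miss <- setdiff(c(group_a, group_b), expr$sample_ids)
  if (length(miss) > 0) {
    stop("unknown samples: ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  la <- log1p(expr$tpm[, group_a, drop = FALSE])
  lb <- log1p(expr$tpm[, group_b, drop = FALSE])
  res <- row_welch(la, lb)
  all_zero <- rowSums(la) == 0 & rowSums(lb) == 0
  b <- res$mean_a - res$mean_b
  p <- res$p
  b[all_zero] <- 0
  p[all_zero] <- 1
  data.frame(gene = expr$gene_ids, b = b, t = res$t, df = res$df, p = p,
             all_zero = all_zero, stringsAsFactors = FALSE)
}

#' Storey-Tibshirani q-values with bootstrap pi0
#'
#' Estimates the null proportion pi0 over the lambda grid 0.05..0.95 by
#' the bootstrap mean-squared-error criterion: for each lambda the MSE of
#' the plug-in estimate pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))
#' around the smallest decile of the plug-in curve is computed in closed
#' form (binomial variance plus squared bias), the lambda with minimal
#' MSE is selected, and the estimate is capped at 1. p-values then become
#' q-values: q_i = min over thresholds t >= p_i of
#' pi0 * m * t / #\{p <= t\}. The procedure is deterministic. With fewer
#' than 20 p-values pi0 is not estimable and the function falls back to
#' BH with a warning.
#'
#' @param pvals p-values in [0,1].
#' @param lambda grid for pi0 estimation.
#' @param pi0 optional fixed null proportion overriding the estimate
#'   (pi0 = 1 reproduces BH exactly).
#' @return A list with `q` (input order) and `pi0`.
#' @export
storey_qvalues <- function(pvals, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  if (m < 20) {
    warning("fewer than 20 p-values; falling back to BH (pi0 = 1)")
    return(list(q = bh_adjust(pvals), pi0 = 1))
  }
  if (is.null(pi0)) {
    W <- vapply(lambda, function(l) sum(pvals >= l), numeric(1))
    pi0_hat <- W / (m * (1 - lambda))
    min_pi0 <- stats::quantile(pi0_hat, 0.1, names = FALSE)
    mse <- (W / (m^2 * (1 - lambda)^2)) * (1 - W / m) +
      (pi0_hat - min_pi0)^2
    pi0 <- min(1, max(pi0_hat[which.min(mse)], 0))
  }

  ord <- order(pvals, decreasing = TRUE)
  q <- numeric(m)
  rank_desc <- m:1  # #\{p <= p_(i)\} for the descending order
  q_ord <- pi0 * m * pvals[ord] / rank_desc
  q_ord <- cummin(q_ord)
  q_ord <- pmin(q_ord, 1)
  q[ord] <- q_ord
  list(q = q, pi0 = pi0)
}

#' Edgington's p-value combination
#'
#' Combines k p-values by the distribution of their sum under the null:
#' combined p = P(sum of k independent uniforms <= s), the Irwin-Hall CDF
#' sum_{j=0..floor(s)} (-1)^j C(k,j) (s-j)^k / k!, clamped to [0,1].
#'
#' @param pvals 1 to 20 finite p-values.
#' @return The combined p-value.
#' @export
edgington_combine <- function(pvals) {
  k <- length(pvals)
  if (k == 0) stop("need at least one p-value", call. = FALSE)
  if (k > 20) stop("at most 20 p-values are supported", call. = FALSE)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  }
  s <- sum(pvals)
  j <- 0:floor(s)
  ## log-space magnitudes with alternating signs for stability
  terms <- exp(lchoose(k, j) + k * log(pmax(s - j, 0)) - lfactorial(k))
  p <- sum((-1)^j * terms)
  min(max(p, 0), 1)
}

#' Pi-value ranking statistic
#'
#' pi = b * (-log10 p): effect size weighted by significance. Zero
#' p-values are floored at the smallest positive double with a warning.
#'
#' @param b effect sizes.
#' @param p p-values in [0,1].
#' @return Numeric vector of pi scores (same order as input).
#' @export
pi_rank <- function(b, p) {
  if (length(b) != length(p)) stop("b and p differ in length", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (any(p == 0, na.rm = TRUE)) {
    warning("zero p-values floored at the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  b * (-log10(p))
}

#' A named gene signature
#'
#' @param name signature name.
#' @param genes gene identifiers (deduplicated with a warning).
#' @param direction per-gene direction, "up" or "down" (recycled).
#' @param provenance free-form list recording derivation parameters.
#' @return An object of class `GeneSignature`.
#' @export
gene_signature <- function(name, genes, direction = "up",
                           provenance = list()) {
  if (anyDuplicated(genes)) {
    warning("duplicate genes in signature '", name, "' removed")
    keep <- !duplicated(genes)
    direction <- rep_len(direction, length(genes))[keep]
    genes <- genes[keep]
  }
  direction <- rep_len(direction, length(genes))
  if (length(genes) > 0 && !all(direction %in% c("up", "down"))) {
    stop("direction must be 'up' or 'down'", call. = FALSE)
  }
  structure(list(name = name, genes = genes, direction = direction,
                 provenance = provenance),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat("GeneSignature '", x$name, "': ", length(x$genes), " genes (",
      sum(x$direction == "up"), " up, ", sum(x$direction == "down"),
      " down)\n", sep = "")
  invisible(x)
}

#' Per-sample signature score
#'
#' The score of a sample is the mean of log1p(tpm) over the signature
#' genes present in the matrix (missing genes are reported via an
#' attribute). The direction-aware variant subtracts the mean over "down"
#' genes from the mean over "up" genes.
#'
#' @param expr an [expression_matrix()].
#' @param sig a [gene_signature()].
#' @param direction_aware subtract the down-gene mean (default FALSE:
#'   plain mean over all signature genes).
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(expr, sig, direction_aware = FALSE) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(sig, "GeneSignature"))
  present <- sig$genes %in% expr$gene_ids
  if (!any(present)) {
    stop("no signature gene present in the expression matrix", call. = FALSE)
  }
  lt <- log1p(expr$tpm[sig$genes[present], , drop = FALSE])
  if (direction_aware) {
    dir <- sig$direction[present]
    up <- lt[dir == "up", , drop = FALSE]
    dn <- lt[dir == "down", , drop = FALSE]
    score <- (if (nrow(up)) colMeans(up) else 0) -
      (if (nrow(dn)) colMeans(dn) else 0)
  } else {
    score <- colMeans(lt)
  }
  attr(score, "missing_genes") <- sig$genes[!present]
  score
}

#' Derive cluster-B and cluster-C expression signatures
#'
#' Step-wise statistical filtering over the three one-vs-one contrasts:
#' a gene enters the signature of cluster X (X = B or C) iff it passes
#' q <= `q_max` and |b| >= `b_min` with a consistent sign in both X-vs-A
#' and X-vs-Y (Y the other non-A cluster), and does not pass Y-vs-A with
#' that same sign (cluster-exclusive change). Directions are recorded.
#'
#' @param expr an [expression_matrix()] over the tumor cohort.
#' @param labels cluster labels (A/B/C) named by sample.
#' @param q_max,b_min significance and effect cut-offs.
#' @return A list with `signature_B`, `signature_C` ([gene_signature()]s,
#'   possibly empty) and the per-contrast `tests`.
#' @export
derive_cluster_signatures <- function(expr, labels, q_max = 0.05,
                                      b_min = 0.3) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!is.null(names(labels))) labels <- labels[expr$sample_ids]
  clusters <- c("A", "B", "C")
  if (!all(clusters %in% labels)) {
    stop("all three clusters (A, B, C) must be populated", call. = FALSE)
  }
  grp <- split(expr$sample_ids, labels)
  contrast <- function(x, y) {
    de <- de_test(expr, grp[[x]], grp[[y]])
    de$q <- storey_qvalues(de$p)$q
    de
  }
  tests <- list(B_vs_A = contrast("B", "A"),
                C_vs_A = contrast("C", "A"),
                B_vs_C = contrast("B", "C"))

  passes_signed <- function(de, sgn) {
    de$q <= q_max & abs(de$b) >= b_min & sign(de$b) == sgn
  }
  build <- function(x) {
    y <- setdiff(c("B", "C"), x)
    vs_a <- tests[[paste0(x, "_vs_A")]]
    y_vs_a <- tests[[paste0(y, "_vs_A")]]
    ## B_vs_C holds B minus C; for X = C the X-vs-Y effect flips sign
    x_vs_y_b <- if (x == "B") tests$B_vs_C$b else -tests$B_vs_C$b
    x_vs_y_q <- tests$B_vs_C$q
    genes <- character(0); dirs <- character(0)
    for (sgn in c(1, -1)) {
      sel <- passes_signed(vs_a, sgn) &
        (x_vs_y_q <= q_max & abs(x_vs_y_b) >= b_min & sign(x_vs_y_b) == sgn) &
        !passes_signed(y_vs_a, sgn)
      genes <- c(genes, vs_a$gene[sel])
      dirs <- c(dirs, rep(if (sgn > 0) "up" else "down", sum(sel)))
    }
    gene_signature(paste0("cluster_", x), genes, dirs,
                   provenance = list(q_max = q_max, b_min = b_min))
  }
  sig_B <- build("B")
  sig_C <- build("C")
  if (length(sig_B$genes) == 0 && length(sig_C$genes) == 0) {
    warning("no gene passed the signature filters; both signatures empty")
  }
  list(signature_B = sig_B, signature_C = sig_C, tests = tests)
}

#' Derive the MYCN-RB signature from an inducible-knockdown experiment
#'
#' Per cell line, induced-vs-control differential expression; per gene,
#' the line-level p-values are Edgington-combined and converted to Storey
#' q-values. A gene belongs to the common knockdown-responsive set iff
#' q <= `q_max` and its effect has the same sign in every line. The
#' MYCN-RB signature is the commonly downregulated genes intersected with
#' the union of the provided MYC(N)-target sets.
#'
#' @param expr an [expression_matrix()] whose `samples` table has columns
#'   `line` and `condition` ("induced"/"control"), >= 2 replicates each.
#' @param target_sets list of character vectors of known target genes.
#' @param q_max q-value cut-off for the common set.
#' @return A list with `common` (data.frame: gene, b per line, combined p,
#'   q, direction), `signature` (a [gene_signature()]), and `tests`.
#' @export
derive_mycn_rb_signature <- function(expr, target_sets, q_max = 0.1) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  ann <- expr$samples
  if (is.null(ann) || !all(c("line", "condition") %in% names(ann))) {
    stop("expr$samples must provide line and condition", call. = FALSE)
  }
  lines <- unique(ann$line)
  if (length(lines) < 2) stop("need at least 2 lines", call. = FALSE)
  per_line <- lapply(lines, function(l) {
    ind <- ann$sample_id[ann$line == l & ann$condition == "induced"]
    ctl <- ann$sample_id[ann$line == l & ann$condition == "control"]
    if (length(ind) < 2 || length(ctl) < 2) {
      stop("line ", l, " lacks a condition with >= 2 replicates",
           call. = FALSE)
    }
    de_test(expr, ind, ctl)
  })
  names(per_line) <- lines

  genes <- per_line[[1]]$gene
  P <- vapply(per_line, function(d) d$p, numeric(length(genes)))
  B <- vapply(per_line, function(d) d$b, numeric(length(genes)))
  combined_p <- apply(P, 1, edgington_combine)
  st <- storey_qvalues(combined_p)

  signs <- sign(B)
  consistent <- apply(signs, 1, function(s) all(s == s[1]) && all(s != 0))
  common_sel <- st$q <= q_max & consistent
  direction <- ifelse(rowMeans(B) > 0, "up", "down")

  common <- data.frame(gene = genes, b_mean = rowMeans(B),
                       p_combined = combined_p, q = st$q,
                       direction = direction,
                       stringsAsFactors = FALSE)[common_sel, , drop = FALSE]
  rownames(common) <- NULL

  targets <- unique(unlist(target_sets))
  sig_genes <- intersect(common$gene[common$direction == "down"], targets)
  if (length(targets) == 0) {
    warning("empty target sets; MYCN-RB signature is empty")
  }
  sig <- gene_signature("MYCN_RB", sig_genes, "down",
                        provenance = list(q_max = q_max,
                                          n_common = nrow(common),
                                          n_down = sum(common$direction == "down"),
                                          pi0 = st$pi0))
  list(common = common, signature = sig, tests = per_line, pi0 = st$pi0)
}

#' Methylation-based subtype call from a small probe classifier
#'
#' Hierarchical clustering (Manhattan distance, Ward.D2 linkage) of the
#' samples on the classifier-probe beta submatrix, cut into two groups.
#' Missing probes may be substituted via `substitutions` (e.g. the closest
#' EPIC probe standing in for a 450k-only probe); a probe that is neither
#' present nor substitutable raises an error naming it. When a reference
#' profile (named per-probe beta means of one subtype) is supplied, the
#' group whose centroid is closer to it receives that subtype's name.
#'
#' @param beta a [beta_matrix()] (>= 2 samples).
#' @param classifier_probes probe IDs of the classifier.
#' @param substitutions named character vector, primary probe -> stand-in.
#' @param reference optional named numeric vector (per-probe profile) with
#'   a `subtype` attribute or name via `reference_label`.
#' @param reference_label subtype name for the reference-matched group.
#' @return Character vector of subtype labels named by sample.
#' @export
classifier_subtypes <- function(beta, classifier_probes,
                                substitutions = NULL, reference = NULL,
                                reference_label = "subtype1") {
  stopifnot(inherits(beta, "BetaMatrix"))
  if (ncol(beta$values) < 2) {
    stop("need at least 2 samples", call. = FALSE)
  }
  resolved <- vapply(classifier_probes, function(p) {
    if (p %in% beta$probe_ids) return(p)
    if (!is.null(substitutions) && p %in% names(substitutions) &&
        substitutions[[p]] %in% beta$probe_ids) {
      return(substitutions[[p]])
    }
    stop("classifier probe not resolvable: ", p, call. = FALSE)
  }, character(1))
  sub <- t(beta$values[resolved, , drop = FALSE])
  hc <- stats::hclust(stats::dist(sub, method = "manhattan"),
                      method = "ward.D2")
  grp <- stats::cutree(hc, k = 2)
  labels <- paste0("subtype", grp)
  if (!is.null(reference)) {
    ref <- reference[resolved]
    cent <- rbind(colMeans(sub[grp == 1, , drop = FALSE]),
                  colMeans(sub[grp == 2, , drop = FALSE]))
    d_ref <- rowSums(abs(sweep(cent, 2, ref)))
    match_grp <- which.min(d_ref)
    other <- setdiff(c("subtype1", "subtype2"), reference_label)
    labels <- ifelse(grp == match_grp, reference_label, other)
  }
  stats::setNames(labels, rownames(sub))
}
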