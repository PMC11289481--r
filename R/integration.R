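#' Correlate local CpG methylation with gene expression
#'
#' For every mapped CpG-gene pair, the Pearson correlation between the
#' probe's beta-values and the gene's log1p(tpm) across the shared
#' samples. Pairs whose beta-value variance falls below `var_min` are
#' excluded before testing; p-values come from the t transform of r with
#' n-2 degrees of freedom and are BH-adjusted across all tested pairs. A
#' pair is classed "positive" if r >= `r_min`, "negative" if
#' r <= -`r_min`, in both cases requiring adjusted p < `max_adj_p`;
#' otherwise "none". Pairs whose gene is absent from the expression matrix
#' are skipped and reported.
#'
#' @param beta a [beta_matrix()].
#' @param expr an [expression_matrix()].
#' @param mapping data.frame with columns `probe_id`, `gene` (one row per
#'   pair); an `island` column is carried through (otherwise taken from
#'   the beta annotation when available).
#' @param var_min minimum beta-value variance.
#' @param r_min absolute correlation cut-off for sign classification.
#' @param max_adj_p adjusted-p cut-off.
#' @return A data.frame of class `CorrelationResult`: probe_id, gene,
#'   island, r, p, p_adj, sign_class, with skipped pairs in attribute
#'   `skipped`.
#' @export
correlate_cpg_gene <- function(beta, expr, mapping, var_min = 1e-4,
                               r_min = 0.4, max_adj_p = 0.05) {
  stopifnot(inherits(beta, "BetaMatrix"), inherits(expr, "ExpressionMatrix"))
  if (nrow(mapping) == 0) stop("empty CpG-gene mapping", call. = FALSE)
  shared <- intersect(beta$sample_ids, expr$sample_ids)
  if (length(shared) < 4) {
    stop("need at least 4 shared samples", call. = FALSE)
  }
  if (!"island" %in% names(mapping) && !is.null(beta$annotation)) {
    mapping$island <- beta$annotation$island[match(mapping$probe_id,
                                                   beta$annotation$probe_id)]
  }
  if (!"island" %in% names(mapping)) mapping$island <- NA

  known_probe <- mapping$probe_id %in% beta$probe_ids
  known_gene <- mapping$gene %in% expr$gene_ids
  skipped <- mapping[!(known_probe & known_gene), , drop = FALSE]
  mapping <- mapping[known_probe & known_gene, , drop = FALSE]
  if (nrow(mapping) == 0) stop("no testable CpG-gene pair", call. = FALSE)

  bm <- beta$values[mapping$probe_id, shared, drop = FALSE]
  em <- log1p(expr$tpm[mapping$gene, shared, drop = FALSE])
  n <- length(shared)

  bvar <- rowSums((bm - rowMeans(bm))^2) / (n - 1)
  tested <- bvar >= var_min
  bm <- bm[tested, , drop = FALSE]
  em <- em[tested, , drop = FALSE]
  mp <- mapping[tested, , drop = FALSE]

  bc <- bm - rowMeans(bm)
  ec <- em - rowMeans(em)
  denom <- sqrt(rowSums(bc^2) * rowSums(ec^2))
  r <- rowSums(bc * ec) / denom
  r[denom == 0] <- 0           # constant expression: no correlation
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  p_adj <- bh_adjust(p)

  sign_class <- rep("none", nrow(mp))
  sign_class[r >= r_min & p_adj < max_adj_p] <- "positive"
  sign_class[r <= -r_min & p_adj < max_adj_p] <- "negative"

  out <- data.frame(probe_id = mp$probe_id, gene = mp$gene,
                    island = mp$island, r = r, p = p, p_adj = p_adj,
                    sign_class = sign_class, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "n_variance_filtered") <- sum(!tested)
  attr(out, "n_samples") <- n
  class(out) <- c("CorrelationResult", "data.frame")
  out
}

#' Summarize classified CpG-gene correlations
#'
#' Counts of pairs and of distinct genes per sign class, split by
#' CpG-island context and, when a differential-methylation result is
#' supplied, by the hypo/hyper status of the CpG.
#'
#' @param results a `CorrelationResult`.
#' @param dm optional `DifferentialResult` used to attach hypo/hyper
#'   status to each CpG (passing probes only).
#' @return A data.frame with sign_class, island, (direction), n_pairs,
#'   n_genes; empty input gives an all-zero summary.
#' @export
summarize_correlations <- function(results, dm = NULL) {
  df <- as.data.frame(results)
  if (!is.null(dm)) {
    pass <- dm[dm$pass, c("probe", "direction")]
    df$direction <- pass$direction[match(df$probe_id, pass$probe)]
    df$direction[is.na(df$direction)] <- "not_dm"
    keys <- c("sign_class", "island", "direction")
  } else {
    keys <- c("sign_class", "island")
  }
  if (nrow(df) == 0) {
    out <- data.frame(sign_class = character(0), island = logical(0),
                      n_pairs = integer(0), n_genes = integer(0))
    return(out)
  }
  split_keys <- interaction(df[keys], drop = TRUE)
  parts <- split(df, split_keys)
  out <- do.call(rbind, lapply(parts, function(pp) {
    cbind(pp[1, keys, drop = FALSE],
          data.frame(n_pairs = nrow(pp),
                     n_genes = length(unique(pp$gene))))
  }))
  rownames(out) <- NULL
  out[order(out$sign_class, out$island), , drop = FALSE]
}
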