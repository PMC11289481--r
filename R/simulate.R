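#' Generate a synthetic methylation cohort with planted cluster structure
#'
#' Draws a probe-by-sample beta-value matrix emulating a normalised
#' methylation-array cohort with three planted tumor clusters. Each probe
#' gets a baseline mean from a bimodal beta mixture
#' (0.465*Beta(1.5,15) + 0.465*Beta(15,1.5) + 0.07*Beta(8,8): the
#' unmethylated and methylated modes the discretizer assumes, plus a small
#' intermediate-methylation fraction as found on real arrays); a planted
#' fraction of probes is shifted
#' by +delta in cluster B (hypermethylation, enriched in CpG islands) and
#' by -delta in cluster C (hypomethylation, mostly outside islands).
#' Per-value noise is Beta(mu*kappa, (1-mu)*kappa). Differentially
#' methylated probes are planted only where the full shift fits inside
#' [0.02, 0.98], so the planted |delta beta| is exact rather than clipped:
#' hypomethylation is planted at methylated baselines and hypermethylation
#' at unmethylated ones, as in tumor methylomes.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; output is bit-identical for a given
#'   config + seed.
#' @return A list with elements `beta` (a [beta_matrix()] with probe
#'   annotation) and `truth` (planted labels, DM probe sets with
#'   directions, gene effects and coupled CpG-gene pairs).
#' @export
generate_methylation_cohort <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  set.seed(seed)

  sizes <- config$cluster_sizes
  labels <- rep(names(sizes), times = sizes)
  n_samples <- length(labels)
  sample_ids <- sprintf("RB_%02d", seq_len(n_samples))
  names(labels) <- sample_ids

  n_probes <- as.integer(config$n_probes)
  probe_ids <- sprintf("cg%08d", seq_len(n_probes))

  ## baseline means: two dominant modes (unmethylated / methylated) plus
  ## a small intermediate-methylation fraction, as in real methylomes
  ## (imprinted loci, partially methylated domains); the intermediate
  ## fraction also identifies the discretizer's middle component
  u <- stats::runif(n_probes)
  mu <- ifelse(u < 0.465, stats::rbeta(n_probes, 1.5, 15),
        ifelse(u < 0.93, stats::rbeta(n_probes, 15, 1.5),
               stats::rbeta(n_probes, 8, 8)))
  mu <- pmin(pmax(mu, 0.02), 0.98)

  ## plant DM probes where the full shift fits without clipping
  delta <- config$delta
  n_dm_C <- round(config$frac_dm_C * n_probes)
  n_dm_B <- round(config$frac_dm_B * n_probes)
  elig_C <- which(mu >= 0.02 + delta)
  if (length(elig_C) < n_dm_C) {
    stop("not enough eligible probes to plant the requested DM fractions",
         call. = FALSE)
  }
  dm_C <- if (n_dm_C > 0) sample(elig_C, n_dm_C) else integer(0)
  elig_B <- setdiff(which(mu <= 0.98 - delta), dm_C)  # planted sets disjoint
  if (length(elig_B) < n_dm_B) {
    stop("not enough eligible probes to plant the requested DM fractions",
         call. = FALSE)
  }
  dm_B <- if (n_dm_B > 0) sample(elig_B, n_dm_B) else integer(0)

  ## per-sample means with planted shifts
  mu_mat <- matrix(mu, nrow = n_probes, ncol = n_samples)
  in_B <- labels == "B"
  in_C <- labels == "C"
  if (length(dm_B) > 0) mu_mat[dm_B, in_B] <- mu_mat[dm_B, in_B] + delta
  if (length(dm_C) > 0) mu_mat[dm_C, in_C] <- mu_mat[dm_C, in_C] - delta
  mu_mat <- pmin(pmax(mu_mat, 0.02), 0.98)

  kappa <- config$concentration
  values <- matrix(stats::rbeta(length(mu_mat),
                                shape1 = mu_mat * kappa,
                                shape2 = (1 - mu_mat) * kappa),
                   nrow = n_probes, ncol = n_samples,
                   dimnames = list(probe_ids, sample_ids))
  values <- pmin(pmax(values, 1e-6), 1 - 1e-6)

  ## island flags with exact planted fractions per probe class
  island <- logical(n_probes)
  assign_islands <- function(idx, frac) {
    n_isl <- round(frac * length(idx))
    if (n_isl > 0) island[sample(idx, n_isl)] <<- TRUE
  }
  assign_islands(dm_B, config$island_frac_dm_B)
  assign_islands(dm_C, config$island_frac_dm_C)
  background <- setdiff(seq_len(n_probes), c(dm_B, dm_C))
  assign_islands(background, config$island_frac_background)

  ## gene universe and planted expression effects
  gene_plan <- plan_gene_effects(config)

  ## CpG-gene coupling: negative pairs pair C-hypo probes with C-up genes
  ## and B-hyper probes with B-down genes; positive pairs pair C-hypo
  ## probes with C-down genes. Correlation is carried by the shared
  ## cluster structure.
  free_C <- dm_C
  free_B <- dm_B
  take <- function(pool, n) {
    n <- min(n, length(pool))
    if (n == 0) return(integer(0))
    pool[seq_len(n)]
  }
  free_C <- sample(free_C)
  free_B <- sample(free_B)
  n_negB <- min(length(gene_plan$neg_B_genes), length(free_B))
  n_negC <- min(length(gene_plan$neg_C_genes), length(free_C))
  pr_negB <- take(free_B, n_negB); free_B <- setdiff(free_B, pr_negB)
  pr_negC <- take(free_C, n_negC); free_C <- setdiff(free_C, pr_negC)
  n_pos <- min(length(gene_plan$pos_C_genes), length(free_C))
  pr_pos <- take(free_C, n_pos)

  pair_block <- function(idx, genes, sign) {
    if (length(idx) == 0) return(NULL)
    data.frame(probe_id = probe_ids[idx], gene = genes[seq_along(idx)],
               sign = sign, stringsAsFactors = FALSE)
  }
  coupled <- rbind(
    pair_block(pr_negC, gene_plan$neg_C_genes, "negative"),
    pair_block(pr_negB, gene_plan$neg_B_genes, "negative"),
    pair_block(pr_pos, gene_plan$pos_C_genes, "positive")
  )
  if (is.null(coupled)) {
    coupled <- data.frame(probe_id = character(0), gene = character(0),
                          sign = character(0), stringsAsFactors = FALSE)
  }

  ## probe -> gene map: coupled probes map to their gene, plus a pool of
  ## null mappings so downstream correlation runs see true negatives
  gene_map <- rep(NA_character_, n_probes)
  gene_map[match(coupled$probe_id, probe_ids)] <- coupled$gene
  null_pool <- setdiff(background, which(!is.na(gene_map)))
  n_null <- min(500L, length(null_pool))
  null_idx <- sample(null_pool, n_null)
  null_genes <- setdiff(gene_plan$genes, c(coupled$gene,
                                           gene_plan$effects$gene))
  gene_map[null_idx] <- sample(null_genes, n_null, replace = TRUE)

  annotation <- data.frame(
    probe_id = probe_ids,
    island = island,
    gene = gene_map,
    chr = sample(paste0("chr", 1:22), n_probes, replace = TRUE),
    stringsAsFactors = FALSE
  )

  if (isTRUE(config$duplicate_sample)) {
    dup <- which(labels == "A")[1]
    values <- cbind(values, values[, dup, drop = FALSE])
    colnames(values)[n_samples + 1] <- paste0(sample_ids[dup], "_rep")
    labels <- c(labels, stats::setNames("A", paste0(sample_ids[dup], "_rep")))
  }

  truth <- structure(list(
    labels = labels,
    dm_probes_B = data.frame(probe_id = probe_ids[dm_B],
                             direction = rep("hyper", length(dm_B)),
                             stringsAsFactors = FALSE),
    dm_probes_C = data.frame(probe_id = probe_ids[dm_C],
                             direction = rep("hypo", length(dm_C)),
                             stringsAsFactors = FALSE),
    gene_effects = gene_plan$effects,
    genes = gene_plan$genes,
    signature_B = gene_plan$signature_B,
    signature_C = gene_plan$signature_C,
    marker_genes = gene_plan$markers,
    coupled_pairs = coupled
  ), class = "SyntheticTruth")

  list(beta = beta_matrix(values, annotation), truth = truth)
}

## Lay out the gene universe and the planted per-cluster expression
## effects (marker genes, cluster-exclusive signature genes, photoreceptor
## genes, and genes reserved for CpG-expression coupling).
plan_gene_effects <- function(config) {
  n_genes <- as.integer(config$n_genes)
  markers <- c("MYCN", "NKX2-5", "GATA4", "TFF1")
  pr <- sprintf("PRGENE%03d", seq_len(config$n_photoreceptor))
  sig_B <- sprintf("SIGB%03d", seq_len(config$n_signature_B))
  sig_C <- sprintf("SIGC%03d", seq_len(config$n_signature_C))
  n_named <- length(markers) + length(pr) + length(sig_B) + length(sig_C)
  if (n_genes <= n_named + config$n_pairs_negative + config$n_pairs_positive) {
    stop("n_genes too small for the planted gene sets", call. = FALSE)
  }
  generic <- sprintf("GENE%05d", seq_len(n_genes - n_named))
  genes <- c(markers, pr, sig_B, sig_C, generic)

  ce <- 1.5  # coupling effect on the log1p-tpm scale
  me <- config$marker_effect
  se <- config$signature_effect
  n_negC <- ceiling(2 * config$n_pairs_negative / 3)
  n_negB <- config$n_pairs_negative - n_negC
  neg_C_genes <- generic[seq_len(n_negC)]
  neg_B_genes <- generic[n_negC + seq_len(n_negB)]
  pos_C_genes <- generic[n_negC + n_negB + seq_len(config$n_pairs_positive)]

  ## when all planted effects are switched off (null cohort), silence the
  ## CpG-expression coupling as well
  if (me == 0 && se == 0) ce <- 0
  effects <- rbind(
    data.frame(gene = "MYCN", cluster = "C", effect = me),
    data.frame(gene = "NKX2-5", cluster = "B", effect = me),
    data.frame(gene = "GATA4", cluster = "B", effect = 0.75 * me),
    data.frame(gene = "TFF1", cluster = "B", effect = 0.75 * me),
    data.frame(gene = "TFF1", cluster = "C", effect = 0.75 * me),
    if (length(pr)) data.frame(gene = pr, cluster = "A", effect = se),
    if (length(sig_B)) data.frame(gene = sig_B, cluster = "B", effect = se),
    if (length(sig_C)) data.frame(gene = sig_C, cluster = "C", effect = se),
    if (length(neg_C_genes)) data.frame(gene = neg_C_genes, cluster = "C",
                                        effect = ce),
    if (length(neg_B_genes)) data.frame(gene = neg_B_genes, cluster = "B",
                                        effect = -ce),
    if (length(pos_C_genes)) data.frame(gene = pos_C_genes, cluster = "C",
                                        effect = -ce)
  )
  list(genes = genes, effects = effects, markers = markers,
       signature_B = sig_B, signature_C = sig_C,
       neg_C_genes = neg_C_genes, neg_B_genes = neg_B_genes,
       pos_C_genes = pos_C_genes)
}

#' Generate the matched synthetic expression cohort
#'
#' Gene-by-sample tpm for the samples of a synthetic methylation cohort.
#' log1p(tpm) is Normal(mu_g + cluster effect, sd) truncated at zero and
#' transformed back with expm1, so all tpm are non-negative. Planted
#' effects come from the truth object: MYCN high in cluster C, NKX2-5 and
#' GATA4 high in B, TFF1 high in B and C, a photoreceptor set high in A,
#' cluster-exclusive signature genes, and the genes coupled to planted
#' CpGs.
#'
#' @param truth the `truth` element of [generate_methylation_cohort()].
#' @param config the same [cohort_config()].
#' @param seed integer seed.
#' @return An [expression_matrix()] over `truth$genes`.
#' @export
generate_expression_cohort <- function(truth, config = cohort_config(),
                                       seed = 1L) {
  if (is.null(truth$labels) || is.null(truth$genes)) {
    stop("truth must carry sample labels and a gene universe", call. = FALSE)
  }
  if (!all(truth$labels %in% names(config$cluster_sizes))) {
    stop("unknown sample labels in truth", call. = FALSE)
  }
  set.seed(seed + 1L)
  genes <- truth$genes
  n_genes <- length(genes)
  samples <- names(truth$labels)
  mu_g <- pmax(stats::rnorm(n_genes, mean = 2, sd = 1), 0.05)

  eff <- matrix(0, nrow = n_genes, ncol = length(config$cluster_sizes),
                dimnames = list(genes, names(config$cluster_sizes)))
  fx <- truth$gene_effects
  if (!is.null(fx) && nrow(fx) > 0) {
    for (i in seq_len(nrow(fx))) {
      eff[fx$gene[i], fx$cluster[i]] <- eff[fx$gene[i], fx$cluster[i]] +
        fx$effect[i]
    }
  }
  x <- mu_g + eff[, truth$labels, drop = FALSE] +
    matrix(stats::rnorm(n_genes * length(samples), sd = config$expr_sd),
           nrow = n_genes)
  x <- pmax(x, 0)
  tpm <- expm1(x)
  dimnames(tpm) <- list(genes, samples)
  expression_matrix(tpm)
}

#' Generate a synthetic inducible-knockdown expression experiment
#'
#' Emulates an inducible MYCN-knockdown screen: `kd_lines` cell lines,
#' each with induced and control conditions and `kd_replicates` replicates
#' per condition. Planted target genes are downregulated on induction in
#' every line; planted upregulated genes respond in every line; decoy
#' genes respond in all lines but one (round-robin over lines) and carry a
#' mild opposite-sign effect in that non-responding line, so the line-level
#' sign of a decoy is unambiguously not "down". All planted targets are
#' included in an emitted MYC(N)-target list together with
#' `kd_extra_targets` non-responding genes.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param genes optional gene universe (e.g. `truth$genes` of the matched
#'   tumor cohort, so knockdown signatures can be scored on the tumors);
#'   defaults to a standalone universe of `kd_n_genes` genes.
#' @return A list with `expr` (an [expression_matrix()] whose `samples`
#'   table has `line`, `condition`, `replicate`) and `truth` (targets,
#'   upregulated set, decoys with their non-responding line, and the
#'   target list).
#' @export
generate_knockdown_experiment <- function(config = cohort_config(),
                                          seed = 1L, genes = NULL) {
  validate_cohort_config(config)
  set.seed(seed + 2L)
  lines <- config$kd_lines
  reps <- as.integer(config$kd_replicates)
  if (is.null(genes)) {
    genes <- sprintf("KDGENE%05d", seq_len(as.integer(config$kd_n_genes)))
  }
  n_genes <- length(genes)

  mu_g <- pmax(stats::rnorm(n_genes, mean = 2, sd = 1), 0.05)
  ## responsive genes are planted among expressed genes: a knockdown
  ## effect cannot manifest at a silent locus (log1p tpm floored at 0)
  expressed <- which(mu_g >= abs(config$kd_target_effect) + 0.5)
  n_planted <- config$kd_n_targets + config$kd_n_up + config$kd_n_decoys
  if (length(expressed) < n_planted) {
    stop("too few expressed genes to plant the knockdown structure",
         call. = FALSE)
  }
  pick <- sample(expressed)
  targets <- genes[pick[seq_len(config$kd_n_targets)]]
  off <- config$kd_n_targets
  up_genes <- genes[pick[off + seq_len(config$kd_n_up)]]
  off <- off + config$kd_n_up
  decoys <- genes[pick[off + seq_len(config$kd_n_decoys)]]
  extra_pool <- setdiff(seq_len(n_genes), pick[seq_len(off + config$kd_n_decoys)])
  extra_targets <- genes[sample(extra_pool, min(config$kd_extra_targets,
                                                length(extra_pool)))]
  decoy_line <- lines[((seq_along(decoys) - 1L) %% length(lines)) + 1L]

  samples <- expand.grid(replicate = seq_len(reps),
                         condition = c("control", "induced"),
                         line = lines, stringsAsFactors = FALSE)
  samples <- samples[, c("line", "condition", "replicate")]
  samples$sample_id <- sprintf("%s_%s_%d", gsub("[^A-Za-z0-9]", "", samples$line),
                               samples$condition, samples$replicate)

  ## per-line baseline wobble so lines are not identical
  line_shift <- matrix(stats::rnorm(n_genes * length(lines), sd = 0.1),
                       nrow = n_genes, dimnames = list(genes, lines))

  eff <- matrix(0, nrow = n_genes, ncol = length(lines),
                dimnames = list(genes, lines))
  eff[targets, ] <- config$kd_target_effect
  eff[up_genes, ] <- abs(config$kd_target_effect) * 0.8
  eff[decoys, ] <- config$kd_target_effect
  for (i in seq_along(decoys)) {
    eff[decoys[i], decoy_line[i]] <- config$kd_decoy_other_effect
  }

  x <- matrix(0, nrow = n_genes, ncol = nrow(samples),
              dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    base <- mu_g + line_shift[, samples$line[j]]
    if (samples$condition[j] == "induced") {
      base <- base + eff[, samples$line[j]]
    }
    x[, j] <- pmax(base + stats::rnorm(n_genes, sd = config$kd_sd), 0)
  }
  tpm <- expm1(x)

  truth <- structure(list(
    knockdown_targets = targets,
    knockdown_up = up_genes,
    decoys = data.frame(gene = decoys, nonresponder_line = decoy_line,
                        stringsAsFactors = FALSE),
    target_list = c(targets, extra_targets)
  ), class = "SyntheticTruth")

  list(expr = expression_matrix(tpm, samples = samples), truth = truth)
}

#' Generate synthetic clinical metadata
#'
#' Per-sample age at diagnosis (log-normal with cluster-specific medians),
#' RB1 status and MYCN amplification status. Cluster C splits into an
#' RB1-proficient fraction (younger, all MYCN-amplified) and an RB1-null
#' fraction (older, a configurable fraction MYCN-amplified); clusters A
#' and B are RB1-null without amplification.
#'
#' @param truth the `truth` element of [generate_methylation_cohort()].
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return A data.frame with sample_id, cluster, age_years, rb1_status,
#'   mycn_status.
#' @export
generate_metadata <- function(truth, config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  if (is.null(truth$labels)) stop("truth must carry labels", call. = FALSE)
  set.seed(seed + 3L)
  labels <- truth$labels
  n <- length(labels)
  md <- data.frame(sample_id = names(labels),
                   cluster = unname(labels),
                   stringsAsFactors = FALSE)
  md$rb1_status <- "RB1_null"
  md$mycn_status <- "normal"

  idx_C <- which(md$cluster == "C")
  n_wt <- round(config$c_rb1_proficient_frac * length(idx_C))
  wt <- if (n_wt > 0) sample(idx_C, n_wt) else integer(0)
  md$rb1_status[wt] <- "RB1_wt"
  md$mycn_status[wt] <- "amplified"
  null_C <- setdiff(idx_C, wt)
  n_amp <- round(config$c_mycn_amp_rb1null_frac * length(null_C))
  if (n_amp > 0) md$mycn_status[sample(null_C, n_amp)] <- "amplified"

  med <- numeric(n)
  med[md$cluster == "A"] <- config$age_median_A
  med[md$cluster == "B"] <- config$age_median_B
  med[md$cluster == "C" & md$rb1_status == "RB1_wt"] <- config$age_median_C_rb1wt
  med[md$cluster == "C" & md$rb1_status == "RB1_null"] <- config$age_median_C_rb1null
  md$age_years <- stats::rlnorm(n, meanlog = log(med), sdlog = config$age_sdlog)
  md
}
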