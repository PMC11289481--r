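#' Configuration for the synthetic retinoblastoma cohort
#'
#' Bundles every knob of the synthetic-data generators: the methylation
#' cohort (probe count, planted cluster sizes, differential-methylation
#' fractions and effect, CpG-island composition, beta-noise precision),
#' the matched expression cohort (gene count, marker effects, residual sd),
#' the inducible-knockdown experiment and the clinical metadata.
#' Defaults emulate a 62-dataset methylation cohort with three planted
#' clusters (A/B/C of sizes 35/17/10): cluster C carries widespread
#' hypomethylation mostly outside CpG islands, cluster B carries focal
#' hypermethylation enriched in islands.
#'
#' @param n_probes number of CpG probes.
#' @param cluster_sizes named integer vector of planted cluster sizes
#'   (names become the cluster labels).
#' @param frac_dm_B fraction of probes hypermethylated in cluster B.
#' @param frac_dm_C fraction of probes hypomethylated in cluster C.
#' @param island_frac_dm_B fraction of B-hypermethylated probes flagged as
#'   CpG-island probes.
#' @param island_frac_dm_C fraction of C-hypomethylated probes flagged as
#'   CpG-island probes.
#' @param island_frac_background island fraction among non-DM probes.
#' @param delta planted absolute beta-value shift in the affected cluster.
#' @param concentration beta-noise precision kappa (>0); per-value noise is
#'   Beta(mu*kappa, (1-mu)*kappa), sd ~ sqrt(mu(1-mu)/(kappa+1)).
#' @param duplicate_sample logical; duplicate one cluster-A sample to mimic
#'   a cohort in which one tumor contributes two datasets (default off).
#' @param n_genes number of genes in the expression cohort.
#' @param expr_sd residual sd of log1p tpm within a cluster.
#' @param marker_effect log1p-scale effect for the named marker genes
#'   (MYCN up in C, NKX2-5/GATA4 up in B, TFF1 up in B and C).
#' @param n_signature_B,n_signature_C numbers of planted cluster-exclusive
#'   signature genes (effect `signature_effect` in that cluster only).
#' @param signature_effect log1p-scale effect of planted signature genes.
#' @param n_photoreceptor number of planted photoreceptor genes up in A.
#' @param n_pairs_negative,n_pairs_positive numbers of planted CpG-gene
#'   pairs with repressive (negative) and activating (positive)
#'   methylation-expression coupling.
#' @param kd_lines cell-line identifiers for the knockdown experiment.
#' @param kd_replicates replicates per line and condition (>= 2).
#' @param kd_n_genes gene universe of the knockdown experiment.
#' @param kd_n_targets planted targets downregulated on induction in all
#'   lines.
#' @param kd_target_effect log1p-scale knockdown effect (negative).
#' @param kd_n_up planted genes upregulated on induction in all lines.
#' @param kd_n_decoys negative-control genes downregulated in all but one
#'   line.
#' @param kd_decoy_other_effect effect of a decoy in its non-responding
#'   line; mildly positive so that the line-level sign is unambiguous.
#' @param kd_sd residual sd of log1p tpm in the knockdown experiment.
#' @param kd_extra_targets extra genes added to the MYC(N)-target list
#'   beyond the planted knockdown targets.
#' @param age_median_A,age_median_B age medians (years) for clusters A/B.
#' @param age_median_C_rb1wt,age_median_C_rb1null age medians for the
#'   RB1-proficient and RB1-null fractions of cluster C.
#' @param age_sdlog sd of log(age).
#' @param c_rb1_proficient_frac fraction of cluster C that is
#'   RB1-proficient (all of these are MYCN-amplified).
#' @param c_mycn_amp_rb1null_frac fraction of RB1-null cluster-C samples
#'   carrying a MYCN amplification.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_probes = 20000L,
                          cluster_sizes = c(A = 35L, B = 17L, C = 10L),
                          frac_dm_B = 0.005,
                          frac_dm_C = 0.05,
                          island_frac_dm_B = 0.335,
                          island_frac_dm_C = 0.084,
                          island_frac_background = 0.30,
                          delta = 0.3,
                          concentration = 50,
                          duplicate_sample = FALSE,
                          n_genes = 6000L,
                          expr_sd = 0.3,
                          marker_effect = 2,
                          n_signature_B = 50L,
                          n_signature_C = 50L,
                          signature_effect = 1,
                          n_photoreceptor = 25L,
                          n_pairs_negative = 150L,
                          n_pairs_positive = 60L,
                          kd_lines = c("RB355", "RB522", "RB3832", "WERI-Rb1"),
                          kd_replicates = 3L,
                          kd_n_genes = 6000L,
                          kd_n_targets = 250L,
                          kd_target_effect = -1.5,
                          kd_n_up = 80L,
                          kd_n_decoys = 30L,
                          kd_decoy_other_effect = 1,
                          kd_sd = 0.3,
                          kd_extra_targets = 250L,
                          age_median_A = 0.87,
                          age_median_B = 2.36,
                          age_median_C_rb1wt = 0.38,
                          age_median_C_rb1null = 2.86,
                          age_sdlog = 0.5,
                          c_rb1_proficient_frac = 0.6,
                          c_mycn_amp_rb1null_frac = 0.5) {
  cfg <- as.list(environment())
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(is.numeric(cfg$n_probes), cfg$n_probes >= 1)
  if (any(cfg$cluster_sizes <= 0)) {
    stop("cluster sizes must be positive", call. = FALSE)
  }
  if (is.null(names(cfg$cluster_sizes)) || anyDuplicated(names(cfg$cluster_sizes))) {
    stop("cluster_sizes must have unique names", call. = FALSE)
  }
  fracs <- c(cfg$frac_dm_B, cfg$frac_dm_C, cfg$island_frac_dm_B,
             cfg$island_frac_dm_C, cfg$island_frac_background,
             cfg$c_rb1_proficient_frac, cfg$c_mycn_amp_rb1null_frac)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$frac_dm_B + cfg$frac_dm_C > 1) {
    stop("frac_dm_B + frac_dm_C must not exceed 1", call. = FALSE)
  }
  if (cfg$delta <= 0 && cfg$delta != 0) stop("delta must be in [0, 1)", call. = FALSE)
  if (cfg$delta < 0 || cfg$delta >= 1) {
    stop("delta must be in [0, 1)", call. = FALSE)
  }
  if (cfg$concentration <= 0) {
    stop("concentration (kappa) must be > 0", call. = FALSE)
  }
  if (cfg$kd_replicates < 2) {
    stop("kd_replicates must be at least 2", call. = FALSE)
  }
  if (length(cfg$kd_lines) < 2) {
    stop("at least 2 knockdown lines are required", call. = FALSE)
  }
  meds <- c(cfg$age_median_A, cfg$age_median_B,
            cfg$age_median_C_rb1wt, cfg$age_median_C_rb1null)
  if (any(meds <= 0)) stop("age medians must be positive", call. = FALSE)
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  probes:", x$n_probes,
      " clusters:", paste(sprintf("%s=%d", names(x$cluster_sizes),
                                  x$cluster_sizes), collapse = " "), "\n")
  cat("  DM fractions: B", x$frac_dm_B, "(hyper)  C", x$frac_dm_C,
      "(hypo)  delta", x$delta, " kappa", x$concentration, "\n")
  cat("  genes:", x$n_genes, " knockdown:", length(x$kd_lines), "lines x",
      x$kd_replicates, "reps\n")
  invisible(x)
}
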