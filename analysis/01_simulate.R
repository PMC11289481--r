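#!/usr/bin/env Rscript
## Build the synthetic study cohort: a 62-dataset methylation cohort with
## three planted clusters (A/B/C = 35/17/10), the matched tumor expression
## cohort, a 4-line inducible MYCN-knockdown experiment, and clinical
## metadata. Everything downstream runs off the files written here.

library(rbsubtype)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config()
sim <- generate_methylation_cohort(cfg, seed = seed)
expr <- generate_expression_cohort(sim$truth, cfg, seed = seed)
kd <- generate_knockdown_experiment(cfg, seed = seed, genes = sim$truth$genes)
md <- generate_metadata(sim$truth, cfg, seed = seed)

write_matrix_tsv(sim$beta$values, file.path(out, "beta.tsv"), "probe_id")
data.table::fwrite(sim$beta$annotation, file.path(out, "probe_annotation.tsv"),
                   sep = "\t")
write_matrix_tsv(expr$tpm, file.path(out, "tpm.tsv"), "gene")
write_matrix_tsv(kd$expr$tpm, file.path(out, "knockdown_tpm.tsv"), "gene")
data.table::fwrite(kd$expr$samples, file.path(out, "knockdown_samples.tsv"),
                   sep = "\t")
data.table::fwrite(md, file.path(out, "metadata.tsv"), sep = "\t")
write_gmt(list(mycn_targets = kd$truth$target_list),
          file.path(out, "mycn_targets.gmt"))
jsonlite::write_json(
  list(labels = as.list(sim$truth$labels),
       dm_probes_B = sim$truth$dm_probes_B$probe_id,
       dm_probes_C = sim$truth$dm_probes_C$probe_id,
       signature_B = sim$truth$signature_B,
       signature_C = sim$truth$signature_C,
       knockdown_targets = kd$truth$knockdown_targets,
       decoys = kd$truth$decoys),
  file.path(out, "truth.json"), auto_unbox = TRUE)

cat(sprintf("wrote %d x %d beta matrix, %d x %d tpm, %d knockdown samples\n",
            nrow(sim$beta$values), ncol(sim$beta$values),
            nrow(expr$tpm), ncol(expr$tpm), ncol(kd$expr$tpm)))
cat(sprintf("planted: %d B-hyper, %d C-hypo probes; ages median A %.2f y\n",
            nrow(sim$truth$dm_probes_B), nrow(sim$truth$dm_probes_C),
            median(md$age_years[md$cluster == "A"])))
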