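#!/usr/bin/env Rscript
## Methylation-expression integration: Pearson correlation of each mapped
## CpG-gene pair across the cohort (variance >= 1e-4, BH-adjusted
## p < 0.05, |r| >= 0.4), classified as positive or negative regulation
## and summarized by island context and DM direction.

library(rbsubtype)

data_dir <- "results/data"
out <- "results/integration"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- as.data.frame(data.table::fread(file.path(data_dir,
                                                 "probe_annotation.tsv")))
beta <- beta_matrix(read_matrix_tsv(file.path(data_dir, "beta.tsv")), ann)
expr <- expression_matrix(read_matrix_tsv(file.path(data_dir, "tpm.tsv")))
mapping <- ann[!is.na(ann$gene) & ann$gene != "",
               c("probe_id", "gene", "island")]

res <- correlate_cpg_gene(beta, expr, mapping)
dm_tabs <- list.files("results/diffmeth", pattern = "^dm_.*tsv$",
                      full.names = TRUE)
dm <- do.call(rbind, lapply(dm_tabs, function(f)
  as.data.frame(data.table::fread(f))))
sm <- summarize_correlations(res, dm = dm)

n_neg <- sum(res$sign_class == "negative")
n_pos <- sum(res$sign_class == "positive")
cat(sprintf("%d CpG-gene pairs tested; %d negatively (%d genes), %d positively (%d genes) correlated\n",
            nrow(res), n_neg, length(unique(res$gene[res$sign_class == "negative"])),
            n_pos, length(unique(res$gene[res$sign_class == "positive"]))))

data.table::fwrite(res, file.path(out, "correlations.tsv"), sep = "\t")
data.table::fwrite(sm, file.path(out, "correlation_summary.tsv"), sep = "\t")
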