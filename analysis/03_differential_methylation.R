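#!/usr/bin/env Rscript
## One-vs-rest differential methylation for clusters B and C: Welch test,
## BH adjustment, |delta beta| >= 0.2 at adjusted p < 0.001, direction
## labels, CpG-island partition. Runs at the planted labels so the called
## sets are comparable against the generator truth regardless of how the
## consensus stage resolved the cohort (see 02's report for that result).

library(rbsubtype)

data_dir <- "results/data"
out <- "results/diffmeth"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- as.data.frame(data.table::fread(file.path(data_dir,
                                                 "probe_annotation.tsv")))
beta <- beta_matrix(read_matrix_tsv(file.path(data_dir, "beta.tsv")), ann)
truth <- jsonlite::read_json(file.path(data_dir, "truth.json"))
labels <- unlist(truth$labels)

summary <- list()
for (target in intersect(c("B", "C"), unique(labels))) {
  dm <- call_dm_probes(beta, labels, target)
  isl <- island_partition(dm)
  data.table::fwrite(dm, file.path(out, sprintf("dm_%s.tsv", target)),
                     sep = "\t")
  n_pass <- sum(dm$pass)
  hyper <- mean(dm$direction[dm$pass] == "hyper")
  cat(sprintf("cluster %s vs rest: %d DM probes (%.0f%% %s), %.1f%% in islands\n",
              target, n_pass, 100 * max(hyper, 1 - hyper),
              if (hyper >= 0.5) "hypermethylated" else "hypomethylated",
              100 * isl$fraction_in))
  summary[[target]] <- list(n_pass = n_pass,
                            fraction_hyper = hyper,
                            fraction_in_islands = isl$fraction_in)
}
jsonlite::write_json(summary, file.path(out, "summary.json"),
                     auto_unbox = TRUE, digits = NA)
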