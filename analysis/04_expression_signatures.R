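#!/usr/bin/env Rscript
## Expression side of the analysis: cluster-B and cluster-C signatures by
## step-wise statistical filtering over the one-vs-one contrasts, per-
## sample signature scores, and the MYCN-RB signature from the inducible
## knockdown experiment (per-line Welch tests on log1p tpm, Edgington
## combination, Storey q-values, all-lines sign rule, MYC(N)-target
## intersection).

library(rbsubtype)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
data_dir <- "results/data"
out <- "results/signatures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr <- expression_matrix(read_matrix_tsv(file.path(data_dir, "tpm.tsv")))
truth <- jsonlite::read_json(file.path(data_dir, "truth.json"))
labels <- unlist(truth$labels)

sigs <- derive_cluster_signatures(expr, labels)
cat(sprintf("cluster B signature: %d genes; cluster C signature: %d genes\n",
            length(sigs$signature_B$genes), length(sigs$signature_C$genes)))

kd_tpm <- read_matrix_tsv(file.path(data_dir, "knockdown_tpm.tsv"))
kd_samples <- as.data.frame(data.table::fread(
  file.path(data_dir, "knockdown_samples.tsv")))
kd_expr <- expression_matrix(kd_tpm, samples = kd_samples)
targets <- read_gmt(file.path(data_dir, "mycn_targets.gmt"))

kd_res <- derive_mycn_rb_signature(kd_expr, targets, q_max = 0.1)
n_down <- sum(kd_res$common$direction == "down")
cat(sprintf("knockdown common set: %d genes (%d up, %d down), pi0 %.2f\n",
            nrow(kd_res$common), nrow(kd_res$common) - n_down, n_down,
            kd_res$pi0))
cat(sprintf("MYCN-RB signature: %d commonly downregulated known targets\n",
            length(kd_res$signature$genes)))

write_gmt(list(cluster_B = sigs$signature_B,
               cluster_C = sigs$signature_C,
               MYCN_RB = kd_res$signature), file.path(out, "signatures.gmt"))
data.table::fwrite(kd_res$common, file.path(out, "knockdown_common.tsv"),
                   sep = "\t")

## score the tumor cohort on every signature, plus pi-ranking of the
## knockdown response
scores <- rbind(cluster_B = signature_score(expr, sigs$signature_B),
                cluster_C = signature_score(expr, sigs$signature_C),
                MYCN_RB = signature_score(expr, kd_res$signature))
write_matrix_tsv(scores, file.path(out, "signature_scores.tsv"), "signature")

b_mean <- rowMeans(vapply(kd_res$tests, function(d) d$b,
                          numeric(nrow(kd_res$tests[[1]]))))
p_comb <- vapply(seq_along(b_mean), function(i) {
  edgington_combine(vapply(kd_res$tests, function(d) d$p[i], numeric(1)))
}, numeric(1))
pi <- pi_rank(b_mean, pmax(p_comb, .Machine$double.xmin))
rank_tab <- data.frame(gene = kd_res$tests[[1]]$gene, b_mean = b_mean,
                       p_combined = p_comb, pi = pi)
rank_tab <- rank_tab[order(-abs(rank_tab$pi)), ]
data.table::fwrite(rank_tab, file.path(out, "knockdown_pi_ranking.tsv"),
                   sep = "\t")
cat("top pi-ranked knockdown genes:",
    paste(head(rank_tab$gene, 5), collapse = ", "), "\n")

md <- as.data.frame(data.table::fread(file.path(data_dir, "metadata.tsv")))
mycn_scores <- scores["MYCN_RB", md$sample_id]
cat(sprintf("MYCN-RB score by cluster: A %.2f, B %.2f, C %.2f\n",
            mean(mycn_scores[md$cluster == "A"]),
            mean(mycn_scores[md$cluster == "B"]),
            mean(mycn_scores[md$cluster == "C"])))
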