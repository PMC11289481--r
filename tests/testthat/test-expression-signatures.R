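make_expr <- function(tpm, samples = NULL) expression_matrix(tpm, samples)

test_that("de_test reports b on the log1p scale with Welch p-values", {
  tpm <- matrix(c(rep(e <- exp(2) - 1, 6), rep(0, 6)), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  expr <- make_expr(tpm)
  de <- de_test(expr, paste0("s", 1:3), paste0("s", 4:6))
  ## identical groups: b = 0, p = 1; all-zero gene flagged
  expect_equal(de$b, c(0, 0))
  expect_equal(de$p, c(1, 1))
  expect_true(de$all_zero[2])
  expect_error(de_test(expr, "s1", paste0("s", 2:4)), "at least 2")
})

test_that("de_test recovers a planted effect at small n", {
  set.seed(13)
  n_genes <- 200
  x <- matrix(rnorm(n_genes * 6, mean = 3, sd = 0.2), n_genes, 6)
  x[, 1:3] <- x[, 1:3] + 2
  tpm <- expm1(pmax(x, 0))
  dimnames(tpm) <- list(paste0("g", 1:n_genes), paste0("s", 1:6))
  de <- de_test(make_expr(tpm), paste0("s", 1:3), paste0("s", 4:6))
  expect_gte(mean(abs(de$b - 2) < 0.5), 0.95)
  expect_gte(mean(de$p < 0.05), 0.95)
})

test_that("Storey pi0 is near 1 on null p-values and q preserves order", {
  set.seed(17)
  ok <- 0
  for (s in 1:20) {
    p <- runif(1000)
    st <- storey_qvalues(p)
    if (st$pi0 >= 0.85 && st$pi0 <= 1.0) ok <- ok + 1
    if (s <= 3) {
      expect_true(all(diff(st$q[order(p)]) >= -1e-12))
      expect_true(all(st$q >= 0 & st$q <= 1))
    }
  }
  expect_gte(ok, 19)
})

test_that("Storey q-values with pi0 = 1 reproduce BH exactly", {
  set.seed(19)
  p <- c(runif(150), rbeta(50, 0.2, 5))
  st <- storey_qvalues(p, pi0 = 1)
  expect_equal(st$q, bh_adjust(p), tolerance = 1e-12)
  ## short input falls back to BH with a warning
  expect_warning(st2 <- storey_qvalues(runif(5)), "fewer than 20")
  expect_equal(st2$pi0, 1)
})

test_that("Edgington combination matches closed-form and Monte-Carlo", {
  expect_equal(edgington_combine(0.37), 0.37)
  expect_equal(edgington_combine(c(0.1, 0.2)), 0.045)
  expect_equal(edgington_combine(c(1, 1)), 1)
  expect_error(edgington_combine(numeric(0)), "at least one")
  ## Monte-Carlo oracle at k = 2, 3, 5 within 3 standard errors
  set.seed(23)
  for (k in c(2, 3, 5)) {
    p <- runif(k, 0.05, 0.5)
    s <- sum(p)
    draws <- matrix(runif(1e6 * k), ncol = k)
    mc <- mean(rowSums(draws) <= s)
    se <- sqrt(mc * (1 - mc) / 1e6)
    expect_lt(abs(edgington_combine(p) - mc), 3 * se + 1e-9)
  }
})

test_that("pi-value ranking follows its definition", {
  expect_equal(pi_rank(2, 0.01), 4)
  expect_equal(pi_rank(3, 1), 0)
  b <- c(-1.2, 0.5, 2)
  p <- c(0.001, 0.2, 0.04)
  expect_equal(sign(pi_rank(b, p)), sign(b))
  expect_warning(out <- pi_rank(1, 0), "floored")
  expect_true(is.finite(out) && out > 0)
})

test_that("signature scores are mean log1p tpm and order-invariant", {
  tpm <- matrix(c(exp(1) - 1, 3, 10, 0, 0, 0), nrow = 3,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  expr <- make_expr(tpm)
  sig1 <- gene_signature("one", "g1")
  expect_equal(unname(signature_score(expr, sig1)["s1"]), 1)
  ## all-zero sample scores 0
  sig_all <- gene_signature("all", c("g1", "g2", "g3"))
  expect_equal(unname(signature_score(expr, sig_all)["s2"]), 0)
  ## permuting the gene order leaves scores unchanged
  sig_rev <- gene_signature("rev", c("g3", "g2", "g1"))
  expect_equal(unname(signature_score(expr, sig_all)),
               unname(signature_score(expr, sig_rev)))
  ## absent genes are reported; all-absent errors
  sig_mix <- gene_signature("mix", c("g1", "nope"))
  expect_equal(attr(signature_score(expr, sig_mix), "missing_genes"), "nope")
  expect_error(signature_score(expr, gene_signature("none", "nope")),
               "no signature gene")
  expect_warning(gene_signature("dup", c("g1", "g1")), "duplicate")
})

test_that("cluster signatures recover planted cluster-exclusive genes", {
  sim <- small_cohort()
  expr <- small_expression()
  sigs <- derive_cluster_signatures(expr, sim$truth$labels)
  expect_gte(mean(sim$truth$signature_B %in% sigs$signature_B$genes), 0.9)
  expect_gte(mean(sim$truth$signature_C %in% sigs$signature_C$genes), 0.9)
  ## exclusivity: no planted B gene in the C signature and vice versa
  expect_equal(mean(sim$truth$signature_B %in% sigs$signature_C$genes), 0)
  expect_equal(mean(sim$truth$signature_C %in% sigs$signature_B$genes), 0)
  ## TFF1 is up in both B and C, hence excluded from both signatures
  expect_false("TFF1" %in% sigs$signature_B$genes)
  expect_false("TFF1" %in% sigs$signature_C$genes)
  expect_error(derive_cluster_signatures(expr, rep("A", 62)), "populated")
})

test_that("no passing gene yields two flagged empty signatures", {
  set.seed(29)
  tpm <- matrix(rexp(50 * 12), 50,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  labels <- setNames(rep(c("A", "B", "C"), each = 4), paste0("s", 1:12))
  expect_warning(
    sigs <- derive_cluster_signatures(make_expr(tpm), labels, q_max = 1e-12),
    "signatures empty")
  expect_length(sigs$signature_B$genes, 0)
  expect_length(sigs$signature_C$genes, 0)
})

test_that("MYCN-RB derivation applies the all-lines and target rules", {
  cfg <- cohort_config(kd_n_genes = 2000L, kd_n_targets = 120L,
                       kd_n_up = 30L, kd_n_decoys = 12L,
                       kd_extra_targets = 80L)
  kd <- generate_knockdown_experiment(cfg, seed = 11L)
  res <- derive_mycn_rb_signature(kd$expr,
                                  list(targets = kd$truth$target_list))
  expect_gte(mean(kd$truth$knockdown_targets %in% res$signature$genes), 0.95)
  ## genes downregulated in only 3 of 4 lines never enter the common set
  expect_equal(sum(kd$truth$decoys$gene %in% res$common$gene), 0L)
  ## signature genes are all known targets and all downregulated
  expect_true(all(res$signature$genes %in% kd$truth$target_list))
  expect_true(all(res$signature$direction == "down"))
  ## a disjoint target list empties the signature
  res2 <- derive_mycn_rb_signature(kd$expr, list(none = c("NOT_A_GENE")))
  expect_length(res2$signature$genes, 0)
  expect_warning(derive_mycn_rb_signature(kd$expr, list()), "empty target")
})

test_that("MYCN-RB derivation is invariant to gene and sample order", {
  cfg <- cohort_config(kd_n_genes = 600L, kd_n_targets = 40L,
                       kd_n_up = 10L, kd_n_decoys = 4L,
                       kd_extra_targets = 20L)
  kd <- generate_knockdown_experiment(cfg, seed = 31L)
  res1 <- derive_mycn_rb_signature(kd$expr, list(t = kd$truth$target_list))
  set.seed(1)
  gperm <- sample(nrow(kd$expr$tpm))
  sperm <- sample(ncol(kd$expr$tpm))
  expr2 <- expression_matrix(kd$expr$tpm[gperm, sperm],
                             samples = kd$expr$samples[sperm, ])
  res2 <- derive_mycn_rb_signature(expr2, list(t = kd$truth$target_list))
  expect_setequal(res1$signature$genes, res2$signature$genes)
  expect_setequal(res1$common$gene, res2$common$gene)
})

test_that("probe classifier separates groups and applies substitutions", {
  set.seed(37)
  probes <- sprintf("cls%02d", 1:8)
  n1 <- 10; n2 <- 8
  v <- cbind(matrix(rbeta(8 * n1, 2, 10), 8),     # low-methylation group
             matrix(rbeta(8 * n2, 10, 2), 8))     # high-methylation group
  rownames(v) <- probes
  colnames(v) <- paste0("s", 1:(n1 + n2))
  bm <- beta_matrix(v)
  ref <- setNames(rep(0.15, 8), probes)  # profile of the low group
  subtypes <- classifier_subtypes(bm, probes, reference = ref,
                                  reference_label = "subtype1")
  expect_true(all(subtypes[1:n1] == "subtype1"))
  expect_true(all(subtypes[(n1 + 1):(n1 + n2)] == "subtype2"))
  ## substitution map fills in for a missing probe
  v2 <- v
  rownames(v2)[1] <- "epic01"
  bm2 <- beta_matrix(v2)
  subtypes2 <- classifier_subtypes(bm2, probes,
                                   substitutions = c(cls01 = "epic01"),
                                   reference = setNames(ref, c("epic01", probes[-1])))
  expect_equal(unname(subtypes2), unname(subtypes))
  ## unresolvable probe errors with its name; single sample errors
  expect_error(classifier_subtypes(bm2, probes), "cls01")
  one <- beta_matrix(v[, 1, drop = FALSE])
  expect_error(classifier_subtypes(one, probes), "2 samples")
})
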