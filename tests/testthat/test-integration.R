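toy_pair_data <- function() {
  ## 8 samples, hand-checkable vectors
  samples <- paste0("s", 1:8)
  bvals <- c(0.12, 0.25, 0.33, 0.41, 0.55, 0.62, 0.78, 0.91)
  tpm <- c(9.1, 7.6, 7.2, 5.9, 4.4, 3.8, 2.1, 0.9)
  beta <- beta_matrix(matrix(bvals, 1, dimnames = list("cg1", samples)))
  expr <- expression_matrix(matrix(tpm, 1, dimnames = list("g1", samples)))
  list(beta = beta, expr = expr, bvals = bvals, tpm = tpm)
}

test_that("Pearson r matches the definition formula on an 8-sample toy", {
  td <- toy_pair_data()
  mapping <- data.frame(probe_id = "cg1", gene = "g1", island = FALSE)
  res <- correlate_cpg_gene(td$beta, td$expr, mapping, max_adj_p = 1)
  x <- td$bvals; y <- log1p(td$tpm)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$sign_class, "negative")
})

test_that("a perfect linear anti-relation gives r = -1, class negative", {
  samples <- paste0("s", 1:6)
  expr_v <- c(0.2, 0.5, 1.1, 1.9, 2.6, 3.0)
  bvals <- 1 - 0.25 * expr_v
  beta <- beta_matrix(matrix(bvals, 1, dimnames = list("cg1", samples)))
  expr <- expression_matrix(matrix(expm1(expr_v), 1,
                                   dimnames = list("g1", samples)))
  res <- correlate_cpg_gene(beta, expr,
                            data.frame(probe_id = "cg1", gene = "g1"))
  expect_equal(res$r, -1, tolerance = 1e-12)
  expect_equal(res$sign_class, "negative")
  expect_equal(res$p, 0)
})

test_that("r is invariant to affine rescaling of either variable", {
  set.seed(41)
  samples <- paste0("s", 1:10)
  b1 <- runif(10, 0.2, 0.8)
  y <- 2 - b1 + rnorm(10, sd = 0.1)
  mk <- function(bv, ev) {
    list(beta = beta_matrix(matrix(bv, 1, dimnames = list("cg1", samples))),
         expr = expression_matrix(matrix(expm1(ev), 1,
                                         dimnames = list("g1", samples))))
  }
  m1 <- mk(b1, y)
  ## affine transform on beta (kept inside [0,1]) and on log1p expression
  m2 <- mk(0.5 * b1 + 0.1, 3 * y + 1)
  mapping <- data.frame(probe_id = "cg1", gene = "g1")
  r1 <- correlate_cpg_gene(m1$beta, m1$expr, mapping)$r
  r2 <- correlate_cpg_gene(m2$beta, m2$expr, mapping)$r
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("variance filter and missing genes are handled and reported", {
  samples <- paste0("s", 1:6)
  v <- rbind(cg1 = rep(0.5, 6),                    # constant -> filtered
             cg2 = c(0.2, 0.3, 0.4, 0.6, 0.7, 0.8))
  colnames(v) <- samples
  tpm <- matrix(rexp(6), 1, dimnames = list("g1", samples))
  mapping <- data.frame(probe_id = c("cg1", "cg2", "cg2"),
                        gene = c("g1", "g1", "absent"))
  res <- correlate_cpg_gene(beta_matrix(v), expression_matrix(tpm), mapping)
  expect_equal(nrow(res), 1L)
  expect_equal(res$probe_id, "cg2")
  expect_equal(attr(res, "n_variance_filtered"), 1L)
  expect_equal(attr(res, "skipped")$gene, "absent")
  ## fewer than 4 shared samples is an error
  expect_error(correlate_cpg_gene(
    beta_matrix(v[, 1:3]), expression_matrix(tpm[, 1:3, drop = FALSE]),
    mapping), "4 shared")
})

test_that("summaries count pairs and distinct genes per class", {
  res <- data.frame(probe_id = c("c1", "c2", "c3"),
                    gene = c("g1", "g1", "g2"),
                    island = c(TRUE, TRUE, FALSE),
                    r = c(-0.9, -0.8, 0.7),
                    p = c(1e-5, 1e-4, 1e-3),
                    p_adj = c(1e-4, 1e-3, 1e-2),
                    sign_class = c("negative", "negative", "positive"))
  class(res) <- c("CorrelationResult", "data.frame")
  sm <- summarize_correlations(res)
  neg <- sm[sm$sign_class == "negative", ]
  expect_equal(neg$n_pairs, 2L)
  expect_equal(neg$n_genes, 1L)
  expect_true(all(sm$n_pairs >= sm$n_genes))
  ## empty input: all-zero summary
  sm0 <- summarize_correlations(res[0, ])
  expect_equal(nrow(sm0), 0L)
})

test_that("planted repressive CpG-gene couplings are recovered", {
  sim <- small_cohort()
  expr <- small_expression()
  ann <- sim$beta$annotation
  mapping <- ann[!is.na(ann$gene), c("probe_id", "gene", "island")]
  res <- correlate_cpg_gene(sim$beta, expr, mapping)
  truth <- sim$truth$coupled_pairs
  key <- paste(res$probe_id, res$gene)
  negs <- truth[truth$sign == "negative", ]
  expect_gte(mean(paste(negs$probe_id, negs$gene) %in%
                    key[res$sign_class == "negative"]), 0.9)
  poss <- truth[truth$sign == "positive", ]
  expect_gte(mean(paste(poss$probe_id, poss$gene) %in%
                    key[res$sign_class == "positive"]), 0.9)
  ## BH here is the shared adjustment, bit for bit
  expect_identical(res$p_adj, bh_adjust(res$p))
})
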