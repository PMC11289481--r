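test_that("methylation cohort has the configured shape and planted labels", {
  sim <- small_cohort()
  cfg <- small_config()
  expect_equal(dim(sim$beta$values), c(2500L, 62L))
  expect_equal(as.vector(table(sim$truth$labels)[c("A", "B", "C")]),
               c(35L, 17L, 10L))
  expect_true(all(sim$beta$values > 0 & sim$beta$values < 1))
  expect_equal(nrow(sim$truth$dm_probes_B), round(cfg$frac_dm_B * 2500))
  expect_equal(nrow(sim$truth$dm_probes_C), round(cfg$frac_dm_C * 2500))
  expect_length(intersect(sim$truth$dm_probes_B$probe_id,
                          sim$truth$dm_probes_C$probe_id), 0)
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- cohort_config(n_probes = 400L, n_genes = 300L, kd_n_genes = 800L,
                       kd_n_targets = 40L, kd_n_up = 10L, kd_n_decoys = 8L,
                       kd_extra_targets = 20L, n_signature_B = 10L,
                       n_signature_C = 10L, n_photoreceptor = 5L,
                       n_pairs_negative = 15L, n_pairs_positive = 6L)
  a <- generate_methylation_cohort(cfg, seed = 9L)
  b <- generate_methylation_cohort(cfg, seed = 9L)
  expect_identical(a$beta$values, b$beta$values)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_expression_cohort(a$truth, cfg, 9L)$tpm,
                   generate_expression_cohort(b$truth, cfg, 9L)$tpm)
  expect_identical(generate_knockdown_experiment(cfg, 9L)$expr$tpm,
                   generate_knockdown_experiment(cfg, 9L)$expr$tpm)
  expect_identical(generate_metadata(a$truth, cfg, 9L),
                   generate_metadata(a$truth, cfg, 9L))
})

test_that("planted island fractions are recovered from the annotation", {
  sim <- small_cohort()
  ann <- sim$beta$annotation
  isl_B <- ann$island[match(sim$truth$dm_probes_B$probe_id, ann$probe_id)]
  isl_C <- ann$island[match(sim$truth$dm_probes_C$probe_id, ann$probe_id)]
  expect_equal(mean(isl_B), 0.335, tolerance = 0.1)
  expect_equal(mean(isl_C), 0.084, tolerance = 0.05)
})

test_that("expression cohort carries the planted marker effects", {
  sim <- small_cohort()
  expr <- small_expression()
  expect_true(all(expr$tpm >= 0))
  lab <- sim$truth$labels
  lt <- log1p(expr$tpm)
  eff <- mean(lt["MYCN", lab == "C"]) - mean(lt["MYCN", lab == "A"])
  se <- sqrt(stats::var(lt["MYCN", lab == "C"]) / 10 +
             stats::var(lt["MYCN", lab == "A"]) / 35)
  expect_lt(abs(eff - 2), 3 * se + 0.02)
  ## TFF1 is up in both B and C
  expect_gt(mean(lt["TFF1", lab %in% c("B", "C")]),
            mean(lt["TFF1", lab == "A"]) + 0.5)
})

test_that("a zero-effect expression cohort yields uniform group-test p-values", {
  cfg <- cohort_config(n_probes = 400L, n_genes = 1500L, marker_effect = 0,
                       signature_effect = 0, n_pairs_negative = 15L,
                       n_pairs_positive = 6L)
  sim <- generate_methylation_cohort(cfg, seed = 5L)
  expr <- generate_expression_cohort(sim$truth, cfg, seed = 5L)
  lab <- sim$truth$labels
  de <- de_test(expr, names(lab)[lab == "B"], names(lab)[lab == "A"])
  ## Kolmogorov-Smirnov against uniform on the non-degenerate genes
  keep <- !de$all_zero
  ks <- suppressWarnings(stats::ks.test(de$p[keep], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("knockdown experiment has the configured layout", {
  cfg <- cohort_config(kd_n_genes = 1000L, kd_n_targets = 50L,
                       kd_n_up = 15L, kd_n_decoys = 8L,
                       kd_extra_targets = 30L)
  kd <- generate_knockdown_experiment(cfg, seed = 3L)
  expect_equal(ncol(kd$expr$tpm), 24L)
  ann <- kd$expr$samples
  tab <- table(ann$line, ann$condition)
  expect_true(all(tab == 3L))
  expect_true(all(kd$expr$tpm >= 0))
  expect_true(all(kd$truth$knockdown_targets %in% kd$truth$target_list))
  ## every decoy has exactly one non-responding line
  expect_equal(nrow(kd$truth$decoys), 8L)
  expect_true(all(kd$truth$decoys$nonresponder_line %in% cfg$kd_lines))
})

test_that("metadata reproduces the cluster-specific age structure", {
  sim <- small_cohort()
  md <- generate_metadata(sim$truth, small_config(), seed = 1L)
  expect_equal(median(md$age_years[md$cluster == "A"]), 0.87,
               tolerance = 0.35)
  expect_equal(median(md$age_years[md$cluster == "B"]), 2.36,
               tolerance = 0.5)
  ## cluster C: RB1-proficient fraction is young and MYCN-amplified
  cw <- md[md$cluster == "C" & md$rb1_status == "RB1_wt", ]
  expect_equal(nrow(cw), 6L)
  expect_true(all(cw$mycn_status == "amplified"))
  expect_true(all(md$mycn_status[md$cluster %in% c("A", "B")] == "normal"))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(cluster_sizes = c(A = 0L, B = 5L, C = 5L)),
               "positive")
  expect_error(cohort_config(concentration = 0), "kappa")
  expect_error(cohort_config(frac_dm_B = 0.7, frac_dm_C = 0.5), "exceed")
  expect_error(cohort_config(delta = 1.2), "delta")
  expect_error(cohort_config(kd_replicates = 1L), "at least 2")
  expect_error(cohort_config(age_median_A = -1), "positive")
})
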