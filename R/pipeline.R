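#' Pipeline configuration
#'
#' One declarative object driving [run_pipeline()]. Every analysis
#' threshold defaults to the study's stated value: beta-value mean
#' difference 0.2 at adjusted p < 0.001 for differential methylation,
#' >= 10 definite samples for the probe filter, silhouette cutoff 0 and
#' edge threshold 0.5 for the consensus graph, |b| >= 0.3 and q <= 0.05
#' for the cluster signatures, q <= 0.1 for the knockdown common set, and
#' variance >= 1e-4, |r| >= 0.4 at adjusted p < 0.05 for the
#' methylation-expression correlation.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed; fans out deterministically to every
#'   stochastic stage.
#' @param cohort a [cohort_config()] for the simulate stage.
#' @param stages character vector of stages to run, in order.
#' @param grid clustering grid (default [clustering_grid()]).
#' @param min_definite,edge_threshold,silhouette_cutoff,min_delta,max_adj_p
#'   stage parameters (see module functions).
#' @param sig_q_max,sig_b_min,kd_q_max,var_min,r_min,corr_max_adj_p more
#'   stage parameters.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "results/pipeline",
                            seed = 1L,
                            cohort = cohort_config(),
                            stages = c("simulate", "discretize", "cluster",
                                       "diffmeth", "signatures", "integrate"),
                            grid = clustering_grid(),
                            min_definite = 10L,
                            edge_threshold = 0.5,
                            silhouette_cutoff = 0,
                            min_delta = 0.2,
                            max_adj_p = 0.001,
                            sig_q_max = 0.05,
                            sig_b_min = 0.3,
                            kd_q_max = 0.1,
                            var_min = 1e-4,
                            r_min = 0.4,
                            corr_max_adj_p = 0.05) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the enabled stages in order on a synthetic cohort: simulate,
#' discretize (global beta-mixture fit + probe filter), cluster (ensemble
#' consensus), diffmeth (one-vs-rest for clusters B and C at the consensus
#' labels), signatures (cluster signatures from the matched expression
#' cohort and the MYCN-RB signature from the knockdown experiment) and
#' integrate (CpG-expression correlation). Writes each stage's tables
#' under `out_dir` and a JSON run report with per-stage counts, the seeds
#' used, a parameter echo and md5 checksums of every written file. A stage
#' failure aborts with an error naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return The run report, invisibly; also written to
#'   `out_dir/run_report.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ## inputs must exist up front when the simulate stage is disabled
  if (!"simulate" %in% config$stages) {
    beta_path <- file.path(config$out_dir, "beta.tsv")
    if (!file.exists(beta_path)) {
      stop("input file missing: ", beta_path, call. = FALSE)
    }
  }
  report <- list(seed = config$seed,
                 parameters = config[setdiff(names(config),
                                             c("grid", "cohort"))],
                 stages = list())
  files <- character(0)
  state <- new.env(parent = emptyenv())

  stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res$elapsed_s <- round(as.numeric(difftime(Sys.time(), t0, "secs")), 2)
    report$stages[[name]] <<- res
  }
  out <- function(name) file.path(config$out_dir, name)
  track <- function(path) { files <<- c(files, path); path }

  stage("simulate", function() {
    sim <- generate_methylation_cohort(config$cohort, seed = config$seed)
    state$beta <- sim$beta
    state$truth <- sim$truth
    state$expr <- generate_expression_cohort(sim$truth, config$cohort,
                                             seed = config$seed)
    state$kd <- generate_knockdown_experiment(config$cohort,
                                              seed = config$seed,
                                              genes = sim$truth$genes)
    state$metadata <- generate_metadata(sim$truth, config$cohort,
                                        seed = config$seed)
    write_matrix_tsv(state$beta$values, track(out("beta.tsv")), "probe_id")
    data.table::fwrite(state$beta$annotation,
                       track(out("probe_annotation.tsv")), sep = "\t")
    write_matrix_tsv(state$expr$tpm, track(out("tpm.tsv")), "gene")
    data.table::fwrite(state$metadata, track(out("metadata.tsv")), sep = "\t")
    jsonlite::write_json(list(labels = as.list(state$truth$labels)),
                         track(out("truth_labels.json")), auto_unbox = TRUE)
    list(n_probes = nrow(state$beta$values),
         n_samples = ncol(state$beta$values),
         n_genes = nrow(state$expr$tpm))
  })

  stage("discretize", function() {
    if (is.null(state$beta)) {
      path <- out("beta.tsv")
      if (!file.exists(path)) {
        stop("input file missing: ", path, call. = FALSE)
      }
      state$beta <- beta_matrix(read_matrix_tsv(path))
    }
    model <- fit_beta_mixture(as.vector(state$beta$values))
    disc <- discretize(state$beta, model)
    disc <- filter_informative_probes(disc, config$min_definite)
    state$model <- model
    state$disc <- disc
    write_mixture_json(model, track(out("beta_mixture.json")))
    write_matrix_tsv_states(disc, track(out("discrete.tsv")))
    list(t_low = model$t_low, t_high = model$t_high,
         converged = model$converged,
         n_informative = nrow(disc$states),
         n_removed = attr(disc, "removed"))
  })

  stage("cluster", function() {
    cg <- consensus_cluster(state$disc, grid = config$grid,
                            threshold = config$edge_threshold,
                            silhouette_cutoff = config$silhouette_cutoff,
                            seed = config$seed)
    state$consensus <- cg
    state$labels <- cluster_letters(cg$components)
    write_matrix_tsv(cg$similarity, track(out("similarity.tsv")), "sample_id")
    data.table::fwrite(cg$runs, track(out("run_manifest.tsv")), sep = "\t")
    data.table::fwrite(data.frame(sample_id = names(state$labels),
                                  component = unname(cg$components),
                                  cluster = unname(state$labels)),
                       track(out("components.tsv")), sep = "\t")
    list(n_runs = cg$n_runs, n_retained = cg$n_retained,
         n_components = length(unique(cg$components)),
         component_sizes = as.integer(table(cg$components)))
  })

  stage("diffmeth", function() {
    labels <- state$labels
    res <- list()
    for (cl in intersect(c("B", "C"), unique(labels))) {
      dm <- call_dm_probes(state$beta, labels, cl,
                           min_delta = config$min_delta,
                           max_adj_p = config$max_adj_p)
      isl <- island_partition(dm)
      data.table::fwrite(dm, track(out(sprintf("dm_%s.tsv", cl))),
                         sep = "\t")
      state[[paste0("dm_", cl)]] <- dm
      res[[cl]] <- list(n_pass = sum(dm$pass),
                        n_hyper = sum(dm$pass & dm$direction == "hyper"),
                        n_hypo = sum(dm$pass & dm$direction == "hypo"),
                        fraction_in_islands = isl$fraction_in)
    }
    res
  })

  stage("signatures", function() {
    sigs <- derive_cluster_signatures(state$expr, state$labels,
                                      q_max = config$sig_q_max,
                                      b_min = config$sig_b_min)
    kd_res <- derive_mycn_rb_signature(state$kd$expr,
                                       list(mycn_targets =
                                              state$kd$truth$target_list),
                                       q_max = config$kd_q_max)
    state$signatures <- sigs
    state$mycn_rb <- kd_res
    write_gmt(list(cluster_B = sigs$signature_B,
                   cluster_C = sigs$signature_C,
                   MYCN_RB = kd_res$signature),
              track(out("signatures.gmt")))
    scores <- rbind(
      signature_score(state$expr, sigs$signature_B),
      signature_score(state$expr, sigs$signature_C),
      signature_score(state$expr, kd_res$signature))
    rownames(scores) <- c("cluster_B", "cluster_C", "MYCN_RB")
    write_matrix_tsv(scores, track(out("signature_scores.tsv")), "signature")
    list(n_signature_B = length(sigs$signature_B$genes),
         n_signature_C = length(sigs$signature_C$genes),
         n_common = nrow(kd_res$common),
         n_common_down = sum(kd_res$common$direction == "down"),
         n_mycn_rb = length(kd_res$signature$genes))
  })

  stage("integrate", function() {
    ann <- state$beta$annotation
    mapping <- ann[!is.na(ann$gene), c("probe_id", "gene", "island")]
    corr <- correlate_cpg_gene(state$beta, state$expr, mapping,
                               var_min = config$var_min,
                               r_min = config$r_min,
                               max_adj_p = config$corr_max_adj_p)
    dm_all <- rbind(state$dm_B, state$dm_C)
    summary <- summarize_correlations(corr, dm = dm_all)
    data.table::fwrite(corr, track(out("correlations.tsv")), sep = "\t")
    data.table::fwrite(summary, track(out("correlation_summary.tsv")),
                       sep = "\t")
    by_class <- table(corr$sign_class)
    list(n_pairs = nrow(corr),
         n_negative = as.integer(by_class["negative"] %||% 0),
         n_positive = as.integer(by_class["positive"] %||% 0))
  })

  report$checksums <- as.list(tools::md5sum(files))
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

## write a DiscreteMatrix as a U/S/M character TSV
write_matrix_tsv_states <- function(d, path) {
  df <- data.frame(probe_id = rownames(d$states), d$states,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

## map consensus component numbers (1 = largest) to letters A, B, C, ...
cluster_letters <- function(components) {
  stats::setNames(LETTERS[components], names(components))
}
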