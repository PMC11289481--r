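## Small shared fixtures, built once per test run.

small_config <- function(...) {
  cohort_config(n_probes = 2500L, ...)
}

## memoised small cohort used by several test files
.fixtures <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- generate_methylation_cohort(small_config(), seed = 42L)
  }
  .fixtures$sim
}

small_expression <- function() {
  if (is.null(.fixtures$expr)) {
    .fixtures$expr <- generate_expression_cohort(small_cohort()$truth,
                                                 small_config(), seed = 42L)
  }
  .fixtures$expr
}

## tiny discrete matrix with 3 clearly separated sample groups, for
## testing the consensus machinery itself
toy_discrete <- function(n_per = c(6, 5, 4), n_probes = 60, seed = 7) {
  set.seed(seed)
  groups <- rep(seq_along(n_per), n_per)
  n <- length(groups)
  states <- matrix("S", n_probes, n)
  block <- split(seq_len(n_probes),
                 rep(seq_along(n_per), length.out = n_probes))
  for (g in seq_along(n_per)) {
    states[block[[g]], groups == g] <- "M"
    states[block[[g]], groups != g] <- "U"
  }
  flip <- matrix(runif(length(states)) < 0.03, n_probes, n)
  states[flip] <- "S"
  dimnames(states) <- list(sprintf("cg%05d", seq_len(n_probes)),
                           sprintf("S%02d", seq_len(n)))
  d <- structure(list(states = states, probe_ids = rownames(states),
                      sample_ids = colnames(states),
                      t_low = 0.25, t_high = 0.75),
                 class = "DiscreteMatrix")
  list(d = d, groups = groups)
}

## wrap a list of label vectors as a minimal ensemble for the
## co-clustering functions
fake_runs <- function(label_list, ids = NULL) {
  runs <- lapply(seq_along(label_list), function(i) {
    list(algorithm = "fake", preprocessing = "none", k = NA,
         seed = i, labels = label_list[[i]], silhouette = 0.5,
         success = TRUE)
  })
  structure(runs, class = "ClusteringEnsemble", sample_ids = ids)
}
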