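#' Probe-by-sample methylation matrix
#'
#' Light S3 container for beta-values (methylation levels in [0,1]) with an
#' optional probe annotation (CpG-island flag, mapped gene symbol,
#' chromosome). Mirrors what a normalised, batch-corrected 450k/EPIC export
#' looks like after upstream processing.
#'
#' @param values numeric matrix, probes as rows, samples as columns, values
#'   in [0,1]; must carry row and column names.
#' @param annotation optional data.frame with columns `probe_id`, `island`
#'   (logical) and optionally `gene`, `chr`; must cover every probe.
#' @return An object of class `BetaMatrix`.
#' @export
beta_matrix <- function(values, annotation = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have probe rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("probe and sample IDs must be unique", call. = FALSE)
  }
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("beta-values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(annotation)) {
    if (!all(c("probe_id", "island") %in% names(annotation))) {
      stop("annotation needs columns probe_id and island", call. = FALSE)
    }
    missing <- setdiff(rownames(values), annotation$probe_id)
    if (length(missing) > 0) {
      stop("annotation does not cover all probes (e.g. ",
           missing[1], ")", call. = FALSE)
    }
    annotation <- annotation[match(rownames(values), annotation$probe_id), ,
                             drop = FALSE]
    rownames(annotation) <- NULL
  }
  structure(list(values = values,
                 probe_ids = rownames(values),
                 sample_ids = colnames(values),
                 annotation = annotation),
            class = "BetaMatrix")
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat("BetaMatrix:", nrow(x$values), "probes x", ncol(x$values), "samples\n")
  if (!is.null(x$annotation)) {
    cat("  annotated;", sum(x$annotation$island), "island probes\n")
  }
  invisible(x)
}

#' @export
dim.BetaMatrix <- function(x) dim(x$values)

#' Gene-by-sample expression matrix (tpm)
#'
#' @param tpm non-negative numeric matrix, genes as rows, samples as
#'   columns, with row and column names.
#' @param samples optional data.frame of per-sample annotations (e.g. cell
#'   line and condition for a knockdown experiment) with a `sample_id`
#'   column.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(tpm, samples = NULL) {
  if (!is.matrix(tpm) || !is.numeric(tpm)) {
    stop("tpm must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(tpm)) || is.null(colnames(tpm))) {
    stop("tpm must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(tpm)) || anyDuplicated(colnames(tpm))) {
    stop("gene and sample IDs must be unique", call. = FALSE)
  }
  if (min(tpm, na.rm = TRUE) < 0) {
    stop("tpm must be non-negative", call. = FALSE)
  }
  if (!is.null(samples)) {
    if (!"sample_id" %in% names(samples) ||
        !setequal(samples$sample_id, colnames(tpm))) {
      stop("samples must have a sample_id column matching tpm columns",
           call. = FALSE)
    }
    samples <- samples[match(colnames(tpm), samples$sample_id), , drop = FALSE]
    rownames(samples) <- NULL
  }
  structure(list(tpm = tpm,
                 gene_ids = rownames(tpm),
                 sample_ids = colnames(tpm),
                 samples = samples),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$tpm), "genes x", ncol(x$tpm), "samples\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$tpm)
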