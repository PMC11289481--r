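#' Read and write the pipeline's tabular formats
#'
#' Matrices travel as TSV with a header row and the row IDs in the first
#' column; gene sets as GMT (name, description, genes); island intervals
#' as BED (0-based half-open); model objects and run reports as JSON.
#' Numeric round trips are exact to 6 significant digits.
#'
#' @param x matrix to write (probes/genes as rows).
#' @param path file path.
#' @param id_col name of the row-ID column.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_matrix_tsv <- function(x, path, id_col = "id") {
  df <- data.frame(rownames(x), signif(x, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_matrix_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (ncol(df) < 2) stop("malformed matrix TSV: ", path, call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate row IDs in ", path, " (e.g. line ",
         which(duplicated(ids))[1] + 1L, ")", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-numeric column ", names(df)[bad + 1L], " in ", path,
         call. = FALSE)
  }
  rownames(m) <- ids
  m
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: one set per line, tab-separated name,
#'   description, genes. Duplicate genes within a set are removed with a
#'   warning.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("malformed GMT line ", i, " in ", path, call. = FALSE)
    }
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", parts[1], "' deduplicated")
      genes <- unique(genes)
    }
    sets[[parts[1]]] <- genes
  }
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors (or `GeneSignature`s).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    s <- sets[[nm]]
    genes <- if (inherits(s, "GeneSignature")) s$genes else s
    paste(c(nm, "na", genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of island intervals
#'
#' 0-based half-open intervals; an interval whose end is not greater than
#' its start is rejected with its line number.
#'
#' @param path BED file (chrom, start, end, optional name).
#' @return data.frame with chrom, start, end and name when present.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("malformed BED: ", path, call. = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  bad <- which(df$end <= df$start)
  if (length(bad) > 0) {
    stop("BED interval with end <= start at line ", bad[1], call. = FALSE)
  }
  df
}

#' @rdname read_bed
#' @param intervals data.frame with chrom, start, end (0-based half-open)
#'   and optional name.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$end <= intervals$start)) {
    stop("BED interval with end <= start", call. = FALSE)
  }
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  utils::write.table(intervals[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a fitted beta-mixture model to JSON
#'
#' @param model a `BetaMixtureModel`.
#' @param path output path.
#' @export
write_mixture_json <- function(model, path) {
  jsonlite::write_json(list(
    weights = model$weights,
    shape1 = model$shape1,
    shape2 = model$shape2,
    t_low = model$t_low,
    t_high = model$t_high,
    loglik = utils::tail(model$loglik, 1),
    iterations = model$iterations,
    converged = model$converged,
    threshold_fallback = as.list(model$threshold_fallback)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
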