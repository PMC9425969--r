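#' OTU count table with sample metadata
#'
#' A light container pairing an OTU-by-sample matrix of non-negative
#' integer counts with a per-sample metadata sheet. Metadata columns used
#' by the pipeline are `sample_id`, `sex` ("F"/"M"), `time_h` (hours since
#' substrate feeding), `treatment` ("12C", "13C" or "none"), `fraction_class`
#' ("heavy", "light" or "total"), `replicate` and the logical `is_control`
#' (negative extraction/PCR control). Controls are exempt from the
#' completeness requirement on the design columns.
#'
#' @param counts integer matrix, OTUs in rows (rownames = OTU ids), samples
#'   in columns (colnames = sample ids).
#' @param samples data.frame of per-sample metadata containing at least a
#'   `sample_id` column matching `colnames(counts)`.
#' @return An object of class `count_table`: a list with elements `counts`
#'   and `samples`.
#' @examples
#' m <- matrix(c(5L, 3L, 0L, 7L), 2, 2,
#'             dimnames = list(c("otu1", "otu2"), c("s1", "s2")))
#' ct <- count_table(m, data.frame(sample_id = c("s1", "s2"),
#'                                 sex = "F", time_h = 4,
#'                                 treatment = "13C",
#'                                 fraction_class = c("heavy", "light"),
#'                                 replicate = 1, is_control = FALSE))
#' ct
#' @export
count_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must carry OTU rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be non-negative integers")
  storage.mode(counts) <- "integer"
  samples <- as.data.frame(samples)
  if (!"sample_id" %in% names(samples))
    stop("`samples` must contain a sample_id column")
  if (!"is_control" %in% names(samples)) samples$is_control <- FALSE
  missing <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d OTUs x %d samples (%d control)\n",
              nrow(x$counts), ncol(x$counts), sum(x$samples$is_control)))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Subset the samples of a count table
#'
#' Keeps counts and metadata aligned while selecting samples by logical or
#' index vector; `biological_samples()` returns the indices of non-control
#' samples.
#'
#' @param x a [count_table()].
#' @param idx logical or integer sample selector.
#' @return a [count_table()] (or, for `biological_samples`, an integer
#'   vector).
#' @export
ct_subset_samples <- function(x, idx) {
  count_table(x$counts[, idx, drop = FALSE], x$samples[idx, , drop = FALSE])
}

#' @rdname ct_subset_samples
#' @export
biological_samples <- function(x) which(!x$samples$is_control)

#' Per-sample relative abundance
#'
#' Converts counts to within-sample proportions; every column of the
#' returned matrix sums to 1.
#'
#' @param table a [count_table()] (or a bare counts matrix).
#' @return numeric matrix of the same shape as the counts.
#' @examples
#' m <- matrix(c(10L, 30L), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' relative_abundance(m)
#' @export
relative_abundance <- function(table) {
  counts <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("degenerate all-zero sample(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(counts, 2, tot, "/")
}
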