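#' Remove negative-control contaminants
#'
#' An OTU is removed, table-wide, when it is detected (count > 0) in a
#' negative control sample and its maximum relative abundance across
#' biological samples is less than 10 times its relative abundance in the
#' negative control. OTUs absent from the controls are kept regardless of
#' abundance. When the table carries no negative control the filter is
#' skipped with a warning.
#'
#' @param table a [count_table()]; controls are samples with
#'   `is_control = TRUE`.
#' @param fold required fold difference over the control, default 10.
#' @return list with `table` (filtered [count_table()]) and `removed`
#'   (character vector of removed OTU ids).
#' @export
contaminant_filter <- function(table, fold = 10) {
  stopifnot(inherits(table, "count_table"))
  ctrl <- which(table$samples$is_control)
  if (!length(ctrl)) {
    warning("no negative control sample present; contaminant filter skipped")
    return(list(table = table, removed = character()))
  }
  bio <- biological_samples(table)
  if (!length(bio)) stop("no biological samples present")
  # zero-total columns (e.g. a blank control already stripped of its
  # contaminants) contribute zero relative abundance everywhere
  tot <- colSums(table$counts)
  ra <- sweep(table$counts, 2, pmax(tot, 1L), "/")
  ctrl_ra <- apply(ra[, ctrl, drop = FALSE], 1, max)
  detected <- apply(table$counts[, ctrl, drop = FALSE] > 0, 1, any)
  bio_max <- apply(ra[, bio, drop = FALSE], 1, max)
  remove <- detected & bio_max < fold * ctrl_ra
  kept <- table$counts[!remove, , drop = FALSE]
  list(table = count_table(kept, table$samples),
       removed = rownames(table$counts)[remove])
}

#' Rarefy a count table to fixed depth
#'
#' Subsamples every sample without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Samples with fewer than
#' `depth` reads are dropped and listed in the `dropped_samples` attribute
#' (and a message). Deterministic for a given `seed`.
#'
#' @param table a [count_table()].
#' @param depth target depth, default 3248.
#' @param seed integer RNG seed.
#' @return rarefied [count_table()] with attribute `dropped_samples`.
#' @export
rarefy <- function(table, depth = 3248, seed = 1) {
  stopifnot(inherits(table, "count_table"))
  if (depth < 1) stop("depth must be a positive integer")
  depth <- as.integer(depth)
  tot <- colSums(table$counts)
  keep <- tot >= depth
  dropped <- colnames(table$counts)[!keep]
  if (length(dropped))
    message("dropped ", length(dropped), " sample(s) below depth ", depth,
            ": ", paste(dropped, collapse = ", "))
  if (!any(keep)) stop("no sample reaches depth ", depth)
  cn <- table$counts[, keep, drop = FALSE]
  out <- with_seed(seed, {
    vapply(seq_len(ncol(cn)), function(j) {
      col <- cn[, j]
      if (sum(col) == depth) return(col)
      pool <- rep.int(seq_along(col), col)
      picked <- sample(pool, depth)
      tabulate(picked, nbins = length(col))
    }, integer(nrow(cn)))
  })
  dimnames(out) <- dimnames(cn)
  res <- count_table(out, table$samples[keep, , drop = FALSE])
  attr(res, "dropped_samples") <- dropped
  res
}

#' Parse mothur-style taxonomy lineage strings
#'
#' Reads tab-separated lines `otu_id<TAB>lineage` where the lineage is
#' `Kingdom(boot);Phylum(boot);...;Genus(boot);`. Bootstrap values are
#' optional; ranks below `min_boot` (when bootstraps are present) or
#' labeled "unclassified"/"unknown" become NA.
#'
#' @param path file path, or a character vector of lineage lines.
#' @param min_boot minimum bootstrap confidence (0-100) to accept a rank
#'   label, default 80.
#' @return data.frame with columns `otu_id`, `kingdom`, `phylum`, `class`,
#'   `order`, `family`, `genus` plus matching `*_boot` columns.
#' @export
parse_taxonomy <- function(path, min_boot = 80) {
  lines <- if (length(path) == 1 && file.exists(path))
    readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed taxonomy line: ", l)
    toks <- strsplit(sub(";$", "", parts[2]), ";", fixed = TRUE)[[1]]
    lab <- sub("\\(\\d+\\)$", "", toks)
    boot <- suppressWarnings(as.numeric(sub("^.*\\((\\d+)\\)$", "\\1", toks)))
    bad <- (!is.na(boot) & boot < min_boot) |
      tolower(lab) %in% c("unclassified", "unknown", "")
    lab[bad] <- NA
    lab <- c(lab, rep(NA, max(0, length(ranks) - length(lab))))[seq_along(ranks)]
    boot <- c(boot, rep(NA, max(0, length(ranks) - length(boot))))[seq_along(ranks)]
    c(parts[1], lab, boot)
  })
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("otu_id", ranks, paste0(ranks, "_boot"))
  for (r in paste0(ranks, "_boot")) df[[r]] <- as.numeric(df[[r]])
  df
}

#' Aggregate counts to a taxonomic rank
#'
#' Sums counts over OTUs sharing the label at `rank`; OTUs unassigned at
#' that rank are pooled under "unclassified". Per-sample totals are
#' conserved exactly.
#'
#' @param table a [count_table()].
#' @param taxonomy taxonomy data.frame as from [parse_taxonomy()] (an
#'   `otu_id` column plus rank columns).
#' @param rank rank name, e.g. "family" or "genus".
#' @return a [count_table()] with taxon labels as rownames.
#' @export
aggregate_taxa <- function(table, taxonomy, rank = "genus") {
  stopifnot(inherits(table, "count_table"))
  if (!rank %in% names(taxonomy)) stop("unknown rank: ", rank)
  lab <- taxonomy[[rank]][match(rownames(table$counts), taxonomy$otu_id)]
  lab[is.na(lab) | lab == ""] <- "unclassified"
  agg <- rowsum(table$counts, group = lab)
  storage.mode(agg) <- "integer"
  count_table(agg, table$samples)
}
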