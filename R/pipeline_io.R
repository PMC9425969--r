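# File dialects:
#   OTU table        TSV, first column otu_id, remaining columns samples
#   sample metadata  CSV keyed by sample_id
#   taxonomy         TSV otu_id <TAB> mothur-style lineage string
#   fraction profile CSV: fraction_index, density_g_per_ml, dna_ng_per_ul,
#                    delta13C_permil (blank allowed)
#   isotopologue     CSV: metabolite_id, n_carbons, sex, time_h,
#                    compartment, replicate, M0..Mn (ragged tails blank)

#' Write / read an OTU count table with metadata
#'
#' @param table a [count_table()].
#' @param counts_path TSV path for counts; `meta_path` CSV path for the
#'   sample sheet.
#' @return `read_count_table()` returns a [count_table()];
#'   `write_count_table()` returns the paths invisibly.
#' @export
write_count_table <- function(table, counts_path, meta_path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(otu_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv_plain(table$samples, meta_path)
  invisible(c(counts_path, meta_path))
}

write.csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(counts_path, meta_path) {
  df <- read.delim(counts_path, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "otu_id")
    stop("parse error in ", counts_path, ": first column must be otu_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$otu_id
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("parse error in ", counts_path, ": invalid count at OTU ",
         rownames(m)[bad[1, 1]], ", sample ", colnames(m)[bad[1, 2]])
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  if ("is_control" %in% names(meta))
    meta$is_control <- as.logical(meta$is_control)
  missing <- setdiff(colnames(m), meta$sample_id)
  if (length(missing))
    stop("validation error: sample(s) in counts but absent from metadata: ",
         paste(missing, collapse = ", "))
  count_table(m, meta)
}

#' Read / write a gradient fraction profile
#'
#' @param path CSV with columns `fraction_index`, `density_g_per_ml`,
#'   `dna_ng_per_ul`, `delta13C_permil` (blank = unmeasured).
#' @return a [fraction_profile()].
#' @export
read_fraction_profile <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fraction_index", "density_g_per_ml", "dna_ng_per_ul",
            "delta13C_permil")
  if (!all(need %in% names(df)))
    stop("parse error in ", path, ": need columns ",
         paste(need, collapse = ", "))
  fraction_profile(df$fraction_index, df$density_g_per_ml,
                   df$dna_ng_per_ul, df$delta13C_permil)
}

#' @rdname read_fraction_profile
#' @param profile a [fraction_profile()].
#' @export
write_fraction_profile <- function(profile, path) {
  df <- data.frame(fraction_index = profile$fraction_index,
                   density_g_per_ml = profile$density,
                   dna_ng_per_ul = profile$dna_amount,
                   delta13C_permil = profile$delta13C)
  write.csv_plain(df, path)
  invisible(path)
}

#' Read / write an isotopologue intensity table
#'
#' Comma-separated with key columns `metabolite_id`, `n_carbons`, `sex`,
#' `time_h`, `compartment`, `replicate` followed by `M0..Mn` intensity
#' columns; tails beyond a metabolite's carbon count may be blank.
#'
#' @param path CSV path.
#' @return data.frame; use [correct_cid_table()] to process it.
#' @export
read_isotopologue_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("metabolite_id", "n_carbons")
  if (!all(need %in% names(df)))
    stop("parse error in ", path, ": need columns ",
         paste(need, collapse = ", "))
  mcols <- grep("^M\\d+$", names(df), value = TRUE)
  if (!length(mcols)) stop("parse error in ", path, ": no M0..Mn columns")
  df
}

#' @rdname read_isotopologue_table
#' @param df isotopologue data.frame.
#' @export
write_isotopologue_table <- function(df, path) {
  write.csv_plain(df, path)
  invisible(path)
}

#' Correct every row of an isotopologue table
#'
#' Applies [correct_cid()] to each row of an isotopologue table (as read
#' by [read_isotopologue_table()]), building one correction model per
#' carbon count.
#'
#' @param df isotopologue table data.frame.
#' @param natural_13C,tracer_purity correction model parameters.
#' @return data.frame: key columns, `x0..xn` corrected fractions (NA
#'   beyond each metabolite's carbon count) and `mean_enrichment`.
#' @export
correct_cid_table <- function(df, natural_13C = 0.0107, tracer_purity = 0.98) {
  mcols <- grep("^M\\d+$", names(df), value = TRUE)
  mcols <- mcols[order(as.integer(sub("^M", "", mcols)))]
  keys <- setdiff(names(df), mcols)
  models <- list()
  nmax <- max(df$n_carbons)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    n <- df$n_carbons[i]
    key <- as.character(n)
    if (is.null(models[[key]]))
      models[[key]] <<- build_correction_matrix(n, natural_13C, tracer_purity)
    m <- as.numeric(df[i, mcols[seq_len(n + 1)]])
    if (anyNA(m))
      stop("missing intensity M", which(is.na(m))[1] - 1, " for ",
           df$metabolite_id[i], " (row ", i, ")")
    cid <- correct_cid(isotopologue_vector(df$metabolite_id[i], n, m),
                       models[[key]])
    x <- rep(NA_real_, nmax + 1)
    x[seq_len(n + 1)] <- cid$fractions
    cbind(df[i, keys, drop = FALSE],
          stats::setNames(as.data.frame(t(x)), paste0("x", 0:nmax)),
          mean_enrichment = cid$mean_enrichment)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline run configuration
#'
#' Assembles and validates the configuration of an end-to-end run. Every
#' numeric default is the package-wide default of the corresponding stage.
#'
#' @param seed top-level seed; each stage derives a named substream.
#' @param simulate logical; simulate inputs (TRUE, default) or read them
#'   from `paths` (named list: counts, metadata, taxonomy, profile,
#'   isotopologues).
#' @param windows a [fraction_windows()].
#' @param ef_threshold,ra_threshold enrichment classification thresholds.
#' @param depth rarefaction depth.
#' @param natural_13C,tracer_purity isotopologue correction parameters.
#' @param reference_ratio delta-13C reference isotope ratio (V-PDB).
#' @param cor_method,alpha correlation method and significance level.
#' @param sim_args overrides for [gen_linked_dataset()] when simulating.
#' @param paths input file paths when `simulate = FALSE`.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, simulate = TRUE,
                       windows = fraction_windows(),
                       ef_threshold = 0.5, ra_threshold = 0.001,
                       depth = 3248, natural_13C = 0.0107,
                       tracer_purity = 0.98, reference_ratio = 0.0111802,
                       cor_method = "spearman", alpha = 0.05,
                       sim_args = list(), paths = list()) {
  stopifnot(inherits(windows, "fraction_windows"))
  if (ef_threshold <= 0 || ra_threshold <= 0 || depth <= 0 || alpha <= 0)
    stop("thresholds, depth and alpha must be positive")
  structure(list(seed = as.integer(seed), simulate = simulate,
                 windows = windows, ef_threshold = ef_threshold,
                 ra_threshold = ra_threshold, depth = as.integer(depth),
                 natural_13C = natural_13C, tracer_purity = tracer_purity,
                 reference_ratio = reference_ratio,
                 cor_method = cor_method, alpha = alpha,
                 sim_args = sim_args, paths = paths),
            class = "run_config")
}

config_json <- function(config) {
  x <- unclass(config)
  x$windows <- list(light = config$windows$light,
                    heavy = config$windows$heavy)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

# Small deterministic checksum of a string (for the run log).
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full SIP + 13C-metabolomics pipeline
#'
#' Executes, in order: input simulation (or reading), contaminant
#' filtering, rarefaction, enrichment-factor computation per (sex, time)
#' with genus aggregation (SIP arm); isotopologue correction and
#' enrichment summaries (metabolomics arm); gradient peak detection; and
#' the taxa-metabolite correlation matrix joining the two arms. All result
#' tables, the effective configuration, a run log and a plain-text summary
#' are written under `out_dir`. Outputs contain no timestamps, so a rerun
#' with the same config and seed is byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly. Side effects: writes `ef_table.tsv`,
#'   `ef_by_genus.tsv`, `corrected_cids.tsv`, `enrichment_summary.tsv`,
#'   `correlations.tsv`, `gradient_peak.tsv`, `removed_otus.txt`,
#'   `config.json`, `run_log.txt`, `summary.txt`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("sip_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cjson <- config_json(config)
  note("seed: %d", config$seed)
  note("config_hash: %s", config_hash(as.character(cjson)))

  bundle <- stage("inputs", {
    if (config$simulate) {
      do.call(gen_linked_dataset,
              utils::modifyList(list(seed = child_seed(config$seed, "sim")),
                                config$sim_args))
    } else {
      p <- config$paths
      comm <- list(table = read_count_table(p$counts, p$metadata),
                   taxonomy = parse_taxonomy(p$taxonomy), truth = NULL)
      list(community = comm,
           gradient = read_fraction_profile(p$profile),
           iso_table = read_isotopologue_table(p$isotopologues),
           taxa = NULL, metabolites = NULL)
    }
  })
  comm <- bundle$community
  note("input OTUs: %d, samples: %d", nrow(comm$table$counts),
       ncol(comm$table$counts))

  filt <- stage("contaminant_filter", contaminant_filter(comm$table))
  writeLines(filt$removed, file.path(out_dir, "removed_otus.txt"))
  note("contaminants removed: %d", length(filt$removed))

  bio <- ct_subset_samples(filt$table, biological_samples(filt$table))
  rare <- stage("rarefy",
                suppressMessages(rarefy(bio, depth = config$depth,
                                        seed = child_seed(config$seed,
                                                          "rarefy"))))
  note("samples after rarefaction: %d (dropped %d)", ncol(rare$counts),
       length(attr(rare, "dropped_samples")))

  ef <- stage("ef_table",
              ef_table(rare, ef_threshold = config$ef_threshold,
                       ra_threshold = config$ra_threshold))
  write_tsv <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  write_tsv(ef, "ef_table.tsv")
  ef_gen <- stage("ef_by_genus", ef_by_rank(ef, comm$taxonomy, "genus"))
  write_tsv(ef_gen, "ef_by_genus.tsv")
  note("enriched OTU calls: %d", sum(ef$enriched, na.rm = TRUE))

  peak <- stage("gradient_peak", {
    pk <- find_enrichment_peak(bundle$gradient)
    if (is.null(pk)) data.frame(density = NA_real_, delta13C = NA_real_)
    else as.data.frame(pk)
  })
  write_tsv(peak, "gradient_peak.tsv")

  cid_df <- stage("correct_cid", {
    if (!is.null(bundle$cids)) {
      do.call(rbind, lapply(bundle$cids, function(iv) {
        cid <- correct_cid(iv, attr(iv, "model"))
        data.frame(metabolite_id = cid$metabolite_id,
                   mean_enrichment = cid$mean_enrichment)
      }))
    } else {
      correct_cid_table(bundle$iso_table, config$natural_13C,
                        config$tracer_purity)
    }
  })
  write_tsv(cid_df, "corrected_cids.tsv")
  summ <- stage("summarize_enrichment", summarize_enrichment(cid_df))
  write_tsv(summ, "enrichment_summary.tsv")

  cors <- stage("correlation_matrix", {
    if (!is.null(bundle$taxa)) {
      correlation_matrix(bundle$taxa, bundle$metabolites,
                         method = config$cor_method, alpha = config$alpha,
                         seed = child_seed(config$seed, "correlation"))
    } else NULL
  })
  if (!is.null(cors)) write_tsv(cors, "correlations.tsv")

  writeLines(as.character(cjson), file.path(out_dir, "config.json"))
  writeLines(log, file.path(out_dir, "run_log.txt"))

  enr <- ef_gen[ef_gen$enriched, , drop = FALSE]
  summary_lines <- c(
    "SIP + 13C-metabolomics pipeline summary",
    sprintf("seed: %d", config$seed),
    sprintf("OTUs after contaminant filter: %d", nrow(filt$table$counts)),
    sprintf("enriched genus calls per (sex, time): %s",
            if (nrow(enr)) paste(sprintf("%s/%sh:%s", enr$sex, enr$time_h,
                                         enr$taxon), collapse = ", ")
            else "none"),
    if (!is.null(cors))
      sprintf("significant taxa-metabolite correlations: %d of %d",
              sum(cors$significant, na.rm = TRUE), nrow(cors))
    else "correlation arm: not run (no shared units provided)")
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
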