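#' delta-13C of an isotope ratio
#'
#' Expresses a 13C/12C ratio in per-mil deviation from a reference scale:
#' `(ratio / reference - 1) * 1000`.
#'
#' @param ratio_13_12 measured 13C/12C ratio (> 0).
#' @param reference_ratio reference 13C/12C ratio; default 0.0111802, the
#'   V-PDB standard.
#' @return delta value in per mil.
#' @examples
#' delta13C(0.0111802)        # 0
#' delta13C(2 * 0.0111802)    # +1000
#' @export
delta13C <- function(ratio_13_12, reference_ratio = 0.0111802) {
  if (any(ratio_13_12 <= 0) || any(reference_ratio <= 0))
    stop("isotope ratios must be positive")
  (ratio_13_12 / reference_ratio - 1) * 1000
}

#' Build a gradient fraction profile
#'
#' @param fraction_index integer order of collection (top to bottom).
#' @param density buoyant density in g/mL, within \[1.60, 1.80\].
#' @param dna_amount fluorometric DNA amount (>= 0).
#' @param delta13C per-mil delta-13C of the fraction DNA (NA if unmeasured).
#' @return data.frame of class `fraction_profile`.
#' @export
fraction_profile <- function(fraction_index, density, dna_amount,
                             delta13C = NA_real_) {
  if (any(density < 1.60 | density > 1.80))
    stop("densities must lie in [1.60, 1.80] g/mL")
  if (any(dna_amount < 0)) stop("dna_amount must be non-negative")
  out <- data.frame(fraction_index = as.integer(fraction_index),
                    density = as.numeric(density),
                    dna_amount = as.numeric(dna_amount),
                    delta13C = as.numeric(delta13C))
  class(out) <- c("fraction_profile", "data.frame")
  out
}

#' Heavy/light density windows
#'
#' Closed density intervals used to pick the light (unlabeled) and heavy
#' (labeled) DNA fractions from a CsCl gradient. Defaults are the windows
#' used throughout this pipeline: light 1.68-1.69 g/mL, heavy
#' 1.71-1.72 g/mL.
#'
#' @param light,heavy numeric length-2 closed intervals (g/mL); the light
#'   window must lie entirely below the heavy one and both inside
#'   \[1.60, 1.80\].
#' @return list of class `fraction_windows`.
#' @export
fraction_windows <- function(light = c(1.68, 1.69), heavy = c(1.71, 1.72)) {
  stopifnot(length(light) == 2, length(heavy) == 2)
  light <- sort(as.numeric(light)); heavy <- sort(as.numeric(heavy))
  if (light[2] >= heavy[1])
    stop("light window must lie strictly below the heavy window")
  if (light[1] < 1.60 || heavy[2] > 1.80)
    stop("windows must lie inside [1.60, 1.80] g/mL")
  structure(list(light = light, heavy = heavy), class = "fraction_windows")
}

#' Select heavy and light fractions from a gradient profile
#'
#' Returns the fractions whose density falls in each closed window.
#' Densities are rounded to 3 decimals before comparison to absorb
#' refractometer precision; output is sorted by density, so the selection
#' is invariant to input ordering.
#'
#' @param profile a [fraction_profile()] (or data.frame with columns
#'   `fraction_index`, `density`, `dna_amount`, `delta13C`).
#' @param windows a [fraction_windows()].
#' @return list with elements `light` and `heavy`, each a subset of
#'   `profile`; errors if either window captures no fraction.
#' @export
select_fractions <- function(profile, windows = fraction_windows()) {
  stopifnot(inherits(windows, "fraction_windows"))
  profile <- as.data.frame(profile)
  if (nrow(profile) == 0) stop("empty fraction profile")
  d <- round(profile$density, 3)
  pick <- function(win, name) {
    idx <- which(d >= round(win[1], 3) & d <= round(win[2], 3))
    if (!length(idx))
      stop("no fractions fall in the ", name, " window [",
           win[1], ", ", win[2], "] g/mL")
    sel <- profile[idx, , drop = FALSE]
    sel[order(sel$density, sel$fraction_index), , drop = FALSE]
  }
  list(light = pick(windows$light, "light"),
       heavy = pick(windows$heavy, "heavy"))
}

#' Locate the 13C enrichment peak of a gradient
#'
#' Finds the fraction that is a strict local maximum of delta-13C along the
#' density axis (strictly greater than both density neighbors, interior
#' fractions only). A labeled ("heavy") DNA population shows up as such an
#' interior peak even when the unlabeled baseline rises monotonically with
#' density. Ties between several equal-evidence peaks are broken by the
#' larger DNA amount.
#'
#' @param profile a [fraction_profile()]; at least 3 fractions with
#'   measured (non-NA) delta-13C are required.
#' @return list with `density` and `delta13C` of the peak fraction, or
#'   `NULL` (with a message) when no interior local maximum exists.
#' @export
find_enrichment_peak <- function(profile) {
  profile <- as.data.frame(profile)
  p <- profile[!is.na(profile$delta13C), , drop = FALSE]
  if (nrow(p) < 3)
    stop("insufficient data: need >= 3 fractions with measured delta13C")
  p <- p[order(p$density, p$fraction_index), , drop = FALSE]
  d <- p$delta13C
  n <- nrow(p)
  is_peak <- c(FALSE, d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] > d[3:n],
               FALSE)
  if (!any(is_peak)) {
    message("no interior delta13C peak found")
    return(NULL)
  }
  cand <- p[is_peak, , drop = FALSE]
  # several local maxima: the enrichment peak is the one backed by the
  # larger DNA amount (labeled DNA accumulates where the heavy band is)
  best <- cand[which.max(cand$dna_amount), ]
  list(density = best$density, delta13C = best$delta13C)
}

#' Sum selected fractions into heavy/light composite samples
#'
#' The sequencing design sequences two fractions per density class per
#' gradient; their counts are summed (counts are additive) into one heavy
#' and one light composite sample per (sex, time, treatment, replicate)
#' gradient, carrying the metadata over.
#'
#' @param table a [count_table()] whose sample metadata includes a
#'   `fraction_index` column (per-fraction samples).
#' @param selection list with `light` and `heavy` vectors of fraction
#'   indices (e.g. derived from [select_fractions()]).
#' @return a [count_table()] of composite samples with `fraction_class`
#'   set to "light"/"heavy" and `fraction_index` dropped.
#' @export
combine_fraction_counts <- function(table, selection) {
  stopifnot(inherits(table, "count_table"))
  md <- table$samples
  if (!"fraction_index" %in% names(md))
    stop("sample metadata lacks a fraction_index column")
  sel_idx <- c(selection$light, selection$heavy)
  missing <- setdiff(sel_idx, md$fraction_index)
  if (length(missing))
    stop("selected fractions absent from table: ",
         paste(missing, collapse = ", "))
  md$fraction_class <- ifelse(md$fraction_index %in% selection$light, "light",
                       ifelse(md$fraction_index %in% selection$heavy, "heavy",
                              NA))
  keep <- !is.na(md$fraction_class) & !md$is_control
  cn <- table$counts[, keep, drop = FALSE]
  mk <- md[keep, , drop = FALSE]
  key <- interaction(mk$sex, mk$time_h, mk$treatment, mk$replicate,
                     mk$fraction_class, drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(ncol(cn)), key)
  comp <- vapply(groups, function(ix) rowSums(cn[, ix, drop = FALSE]),
                 numeric(nrow(cn)))
  meta <- do.call(rbind, lapply(groups, function(ix) {
    r <- mk[ix[1], setdiff(names(mk), "fraction_index"), drop = FALSE]
    r
  }))
  meta$sample_id <- sprintf("%s_%sh_%s_r%s_%s", meta$sex, meta$time_h,
                            meta$treatment, meta$replicate,
                            meta$fraction_class)
  colnames(comp) <- meta$sample_id
  count_table(comp, meta)
}

#' Per-OTU enrichment factor
#'
#' `EF = 13C_heavy/13C_light - 12C_heavy/12C_light`, where the four terms
#' are the OTU's relative abundances in the heavy and light composite
#' samples of the labeled (13C) and unlabeled (12C) feeding arms. Positive
#' EF means the OTU is over-represented in heavy DNA specifically under
#' labeled feeding, i.e. it assimilated the labeled substrate.
#'
#' @param ra_13_heavy,ra_13_light,ra_12_heavy,ra_12_light relative
#'   abundances in \[0, 1\].
#' @param pseudo pseudocount added to all four relative abundances before
#'   forming the ratios; default 0 (the plain formula). With `pseudo = 0`
#'   a zero denominator makes EF undefined and raises an error (callers
#'   such as [ef_table()] catch it and flag the OTU rather than dropping it).
#' @return EF value (may be negative).
#' @examples
#' enrichment_factor(0.40, 0.20, 0.10, 0.10)  # 1
#' @export
enrichment_factor <- function(ra_13_heavy, ra_13_light, ra_12_heavy,
                              ra_12_light, pseudo = 0) {
  v <- c(ra_13_heavy, ra_13_light, ra_12_heavy, ra_12_light)
  if (any(v < 0 | v > 1)) stop("relative abundances must lie in [0, 1]")
  if (pseudo == 0 && (ra_13_light == 0 || ra_12_light == 0))
    stop("undefined EF: zero light-fraction relative abundance")
  (ra_13_heavy + pseudo) / (ra_13_light + pseudo) -
    (ra_12_heavy + pseudo) / (ra_12_light + pseudo)
}

#' Classify an OTU as 13C-enriched
#'
#' An OTU is called enriched when its enrichment factor exceeds
#' `ef_threshold` and its relative abundance exceeds `ra_threshold`
#' (both strict inequalities).
#'
#' @param ef enrichment factor.
#' @param relative_abundance relative abundance in \[0, 1\].
#' @param ef_threshold default 0.5.
#' @param ra_threshold default 0.001 (0.1 %).
#' @return logical.
#' @export
classify_enriched <- function(ef, relative_abundance, ef_threshold = 0.5,
                              ra_threshold = 0.001) {
  if (any(relative_abundance < 0 | relative_abundance > 1, na.rm = TRUE))
    stop("relative_abundance must lie in [0, 1]")
  !is.na(ef) & ef > ef_threshold & relative_abundance > ra_threshold
}

#' Enrichment-factor table for a composite count table
#'
#' For every (sex, time) cell, computes each OTU's EF from the four
#' composite samples (12C/13C x heavy/light) of each replicate, averages EF
#' across replicates (`mode = "replicate"`, default) or pools replicate
#' counts before a single EF (`mode = "pooled"`), reports the OTU's mean
#' relative abundance across the 13C composite samples of the cell, and
#' applies the enrichment classification to the averages. Replicates where
#' an OTU has a zero light-fraction abundance yield an undefined EF; such
#' OTUs are flagged `undefined_ef` (never silently dropped) and are not
#' classified enriched from the remaining evidence.
#'
#' @param table composite [count_table()] whose samples carry `sex`,
#'   `time_h`, `treatment` ("12C"/"13C"), `fraction_class`
#'   ("heavy"/"light") and `replicate` metadata.
#' @param pseudo pseudocount forwarded to [enrichment_factor()]; default 0.
#' @param ef_threshold,ra_threshold classification thresholds, see
#'   [classify_enriched()].
#' @param mode "replicate" (EF per replicate, then averaged) or "pooled"
#'   (replicate counts summed first).
#' @return data.frame with columns `otu_id`, `sex`, `time_h`, `ef`,
#'   `relative_abundance`, `enriched`, `n_replicates`, `flags`.
#' @export
ef_table <- function(table, pseudo = 0, ef_threshold = 0.5,
                     ra_threshold = 0.001, mode = c("replicate", "pooled")) {
  stopifnot(inherits(table, "count_table"))
  mode <- match.arg(mode)
  md <- table$samples
  need <- c("sex", "time_h", "treatment", "fraction_class", "replicate")
  if (!all(need %in% names(md)))
    stop("sample metadata must contain: ", paste(need, collapse = ", "))
  md <- md[!md$is_control, , drop = FALSE]
  cells <- unique(md[md$treatment %in% c("12C", "13C"), c("sex", "time_h")])
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    sx <- cells$sex[ci]; tm <- cells$time_h[ci]
    sub <- md[md$sex == sx & md$time_h == tm &
                md$treatment %in% c("12C", "13C"), , drop = FALSE]
    reps <- if (mode == "replicate") sort(unique(sub$replicate)) else "pooled"
    ef_mat <- matrix(NA_real_, nrow(table$counts), length(reps))
    ra13 <- matrix(NA_real_, nrow(table$counts), 0)
    for (ri in seq_along(reps)) {
      pick <- function(trt, fc) {
        rows <- sub$treatment == trt & sub$fraction_class == fc
        if (mode == "replicate") rows <- rows & sub$replicate == reps[ri]
        ids <- sub$sample_id[rows]
        if (!length(ids))
          stop("incomplete design for (", sx, ", ", tm, "h): missing ",
               trt, " ", fc,
               if (mode == "replicate") paste0(" replicate ", reps[ri]) else "")
        cnt <- rowSums(table$counts[, ids, drop = FALSE])
        cnt / sum(cnt)
      }
      r13h <- pick("13C", "heavy"); r13l <- pick("13C", "light")
      r12h <- pick("12C", "heavy"); r12l <- pick("12C", "light")
      ra13 <- cbind(ra13, r13h, r13l)
      num13 <- (r13h + pseudo) / (r13l + pseudo)
      num12 <- (r12h + pseudo) / (r12l + pseudo)
      ef <- num13 - num12
      if (pseudo == 0) {
        # 0/0 contributes a zero ratio (OTU absent from that arm entirely);
        # x/0 with x > 0 is undefined and stays NA
        num13[r13l == 0 & r13h == 0] <- 0
        num12[r12l == 0 & r12h == 0] <- 0
        num13[r13l == 0 & r13h > 0] <- NA
        num12[r12l == 0 & r12h > 0] <- NA
        ef <- num13 - num12
      }
      ef_mat[, ri] <- ef
    }
    n_def <- rowSums(!is.na(ef_mat))
    mean_ef <- ifelse(n_def == ncol(ef_mat), rowMeans(ef_mat), NA_real_)
    mean_ra <- rowMeans(ra13)
    flags <- ifelse(n_def < ncol(ef_mat), "undefined_ef", "")
    out[[length(out) + 1]] <- data.frame(
      otu_id = rownames(table$counts), sex = sx, time_h = tm,
      ef = mean_ef, relative_abundance = mean_ra,
      enriched = classify_enriched(mean_ef, mean_ra, ef_threshold,
                                   ra_threshold),
      n_replicates = if (mode == "replicate") length(reps) else
        length(unique(sub$replicate)),
      flags = flags, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Aggregate an EF table to a taxonomic rank
#'
#' Per (sex, time, rank label), keeps the maximum-EF OTU as the rank's
#' representative (default) or the mean EF across classified-enriched OTUs'
#' parent rank. An unassigned OTU contributes to "unclassified".
#'
#' @param ef_df output of [ef_table()].
#' @param taxonomy a taxonomy data.frame (see [parse_taxonomy()]).
#' @param rank rank column name, default "genus".
#' @param mode "max" (default) or "mean" EF per rank label.
#' @return data.frame like `ef_df` with `otu_id` replaced by `taxon`.
#' @export
ef_by_rank <- function(ef_df, taxonomy, rank = "genus",
                       mode = c("max", "mean")) {
  mode <- match.arg(mode)
  if (!rank %in% names(taxonomy)) stop("unknown rank: ", rank)
  lab <- taxonomy[[rank]][match(ef_df$otu_id, taxonomy$otu_id)]
  lab[is.na(lab) | lab == ""] <- "unclassified"
  key <- interaction(ef_df$sex, ef_df$time_h, lab, drop = TRUE)
  ef_df$.taxon <- lab
  out <- do.call(rbind, lapply(split(ef_df, key), function(g) {
    defined <- !is.na(g$ef)
    row <- g[1, c("sex", "time_h"), drop = FALSE]
    row$taxon <- g$.taxon[1]
    row$ef <- if (!any(defined)) NA_real_
      else if (mode == "max") max(g$ef[defined])
      else mean(g$ef[defined])
    row$relative_abundance <- sum(g$relative_abundance)
    row$enriched <- any(g$enriched, na.rm = TRUE)
    row
  }))
  rownames(out) <- NULL
  out
}
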