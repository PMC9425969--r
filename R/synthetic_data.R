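# Forward simulators for every input the pipeline consumes. All are pure
# functions of (arguments, seed): same seed, same output.

# Genus roster used for simulated taxonomies; mirrors the genera commonly
# recovered from sugar-fed mosquito gut mycobiota.
sim_genera <- c("Cladosporium", "Aureobasidium", "Cyberlindnera", "Candida",
                "Saccharomyces", "Aspergillus", "Penicillium", "Alternaria",
                "Malassezia", "Sarocladium", "Pezoloma")

sim_families <- c(Cladosporium = "Davidiellaceae",
                  Aureobasidium = "Dothioraceae",
                  Cyberlindnera = "Phaffomycetaceae",
                  Candida = "Saccharomycetaceae",
                  Saccharomyces = "Saccharomycetaceae",
                  Aspergillus = "Trichocomaceae",
                  Penicillium = "Trichocomaceae",
                  Alternaria = "Pleosporaceae",
                  Malassezia = "Malasseziaceae",
                  Sarocladium = "Incertae_sedis",
                  Pezoloma = "Helotiaceae")

#' Simulate a CsCl buoyant-density gradient profile
#'
#' DNA amount along the gradient is a mixture with weights
#' `(1 - labeled_fraction, labeled_fraction)` of an unlabeled component -
#' a "light" band centered near 1.685 g/mL plus a small gradient-wide
#' smear (sheared and GC-heterogeneous genomic DNA spreads across the
#' gradient) - and a labeled "heavy" band near 1.715 g/mL. The
#' per-fraction delta-13C is the DNA-weighted mixture of a linearly rising
#' unlabeled baseline (-38.5 to -35.6 per mil across the density span) and
#' a strongly positive labeled component, plus small measurement noise.
#' Because the smear keeps unlabeled DNA present in the deepest fractions,
#' the labeled share - and hence delta-13C - peaks at the heavy band and
#' declines toward the bottom: an interior local maximum despite the
#' rising baseline tail, the signature of a labeled DNA population. With
#' `labeled_fraction = 0` the delta profile is monotone (no interior
#' peak).
#'
#' @param labeled_fraction fraction of total DNA that is labeled, in
#'   \[0, 1\].
#' @param n_fractions number of fractions (>= 8), default 14.
#' @param seed RNG seed.
#' @param density_range span of collected densities, default
#'   c(1.66, 1.73) g/mL.
#' @param light_center,heavy_center band centers (g/mL).
#' @param light_sd,heavy_sd within-band density SDs (g/mL).
#' @param smear fraction of the unlabeled DNA spread uniformly across the
#'   gradient, default 0.15.
#' @param delta_labeled delta-13C of pure labeled DNA (per mil), default
#'   +500.
#' @param delta_baseline baseline delta-13C at the top and bottom of the
#'   gradient, default c(-38.5, -35.6).
#' @param dna_noise_cv,delta_noise_sd measurement noise levels.
#' @return a [fraction_profile()].
#' @export
gen_gradient <- function(labeled_fraction, n_fractions = 14, seed = 1,
                         density_range = c(1.66, 1.73),
                         light_center = 1.685, heavy_center = 1.715,
                         light_sd = 0.010, heavy_sd = 0.006, smear = 0.15,
                         delta_labeled = 500,
                         delta_baseline = c(-38.5, -35.6),
                         dna_noise_cv = 0.03, delta_noise_sd = 0.05) {
  if (labeled_fraction < 0 || labeled_fraction > 1)
    stop("labeled_fraction must lie in [0, 1]")
  if (n_fractions < 8) stop("need at least 8 fractions")
  d <- seq(density_range[1], density_range[2], length.out = n_fractions)
  g_light <- (1 - smear) * stats::dnorm(d, light_center, light_sd) +
    smear / diff(density_range)
  g_heavy <- stats::dnorm(d, heavy_center, heavy_sd)
  w_heavy_num <- labeled_fraction * g_heavy
  mix <- (1 - labeled_fraction) * g_light + w_heavy_num
  w_heavy <- ifelse(mix > 0, w_heavy_num / mix, 0)
  base <- delta_baseline[1] +
    (d - density_range[1]) / diff(density_range) * diff(delta_baseline)
  with_seed(seed, {
    dna <- mix / max(mix) * 100
    dna <- pmax(0, dna * (1 + rnorm(n_fractions, 0, dna_noise_cv)))
    delta <- base + w_heavy * (delta_labeled - base) +
      rnorm(n_fractions, 0, delta_noise_sd)
    fraction_profile(seq_len(n_fractions), round(d, 3), dna, delta)
  })
}

#' Simulate a labeled/unlabeled community sequencing experiment
#'
#' Draws a long-tailed base composition from a symmetric Dirichlet, plants
#' `n_active` substrate assimilators, and emits multinomial composite
#' samples for a (sexes x times x 12C/13C x heavy/light x replicates)
#' design at fixed depth. In the 12C arm heavy and light composites share
#' the base composition; in the 13C arm the active OTUs' weight is
#' multiplied by `heavy_shift_factor` in the heavy composites (and the
#' composition renormalized). Reagent contaminant OTUs are spiked into a
#' blank negative-control sample and carry zero community weight, so the
#' 10-fold contaminant rule removes exactly them. A taxonomy assigning
#' genera from a mosquito
#' mycobiota roster and a ground-truth record accompany the table.
#'
#' @param n_otus community richness, default 200.
#' @param n_active number of planted active OTUs, default 5. Actives are
#'   drawn among OTUs with base relative abundance >= `active_min_ra`
#'   so that planted truth is detectable at the sequencing depth.
#' @param heavy_shift_factor multiplicative heavy-fraction weight gain of
#'   active OTUs under 13C feeding (>= 1), default 5.
#' @param depth reads per composite sample, default 3248.
#' @param n_replicates replicates per cell, default 3.
#' @param seed RNG seed.
#' @param sexes,times design cells; by default females and males at 4, 10
#'   and 30 h, with the male 30 h cell omitted (mirroring male mortality
#'   late in such experiments) unless `drop_male_30h = FALSE`.
#' @param concentration Dirichlet concentration of the base composition,
#'   default 0.3 (long-tailed, dominance-structured).
#' @param active_min_ra abundance floor for planting actives, default 0.005.
#' @param n_contaminants OTUs spiked into the negative control, default 3.
#' @param drop_male_30h omit the male 30 h cell, default TRUE.
#' @return list with `table` (a [count_table()] of composite samples),
#'   `taxonomy` (data.frame), and `truth` (list: `seed`, `active_otu_ids`,
#'   `heavy_shift_factor`, `contaminant_otu_ids`, `base_weights`).
#' @export
gen_community <- function(n_otus = 200, n_active = 5, heavy_shift_factor = 5,
                          depth = 3248, n_replicates = 3, seed = 1,
                          sexes = c("F", "M"), times = c(4, 10, 30),
                          concentration = 0.3, active_min_ra = 0.005,
                          n_contaminants = 3, drop_male_30h = TRUE) {
  if (n_active >= n_otus) stop("n_active must be smaller than n_otus")
  if (heavy_shift_factor < 1) stop("heavy_shift_factor must be >= 1")
  if (depth < 500) stop("depth must be >= 500")
  with_seed(seed, {
    otu_ids <- sprintf("OTU%03d", seq_len(n_otus))
    w <- rgamma(n_otus, concentration)
    w <- w / sum(w)
    # reagent contaminants live only in the blank control: zero community
    # weight, so filtering them never perturbs biological sample totals
    contam <- integer(0)
    if (n_contaminants > 0) {
      contam <- sort(sample(which(w < stats::median(w)), n_contaminants))
      w[contam] <- 0
      w <- w / sum(w)
    }
    active <- integer(0)
    if (n_active > 0) {
      cand <- which(w >= active_min_ra)
      if (length(cand) < n_active)
        cand <- order(w, decreasing = TRUE)[seq_len(max(n_active, 10))]
      active <- sort(sample(cand, n_active))
    }
    w13h <- w
    w13h[active] <- w13h[active] * heavy_shift_factor
    w13h <- w13h / sum(w13h)

    design <- expand.grid(replicate = seq_len(n_replicates),
                          fraction_class = c("heavy", "light"),
                          treatment = c("12C", "13C"),
                          time_h = times, sex = sexes,
                          stringsAsFactors = FALSE)
    if (drop_male_30h)
      design <- design[!(design$sex == "M" & design$time_h == 30), ]
    design$sample_id <- sprintf("%s_%sh_%s_r%d_%s", design$sex,
                                design$time_h, design$treatment,
                                design$replicate, design$fraction_class)
    design$is_control <- FALSE
    counts <- vapply(seq_len(nrow(design)), function(i) {
      p <- if (design$treatment[i] == "13C" &&
               design$fraction_class[i] == "heavy") w13h else w
      as.integer(rmultinom(1, depth, p))
    }, integer(n_otus))
    rownames(counts) <- otu_ids
    colnames(counts) <- design$sample_id

    # negative control: a blank extraction dominated by the reagent
    # contaminant OTUs (absent from biological samples, so their
    # biological relative abundance of 0 is below the 10x rule)
    ctrl <- integer(n_otus)
    if (n_contaminants > 0)
      ctrl[contam] <- 150L + rbinom(n_contaminants, 100, 0.5)
    if (n_contaminants > 0) {
      counts <- cbind(counts, neg_ctrl = as.integer(ctrl))
      design <- rbind(design,
                      data.frame(replicate = NA, fraction_class = "total",
                                 treatment = "none", time_h = NA, sex = NA,
                                 sample_id = "neg_ctrl", is_control = TRUE))
    }
    genus <- sample(sim_genera, n_otus, replace = TRUE)
    # leave some OTUs unassigned at genus level
    genus[runif(n_otus) < 0.15] <- NA
    fam <- ifelse(is.na(genus), NA, unname(sim_families[genus]))
    taxonomy <- data.frame(otu_id = otu_ids, kingdom = "Fungi",
                           phylum = NA, class = NA, order = NA,
                           family = fam, genus = genus,
                           stringsAsFactors = FALSE)
    list(table = count_table(counts, design),
         taxonomy = taxonomy,
         truth = list(seed = seed,
                      active_otu_ids = otu_ids[active],
                      heavy_shift_factor = heavy_shift_factor,
                      contaminant_otu_ids = otu_ids[contam],
                      base_weights = stats::setNames(w, otu_ids)))
  })
}

#' Simulate a measured isotopologue cluster
#'
#' Forward model: the true 13C labeling distribution `x` is either the
#' supplied simplex vector or, for a scalar labeling probability `p`,
#' `Binomial(n, p * purity)` - tracer impurity thins the intended labeling
#' at synthesis, so the realized per-position 13C probability is
#' `p * purity`. The measured cluster is `B x` where `B` convolves natural
#' 13C abundance onto the unlabeled positions (the purity-1 correction
#' matrix), plus optional truncated Gaussian noise, renormalized.
#' `correct_cid()` with the matching natural-abundance model inverts this
#' exactly at zero noise.
#'
#' @param n_carbons carbon count.
#' @param true_labeling scalar labeling probability `p` in \[0, 1\], or a
#'   simplex vector of length `n_carbons + 1` used as-is.
#' @param purity tracer atom-fraction 13C, default 0.98; only applied in
#'   the scalar-`p` case.
#' @param natural_13C natural abundance, default 0.0107.
#' @param noise_sd SD of additive Gaussian intensity noise, default 0.
#' @param seed RNG seed.
#' @param metabolite_id label for the output vector.
#' @return an [isotopologue_vector()] with attributes `x_true` (the true
#'   labeling distribution) and `model` (the matching correction model).
#' @export
gen_cid <- function(n_carbons, true_labeling, purity = 0.98,
                    natural_13C = 0.0107, noise_sd = 0, seed = 1,
                    metabolite_id = "synthetic") {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- as.integer(n_carbons)
  if (length(true_labeling) == 1) {
    p <- true_labeling
    if (p < 0 || p > 1) stop("labeling probability must lie in [0, 1]")
    x <- dbinom(0:n, n, p * purity)
  } else {
    x <- as.numeric(true_labeling)
    if (length(x) != n + 1 || any(x < 0) || abs(sum(x) - 1) > 1e-8)
      stop("true_labeling must be a simplex vector of length n_carbons + 1")
  }
  model <- build_correction_matrix(n, natural_13C = natural_13C,
                                   tracer_purity = 1)
  m <- as.numeric(model$matrix %*% x)
  if (noise_sd > 0) {
    m <- with_seed(seed, pmax(0, m + rnorm(n + 1, 0, noise_sd)))
    if (sum(m) == 0) m <- rep(1 / (n + 1), n + 1)
  }
  m <- m / sum(m)
  out <- isotopologue_vector(metabolite_id, n, m)
  attr(out, "x_true") <- x
  attr(out, "model") <- model
  out
}

#' Simulate a linked taxa-metabolite dataset
#'
#' Generates a full input bundle sharing latent structure between the
#' community and metabolomics arms: genus-level activity scores and
#' metabolite mean enrichments across observation units (replicates x
#' times within one sex), with planted (taxon, metabolite) pairs tied
#' through a common latent factor at correlation `rho`, plus a community
#' table ([gen_community()]), a gradient profile ([gen_gradient()]) and
#' per-metabolite isotopologue spectra ([gen_cid()]).
#'
#' @param seed RNG seed.
#' @param n_taxa,n_metabolites numbers of genus-level activity and
#'   metabolite columns, defaults 8 and 10.
#' @param n_replicates,times observation-unit design (units = replicates x
#'   times), defaults 3 and c(4, 10, 30).
#' @param planted data.frame with columns `taxon`, `metabolite` (integer
#'   column indices) of linked pairs; default none.
#' @param rho latent correlation of planted pairs, default 0.95.
#' @param community_args list of overrides for [gen_community()].
#' @return list with `taxa` (units x taxa matrix), `metabolites` (units x
#'   metabolites matrix of mean enrichments in \[0, 1\]), `community`
#'   (a [gen_community()] bundle), `gradient` (a [fraction_profile()]),
#'   `cids` (list of [gen_cid()] vectors, one per metabolite column) and
#'   `truth` (planted pairs, seed).
#' @export
gen_linked_dataset <- function(seed = 1, n_taxa = 8, n_metabolites = 10,
                               n_replicates = 3, times = c(4, 10, 30),
                               planted = NULL, rho = 0.95,
                               community_args = list()) {
  units <- expand.grid(replicate = seq_len(n_replicates), time_h = times)
  nu <- nrow(units)
  unit_ids <- sprintf("t%d_r%d", units$time_h, units$replicate)
  taxa_names <- sim_genera[seq_len(min(n_taxa, length(sim_genera)))]
  if (n_taxa > length(sim_genera))
    taxa_names <- c(taxa_names,
                    sprintf("Genus%02d", seq_len(n_taxa - length(sim_genera))))
  metab_names <- metabolite_carbons()$metabolite_id[seq_len(n_metabolites)]
  with_seed(seed, {
    taxa <- matrix(rnorm(nu * n_taxa), nu, n_taxa,
                   dimnames = list(unit_ids, taxa_names))
    metab_z <- matrix(rnorm(nu * n_metabolites), nu, n_metabolites,
                      dimnames = list(unit_ids, metab_names))
    if (!is.null(planted) && nrow(planted) > 0) {
      for (k in seq_len(nrow(planted))) {
        ti <- planted$taxon[k]; mi <- planted$metabolite[k]
        z <- rnorm(nu)
        taxa[, ti] <- z
        metab_z[, mi] <- rho * z + sqrt(1 - rho^2) * rnorm(nu)
      }
    }
    # map metabolite latent scores to mean enrichments in (0, 1)
    metabolites <- stats::pnorm(metab_z)
    comm <- do.call(gen_community,
                    utils::modifyList(
                      list(seed = child_seed(seed, "community"),
                           sexes = "F", times = times,
                           n_replicates = n_replicates),
                      community_args))
    grad <- gen_gradient(0.3, seed = child_seed(seed, "gradient"))
    cids <- lapply(seq_len(n_metabolites), function(mi) {
      nc <- metabolite_carbons()$n_carbons[mi]
      gen_cid(nc, mean(metabolites[, mi]),
              seed = child_seed(seed, paste0("cid", mi)),
              noise_sd = 0.003,
              metabolite_id = metab_names[mi])
    })
    list(taxa = taxa, metabolites = metabolites, community = comm,
         gradient = grad, cids = cids,
         truth = list(seed = seed, planted = planted, rho = rho))
  })
}
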