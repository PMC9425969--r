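test_that("delta13C is the per-mil ratio deviation", {
  expect_equal(delta13C(0.0111802), 0)
  expect_equal(delta13C(2 * 0.0111802), 1000)
  expect_equal(delta13C(0.011), -16.12, tolerance = 1e-3)
  expect_error(delta13C(0), "positive")
  # strictly increasing in the ratio
  r <- seq(0.009, 0.014, by = 0.001)
  expect_true(all(diff(delta13C(r)) > 0))
})

test_that("fraction selection honors closed density windows", {
  prof <- fraction_profile(1:8,
                           c(1.66, 1.67, 1.68, 1.69, 1.70, 1.71, 1.72, 1.73),
                           dna_amount = 1:8)
  sel <- select_fractions(prof)
  expect_equal(sel$light$density, c(1.68, 1.69))
  expect_equal(sel$heavy$density, c(1.71, 1.72))
  # boundary densities are included; ordering of the input is irrelevant
  shuf <- prof[sample(nrow(prof)), ]
  sel2 <- select_fractions(shuf)
  expect_equal(sel2$light$density, sel$light$density)
  expect_equal(sel2$heavy$density, sel$heavy$density)
  low <- fraction_profile(1:3, c(1.66, 1.665, 1.67), 1:3)
  expect_error(select_fractions(low), "light window")
  expect_error(fraction_windows(light = c(1.70, 1.73), heavy = c(1.71, 1.72)),
               "strictly below")
})

test_that("enrichment peak is an interior local maximum", {
  prof <- fraction_profile(1:5, c(1.66, 1.69, 1.71, 1.72, 1.73),
                           dna_amount = c(1, 2, 5, 2, 1),
                           delta13C = c(-38.0, -37.0, -36.5, -37.2, -35.6))
  pk <- find_enrichment_peak(prof)
  expect_equal(pk$density, 1.71)
  expect_equal(pk$delta13C, -36.5)
  # strictly monotone profile: no peak
  mono <- fraction_profile(1:5, c(1.66, 1.68, 1.70, 1.72, 1.73),
                           dna_amount = 1:5,
                           delta13C = c(-38, -37.5, -37, -36.5, -36))
  expect_message(res <- find_enrichment_peak(mono), "no interior")
  expect_null(res)
  # two equal-height maxima: the one with larger DNA amount wins
  two <- fraction_profile(1:5, c(1.66, 1.68, 1.70, 1.72, 1.73),
                          dna_amount = c(1, 2, 1, 5, 1),
                          delta13C = c(-38, -36, -37, -36, -38))
  expect_equal(find_enrichment_peak(two)$density, 1.72)
  expect_error(find_enrichment_peak(prof[1:2, ]), "insufficient")
})

test_that("selected fraction counts sum into composites", {
  m <- matrix(c(3L, 0L, 7L, 0L, 2L, 5L, 4L, 5L), nrow = 2,
              dimnames = list(c("otu1", "otu2"),
                              c("f3", "f4", "f6", "f7")))
  meta <- data.frame(sample_id = c("f3", "f4", "f6", "f7"),
                     sex = "F", time_h = 4, treatment = "13C",
                     replicate = 1, fraction_index = c(3, 4, 6, 7),
                     is_control = FALSE)
  ct <- count_table(m, meta)
  # columns: f3 = (3,0), f4 = (7,0), f6 = (2,5), f7 = (4,5)
  comp <- combine_fraction_counts(ct, list(light = c(3, 4), heavy = c(6, 7)))
  expect_equal(ncol(comp$counts), 2)
  hv <- comp$counts[, comp$samples$fraction_class == "heavy"]
  lt <- comp$counts[, comp$samples$fraction_class == "light"]
  expect_equal(unname(hv), c(2L + 4L, 5L + 5L))
  expect_equal(unname(lt), c(3L + 7L, 0L))  # otu2 absent in both -> 0
  # single selected fraction: composite equals it
  comp1 <- combine_fraction_counts(ct, list(light = 3, heavy = 6))
  expect_equal(unname(comp1$counts[, comp1$samples$fraction_class == "light"]),
               c(3L, 0L))
  expect_error(combine_fraction_counts(ct, list(light = 1, heavy = 6)),
               "absent")
})

test_that("enrichment factor follows the two-arm ratio contrast", {
  expect_equal(enrichment_factor(0.40, 0.20, 0.10, 0.10), 1.0)
  expect_equal(enrichment_factor(0.25, 0.25, 0.25, 0.25), 0)
  expect_equal(enrichment_factor(0.30, 0.30, 0.20, 0.40), 0.5)
  expect_error(enrichment_factor(0.1, 0, 0.1, 0.1), "undefined EF")
  expect_equal(enrichment_factor(0.1, 0, 0.1, 0.1, pseudo = 0.001),
               (0.101 / 0.001) - (0.101 / 0.101))
  expect_error(enrichment_factor(1.2, 0.1, 0.1, 0.1), "\\[0, 1\\]")
})

test_that("EF is antisymmetric under treatment swap", {
  set.seed(11)
  for (i in 1:20) {
    ra <- runif(4, 0.01, 0.9)
    expect_equal(enrichment_factor(ra[1], ra[2], ra[3], ra[4]),
                 -enrichment_factor(ra[3], ra[4], ra[1], ra[2]),
                 tolerance = 1e-12)
  }
})

test_that("enrichment classification applies strict dual thresholds", {
  expect_true(classify_enriched(0.6, 0.002))
  expect_false(classify_enriched(0.5, 0.5))     # EF bound is strict
  expect_false(classify_enriched(5.0, 0.0009))  # abundance too low
  expect_false(classify_enriched(5.0, 0.001))   # RA bound is strict
  expect_false(classify_enriched(NA, 0.5))
})

test_that("ef_table reproduces hand-computed EFs across replicates", {
  # one clear assimilator among four OTUs, identical across 3 replicates:
  # relative abundances (0.40, 0.20, 0.10, 0.10) for otu1
  per_otu <- list(otu1 = c(40, 20, 10, 10) * 10,
                  otu2 = c(20, 30, 30, 30) * 10,
                  otu3 = c(20, 30, 30, 30) * 10,
                  otu4 = c(20, 20, 30, 30) * 10)
  ct <- make_composite_table(per_otu)
  ef <- ef_table(ct)
  o1 <- ef[ef$otu_id == "otu1", ]
  expect_equal(o1$ef, 1.0)
  expect_true(o1$enriched)
  expect_equal(o1$relative_abundance, mean(c(0.4, 0.2)))
  expect_equal(o1$n_replicates, 3L)
  # uniform community: EF identically zero, nothing enriched
  unif <- make_composite_table(list(a = rep(100, 4), b = rep(300, 4),
                                    c = rep(600, 4)))
  efu <- ef_table(unif)
  expect_equal(efu$ef, rep(0, 3))
  expect_false(any(efu$enriched))
  # missing composite -> incomplete-design error naming the cell
  drop <- ct_subset_samples(ct, ct$samples$sample_id != "F_4h_12C_r2_light")
  expect_error(ef_table(drop), "missing 12C light")
})

test_that("ef_table flags undefined EFs instead of dropping OTUs", {
  per_otu <- list(otu1 = c(40, 0, 10, 10), otu2 = c(60, 100, 90, 90))
  ct <- make_composite_table(per_otu, n_replicates = 2)
  ef <- ef_table(ct)
  o1 <- ef[ef$otu_id == "otu1", ]
  expect_equal(o1$flags, "undefined_ef")
  expect_true(is.na(o1$ef))
  expect_false(o1$enriched)
  # pooled mode agrees with replicate mode on replicate-identical data
  per2 <- list(otu1 = c(40, 20, 10, 10), otu2 = c(60, 80, 90, 90))
  ctr <- make_composite_table(per2, n_replicates = 3)
  expect_equal(ef_table(ctr, mode = "pooled")$ef, ef_table(ctr)$ef)
})

test_that("ef_by_rank aggregates OTU calls to genus", {
  per_otu <- list(otu1 = c(40, 20, 10, 10) * 10,
                  otu2 = c(35, 25, 10, 10) * 10,
                  otu3 = c(25, 55, 80, 80) * 10)
  ct <- make_composite_table(per_otu)
  ef <- ef_table(ct)
  tax <- data.frame(otu_id = c("otu1", "otu2", "otu3"),
                    genus = c("Cladosporium", "Cladosporium", NA))
  byg <- ef_by_rank(ef, tax, "genus")
  cla <- byg[byg$taxon == "Cladosporium", ]
  expect_equal(cla$ef, max(ef$ef[ef$otu_id %in% c("otu1", "otu2")]))
  expect_true(cla$enriched)
  expect_true("unclassified" %in% byg$taxon)
})
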