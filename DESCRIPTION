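Package: mycosip
Title: DNA Stable Isotope Probing and 13C-Metabolomics of Host-Associated
    Fungal Communities
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint analysis of DNA stable isotope probing (SIP) and
    13C-metabolomics experiments on host-associated mycobiota. Corrects
    measured carbon isotopologue clusters for natural isotope abundance
    and tracer impurity and quantifies mean 13C enrichment; computes
    delta-13C values and selects heavy/light buoyant-density fractions
    from CsCl gradient profiles; identifies isotopically enriched
    ("active") taxa with a per-OTU enrichment factor contrasting labeled
    and unlabeled feeding arms; provides OTU-table hygiene (negative
    control contaminant filtering, rarefaction, taxonomic aggregation),
    exact small-sample rank-sum and permutation correlation tests, and a
    forward simulator of gradients, communities and isotopologue spectra
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
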