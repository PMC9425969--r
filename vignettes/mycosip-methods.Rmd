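---
title: "Methods: isotopologue correction, SIP enrichment factors, and their calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotopologue correction, SIP enrichment factors, and their calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycosip)
```

# Scope

`mycosip` analyzes substrate-tracing experiments that feed a ¹³C-labeled
carbon source to a host (here, sugar-fed mosquitoes are the motivating
system) and follow the label simultaneously into (i) the host's central
metabolites, measured as isotopologue clusters by high-resolution mass
spectrometry, and (ii) the DNA of the gut microorganisms that assimilate
the substrate, separated by CsCl buoyant-density ultracentrifugation into
"heavy" (labeled) and "light" (unlabeled) fractions and sequenced as
amplicon OTU tables. The package starts from count tables, gradient
profiles and intensity vectors; peak picking, OTU clustering and
taxonomic assignment are upstream and out of scope.

# The correction model for isotopologue clusters

## Model

For a metabolite with $n$ carbons, let $x_j$ be the fraction of
molecules with exactly $j$ tracer-derived carbon positions
($\sum_j x_j = 1$). A molecule with $j$ labeled positions produces a
measured mass distribution that is the convolution of
$\mathrm{Bin}(j, \pi)$ — each labeled position is actually ¹³C with the
tracer purity $\pi$ — with $\mathrm{Bin}(n-j, a)$ — each unlabeled
position is ¹³C with the natural abundance $a$. Stacking these as
columns gives the $(n+1)\times(n+1)$ matrix $A$ of
`build_correction_matrix()`; every column is a probability distribution.

Only carbon is convolved. At a resolving power of 60,000 (at m/z 400)
the isotopic species of H, N, O and P are mass-resolved from the ¹³C
cluster, so the carbon-only correction is the appropriate regime;
full-formula correction is deliberately not implemented.

Defaults: $a = 0.0107$ (the IUPAC representative isotopic composition of
carbon; the choice matters in the third decimal of corrected fractions
and is configurable) and $\pi = 0.98$, the lower bound of a typical
"> 98 atom % ¹³C" commercial tracer. Both are plain arguments because
neither is a property of the algorithm.

## Inversion

`correct_cid()` normalizes the measured intensities to sum 1 and solves
the non-negativity-constrained least-squares problem
$\min_{x \ge 0} \lVert Ax - m\rVert_2$ with a Lawson–Hanson active-set
solver, then renormalizes $x$ to the simplex. NNLS rather than
$A^{-1}m$: measured clusters carry noise, and unconstrained inversion
routinely returns small negative isotopologue fractions which then
corrupt ratios and enrichment values. The NNLS optimum is verified in
the test suite against an exhaustive grid search over the simplex. Mean
¹³C enrichment is $\sum_j j\,x_j / n$, the average fraction of labeled
carbon positions.

Degenerate inputs: all-zero intensity vectors and dimension mismatches
are errors, not warnings; an exactly-zero denominator isotopologue makes
`isotopologue_ratio()` error (the ratio is undefined and excluded
downstream, never coerced to 0 or Inf).

# The SIP arm

## δ¹³C and fraction selection

`delta13C()` is the per-mil deviation
$(R/R_{\mathrm{ref}} - 1)\times 1000$ with $R_{\mathrm{ref}} = 0.0111802$
(V-PDB) by default — the scale is standard, the constant configurable.
Fractions are selected in closed density windows (defaults 1.68–1.69 and
1.71–1.72 g·mL⁻¹) after rounding densities to 3 decimals, absorbing
refractometer precision; boundary densities are included.
`find_enrichment_peak()` reports the fraction that is a strict local
maximum of δ¹³C along density — the signature of a labeled DNA band —
with ties between maxima broken toward the larger DNA amount, because
the enrichment peak co-occurs with a DNA-amount increase. An interior
peak is required: a monotone profile has no labeled band, however high
its deep-density tail.

## Enrichment factor

Two fractions per density class are sequenced per gradient and their
counts **summed** (counts are additive; relative abundance is then
well-defined on the composite). For each OTU,

$$\mathrm{EF} =
\frac{{}^{13}\mathrm{C}_{\mathrm{heavy}}}{{}^{13}\mathrm{C}_{\mathrm{light}}}
- \frac{{}^{12}\mathrm{C}_{\mathrm{heavy}}}{{}^{12}\mathrm{C}_{\mathrm{light}}},$$

the contrast of heavy-fraction over-representation between the labeled
and unlabeled feeding arms. EF is computed per replicate and averaged
(`mode = "replicate"`, default; pooling counts first is available and
has identical first two moments under the null). An OTU is called
enriched when mean EF > 0.5 **and** its relative abundance exceeds
0.1 %, both strict.

Choices the underlying rule leaves open, decided here:

* **Denominator of the 0.1 % rule** — the OTU's mean relative abundance
  over the ¹³C-arm composite samples of the (sex, time) cell, because
  the enrichment evidence lives in the ¹³C arm.
* **Zero denominators** — with the default pseudocount of 0, an OTU
  absent from a light composite but present in the matching heavy one
  has an undefined ratio; the OTU is flagged `undefined_ef` and not
  classified, never silently dropped. An optional pseudocount shrinks
  such ratios instead.
* **Genus-level reporting** — `ef_by_rank()` represents a genus by its
  maximum-EF OTU (mean-EF mode available): genus plots ask "does this
  genus contain an assimilator", not "is the average member one".

## Table hygiene

The contaminant rule removes an OTU table-wide when it is detected in a
negative control and its **best** biological relative abundance is below
10× its control relative abundance — the most permissive reading of the
rule, so real community members that bleed faintly into controls
survive. Filtering precedes rarefaction (the order the upstream protocol
states). Rarefaction is multivariate-hypergeometric subsampling without
replacement to exactly 3248 reads by default, seeded for
reproducibility; shallower samples are dropped and listed.

# Statistics

Group comparisons use an exact two-sided Wilcoxon rank-sum test:
midranks for ties, the full permutation distribution of the rank-sum
computed by dynamic programming over doubled midranks (exact also under
ties), two-sided via symmetric deviation from the null expectation —
invariant under swapping groups. At 5 vs 5 the smallest attainable
two-sided p is 2/252 ≈ 0.0079 and at 4 vs 4 it is 2/70 ≈ 0.0286;
observed p-values at these exact floors indicate complete separation.
Beyond group size 12 a tie-corrected normal approximation is used, with
a message.

Taxa–metabolite association uses Spearman correlation by default (small
$n$, non-normal enrichment data; Pearson is a switch) with permutation
p-values: exact enumeration of all $n!$ permutations for $n \le 7$,
otherwise 10,000 seeded permutations shared across all pairs of a
matrix. Significance is uncorrected at $\alpha = 0.05$ by default, the
convention of the motivating analyses; Benjamini–Hochberg is available.

# What the simulator states, and what it does not

All generators are pure functions of (config, seed).

* `gen_gradient()` — DNA amount is a light band (Gaussian at
  1.685 g·mL⁻¹) plus a heavy band (1.715 g·mL⁻¹) weighted by the labeled
  fraction. The unlabeled component additionally carries a small uniform
  smear (15 %) across the gradient: sheared and GC-heterogeneous
  genomic DNA spreads in real gradients, and without it the labeled
  share of DNA — and hence δ¹³C — would saturate past the heavy band
  instead of peaking there. δ¹³C is the DNA-weighted mixture of a
  linearly rising unlabeled baseline (−38.5 to −35.6 ‰) and a strongly
  positive labeled component, plus 0.05 ‰ measurement noise. This
  reproduces the diagnostic pattern of real gradients: an interior peak
  in the heavy window despite a rising baseline tail.
* `gen_community()` — base composition from a symmetric Dirichlet
  (concentration 0.3: long-tailed, dominance-structured, as observed in
  gut mycobiota); design sexes × {4, 10, 30} h × {¹²C, ¹³C} ×
  {heavy, light} × 3 replicates with the male 30 h cell omitted
  (mirroring late male mortality in such experiments); counts
  multinomial at depth 3248 per composite. Active OTUs get their weight
  multiplied by the heavy-shift factor (default 5) in ¹³C-heavy
  composites only. Actives are planted among OTUs with base abundance
  ≥ 0.5 % — an undetectable active is not a useful truth. Reagent
  contaminants live only in the blank control (zero community weight),
  so the 10× rule removes exactly them and never perturbs biological
  sample totals.
* `gen_cid()` — for scalar labeling probability $p$, the true ¹³C
  distribution is $\mathrm{Bin}(n, p\pi)$: tracer impurity thins the
  label at synthesis, so the recoverable enrichment is $p\pi$ (e.g.
  0.49 for $p = 0.5$, $\pi = 0.98$). The measured vector convolves
  natural abundance onto unlabeled positions; the paired correction
  model inverts this exactly at zero noise. Arbitrary simplex truths are
  accepted as-is, to emulate bimodal distributions such as
  ribose-only vs fully labeled nucleotides.
* `gen_linked_dataset()` — planted (taxon, metabolite) pairs share a
  latent factor at correlation 0.95; unlinked columns are independent.
  Observation units are replicates × times (9 by default).

What the generators do **not** emulate: PCR and primer bias,
chimeras, compositional coupling between taxa beyond the multinomial
constraint, chromatographic noise structure, or between-replicate
biological variance in community composition (replicates differ only by
counting noise). A green recovery test therefore establishes that the
algorithms are correct on their stated model, not that the thresholds
are well-calibrated for any real dataset.

# Numerical choices

* NNLS tolerance 1e-12; corrected fractions renormalized to the simplex.
* Densities compared after rounding to 3 decimals; closed intervals.
* Rank-sum p-values computed from exact integer counts (doubled
  midranks), exact up to double precision (< 2^53 assignments).
* Monte-Carlo permutation p-values include the identity:
  $(1 + k)/(1 + B)$, slightly conservative.
* All randomness flows from one top-level seed through named substreams
  (`run_pipeline()`), and generators restore the caller's RNG state.
* Pipeline outputs carry no timestamps, so reruns are byte-identical.

# Limitations: calibration of the EF rule at depth 3248

The fixed-threshold classification (EF > 0.5 ∧ RA > 0.1 %) is **not**
a calibrated test, and the package's acceptance suite documents this
honestly rather than tuning the simulator around it. For an OTU at
relative abundance $q$, each composite count is approximately
$\mathrm{Poisson}(\lambda = 3248q)$, each heavy/light ratio has variance
$\approx 2/\lambda$, and the replicate-averaged EF has standard
deviation $\approx \sqrt{4/(3\lambda)}$ under the null. At
$\lambda = 4$–30 (abundances 0.12–1 %) this is 0.2–0.6, so the
probability of a null OTU exceeding EF = 0.5 ranges from ~1 % to ~19 % —
and a long-tailed community of 200 OTUs always contains dozens of OTUs
in that band just above the 0.1 % abundance gate. Empirically the null
false-positive proportion is ≈ 5 % of OTUs (not < 1 %), and exact-set
recovery of 5 planted actives succeeds in only ~2/20 seeds despite
sensitivity 1 in every seed (~3 borderline-abundance false positives per
seed). No defensible choice among the open design decisions (abundance
denominator, replicate averaging vs pooling, undefined-EF policy)
changes this materially; only much deeper sequencing, a higher EF
threshold, or an explicit significance test for EF would. Practically:
treat EF calls for taxa near the abundance threshold with suspicion, or
raise the abundance gate toward ~2 % at this depth.
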