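---
title: "Mass-cytometry phenotyping of circulating tumour cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-cytometry phenotyping of circulating tumour cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ctcyto` implements a single-cell mass-cytometry (CyTOF) analysis of
circulating tumour cells (CTCs) enriched from blood, from raw event
tables to phenotype subgroups and downstream statistics, together with a
synthetic-data module that emulates the cohort structure the analysis
assumes. This vignette explains the model behind each stage, the
tunable parameters and their defaults, what the generator does and does
not emulate, and the numerical choices made where the design was
genuinely open.

## The analytical problem

CTCs are rare (tens to hundreds per 9 ml blood draw) and arrive embedded
in a far larger pool of cells: after microfluidic size-based enrichment,
the acquired sample contains the enriched fraction (CTCs plus
carried-over leucocytes), ~900,000 autologous carrier PBMCs barcoded
with a cadmium-106 anti-B2M/CD298 antibody to minimise cell loss during
staining, ~100,000 osmium-labelled stimulated PBMCs as a phospho-protein
staining control, and debris/doublets. A 41-antibody panel (40
analytical markers + the barcode) covers immune lineage, epithelial
lineage, EMT, stemness/proliferation, immune checkpoints and eight
phospho-epitopes.

The pipeline must therefore (i) remove debris using the per-event
acquisition Gaussian parameters, (ii) deconvolute carrier / control /
enriched populations from the barcode and osmium channels, (iii)
identify CTCs by a marker rule, (iv) score patient positivity against a
healthy-donor background, (v) cluster the pooled CTCs into phenotype
subgroups, and (vi) compare the result with bulk gene-expression
comparators.

## Event model and the synthetic cohort

No real event files ship with the package; every stage is validated
against a generator whose defaults *are* the modelled study
conditions:

* 14 patients with fixed per-patient CTC totals (97, 40, 54, 98, 58,
  167, 86, 18, 39, 25, 183, 0, 61, 218 per 9 ml) and six healthy
  donors, two of which carry 2 and 3 background cells per draw. The
  cohort table records the stage-I patient at 0 cells; an alternate
  reading treats that patient as carrying 4 background-level cells, and
  `hn_cohort(patient12_alt = TRUE)` switches to it.
* Carrier and control populations are scaled down 100-fold (9,000 and
  1,000 cells) and the enriched fraction to 2,000 cells, preserving the
  composition ratios at desk-scale runtimes. CTC counts are **not**
  scaled: the generator plants exactly `ctc_total` CTC events so that
  gate recovery can be judged in cells.
* Intensities are zero-inflated lognormal per (population, marker): with
  probability `zero_prob` the ion count is 0, otherwise lognormal with
  log-sd 0.35 and a location chosen so the typical ArcSinh (cofactor 5)
  value equals the archetype level. Archetype levels use a conventional
  ArcSinh scale (negative ~0.4, moderate 2-3, bright 4-4.5).
  `expected_arcsinh_mean()` integrates the model exactly for
  moment-fidelity checks.
* The three CTC archetypes encode the subgroup co-patterns the
  pipeline targets:
  epithelial (EpCAM/E-cadherin/pan-cytokeratin bright, vimentin low,
  stemness and checkpoint markers elevated, pSTAT1/3/5, pPARP, pAKT
  elevated), early EMT (vimentin bright, EpCAM/E-cadherin moderate,
  Twist/CD44/pERK/pCREB elevated) and advanced EMT (vimentin bright,
  EpCAM/E-cadherin low, Snail1 elevated, Ki-67 and pSTAT1 low, pCREB
  elevated).
* Debris and doublets carry shifted acquisition Gaussian parameters
  (Residual and Offset strongly inflated, Width broadened) at an
  expected 5% of events.

What the generator does **not** emulate: spillover and isotopic
impurity, acquisition drift and bead normalization (events are generated
drift-free, i.e. already normalized), staining chemistry, doublet
intensity mixing (doublets differ only in acquisition parameters) and
batch effects. Passing tests therefore demonstrate that the gating and
clustering machinery recovers a *well-specified* population structure;
they do not certify performance on real files with compensation or
drift artefacts.

## Gating

**ArcSinh transform.** `asinh(x / cofactor)` with cofactor 5, the
conventional value for mass cytometry; no single value is canonical,
so it is configurable. Acquisition channels are never
transformed and a `transformed` flag forbids double application.

**Gaussian clean-up.** An event outside the retention window of any
acquisition channel is debris. The default windows are robust: median
+/- 5 scaled MADs per channel. A fixed central-percentile default
(e.g. 1st-99th) was rejected because a quantile window removes a fixed
share of events by construction and so can neither remove a 5%
contaminant nor leave a clean sample untouched; the MAD form adapts to
the actual spread, removes essentially nothing when there is no debris,
and catches the strongly shifted debris distributions. Explicit
quantile windows and fixed bounds remain available
(`gate_thresholds(acq_quantiles=, acq_fixed=)`).

**Deconvolution and the CTC rule.** Barcode-high events are carriers,
osmium-high events are controls, double-negatives form the enriched
fraction. Cut points are found by valley-seeking: the minimum of the
kernel density between the two dominant, well-separated modes of the
channel's ArcSinh distribution, provided each side carries at least 2%
of events; otherwise the configured fixed cut (barcode/osmium 2,
CD45 2, lineage 1.5, pan-cytokeratin 2 on the ArcSinh scale) is used.
This mirrors gating that was done visually on biaxial plots while
remaining reproducible; the fallbacks matter in degenerate samples
(no control cells, a patient with no CTCs) where a channel is unimodal.
A CTC is an enriched event with CD45 low, all seven immune-lineage
exclusion markers (CD3, CD4, CD8, CD19, CD14, CD56, CD66b) low and
pan-cytokeratin at least intermediate. A single lower pan-cytokeratin
cut is used; no upper cut excludes a very-bright tail.

**Positivity.** A patient with at most `background_ctc_threshold = 4`
CTCs per draw is negative — fixed by the handling of the stage-I
patient, whose 4 cells were scored negative as comparable to the
healthy-donor background (2-3 CTC-like cells per draw in two of six
donors). That background could equally be read per ml or per draw;
the per-draw reading is used. Concentrations are reported as
round-half-up cells/ml, which reproduces the cohort's 2-24 cells/ml
range from the per-draw totals at 9 ml.

## Clustering and subgrouping

CTC events from positive patients are concatenated and quantized with a
batch self-organizing map: 10 x 10 grid, 10 epochs, Gaussian
neighbourhood whose radius shrinks linearly from half the grid to 0.5,
PCA-grid initialization, seeded throughout. All 40 analytical markers
enter on the ArcSinh scale with no further scaling (cytometry
convention); a z-scaling flag exists. Hosted clustering platforms
expose few of these settings, so they are package defaults chosen at
conventional values.

Metaclustering is an explicit elbow rule, because "elbow
meta-clustering" is otherwise operationally undefined: Ward clustering
of the codebook, and walking k upward, k is accepted as soon as moving
to k+1 recovers less than 5% of the total within-cluster
sum-of-squares decrease. A degenerate (exactly flat) curve yields the
smallest k in range. Note that for a single diffuse Gaussian cloud the
WSS declines smoothly and the rule returns a k reflecting that decline
rather than 2 — relative drops are scale-invariant, so only genuinely
flat curves collapse. A single agglomerative pass is used (no
consensus resampling).

Metacluster median profiles are cut into exactly three parent groups
(euclidean distance, average linkage) because the analysis targets
three subgroups; the count is configurable for reuse. Labels follow
the subgroup definition: lowest mean vimentin median → epithelial; of the
two vimentin-expressing groups, higher mean EpCAM/E-cadherin →
early EMT, the other → advanced EMT. Exact ties on a deciding
statistic raise an error rather than being silently broken.

The per-event 2-D embedding (`embed_events`) is a seeded PCA layout for
visual inspection only; nothing downstream consumes it.

## Statistics

`mann_whitney_u` uses the pairwise U with half-weight ties (midranks).
For n1+n2 <= 12 the two-sided p is exact by full enumeration of the
label assignments, `P(min(U*, n1n2-U*) <= min(u, n1n2-u))`; larger
samples use the tie-corrected normal approximation without continuity
correction (which keeps null p values uniform). Enumeration with ties
beyond n = 12 is refused rather than approximated silently. Subgroup
contrasts are run per marker and subgroup pair on cell-level ArcSinh
intensities by default, pooling every cell of the concatenated
dataset; per-cluster-median testing is available. No multiple-testing
correction is applied by default (raw p values are reported);
Benjamini-Hochberg is a flag.

Composition PCA is centred (not scaled) on the patients x metaclusters
fraction matrix. Score plots are often grouped visually; here the
grouping is explicit — k-means on the scores with k
chosen by mean silhouette width over 2..6 — so it is reproducible, but
it remains one defensible rule among several. Clinical associations are
univariate logistic fits (Wald p) of advanced T stage, nodal positivity
and advanced overall stage on CTC count, a Welch t-test of EMT fraction
by nodal status (Welch by default),
and one-way ANOVA of CTC count across tumour classes; complete
separation is flagged as non-convergence, not an error.

## Expression comparators

Normalization is median-of-ratios (reference: genes with no zero
counts), with size factors rescaled to geometric mean 1 so that
normalizing twice is the identity. The differential-expression test is
a deliberately simplified negative-binomial Wald: per-gene
method-of-moments dispersion from pooled within-group excess variance,
shrunk 50/50 toward the across-gene median (raw moment estimates are
unusably noisy below ~5 samples per group), delta-method standard error
`sqrt((1/mu1+alpha)/n1 + (1/mu2+alpha)/n2)` on the log scale, and a t
reference on n1+n2-2 df when the dispersion was estimated (absorbing
the estimation noise; simulation at n = 5-10 per group shows uniform
null p and type-I error at or below nominal) or a plain normal
reference when a dispersion is supplied. The full empirical-Bayes
dispersion machinery and independent filtering of dedicated DE tools
are out of scope by design. Paired per-patient enriched-vs-PBMC
comparisons have one sample per group, so they use a fixed prior
dispersion (0.1). The 0.05 FDR threshold for calling a marker gene
"detected" is a configurable default.

The tumour classifier z-scores the log-normalized EMT-signature
submatrix gene-wise, clusters samples (euclidean, complete linkage),
cuts at three and names the branches by their mean
epithelial-minus-mesenchymal z contrast (extremes → epithelial /
mesenchymal, middle → mixed). A fixed zero threshold on branch
z-scores was rejected: with a balanced design, gene-wise centering
places mixed samples at z of about 0 on both scores, making a zero cut
a coin flip. The gene list of the validated HNSCC EMT signature is
not bundled; a synthetic 25+25-gene stand-in (`emt_signature()`)
carries the same structure.

The bulk comparator's generator elevates a marker gene in the enriched
sample in proportion to the fraction of cells expressing the protein,
with a per-cell relative abundance `gain = 1000` (so a 1% expressing
fraction gives a ~10-fold elevation). With the leucocyte vimentin
level set moderate-low, this realizes the qualitative sensitivity gap
the comparison is about: epithelial transcripts are detectable for
most CTC-positive patients, while vimentin becomes detectable only
when EMT CTCs are abundant — at a fixed total CTC count, lowering the
EMT fraction monotonically lowers the vimentin detection probability.
Per-patient concordance figures measured on a real cohort depend on
patient data that are not available, so the comparator is validated by
this monotone property instead.

## Problem sizes and determinism

The default synthetic cohort is 14 patients x ~12,600 events x 48
channels (~177,000 events with donors), which gates and clusters in a
few seconds; test and acceptance runs use this full default cohort, with
null calibrations at 5 samples per group x ~300 genes x 5 seeds and the
sensitivity-gap sweep at 10 seeds per EMT fraction. Every stochastic
stage takes an explicit integer seed and is a pure function of
(configuration, parameters, seed); re-running a pipeline configuration
reproduces its output files byte for byte.

## Known limitations

* FCS support covers the common case written by modern instruments
  (FCS 3.0/3.1, list mode, float/double data, single dataset); integer
  data types, multi-dataset files and analysis segments are not parsed.
* The SOM + elbow machinery recovers the three generated archetypes; it
  is not expected to reproduce the finer-grained (e.g. 13-cluster)
  structure real data can show, which reflects within-subgroup
  variation the generator only partly emulates.
* The clinical-association battery is descriptive; with 14 patients the
  logistic Wald p values are approximate and are reported as such.
* Healthy-donor background cells are modelled as a single
  panCK-moderate/CD45-low archetype labelled `ctc_background`, an
  extension of the truth-label vocabulary.
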