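---
title: "Methods: quantifying mRNA localization to myelin sheaths and discovering 3' UTR motifs"
author: "sheathrna authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mRNA localization to myelin sheaths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheathrna)
library(dplyr)
```

# Scope

Oligodendrocytes extend nascent myelin sheaths around axons, and a subset of
mRNAs — most famously *Mbp* — is transported into the sheath and locally
translated there, with the localization information carried by *cis*-regulatory
elements in the 3' UTR. `sheathrna` packages the complete computational side
of this kind of study as one tested pipeline:

1. **Imaging quantification** of smFISH puncta and MS2 live-reporter signal in
   sheaths: background subtraction, thresholding, particle analysis with
   integrated density, line-scan enrichment profiles at sheath termini, and
   the associated statistics.
2. **Transcriptome filtering** that defines a myelin transcriptome and
   candidate 3' UTRs from replicate FPKM tables and keyword-matched ontology
   terms.
3. **A motif workflow**: ZOOPS EM discovery, PWM log-odds scanning with exact
   background p-values, region classification of occurrences, and enrichment
   testing against shuffled controls.
4. **Seeded synthetic-data generators** for every input, with ground truth
   attached, so each stage can be validated by parameter recovery without any
   external download.

# Imaging quantification

## Puncta analysis

The smFISH quantification mirrors the standard ImageJ-style recipe, with each
step an explicit, testable function:

* `max_project()` — pixelwise maximum over a z-range.
* `subtract_background()` — rolling-ball background subtraction, implemented
  as a true grayscale **opening by a ball** (sphere-cap) structuring element:
  erosion $\min_o\,[I(p+o) - h(o)]$ then dilation $\max_o\,[E(p-o) + h(o)]$
  with $h(o)=\sqrt{r^2-\lVert o\rVert^2}$ and edge replication at borders.
  We deliberately use the exact morphological definition rather than the
  ImageJ paraboloid approximation because it has a brute-force per-pixel
  oracle that the test suite checks against on random images. The radius
  (default 2.5) is interpreted in **pixels**; the units of published
  "rolling ball 2.5" settings are ambiguous, and pixels is the ImageJ
  convention for that dialog.
* `threshold_mask()` — strict `image > mean + k * SD` with the **sample** SD
  (n−1) and default `k = 3`. Whether published scripts used population or
  sample SD is typically unstated; we fix sample SD as a documented
  convention (the two differ negligibly at image scale).
* `detect_puncta()` — 8-connected component labeling (the ImageJ particle
  analyzer default), calibrated area filter (default 0.01 µm² to ∞),
  circularity filter $4\pi A/P^2$ with the perimeter counted as exposed pixel
  edges and the ratio clamped to ≤ 1, and per-punctum **integrated density**
  = area (µm²) × mean intensity, the calibrated "IntDen" convention.
* `roi_puncta_density()` — mean integrated density over puncta fully inside
  an ROI; any punctum whose pixel set touches the ROI border is excluded,
  reproducing the border-exclusion rule used when counting puncta in
  hand-drawn ROIs.

## Line profiles at sheath termini

`extract_line_profile()` samples a maximum projection by bilinear
interpolation (1-px line width) every 0.2 µm along a polyline that starts at
the sheath terminus, over a fixed 7 µm grid (36 samples); paths within the
±0.3 µm length tolerance but shorter than the grid have their tail samples
clamped to the path end so the grid length is invariant. `normalize_profile()`
divides by the per-sheath mean, so normalized profiles average to exactly 1 —
this is asserted in tests for every input.

`profile_group_compare()` evaluates the two groups at every distance with a
two-sided Wilcoxon rank-sum test: exact enumeration whenever the smaller
group has ≤ 8 profiles and the values are untied, otherwise the normal
approximation with tie correction and no continuity correction; a degenerate
statistic (z = 0, e.g. all values tied) reports p = 1 by convention. The
implementation is `stats::wilcox.test` driven by these rules, and the test
suite checks it against exhaustive rank enumeration for all group sizes ≤ 6.

**Terminal enrichment** is never given an operational definition in the
imaging literature that reports "proportion of sheaths with terminal
enrichment"; we adopt the simplest reading consistent with the line-scan
figures: a sheath is enriched when the mean normalized intensity within 2 µm
of the terminus strictly exceeds the mean over the remaining distances (a
configurable margin defaults to 0). Proportions of sheath counts are reported
as integer percents; 18/38 gives 47%, 10/35 gives 28.6% ≈ 29%.

Cell-body reporter intensity (`cell_body_intensity()`) averages three 3×3-px
ROI means (periphery, center, between) and `normalize_to_control()` divides by
the control-group mean, so the control normalized by itself has mean exactly 1.
`density_length_correlation()` is Spearman's rho with average ranks and a
permutation p-value — exact over all $n!$ permutations for $n \le 8$, seeded
Monte Carlo above.

# Transcriptome filtering

All thresholds are **strict** comparisons, exactly as filter descriptions are
usually worded ("greater than 20", "less than 0.05"): boundary genes are
excluded, and the tests pin this down.

* `filter_min_expression()` keeps genes with every treatment replicate > 20
  normalized counts.
* `keyword_lists()` matches lowercase stems (`synap`, `translation`,
  `myelin`, `oligodend` by default) as case-insensitive substrings against
  each gene's ontology terms and deduplicates per-stem gene lists;
  `multi_list_candidates()` intersects the lists (≥ 2 memberships by
  default).
* `call_myelin_enriched()` keeps genes with q < 0.05 **and** mean FPKM > 5 in
  treatment or control, attaches fold change (mean treatment / mean control),
  and marks as `localized` the subset with fold change > 1 that carries the
  `fully_annotated` flag. Supplied q-values are used as-is (published tables
  usually ship them pre-computed); when only p-values are present,
  Benjamini–Hochberg q-values are computed with `stats::p.adjust`. What
  exactly "fully annotated" means in published gene tallies is not
  recoverable, so it is an input flag here, not a computation. The manual
  narrowing steps of candidate selection (database lookups, literature
  search, ortholog identification) are likewise represented as an allow-list
  input, not computation.
* `select_longest_variant()` keeps the longest splice variant per gene, ties
  broken by the lexicographically smallest transcript id (the tie rule is
  arbitrary but fixed and tested).
* `rank_terms()` filters an ontology-term table to FDR < 0.05, sorts
  ascending, deduplicates term names keeping the best FDR, and takes the top
  20.

# Motif workflow

## ZOOPS EM discovery

`discover_motifs()` implements classic MEME-style discovery under the
zero-or-one-occurrence-per-sequence model. For sequence $i$ with $m_i$
candidate start positions, the likelihood is

$$P(s_i) = P_{bg}(s_i)\Big[(1-\gamma) + \frac{\gamma}{m_i}
\sum_{j} \prod_{k=1}^{w} \frac{\theta_{k}(s_{i,j+k})}{\theta_0(s_{i,j+k})}\Big]$$

with site prior $\gamma$, PPM $\theta$, and a 0-order background $\theta_0$.
The E-step computes the per-sequence posterior over "no site" versus each
start; the M-step re-estimates the PPM with a Dirichlet pseudocount (0.1 per
cell) and $\gamma$. Design choices, made once:

* **Background fixed.** $\theta_0$ is estimated from the input once and held
  fixed across EM iterations — it then matches the background the scanner
  uses, and the EM objective (log likelihood plus Dirichlet log-prior) is
  still provably nondecreasing, which the tests assert on every run via the
  recorded `objective_trace`.
* **Seeding.** Candidate PPMs are seeded from enumerated input subsequences
  (0.82 on the seed base), screened by one E-step likelihood, and the top
  `n_seed_starts` (default 5) are refined by full EM. When there are more
  than `max_seed_candidates` (default 600) windows, seeds are subsampled
  deterministically from the seed.
* **Width search.** Every width in `width_min:width_max` is tried and ranked
  by a BIC-penalized log-likelihood ratio ($\mathrm{LLR} - \frac{1}{2}(3w+1)\log n$).
  The package default range is 6–12 — a desk-scale exhaustive search;
  callers analyzing longer elements can widen it.
* **Multiple motifs.** After a motif is accepted, its sites (posterior site
  probability > 0.5) are masked and discovery repeats, up to `max_motifs`.

Bit-for-bit equivalence with MEME is a non-goal; what is required — and
tested — is parameter recovery: an 8-nt consensus planted in 80% of twenty
100-nt sequences is recovered within Hamming distance 1 in ≥ 8 of 10
replicate datasets.

## Scanning and exact p-values

`log_odds_score()` scores a window in bits as
$\sum_k \log_2 (\theta'_k(b_k)/\theta_0(b_k))$, where
$\theta' = (\theta + c\,\theta_0)/(1+c)$ applies the pseudocount $c = 0.1$
proportionally to the background (close to FIMO's prior, and it keeps scores
finite). `score_pvalue()` computes $P(\text{score} \ge s)$ under the 0-order
background **exactly up to discretization** by dynamic programming over the
per-column score distribution on a 1/1000-bit integer grid; the scanner
computes window scores on the same grid, so scan p-values and the DP agree
identically, and the tests verify the DP against exhaustive enumeration of
all $4^w$ windows for widths ≤ 5.

`scan_sequences()` reports every forward-strand window with $p \le$ `p_max`
(default 1e-4, the FIMO default), overlapping hits allowed, coordinates
0-based half-open. Inputs here are cDNA/3' UTR sequences, i.e.
single-stranded RNA in DNA alphabet, so only the forward strand is scanned by
default; DNA-style double-strand scanning is available with
`both_strands = TRUE`. Windows containing non-ACGT/U letters are skipped with
a warning by default (`on_invalid = "error"` raises instead). The background
is re-estimated from the scanned set unless supplied, and clamped away from
zero for degenerate compositions.

## Region classification and enrichment

`classify_positions()` labels an occurrence with the region (5' UTR / CDS /
3' UTR) that fully contains it and labels occurrences straddling a region
boundary `other`. `summarize_presence()` reports occurrences, distinct
sequences with ≥ 1 hit, and the percentage of the universe with a hit to one
decimal; `presence_from_counts()` / `position_summary_from_counts()` apply
the same reporting arithmetic to published count tables (shipped under
`inst/extdata/` as plain TSV).

`enrichment_test()` labels each foreground and control sequence
present/absent at `p_max` and applies the one-sided Fisher exact test
(hypergeometric tail; `stats::fisher.test`), with the sample odds ratio given
a Haldane 0.5 correction when a cell is empty. When no control set is
supplied, per-sequence shuffles of the foreground are generated:
`shuffle_sequences()` offers exact letter permutation (`mono`) and an
Altschul–Erickson Euler-path doublet shuffle (`di`) that preserves each
sequence's exact dinucleotide multiset.

`delete_sites()` and `build_insertion()` are the in-silico counterparts of
the reporter-construct designs used to test motif necessity and sufficiency:
deletion of merged 0-based half-open intervals, and assembly of motifs
separated by seeded random 3–4-nt spacers between flanks.

# Synthetic data: what it emulates, and what it does not

The generators define the study conditions under which the package validates
itself.

**Imaging** (`sim_image_stack()`): horizontal capsule-shaped sheaths
(membrane channel) with diffraction-limited mRNA puncta rendered as
isotropic 3D Gaussians in physical units (default σ = 0.15 µm, 0.1 µm
pixels, 0.3 µm z-steps — the finer of the usual confocal z-intervals), over
a constant-plus-linear-gradient background, with Poisson shot noise plus
Gaussian read noise applied last (both switchable off so oracle tests can
run on the noiseless render). A `terminal_bias` fraction of spots is forced
into the distal 2 µm, emulating terminally enriched transcripts; bias 0
gives the uniform control. Ground truth records every spot coordinate and
the sheath skeletons used for line scans. Not emulated: real optics
(aberration, anisotropic PSF, Airyscan processing), sheath curvature, or
autofluorescence structure — so passing recovery tests demonstrates the
correctness of the quantification pipeline, not robustness to every real
imaging artifact.

**Sequences** (`sim_transcripts()`): i.i.d. background with configurable GC
(default 0.45, a typical vertebrate transcriptome value), region lengths
drawn per transcript (defaults 50–150 / 300–900 / 200–600 nt, CDS rounded to
a codon multiple), planted motif instances per region with exact recorded
coordinates. The 0-order background matches the scanner's model by design;
real UTRs have repeat structure and compositional heterogeneity that this
does not reproduce.

**Abundance** (`sim_abundance()`): log-normal baseline FPKM (mean log 20,
SD 1 on the natural-log scale), 3 treatment versus 6 control replicates —
the purified-myelin versus cultured-oligodendrocyte design — with a planted
enriched fraction (default 10%) at a configurable fold change and replicate
log-SD `dispersion` = 0.25, our one-time choice of a "modest" replicate
noise for well-behaved RNA-seq abundance estimates. p-values come from a
Welch t test on log FPKM with BH q-values attached. No count-level model
(no mean–variance trend, no length bias) is simulated; differential
expression modeling is out of scope.

All generators are pure functions of their arguments: the same seed gives
byte-identical output, asserted in tests.

# Pipeline, problem sizes, and reproducibility

`run_pipeline()` chains the stages on synthetic inputs and emits the four
summary tables (presence, position, enrichment, imaging) plus a provenance
block (seed, config hash). One global seed fans out to per-stage seeds via a
stage-name hash, so any stage is reproducible in isolation. The bundled demo
configuration uses 400 genes, 40 short transcripts (≈ 200–300 nt, planted
consensus at 80% in the 3' UTR so single-run discovery is well-posed), and
two 6-sheath imaging groups — sizes chosen so the full demo completes in
well under a minute on one CPU while still exercising every code path; the
validation suite uses the larger, harder configurations quoted above for
parameter recovery (2,000-gene abundance tables, 10 replicate discovery
datasets).

The companion script `scripts/acceptance.R` recomputes, from scratch at a
given seed, the derived statistics from the published count-table fixtures
and all parameter-recovery metrics, and writes them as JSON (see the README).

# Known limitations

* Discovery assumes ACGT/U-only input and a 0-order background; it will not
  model CpG-like dinucleotide bias (use the dinucleotide shuffle for
  enrichment controls instead).
* The rolling-ball radius and SD conventions are fixed interpretations of
  ambiguous published settings (pixels; sample SD); both are parameters, so
  other readings are one argument away.
* Line profiles use a 2D maximum projection, as the source protocols do; no
  3D spot fitting or deconvolution is attempted.
* `classify_positions()` requires complete region tables; transcripts with
  partial annotation must be filtered or repaired first
  (`validate_formats()` reports tiling violations).
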