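---
title: "EP-Seq scoring: model, estimator and design notes"
author: "epseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EP-Seq scoring: model, estimator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epseq)
```

## The assay and its generative model

EP-Seq is a sort-seq deep mutational scan: a barcoded site-saturation
library of an enzyme is displayed on yeast, stained either for display
level (expression branch, a folding-stability proxy) or for catalytic
activity via peroxidase-mediated proximity labeling, and FACS-sorted
into four fluorescence bins. Gate 1 is placed to capture 99% of a
negative-control (non-fluorescent) population; the remaining expressing
cells are split into three bins of equal occupancy. Each bin is
sequenced through the 15-nt UMI that links every plasmid to its variant.

The scoring model treats reads as proportional evidence of sorted
cells. Within a bin, variant *v*'s cell count is

$$c_v = r_v \cdot \frac{c_{tot}}{r_{tot}}$$

and its expected fluorescence across the sort is the bin-median-weighted
mean

$$\beta_v = \frac{\sum_i \omega_i c_{vi}}{\sum_i c_{vi}},
\qquad F_v = \log_2\!\left(\frac{\beta_v}{\beta_{wt}}\right).$$

Replicates are combined with the cell-weighted mean
$F_{fin} = \sum_j F_{vj} c_{vj} / \sum_j c_{vj}$, where $c_{vj}$ is the
variant's reads-derived cell total in replicate *j* (FACS event counts
per variant are not observable in a pooled sort, so the reads-derived
total is the only available weight). For clones assayed individually,
the same weighted mean over gate percentages gives a *plain-ratio*
score $\beta_v/\beta_{wt}$, deliberately not log-transformed, matching
how single-clone flow data are reported.

This estimator is intentionally the assay's own simple weighted-mean
scheme; maximum-likelihood sort-seq estimators are out of scope.

## What the synthetic generator emulates

`generateLibrary()` + `simulateSortAndSequence()` produce a complete
experiment with known truth:

* **Library.** Every NNK-realizable substitution per mutagenized codon:
  up to 19 missense, one nonsense (TAG is the only NNK stop) and a
  synonymous codon swap. The wild-type codon defaults to the
  alphabetically first standard codon of the residue — a stand-in for a
  real (often codon-optimized) gene — so nearly every position carries a
  synonymous variant, as in a real NNK library; only Met and Trp
  (single-codon residues whose codon is itself NNK) cannot.
* **Fluorescence.** Per-cell log2 fluorescence is
  $\mathcal{N}(\log_2 \mu_{wt} + f_{true},\ \sigma)$, i.e. log-normal
  with geometric mean $\mu_{wt} 2^{f_{true}}$ — the flow-cytometry
  convention, chosen so that the ratio of geometric means inverts to
  exactly $f_{true}$ under the log2 score. The instrument noise
  magnitude is not published for this assay, so $\sigma$ is an explicit
  free parameter (default 0.5 log2 units, a typical yeast-display
  spread).
* **Sorting and sequencing.** Cells are gated by thresholds from
  `placeGates()` (negative-control 99th percentile, then expressing
  tertiles), each bin's $\omega$ is the realized median, and reads are
  Poisson at 25 per sorted cell (the assay's stated average depth),
  spread multinomially over the bin's cells. UMIs can be corrupted per
  base; conflicted barcodes are injected as exact ties so the
  conflict-resolution rules must drop them.
* **Truth conventions.** Synonymous variants are exactly neutral;
  nonsense variants default to −0.7 except in the C-terminal tail
  (positions beyond 350/365 of the sequence), where a stop leaves a
  functional protein; missense truths are uniform on (−0.8, 0.3).
  Cells are allocated equally by default, with a per-variant vector
  available (the wild-type reference is typically given ~10× the cells
  of a single variant, reflecting its real abundance and keeping the
  shared $\beta_{wt}$ denominator from adding a common offset to every
  score).

What it deliberately does **not** model: PacBio subreads or consensus
calling (the pre-LUT record is the input boundary), FACS optical
artifacts (doublets, spillover), uneven PCR amplification, and
position-dependent staggered-primer offsets (flank anchoring makes UMI
localization offset-free). Passing tests therefore demonstrate the
pipeline's correctness given the model, not robustness to every real
instrument artifact.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `read_depth_factor` | 25 | reads/cell | the assay's stated average sequencing depth |
| `sigma_log2_fi` | 0.5 | log2 FI | free noise parameter (unpublished for the instrument) |
| `gates$neg_quantile` | 0.99 | fraction | gate 1 captures 99% of the negative control |
| `min_mean_q` (LUT, tags) | 20 | Phred | the Q20 quality filter, applied inclusively (≥) |
| UMI length | 15 | nt | barcode design; any other length is tag 3 |
| `min_cells` | 10 | cells | replicate-support filter for reported variants |
| `k` (neutral range) | 1 | SD | neutrality as mean ± 1 SD of synonymous scores |
| `contact_cutoff` | 5.0 | Å | heavy-atom distance defining interface residues |
| SASA `probe` | 1.4 | Å | water probe radius |
| SASA `n_points` | 240 | — | lattice density; see numerical notes |

## Numerical and design choices

* **Fractional cells.** The reads-to-cells conversion is a proportion
  and is never rounded; rounding biases low-count variants.
* **No pseudo-counts.** A variant with cells only in bin 1 still gets
  $\beta = \omega_1 > 0$; fluorescence units are positive, so no
  smoothing is needed anywhere.
* **Q20 boundary.** The quality filter is `>= 20` uniformly (the
  threshold is an argument everywhere it appears).
* **Tag precedence.** Size → quality → lookup (3 beats 2 beats 1/0):
  a wrong-size UMI is never quality-checked, and a low-quality UMI is
  never looked up. UMIs containing N count as quality failures.
* **Conflict ties.** Support compared first as the per-variant read
  count, then as the maximum mean barcode quality among supporting
  reads, then the minimum indel count; a full tie removes the UMI. The
  resolution is order-independent (tested by permutation).
* **Expression floor.** The normalized-activity floor is computed from
  the data at hand as nonsense mean + 1 SD, not hard-coded; on the
  published dataset that instance was −0.69 + 0.04 = −0.65.
* **Hotspot ties.** Ranking by normalized activity breaks ties by
  variant id so the top-1000 set is deterministic and
  permutation-invariant.
* **Position averages.** Per-position summaries average missense
  variants only; synonymous and nonsense rows are excluded (the heatmap
  keeps the stop row separately). Percent differences in subgroup
  contrasts are reported against the absolute overall mean.
* **Correlations.** Pairwise-complete deletion; two-sided p values; no
  multiple-testing correction (single named comparisons).
* **PDB parsing.** Via `bio3d`; alternate locations resolve to the
  highest occupancy (ties: first encountered); hydrogens are dropped
  (structures of this vintage lack them); unknown elements fall back to
  the carbon radius with a warning.
* **Interface detection** uses a heavy-atom contact distance (default
  5 Å) rather than a buried-surface-area tool — a deliberate
  substitution that keeps the feature self-contained; the cutoff is an
  argument. `d_interface` is the Cα distance to the nearest interface
  Cα, 0 for interface residues themselves.
* **SASA.** Shrake–Rupley with a deterministic Fibonacci sphere
  lattice. An isolated atom reproduces $4\pi(r+1.4)^2$ to well under 1%
  at 240 points; rigid-body invariance holds to 0.5% at 960 points
  (the lattice is fixed in space, so rotation changes the quadrature
  slightly — use more points where that matters). Relative SASA divides
  by Tien-style theoretical maxima (shipped, replaceable) and is capped
  at 100.
* **Property scales.** The defaults are Kyte–Doolittle hydrophobicity
  and Zimmerman bulkiness/polarity; the landscape analyses treat the
  table as configuration, and delta scales are mutant − wild-type.
* **Active site.** There is no universal definition of "the catalytic
  centre", so it is an explicit input: a coordinate or a ligand residue
  name whose centroid is used.
* **Numbering.** Structure features are keyed by PDB residue numbers;
  `joinFitnessFeatures()` accepts a mapping table to reconcile library
  codon numbering with structure numbering, and flags (never drops)
  positions missing from the feature table.

## Validation problem sizes

The test suite validates parameter recovery at deliberately desk-sized
conditions: ~320 synonymous variants at 100 cells each for the
neutrality check; ~500 missense variants, 100 cells/variant, depth 25,
$\sigma = 0.5$, two replicates for recovery (Pearson r ≥ 0.9 against
truth and between replicates); 10^5 cells for gate-capture checks.
These sizes were chosen to give stable statistics (binomial/CLT error
well inside the asserted tolerances) while keeping the whole suite fast.

## Known limitations

* The weighted-mean estimator compresses strongly deleterious scores:
  once a variant's cells are all in bin 1, further loss of fluorescence
  cannot lower $\beta$ below $\omega_1$. The real assay shares this
  floor; treat very negative scores as censored.
* $\beta_{wt}$ is a shared denominator: its sampling error shifts all
  scores coherently, which is why the WT reference needs generous cell
  support (and why the synonymous distribution, not WT alone, defines
  neutrality).
* Activity truths in the generator default to the expression truths;
  planted activity/expression decoupling (e.g. a catalytic term near a
  chosen site) must be supplied through `f_act` to study tradeoff
  recovery.
* The conflict-resolution rules operate on aggregated per-variant
  summaries (count, max quality, min indels); the original pipeline's
  aggregation granularity is not published, and a different convention
  could resolve a small set of borderline UMIs differently.
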