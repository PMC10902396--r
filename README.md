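# epseq

Expression and activity fitness estimation for enzyme proximity
sequencing (EP-Seq), a FACS sort-seq deep mutational scanning assay.

## What this package does

EP-Seq measures two phenotypes for every variant in a barcoded enzyme
library displayed on yeast: an **expression** phenotype (display level, a
proxy for folding stability) and a **catalytic activity** phenotype
(peroxidase-mediated proximity labeling). In both branches the cell pool
is sorted into four fluorescence bins — gate 1 capturing 99% of a
non-fluorescent negative-control population, the expressing remainder
split into three equal-occupancy bins — and each bin is sequenced through
the 15-nt UMI barcode that identifies the variant carried by each cell.

The package implements the computational pipeline from raw inputs to
interpreted landscapes:

* **Look-up table (LUT)** — UMI → variant maps built from long-read
  derived records, with a Q20 mean-quality filter, a 15-nt size filter,
  and conflict resolution: ties between variants sharing a UMI are broken
  by supporting-read count, then maximum barcode quality, then minimum
  indel count; unresolvable UMIs are dropped.
* **Counting** — anchored flank matching extracts UMIs from per-bin short
  reads; each read is tagged (3: wrong size; 2: below Q20; 1: in the LUT;
  0: absent) and tag-1 reads are grouped into a variants × bins count
  table.
* **Fitness** — reads are converted to sorted-cell numbers,
  `c_v = r_v · c_tot / r_tot`; each variant's weighted mean fluorescence
  is

      β = Σᵢ ωᵢ·c_vi / Σᵢ c_vi

  with ωᵢ the median fluorescence of bin *i*, and its fitness is
  `F = log2(β_v / β_wt)`. Replicates are combined by a cell-weighted
  mean, `F_fin = Σⱼ F_vj·c_vj / Σⱼ c_vj`. Synonymous variants define the
  assay's neutral range (mean ± SD); nonsense variants define the
  expression floor used by the **normalized activity**
  `na = 2^F_act / 2^F_exp`, which isolates catalytic effects from
  expression effects (na > 1 flags expression-independent enhancement).
* **Structure** — per-residue features from a PDB file: Shrake–Rupley
  relative solvent accessibility (deterministic Fibonacci sphere
  sampling), Cα B-factors, mean Cα distance to the FAD cofactor atoms,
  distance to the nearest dimer-interface residue (heavy-atom contact
  criterion), distance to an explicit active-site centre, and
  hydrophobicity/bulkiness/polarity scales.
* **Analysis** — fitness/feature joins, per-position summaries,
  Pearson/Spearman correlations with two-sided p values, subgroup
  contrasts (e.g. residues within 4 Å of FAD), conserved-site screens,
  heatmap matrices, and activity-hotspot ranking (six most frequent
  positions among the top 1000 normalized-activity variants).
* **Synthetic generator** — a ground-truth simulator of the whole assay
  (NNK site-saturation library, per-cell log-normal fluorescence with
  geometric mean `μ_wt·2^f_true`, gate placement, multinomial sorting and
  read sampling at 25 reads/cell, UMI errors, barcode-conflict
  injection), so the entire pipeline is testable with no external data.

## Worked example

Simulate a 10-codon saturation library, run both replicates through the
full pipeline, and compare estimates to the generator's truth:

```r
library(epseq)
cfg <- simConfig(wt_protein = "MKTAYIAKQR", n_cells_total = 20000,
                 seed = 42)
res <- runPipeline(cfg, n_replicates = 2)
cons <- as.data.frame(res$consensus)
tr <- as.data.frame(res$truth)
m <- merge(cons, tr[, c("variant_id", "f_true_exp")], by = "variant_id")
head(m[, c("variant_id", "variant_class", "F_fin", "cells_total",
           "f_true_exp")], 5)
#>   variant_id variant_class   F_fin cells_total f_true_exp
#> 1        A4*      nonsense -0.4682         190     -0.700
#> 2        A4A    synonymous -0.0456         190      0.000
#> 3        A4C      missense -0.2148         187     -0.160
#> 4        A4D      missense -0.1659         190     -0.234
#> 5        A4E      missense  0.0890         194      0.135

cor(m$F_fin, m$f_true_exp)
#> [1] 0.989
neutralRange(m$F_fin[m$variant_class == "synonymous"])[c("mean", "sd")]
#> $mean 0.013   $sd 0.035
```

Each row is one codon variant (`A4C` = Ala4→Cys): `F_fin` is its
consensus log2 fitness across the two simulated replicates, weighted by
the ~190 reads-derived cells supporting it, and tracks the planted truth
closely (r = 0.989 here). The synonymous variants sit in a narrow band
around zero — the assay's neutral range. Strongly negative scores (the
stop codon `A4*`) are compressed toward the bottom gate, as in the real
assay, because all poorly displaying cells collect in bin 1.

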