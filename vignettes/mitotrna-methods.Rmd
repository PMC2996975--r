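---
title: "Methods: translational and deamination constraints on mitochondrial tRNA gene arrangement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translational and deamination constraints on mitochondrial tRNA gene arrangement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotrna)
```

## The scientific question

The gene arrangement of vertebrate mitochondrial genomes — 13 protein-coding
genes, 2 rRNAs, 22 tRNAs and one control region (CR) on a circular molecule of
roughly 16.5 kb — has been conserved from jawless fishes to mammals. Two
mechanistic hypotheses predict *where* tRNA genes should sit if the arrangement
is under selection rather than merely inherited:

1. **Translational efficiency.** Both strands are transcribed from promoters
   in the CR, and transcripts covering genes far from the CR are more often
   incomplete. tRNAs decoding heavily used codons should therefore sit close
   to the CR. Because all 13 mitochondrial proteins are transmembrane and
   hydrophobic-residue-rich, the tRNAs of hydrophobic amino acids are the
   heavily used ones.
2. **Deamination avoidance.** Under the strand-displacement model of mtDNA
   replication, the parental heavy (H) strand is left single-stranded from the
   time the H-strand replication origin (O~H~, in the CR) fires until
   light-strand synthesis, initiated at O~L~ (in the WANCY tRNA cluster),
   passes back over it. Single-stranded DNA deaminates (A→hypoxanthine, read
   as G; C→U, read as T), so long-exposed tRNA loci should be enriched for G
   and T at mutation-sensitive anticodon positions if selection has already
   adjusted their composition, or should avoid long-exposure positions
   otherwise.

`mitotrna` implements both analyses as a tested pipeline over annotated
genome records, plus a seeded synthetic-data generator so that every stage can
be validated against known ground truth without any downloads.

## Distance from the control region

Distances are measured from the CR's 3′ end *on each strand* to the 5′ base of
each tRNA gene, with the adjacent base at distance 1. The CR has two
boundaries; the one whose next base (in increasing coordinates) starts the
H-strand gene block is the H-strand reference, and the opposite boundary is
the L-strand reference. In the typical arrangement tRNA-Phe (H) and tRNA-Pro
(L) flank the CR and both get distance 1; this anchoring is what makes
distances comparable across strands. Coordinates are 1-based inclusive and
wrap-around features are stored as two-interval joins, so the measurement is
invariant to rotating the circular coordinate origin (tested property).

**Transcription-start offsets.** True transcription start sites are not
exactly at the CR boundary and may differ between strands. The
`offset_sensitivity()` rerun displaces both references by ±150 and ±500 bp and
repeats the hydropathy rank test. An offset distance is computed as
`d - delta` clamped below at 1: a gene lying at or upstream of the displaced
start is treated as adjacent to it. The alternative — wrapping the distance
around the whole circle — would teleport the CR-adjacent genes (Phe, Pro) to
~16 kb, which no model of transcription supports and which would make the
robustness rerun answer a different question. Clamping preserves the rank
order of all genes, so the test's significance classification is stable by
construction wherever no gene order straddles the offset.

## Codon usage

Usage is counted over the 13 protein-coding genes under the vertebrate
mitochondrial genetic code (AGA/AGG are stops, ATA is Met, TGA is Trp; 60
sense codons). Each CDS is read in its own frame from its own 5′ start
(L-strand genes reverse-complemented first), so the ATP8/ATP6 and ND4L/ND4
overlaps contribute once per gene — they are different codons in different
frames. Complete stop codons and incomplete (polyadenylation-completed)
terminal codons are excluded: usage is tallied only for codons a tRNA
decodes. The 22 codon families (eight 4-codon boxes read via a wobble-U
anticodon, fourteen 2-codon sets) partition the 60 sense codons; this
partition is asserted by exhaustive enumeration and cross-checked against the
reference genetic-code table in the test suite. Downstream analyses use
relative family frequencies (counts / total sense codons), so genomes of
different lengths are comparable; the log transform happens at the contrasts
stage, with a pseudocount of `0.5 / total_sense` for a zero-usage family.

## Rank test and correlations

* **Mann-Whitney U** (hydrophobic vs hydrophilic tRNA distances, 10 vs 12):
  U is computed from midrank sums; for n₁+n₂ ≤ 25 the p-values are exact,
  obtained from a subset-sum count over the doubled midranks (equivalent to
  enumerating all `choose(n1+n2, n1)` labelings and conditioned on the
  observed tie pattern). Both tails are always reported; the headline is
  two-tailed, which is the convention the exact human-table p (0.029)
  matches. Larger samples use the tie-corrected normal approximation with
  continuity correction.
* **One-tailed Pearson and Spearman** correlations use the t statistic on
  n − 2 df; Spearman is Pearson on midranks with the same t approximation
  (not an exact rank permutation), matching how comparative analyses
  conventionally report rank correlations with t and df.
* **Through-origin correlation** for contrasts: r = Σxy / √(Σx²·Σy²) with
  n − 1 df. Contrasts have zero expectation and arbitrary sign, so no
  intercept is fitted, and the statistic is invariant to flipping both
  members of any pair (tested).
* **Meta-analysis across tRNA families**: the pooled effect is the inverse
  Fisher transform of the (nᵢ − 3)-weighted mean of atanh(rᵢ); evidence is
  combined with an unweighted Stouffer sum, Z = Σ Φ⁻¹(1 − pᵢ)/√k. The
  unweighted form is the default because the original weighting convention
  for this analysis is not recorded; a weighted variant would only differ
  when family sizes differ, which under this pipeline they rarely do.

## Independent contrasts

Species values are not independent draws; shared ancestry inflates nominal
degrees of freedom. The pipeline uses Felsenstein's independent contrasts: at
each internal node of a rooted binary tree with daughter values $x_i, x_j$ on
(tie-adjusted) branch lengths $b_i, b_j$, the standardized contrast is
$(x_i - x_j)/\sqrt{b_i + b_j}$, the nodal value is the
branch-length-weighted mean, and the parent branch is extended by
$b_i b_j/(b_i + b_j)$; a tree with $n$ tips yields $n-1$ contrasts. The
implementation is cross-checked in the tests against `ape::pic` (values,
up to sign) and against a brute-force GLS oracle under the Brownian
covariance matrix (the through-origin correlation of contrasts equals the
GLS correlation; asserted to 1e-10 on random trees).

Choices where the procedure is genuinely open:

* **Branch lengths default to 1.** Composite literature trees carry no rate
  estimates; equal lengths is the classic default for that situation, and a
  user-supplied tree with lengths is honored.
* **Sign orientation**: pairs are oriented so the usage contrast is ≥ 0.
  The through-origin correlation is unaffected; orientation only
  standardizes output.
* **Variables**: log10 relative family usage (x) against log10 distance in
  bp (y). Logs focus the analysis on proportional change; both variables are
  strictly positive (pseudocount above).
* **Polytomies are rejected**, not silently resolved: contrasts at a
  polytomy are not independent, and silent resolution would manufacture
  data. The synthetic trees are always binary.

## Replication exposure and anticodon composition

The replication map reduces each genome to two origin points: O~L~ from the
annotated L-strand origin midpoint, or — when the annotation is missing —
imputed at the midpoint of the gap between tRNA-Asn and tRNA-Cys, the WANCY
position where O~L~ resides in vertebrates; O~H~ from an annotated H-strand
origin, with the CR's H-strand reference as fallback. L-strand synthesis is
oriented in increasing coordinates (the orientation in which Cys…Pro lie
downstream of O~L~ in the typical order). For each tRNA, α is the distance
from O~L~ along that direction to the gene's reference point (its coding 5′
end, the same anchor the CR distances use; a midpoint alternative is a
configuration switch), β = genome length − α, and the exposure score is α for
genes on the O~L~→O~H~ arc ("between origins"; 13 genes in the human
genome) and α − β for the other 9. On the human annotation this reproduces
the canonical 13/9 split exactly.

Anticodon G+T content is scored at two of the three anticodon positions
under two conventions, both first-class outputs:

* `codon12_pairing` (default): the bases pairing codon positions 1-2
  (structural anticodon positions 36 and 35). These are the
  non-degenerate, mutation-sensitive sites, which is the biological reading
  of "first and second anticodon positions".
* `first_two_5to3`: anticodon bases 1-2 read 5′→3′ (structural 34-35,
  including the wobble base).

Anticodons resolve from the record's qualifier first, then from a built-in
canonical vertebrate table, then error. On the real human anticodons the two
conventions give noticeably different correlations, which is why the
pipeline always reports both rather than silently picking one.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume — not
sequence evolution. Its defaults are the package's study conditions and are
set once:

| parameter | default | meaning |
|---|---|---|
| `n_species` | 47 | cohort size (33 "stable" + 14 "rearranged" in the grouping used by the pipeline tests) |
| `genome_length` | 16,500 bp | typical vertebrate mt-genome size |
| `rho_usage_position` | −0.4 | Brownian cross-correlation of log usage and log distance (the strength of the translational signal once outlier families are excluded) |
| `bm_sigma_usage`, `bm_sigma_position` | 0.15 log₁₀/branch | ≈1.4-fold change between sister taxa, a modest divergence scale |
| `deamination_slope` | 0.5 logit/10 kb | exposure dependence of P(G or T) at a scored anticodon position |
| `deamination_intercept` | 0 | even G+T odds at zero exposure |

Trees are Yule topologies (uniformly chosen tip splits) with unit branch
lengths, matching the contrasts default. For each of the 22 families a
bivariate Brownian process evolves (log usage, log distance) with the chosen
cross-correlation; usage scores are renormalized per species to sum to 1
(the analysis consumes relative frequencies). Root distances follow the
typical arrangement (the human distances, rescaled), or a seeded permutation
of it; root usage is uniform. Genome realization places tRNA genes at their
realized distances (minimum spacing, order-preserving compaction at the far
end), fills the remaining gaps with the 2 rRNA and 13 CDS blocks in typical
order (a large gap hosts several blocks, as in real genomes), and spells each
CDS from a multinomial codon draw matching the target usage — so counting
codons on the emitted record reproduces the generator's intended counts
*exactly*, and measuring distances recovers the realized layout exactly.
These construction identities, plus byte-identical reproducibility under a
fixed seed, are tested.

The anticodon-gradient module draws each scored anticodon position as G/T
with probability `plogis(intercept + slope × exposure)` on a fixed genome,
storing ground truth. The typical-order genome (realized from root
distances) is the geometry used for gradient studies: independent per-family
Brownian noise can scramble the Asn/Cys neighbourhood and hence the imputed
O~L~, which is a generator artifact rather than a feature of replication
geometry.

What the generator does **not** emulate: substitution processes along the
tree (tip genomes are independent draws given tip parameters), gene loss or
duplication, duplicated control regions, and any coupling between codon
usage and amino-acid composition of real proteins. Passing the simulation
suites therefore shows the *machinery* is correct and calibrated; it does
not by itself validate the biological conclusions on real cohorts.

## Calibration results the suites compute

* With ρ = −0.4 on 33-species cohorts, the pooled through-origin contrast
  correlation averages ≈ −0.38 over 200 replicates: the small attenuation
  from −0.4 is the per-species renormalization of usage (a shared
  log-denominator term enters every family's usage), and the mean sits
  inside the ±0.05 recovery band the tests assert.
* With ρ = 0 the one-tailed contrast test at α = 0.05 rejects in ≈ 4-6% of
  1000 replicates — nominal.
* At the default gradient slope (0.5 logit/10 kb) on the typical-order
  genome, the all-22 exposure-G+T correlation averages ≈ 0.16 and is
  positive in roughly three quarters to four fifths of replicate draws.
  This is a real power limit, not a defect: the 22 exposures have a spread
  of ≈ 5,300 bp, so the G+T probabilities span only ≈ [0.50, 0.70] and the
  two-position binomial noise dominates. Detecting the gradient reliably
  (> 90% of draws) needs roughly double the slope, or an exposure spread
  near 9,000 bp. The acceptance script reports the honestly computed
  fraction.

## Problem sizes

The shipped suites use 33-species cohorts with 200 replicates for parameter
recovery, 1000 single-family replicates for null calibration, 200 anticodon
draws for gradient detection, and a 47-genome cohort for the end-to-end
pipeline check — sizes chosen to estimate each rate to about a percentage
point, which is tight enough to detect miscalibration.

## Known limitations

* GenBank parsing covers the feature subset annotated mt-genome records use
  (locations with `join`/`complement`, multi-line qualifiers, anticodon
  qualifiers, D-loop and replication-origin features); it is not a general
  GenBank parser.
* Records with duplicated control regions are refused rather than guessed
  at; the user must designate one CR feature.
* Linear genomes and invertebrate gene complements are out of scope.
* The per-tRNA pooled sample sizes depend on the tree and on data
  availability per family; they are reported, not asserted, since the
  bookkeeping of published pooled counts cannot be reconstructed without
  the original per-node tables.
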