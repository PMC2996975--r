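# mitotrna

Tests of two positional constraints on the tRNA genes of vertebrate
mitochondrial genomes:

* **Translational efficiency** — both strands are transcribed from the
  control region (CR), so genes far from it are more often covered by
  incomplete transcripts. If the arrangement is adaptive, tRNAs decoding
  heavily used codons (in mitochondria: those of the hydrophobic residues
  Phe, Val, Leu, Ile, Met, Trp, Ala, Gly, Pro) should sit close to the CR.
* **Deamination avoidance** — under strand-displacement replication the
  parental H strand is single-stranded from O_H (in the CR) until L-strand
  synthesis from O_L (in the WANCY tRNA cluster) passes back over it.
  Single-stranded DNA deaminates (A→G, C→T as read), so a locus's expected
  exposure time predicts G+T enrichment at its anticodon's
  mutation-sensitive positions.

The package reads annotated circular mt-genome records (GenBank flat
files), counts codon usage over the 13 protein-coding genes under
translation table 2, measures strand-aware base-pair distances from the
CR's 3' end to each tRNA's 5' end, and relates usage to position with:

* an exact Mann-Whitney U test of hydrophobic vs hydrophilic tRNA
  distances (U from midrank sums; exact p by enumeration for
  n1 + n2 <= 25),
* Felsenstein independent contrasts of log10 usage vs log10 distance on a
  user-supplied rooted tree — contrast = (x_i − x_j)/sqrt(b_i + b_j) —
  correlated through the origin (df = n − 1),
* a per-family meta-analysis: weighted Fisher r
  (tanh of the (n_i − 3)-weighted mean of atanh r_i) with Stouffer's
  combined probability Z = Σ Φ⁻¹(1 − p_i)/√k,
* the replication-exposure analysis: α = distance from O_L along the
  L-synthesis direction, β = genome length − α, exposure = α between the
  origins and α − β outside, correlated against anticodon G+T counts
  under two scoring conventions.

A seeded synthetic-data generator (Yule trees; correlated Brownian
usage/position evolution; fully annotated genomes whose realized codon
counts and distances are recovered *exactly* by the analysis modules; an
exposure-dependent anticodon G+T gradient) makes every stage testable with
known ground truth and no downloads. The human reference annotation
(rCRS, NC_012920) ships as a plain-text feature table.

## Worked example

```r
library(mitotrna)

h <- human_mt_genome()
h
#> Annotated circular mt-genome NC_012920 (Homo sapiens)
#>   length: 16569 bp; sequence: absent
#>   features: 22 tRNA, 13 CDS, 2 rRNA, 1 control region

tab <- hydropathy_table(h)
head(tab[tab$class == "hydrophobic", ], 3)
#>    trna strand distance_bp       class
#> 1   Phe      H           1 hydrophobic
#> 22  Pro      L           1 hydrophobic
#> 2   Val      H        1026 hydrophobic

mann_whitney_u(tab$distance_bp[tab$class == "hydrophobic"],
               tab$distance_bp[tab$class == "hydrophilic"])
#> Mann-Whitney U = 27.000 (n1 = 10, n2 = 12, exact)
#>   one-tailed p = 0.0145, two-tailed p = 0.0292
```

The hydrophobic-decoding tRNAs are significantly closer to the control
region than the hydrophilic ones (exact two-tailed p = 0.029): the U of 27
means that of the 120 hydrophobic-hydrophilic distance pairs, only 27 have
the hydrophobic gene farther out.

```r
run_deamination(h)$codon12_pairing$all
#> pearson correlation r = 0.1573 (n = 22, d.f. = 20)
#>   t = 0.7122, one-tailed (positive) p = 0.2423
```

On the human annotation, anticodon G+T content rises weakly (not
significantly, under this scoring convention) with expected single-strand
exposure.

```r
# a synthetic cohort with a built-in usage-position correlation of -0.4
co   <- simulate_cohort(sim_config(n_species = 8, seed = 1))
conf <- mt_config(lapply(co$genomes, `[[`, "record"), tree = co$tree)
run_pipeline(conf, stages = "contrasts")$contrasts$pooled$all
#> pearson_through_origin correlation r = -0.2483 (n = 154, d.f. = 153)
#>   t = -3.1704, one-tailed (negative) p = 0.0009
```

The pooled contrast correlation (22 families x 7 contrasts) recovers the
negative usage-position relationship the generator built in.

See `vignettes/mitotrna-methods.Rmd` for the models, parameter choices and
calibration properties.

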