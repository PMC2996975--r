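# Shared fixture builders: everything is generated in code at test time.

# A minimal hand-laid circular genome: CR at the end, a few genes on
# both strands, optional sequence. Used where a full simulated genome
# would obscure the arithmetic under test.
tiny_genome <- function(length_bp = 2000L, sequence = NULL) {
  feats <- list(
    mt_feature("control_region", "CR", "H", c(1801L, 2000L)),
    mt_feature("tRNA", "Phe", "H", c(1L, 70L), anticodon = "GAA"),
    mt_feature("tRNA", "Val", "H", c(301L, 370L), anticodon = "TAC"),
    mt_feature("tRNA", "Pro", "L", c(1731L, 1800L), anticodon = "TGG"),
    mt_feature("tRNA", "Glu", "L", c(1401L, 1470L), anticodon = "TTC")
  )
  mt_genome("TINY01", taxon = "toy", length_bp = length_bp,
            features = feats, sequence = sequence)
}

# A random fully annotated genome from the generator.
sim_record <- function(seed, n_species = 3L) {
  cfg <- sim_config(n_species = n_species, seed = seed)
  co <- simulate_cohort(cfg)
  co$genomes[[1L]]
}

# The typical-order genome used by the deamination studies: realized
# from the (human-like) root distances, so the replication geometry is
# the canonical 13 / 9 split.
typical_genome <- function(seed = 99L) {
  h <- trna_distance(human_mt_genome())
  rootd <- stats::setNames(pmax(1, round(h$distance_bp * 16500 / 16569)),
                           h$trna)
  u <- stats::setNames(rep(1 / 22, 22L), trna_labels())
  cfg <- sim_config(n_species = 2L, seed = seed)
  realize_genome(cfg, u, rootd, "SYNTYP", seed = seed)
}

# Brute-force GLS correlation under the Brownian covariance of a tree,
# removing the phylogenetic (GLS) mean: the independent oracle for the
# through-origin correlation of contrasts.
gls_correlation <- function(tree, x, y) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]; y <- y[rownames(C)]
  Ci <- solve(C)
  one <- rep(1, nrow(C))
  P <- Ci - Ci %*% one %*% solve(t(one) %*% Ci %*% one) %*% t(one) %*% Ci
  qf <- function(a, b) as.numeric(t(a) %*% P %*% b)
  qf(x, y) / sqrt(qf(x, x) * qf(y, y))
}

# Independent per-codon counting oracle: walk every CDS 3 bp at a time
# in its own frame, excluding stops.
stepper_codon_counts <- function(rec) {
  sense <- setdiff(c(outer(c(outer(c("T","C","A","G"), c("T","C","A","G"),
                                   paste0)), c("T","C","A","G"), paste0)),
                   mt_stop_codons())
  counts <- stats::setNames(integer(length(sense)), sense)
  for (f in rec$features) {
    if (f$kind != "CDS") next
    seg <- character(0)
    for (i in seq_len(nrow(f$intervals))) {
      seg <- c(seg, strsplit(substr(rec$sequence, f$intervals[i, 1],
                                    f$intervals[i, 2]), "")[[1]])
    }
    if (f$strand == "L")
      seg <- rev(chartr("ACGT", "TGCA", seg))
    i <- 1L
    while (i + 2L <= length(seg)) {
      cod <- paste(seg[i:(i + 2L)], collapse = "")
      if (cod %in% sense) counts[cod] <- counts[cod] + 1L
      i <- i + 3L
    }
  }
  counts
}
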