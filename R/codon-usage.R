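## Codon usage over the 13 mitochondrial protein-coding genes and its
## aggregation to the 22 decoding tRNAs.

.cds_labels <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
                 "COX1", "COX2", "COX3", "ATP6", "ATP8", "CYTB")

#' Canonical protein-coding gene labels
#' @return The 13 CDS labels of the vertebrate mitochondrial genome.
#' @export
cds_labels <- function() .cds_labels

#' Count codon usage in a genome record
#'
#' Each CDS is read in its own frame from its own 5' start on its
#' coding strand (L-strand genes are reverse-complemented first).
#' Genes overlapping in different frames -- ATP8/ATP6 and ND4L/ND4 in
#' the typical arrangement -- therefore contribute the overlapped bases
#' once per gene, each in that gene's frame. An incomplete terminal
#' codon (1-2 bp, completed by polyadenylation to a stop in vivo)
#' contributes nothing, and complete stop codons are excluded: usage is
#' tallied only for codons that a tRNA decodes. A stop triplet before
#' the final codon raises a warning (annotation noise) but counting
#' continues.
#'
#' @param rec An `mt_genome` with sequence and CDS features.
#' @return List of class `codon_counts`: `per_gene` (named list of
#'   codon count tables), `aggregate` (named integer vector over the 60
#'   sense codons), `total_sense`.
#' @export
count_codons <- function(rec) {
  if (is.null(rec$sequence)) stop("record has no sequence")
  cds <- features_of(rec, kind = "CDS")
  if (!length(cds)) stop("record has no CDS features")
  sense <- names(.codon_family_table)
  per_gene <- list()
  for (f in cds) {
    s <- feature_sequence(rec, f)
    if (!nzchar(s)) stop("CDS '", f$label, "' has length 0")
    ncod <- nchar(s) %/% 3L
    if (ncod == 0L) {
      per_gene[[f$label]] <- integer(0)
      next
    }
    codons <- substring(s, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
    is_stop <- codons %in% .mt_stop_codons
    if (any(is_stop[-length(is_stop)]))
      warning("internal stop codon(s) in CDS '", f$label, "' of ",
              rec$accession, "; counting continues")
    keep <- codons[!is_stop & !grepl("N", codons, fixed = TRUE)]
    per_gene[[f$label]] <- table(factor(keep, levels = sense))
  }
  agg <- Reduce(`+`, lapply(per_gene, function(t) {
    v <- integer(length(sense)); names(v) <- sense
    if (length(t)) v[names(t)] <- as.integer(t)
    v
  }))
  structure(list(per_gene = per_gene, aggregate = agg,
                 total_sense = sum(agg)),
            class = "codon_counts")
}

#' Aggregate codon counts to tRNA usage
#'
#' Sums each tRNA's codon family (four-codon boxes and two-codon sets
#' of the vertebrate mitochondrial code) and expresses each family as a
#' relative frequency of all sense codons, so genomes of different
#' lengths are comparable.
#'
#' @param counts A `codon_counts` object, or a named integer vector
#'   over sense codons.
#' @return Data frame: `trna`, `count`, `rel_freq` (one row per tRNA;
#'   counts partition `total_sense`, frequencies sum to 1).
#' @export
trna_usage <- function(counts) {
  agg <- if (inherits(counts, "codon_counts")) counts$aggregate else counts
  fam <- codon_to_trna(names(agg))
  cnt <- vapply(trna_labels(), function(l) sum(agg[fam == l]), numeric(1))
  total <- sum(cnt)
  if (total == 0) stop("no sense codons counted")
  data.frame(trna = trna_labels(), count = as.integer(cnt),
             rel_freq = unname(cnt) / total, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write a per-genome usage table
#'
#' @param counts A `codon_counts` object.
#' @param path TSV output path (codon, amino_acid, trna, count,
#'   rel_freq).
#' @return The table, invisibly.
#' @export
write_usage_tsv <- function(counts, path) {
  agg <- counts$aggregate
  fam <- codon_to_trna(names(agg))
  tab <- data.frame(codon = names(agg),
                    amino_acid = trna_amino_acid(fam),
                    trna = fam, count = as.integer(agg),
                    rel_freq = as.integer(agg) / counts$total_sense)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}
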