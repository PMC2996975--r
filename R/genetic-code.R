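## Vertebrate mitochondrial genetic code (translation table 2) and the
## mapping of its 60 sense codons onto the 22 mitochondrial tRNAs.

#' Canonical mitochondrial tRNA labels
#'
#' The 22 tRNA genes of the vertebrate mitochondrial genome. Leucine and
#' serine each have two isoacceptors, distinguished by the codon family
#' they decode: `Leu1` (UUR), `Leu2` (CUN), `Ser1` (UCN), `Ser2` (AGY).
#'
#' @return Character vector of the 22 canonical labels, in the typical
#'   gene-order sequence starting from the control region on the H strand.
#' @export
trna_labels <- function() {
  c("Phe", "Val", "Leu1", "Ile", "Gln", "Met", "Trp", "Ala", "Asn",
    "Cys", "Tyr", "Ser1", "Asp", "Lys", "Gly", "Arg", "His", "Ser2",
    "Leu2", "Glu", "Thr", "Pro")
}

# The four stop codons of translation table 2. AGA/AGG are stops in the
# vertebrate mitochondrial code (arginine only via CGN); UGA codes Trp.
.mt_stop_codons <- c("TAA", "TAG", "AGA", "AGG")

.expand_box <- function(prefix) paste0(prefix, c("T", "C", "A", "G"))

# codon (DNA, coding-strand sense) -> decoding tRNA. Four-codon boxes are
# read by a single tRNA with a wobble-U anticodon; two-codon sets split
# NNY/NNR. The 22 families partition the 60 sense codons.
.codon_family_table <- local({
  fam <- list(
    Phe  = c("TTT", "TTC"),
    Leu1 = c("TTA", "TTG"),
    Leu2 = .expand_box("CT"),
    Ile  = c("ATT", "ATC"),
    Met  = c("ATA", "ATG"),
    Val  = .expand_box("GT"),
    Ser1 = .expand_box("TC"),
    Pro  = .expand_box("CC"),
    Thr  = .expand_box("AC"),
    Ala  = .expand_box("GC"),
    Tyr  = c("TAT", "TAC"),
    His  = c("CAT", "CAC"),
    Gln  = c("CAA", "CAG"),
    Asn  = c("AAT", "AAC"),
    Lys  = c("AAA", "AAG"),
    Asp  = c("GAT", "GAC"),
    Glu  = c("GAA", "GAG"),
    Cys  = c("TGT", "TGC"),
    Trp  = c("TGA", "TGG"),
    Arg  = .expand_box("CG"),
    Ser2 = c("AGT", "AGC"),
    Gly  = .expand_box("GG")
  )
  codons <- unlist(fam, use.names = FALSE)
  stopifnot(length(codons) == 60L, !anyDuplicated(codons))
  structure(rep(names(fam), lengths(fam)), names = codons)
})

#' Map sense codons to their decoding tRNA
#'
#' @param codons Character vector of DNA triplets in coding-strand sense.
#' @return Character vector of canonical tRNA labels.
#' @export
codon_to_trna <- function(codons) {
  codons <- toupper(codons)
  bad <- setdiff(codons, names(.codon_family_table))
  if (length(bad))
    stop("not a sense codon of the vertebrate mitochondrial code: ",
         paste(unique(bad), collapse = ", "))
  unname(.codon_family_table[codons])
}

#' Codon family of a tRNA
#'
#' @param label Canonical tRNA label.
#' @return Character vector of the DNA codons decoded by that tRNA.
#' @export
trna_codon_family <- function(label) {
  label <- match.arg(label, trna_labels())
  names(.codon_family_table)[.codon_family_table == label]
}

#' Stop codons of the vertebrate mitochondrial code
#' @return Character vector of the four stop triplets.
#' @export
mt_stop_codons <- function() .mt_stop_codons

# amino acid encoded by each family (three-letter code)
.trna_amino_acid <- c(
  Phe = "Phe", Val = "Val", Leu1 = "Leu", Leu2 = "Leu", Ile = "Ile",
  Met = "Met", Trp = "Trp", Ala = "Ala", Gly = "Gly", Pro = "Pro",
  Ser1 = "Ser", Ser2 = "Ser", Tyr = "Tyr", His = "His", Gln = "Gln",
  Asn = "Asn", Lys = "Lys", Asp = "Asp", Glu = "Glu", Cys = "Cys",
  Arg = "Arg", Thr = "Thr"
)

# The hydrophobic residue set used to split the tRNAs into two groups.
.hydrophobic_residues <- c("Phe", "Val", "Leu", "Ile", "Met", "Trp",
                           "Ala", "Gly", "Pro")

#' Hydrophobicity class of a tRNA gene
#'
#' Splits the 22 mitochondrial tRNAs by the hydrophobicity of the amino
#' acid they carry. The hydrophobic residues are Phe, Val, Leu, Ile, Met,
#' Trp, Ala, Gly and Pro, giving 10 hydrophobic tRNAs (leucine has two
#' isoacceptors) and 12 hydrophilic ones.
#'
#' @param label Canonical tRNA label(s).
#' @return Character vector, `"hydrophobic"` or `"hydrophilic"`.
#' @export
classify_trna <- function(label) {
  bad <- setdiff(label, trna_labels())
  if (length(bad))
    stop("unknown tRNA label: ", paste(bad, collapse = ", "))
  ifelse(.trna_amino_acid[label] %in% .hydrophobic_residues,
         "hydrophobic", "hydrophilic")
}

#' Amino acid of a tRNA family
#' @param label Canonical tRNA label(s).
#' @return Three-letter amino-acid codes.
#' @export
trna_amino_acid <- function(label) {
  bad <- setdiff(label, trna_labels())
  if (length(bad))
    stop("unknown tRNA label: ", paste(bad, collapse = ", "))
  unname(.trna_amino_acid[label])
}

## Equilibrium amino-acid frequencies of two empirical substitution
## matrices, used to contrast mitochondrial vs nuclear proteome
## composition. mtREV24: Adachi & Hasegawa (1996) J Mol Evol 42:459.
## JTT: Jones, Taylor & Thornton (1992) CABIOS 8:275.
.aa_order <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
               "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
               "Thr", "Trp", "Tyr", "Val")

.mtrev_freq <- structure(
  c(0.072, 0.019, 0.039, 0.019, 0.006, 0.025, 0.024, 0.056, 0.028,
    0.088, 0.169, 0.023, 0.054, 0.061, 0.054, 0.072, 0.086, 0.029,
    0.033, 0.043),
  names = .aa_order)

.jtt_freq <- structure(
  c(0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752,
    0.061830, 0.073152, 0.022944, 0.053761, 0.091904, 0.058676,
    0.023826, 0.040126, 0.050901, 0.068765, 0.058565, 0.014261,
    0.032102, 0.066005),
  names = .aa_order)

#' Built-in amino-acid frequency sets
#'
#' Equilibrium frequencies of the mtREV24 matrix (vertebrate
#' mitochondrial proteins) and the JTT matrix (general nuclear
#' proteins).
#'
#' @param name `"mtREV"` or `"JTT"`.
#' @return Named numeric vector over the 20 amino acids, summing to 1
#'   within rounding of the published matrices.
#' @export
aa_frequency_set <- function(name = c("mtREV", "JTT")) {
  name <- match.arg(name)
  if (name == "mtREV") .mtrev_freq else .jtt_freq
}

#' Fraction of hydrophobic residues in a frequency set
#'
#' Sums the frequencies of the nine hydrophobic residues (Phe, Val, Leu,
#' Ile, Met, Trp, Ala, Gly, Pro). On the built-in sets this contrasts
#' the hydrophobic-rich mitochondrial proteome (mtREV, about 0.62) with
#' a typical nuclear proteome (JTT, about 0.49).
#'
#' @param freq Named numeric vector over the 20 amino acids
#'   (three-letter codes), or the name of a built-in set.
#' @return A single fraction.
#' @export
hydrophobic_fraction <- function(freq) {
  if (is.character(freq) && length(freq) == 1L)
    freq <- aa_frequency_set(freq)
  missing <- setdiff(.hydrophobic_residues, names(freq))
  if (length(missing))
    stop("frequency set lacks amino acid(s): ",
         paste(missing, collapse = ", "))
  sum(freq[.hydrophobic_residues])
}

## Canonical anticodons of the human mitochondrial tRNAs (DNA alphabet,
## coding-strand sense, read 5'->3'; structural positions 34-36).
## Position 34 is the wobble base pairing the degenerate codon third
## position. Used when a record carries no anticodon qualifier.
.canonical_anticodons <- c(
  Phe = "GAA", Val = "TAC", Leu1 = "TAA", Ile = "GAT", Gln = "TTG",
  Met = "CAT", Trp = "TCA", Ala = "TGC", Asn = "GTT", Cys = "GCA",
  Tyr = "GTA", Ser1 = "TGA", Asp = "GTC", Lys = "TTT", Gly = "TCC",
  Arg = "TCG", His = "GTG", Ser2 = "GCT", Leu2 = "TAG", Glu = "TTC",
  Thr = "TGT", Pro = "TGG"
)

#' Canonical vertebrate mitochondrial anticodon table
#'
#' @return Named character vector: canonical tRNA label to anticodon
#'   triplet (DNA alphabet, coding strand, 5' to 3').
#' @export
canonical_anticodons <- function() .canonical_anticodons

#' Reverse complement of a DNA string
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
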