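## Data model for an annotated circular mitochondrial genome.
##
## Coordinates are 1-based inclusive (GenBank convention). A feature
## wrapping the sequence origin is stored as two intervals
## (.., length) then (1, ..), never as start > end. Strand "H" reads in
## increasing coordinates; "L" is the reverse complement.

.feature_kinds <- c("CDS", "tRNA", "rRNA", "control_region",
                    "rep_origin_L", "rep_origin_H")

#' Construct a genome feature
#'
#' @param kind One of `CDS`, `tRNA`, `rRNA`, `control_region`,
#'   `rep_origin_L`, `rep_origin_H`.
#' @param label Canonical gene name (e.g. `"Phe"`, `"ND1"`, `"CR"`).
#' @param strand `"H"` (read in increasing coordinates) or `"L"`.
#' @param intervals Two-column integer matrix of 1-based inclusive
#'   (start, end) rows; a wrap around the origin is a second row
#'   restarting at 1.
#' @param anticodon Optional anticodon triplet (tRNA only; DNA alphabet,
#'   coding-strand sense, 5' to 3').
#' @return A list of class `mt_feature`.
#' @export
mt_feature <- function(kind, label, strand, intervals, anticodon = NA_character_) {
  kind <- match.arg(kind, .feature_kinds)
  stopifnot(strand %in% c("H", "L"))
  intervals <- matrix(as.integer(intervals), ncol = 2)
  if (any(intervals[, 2] < intervals[, 1]))
    stop("feature '", label, "': interval end < start (wraps must be ",
         "encoded as a two-interval join)")
  structure(list(kind = kind, label = as.character(label), strand = strand,
                 intervals = intervals,
                 anticodon = toupper(as.character(anticodon))),
            class = "mt_feature")
}

#' Construct an annotated mitochondrial genome record
#'
#' @param accession Identifier string.
#' @param taxon Free-text species label.
#' @param length_bp Genome length in bp (> 0).
#' @param features List of [mt_feature()] objects.
#' @param sequence Optional nucleotide string over A/C/G/T/N of exactly
#'   `length_bp` characters.
#' @param circular Logical; only circular genomes are supported.
#' @return A list of class `mt_genome`. The element
#'   `geometry_capable` records whether a control-region feature is
#'   present (required for distance analyses).
#' @export
mt_genome <- function(accession, taxon = accession, length_bp,
                      features = list(), sequence = NULL,
                      circular = TRUE) {
  length_bp <- as.integer(length_bp)
  if (is.na(length_bp) || length_bp <= 0L) stop("length_bp must be positive")
  if (!circular) stop("only circular genomes are supported")
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != length_bp)
      stop("sequence length (", nchar(sequence),
           ") does not match length_bp (", length_bp, ")")
    if (grepl("[^ACGTN]", sequence)) stop("sequence has non-ACGTN characters")
  }
  rec <- structure(list(accession = accession, taxon = taxon,
                        length_bp = length_bp, circular = TRUE,
                        sequence = sequence, features = features),
                   class = "mt_genome")
  validate_mt_genome(rec)
}

#' Validate a genome record
#'
#' Checks interval bounds, uniqueness of canonical tRNA labels, and the
#' control-region count; flags the record `geometry_capable = FALSE`
#' (rather than failing) when no control region is annotated.
#'
#' @param rec An `mt_genome`.
#' @return The record, with `geometry_capable` set.
#' @export
validate_mt_genome <- function(rec) {
  for (f in rec$features) {
    if (any(f$intervals < 1L) || any(f$intervals > rec$length_bp))
      stop("feature '", f$label, "' exceeds [1, ", rec$length_bp, "]")
  }
  kinds <- vapply(rec$features, `[[`, "", "kind")
  trna <- vapply(rec$features[kinds == "tRNA"], `[[`, "", "label")
  dup <- unique(trna[duplicated(trna)])
  if (length(dup))
    stop("duplicate canonical tRNA label(s): ", paste(dup, collapse = ", "))
  unknown <- setdiff(trna, trna_labels())
  if (length(unknown))
    stop("non-canonical tRNA label(s): ", paste(unknown, collapse = ", "))
  n_cr <- sum(kinds == "control_region")
  if (n_cr > 1L)
    stop("record '", rec$accession, "' has ", n_cr, " control_region ",
         "features; designate a single one")
  if (sum(kinds == "rep_origin_L") > 1L)
    stop("record '", rec$accession, "' has more than one rep_origin_L")
  rec$geometry_capable <- n_cr == 1L
  rec
}

#' @export
print.mt_genome <- function(x, ...) {
  kinds <- vapply(x$features, `[[`, "", "kind")
  cat("Annotated circular mt-genome ", x$accession, " (", x$taxon, ")\n",
      "  length: ", x$length_bp, " bp; sequence: ",
      if (is.null(x$sequence)) "absent" else "present", "\n",
      "  features: ", sum(kinds == "tRNA"), " tRNA, ",
      sum(kinds == "CDS"), " CDS, ", sum(kinds == "rRNA"), " rRNA, ",
      sum(kinds == "control_region"), " control region\n", sep = "")
  invisible(x)
}

# Find features by kind and/or label; returns a list.
features_of <- function(rec, kind = NULL, label = NULL) {
  keep <- rep(TRUE, length(rec$features))
  if (!is.null(kind))
    keep <- keep & vapply(rec$features, `[[`, "", "kind") %in% kind
  if (!is.null(label))
    keep <- keep & vapply(rec$features, `[[`, "", "label") %in% label
  rec$features[keep]
}

# 5' terminal base of a feature's coding strand, in genomic coordinates.
# H: start of the first interval; L: end of the last interval (a wrap
# join is listed in increasing walk order, so the last interval carries
# the highest position along the walk).
feature_5prime <- function(f) {
  if (f$strand == "H") f$intervals[1L, 1L]
  else f$intervals[nrow(f$intervals), 2L]
}

# Coding-strand sequence of a feature (requires record sequence).
feature_sequence <- function(rec, f) {
  if (is.null(rec$sequence)) stop("record has no sequence")
  seg <- paste(vapply(seq_len(nrow(f$intervals)), function(i) {
    substr(rec$sequence, f$intervals[i, 1L], f$intervals[i, 2L])
  }, character(1)), collapse = "")
  if (f$strand == "L") revcomp(seg) else seg
}

#' Rotate the coordinate origin of a circular genome
#'
#' Shifts every coordinate by `k` bp (the base at position `k + 1`
#' becomes position 1), splitting intervals that come to span the
#' origin into two-row joins and merging joins that become contiguous.
#' Distance and exposure analyses are invariant under rotation.
#'
#' @param rec An `mt_genome`.
#' @param k Rotation in bp.
#' @return The rotated record.
#' @export
rotate_genome <- function(rec, k) {
  L <- rec$length_bp
  k <- ((as.integer(k) %% L) + L) %% L
  if (k == 0L) return(rec)
  shift <- function(p) ((p - k - 1L) %% L) + 1L
  rec$features <- lapply(rec$features, function(f) {
    pieces <- list()
    for (i in seq_len(nrow(f$intervals))) {
      s <- shift(f$intervals[i, 1L]); e <- shift(f$intervals[i, 2L])
      if (s <= e) pieces[[length(pieces) + 1L]] <- c(s, e)
      else {                              # interval now spans the origin
        pieces[[length(pieces) + 1L]] <- c(s, L)
        pieces[[length(pieces) + 1L]] <- c(1L, e)
      }
    }
    # merge rows made contiguous by the rotation (wrap healed)
    merged <- list(pieces[[1L]])
    for (p in pieces[-1L]) {
      last <- merged[[length(merged)]]
      if (p[1L] == last[2L] + 1L) merged[[length(merged)]] <- c(last[1L], p[2L])
      else merged[[length(merged) + 1L]] <- p
    }
    f$intervals <- do.call(rbind, merged)
    f
  })
  if (!is.null(rec$sequence)) {
    rec$sequence <- paste0(substr(rec$sequence, k + 1L, L),
                           substr(rec$sequence, 1L, k))
  }
  validate_mt_genome(rec)
}

#' Reverse-complement a genome record
#'
#' Flips the sequence and every feature's strand and coordinates. Under
#' this transformation the H and L strands swap roles; codon counts and
#' CR distances are invariant.
#'
#' @param rec An `mt_genome`.
#' @return The reflected record.
#' @export
reflect_genome <- function(rec) {
  L <- rec$length_bp
  rec$features <- lapply(rec$features, function(f) {
    iv <- f$intervals
    new <- cbind(L - iv[, 2L] + 1L, L - iv[, 1L] + 1L)
    f$intervals <- new[rev(seq_len(nrow(new))), , drop = FALSE]
    f$strand <- if (f$strand == "H") "L" else "H"
    f
  })
  if (!is.null(rec$sequence)) rec$sequence <- revcomp(rec$sequence)
  validate_mt_genome(rec)
}

## The typical vertebrate mitochondrial gene order, read in increasing
## coordinates from the control region's H-strand 3' end.
.typical_order <- c(
  "Phe", "rrnS", "Val", "rrnL", "Leu1", "ND1", "Ile", "Gln", "Met",
  "ND2", "Trp", "Ala", "Asn", "Cys", "Tyr", "COX1", "Ser1", "Asp",
  "COX2", "Lys", "ATP8", "ATP6", "COX3", "Gly", "ND3", "Arg", "ND4L",
  "ND4", "His", "Ser2", "Leu2", "ND5", "ND6", "Glu", "CYTB", "Thr",
  "Pro")

#' Typical vertebrate mitochondrial gene order
#' @return Character vector of the 37 gene labels in circular order
#'   starting after the control region on the H strand.
#' @export
typical_gene_order <- function() .typical_order

#' Compare a record's gene order with the typical arrangement
#'
#' Lists genes in circular order starting from the control region's
#' H-strand 3' end and reports where the order deviates from the
#' typical vertebrate arrangement. Diagnostic only.
#'
#' @param rec An `mt_genome`.
#' @return List with `order` (observed labels), `match` (logical) and
#'   `mismatches` (data frame of position, observed, expected).
#' @export
check_typical_order <- function(rec) {
  if (!length(rec$features)) stop("record has no features")
  genes <- features_of(rec, kind = c("tRNA", "CDS", "rRNA"))
  start_from <- if (rec$geometry_capable) {
    cr_reference_points(rec)$h_ref
  } else 0L
  pos <- vapply(genes, function(f) f$intervals[1L, 1L], integer(1))
  circ <- ((pos - start_from - 1L) %% rec$length_bp) + 1L
  labels <- vapply(genes, `[[`, "", "label")[order(circ)]
  expected <- typical_gene_order()
  n <- min(length(labels), length(expected))
  cmp <- labels[seq_len(n)] != expected[seq_len(n)]
  mismatches <- data.frame(position = which(cmp),
                           observed = labels[seq_len(n)][cmp],
                           expected = expected[seq_len(n)][cmp],
                           stringsAsFactors = FALSE)
  list(order = labels,
       match = length(labels) == length(expected) && nrow(mismatches) == 0L,
       mismatches = mismatches)
}

#' Human mitochondrial genome annotation
#'
#' The feature annotation of the human mitochondrial genome (revised
#' Cambridge Reference Sequence, NC_012920; 16,569 bp), loaded from a
#' plain-text table shipped with the package. No nucleotide sequence is
#' attached. rCRS coordinates match the AF347015 record up to the 1-bp
#' spacer at rCRS position 3107, so H-strand positions downstream of it
#' are larger by one.
#'
#' @return An `mt_genome` record.
#' @export
human_mt_genome <- function() {
  path <- system.file("extdata", "human_mtdna_rcrs_features.tsv",
                      package = "mitotrna", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(anticodon = "character"))
  feats <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    iv <- if (is.na(row$start2)) {
      c(row$start1, row$end1)
    } else rbind(c(row$start1, row$end1), c(row$start2, row$end2))
    ac <- row$anticodon
    if (is.na(ac) || !nzchar(ac)) ac <- NA_character_
    mt_feature(row$kind, row$label, row$strand, iv, anticodon = ac)
  })
  mt_genome("NC_012920", taxon = "Homo sapiens", length_bp = 16569L,
            features = feats)
}
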