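## Strand-aware distances from the control region to each tRNA gene.
##
## Transcription of both strands initiates near the control region (CR),
## so a gene's cost of incomplete transcription grows with its distance
## from the CR along its own strand. Distances are counted from the CR
## 3' end of the relevant strand to the gene's 5' base, with the
## adjacent base at distance 1. The two CR boundaries serve as the two
## strand references: in the typical arrangement tRNA-Phe (H) sits
## immediately downstream of one boundary and tRNA-Pro (L) of the
## other, and both have distance 1.

#' Control-region reference points
#'
#' Resolves the two strand-specific reference coordinates of a record:
#' `h_ref`, the CR boundary whose next base in increasing coordinates
#' leaves the CR (the tRNA-Phe side in the typical order), and `l_ref`,
#' the opposite boundary (tRNA-Pro side). A CR annotated across the
#' sequence origin (two-interval join) is handled transparently.
#'
#' @param rec An `mt_genome` with exactly one control-region feature.
#' @return List with `h_ref`, `l_ref`, `h_offset`, `l_offset`
#'   (offsets start at 0; see [offset_sensitivity()]).
#' @export
cr_reference_points <- function(rec) {
  cr <- features_of(rec, kind = "control_region")
  if (length(cr) != 1L)
    stop("record '", rec$accession, "' lacks a usable control_region ",
         "feature; geometry analyses are unavailable")
  iv <- cr[[1L]]$intervals
  list(h_ref = iv[nrow(iv), 2L], l_ref = iv[1L, 1L],
       h_offset = 0L, l_offset = 0L)
}

# circular gap walked in increasing coordinates from `from` (exclusive)
# to `to` (inclusive); 0 maps to the full length
.circ_fwd <- function(from, to, L) {
  d <- (to - from) %% L
  ifelse(d == 0, L, d)
}

#' Distance from the control region to tRNA genes
#'
#' For an H-strand gene the distance is the circular gap from
#' `h_ref` to the gene's lowest coordinate (its 5' base), walking in
#' increasing coordinates, with the adjacent base at distance 1. For an
#' L-strand gene the walk runs in decreasing coordinates from `l_ref`
#' to the gene's 5' base on L (its highest coordinate). Reference
#' offsets (hypothetical transcription-start displacements) shift the
#' walk's starting point; a gene lying at or upstream of the shifted
#' start keeps the minimal distance 1, so offsets never wrap a
#' CR-adjacent gene to the far side of the genome.
#'
#' @param rec An `mt_genome`.
#' @param trna Canonical tRNA label(s); default all tRNAs present.
#' @param ref Reference points from [cr_reference_points()]; computed
#'   if missing.
#' @return Data frame: `trna`, `strand`, `distance_bp`.
#' @export
trna_distance <- function(rec, trna = NULL, ref = NULL) {
  if (is.null(ref)) ref <- cr_reference_points(rec)
  L <- rec$length_bp
  feats <- features_of(rec, kind = "tRNA")
  labels <- vapply(feats, `[[`, "", "label")
  if (is.null(trna)) trna <- labels
  missing <- setdiff(trna, labels)
  if (length(missing))
    stop("tRNA gene(s) absent from record '", rec$accession, "': ",
         paste(missing, collapse = ", "))
  feats <- feats[match(trna, labels)]
  strand <- vapply(feats, `[[`, "", "strand")
  p5 <- vapply(feats, feature_5prime, integer(1))
  raw <- ifelse(strand == "H",
                .circ_fwd(ref$h_ref, p5, L),
                .circ_fwd(p5, ref$l_ref, L))
  off <- ifelse(strand == "H", ref$h_offset, ref$l_offset)
  d <- pmax(raw - off, 1L)
  data.frame(trna = trna, strand = strand, distance_bp = as.integer(d),
             stringsAsFactors = FALSE)
}

#' Stability of results under transcription-start offsets
#'
#' The true transcription start sites may lie up- or downstream of the
#' annotated CR boundary on each strand. This recomputes all tRNA
#' distances with both strand references displaced by each offset in
#' `offsets` and reruns the hydropathy rank test, reporting whether its
#' significance classification changes.
#'
#' @param rec An `mt_genome`.
#' @param offsets Signed displacements in bp applied to both strand
#'   references (default `c(0, 150, -150, 500, -500)`).
#' @param alpha Significance level for the classification (default 0.05).
#' @return Data frame with one row per offset: the U statistic, both
#'   tail p-values, and `significant` (two-tailed p < `alpha`).
#' @export
offset_sensitivity <- function(rec, offsets = c(0L, 150L, -150L, 500L, -500L),
                               alpha = 0.05) {
  base_ref <- cr_reference_points(rec)
  out <- lapply(offsets, function(delta) {
    ref <- base_ref
    ref$h_offset <- as.integer(delta)
    ref$l_offset <- as.integer(delta)
    d <- trna_distance(rec, ref = ref)
    cls <- classify_trna(d$trna)
    u <- mann_whitney_u(d$distance_bp[cls == "hydrophobic"],
                        d$distance_bp[cls == "hydrophilic"])
    data.frame(offset = delta, U = u$U,
               p_one_tailed = u$p_one_tailed,
               p_two_tailed = u$p_two_tailed,
               significant = u$p_two_tailed < alpha)
  })
  do.call(rbind, out)
}

#' Per-genome hydropathy distance table
#'
#' Distances of all tRNAs with their hydrophobicity class, in the
#' two-group layout used for the rank test.
#'
#' @param rec An `mt_genome`.
#' @return Data frame: `trna`, `strand`, `distance_bp`, `class`.
#' @export
hydropathy_table <- function(rec) {
  d <- trna_distance(rec)
  d$class <- classify_trna(d$trna)
  d[order(d$class, d$distance_bp), ]
}
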