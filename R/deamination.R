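## Single-strand exposure under the strand-displacement model of mtDNA
## replication, and its relation to anticodon base composition.
##
## Replication starts at the H-strand origin (O_H, in the control
## region); the parental H-strand is displaced and left single-stranded
## until L-strand synthesis, initiated at the L-strand origin (O_L, in
## the WANCY tRNA cluster), has passed back over it. A gene's expected
## single-strand exposure therefore grows with its distance from O_L
## along the direction of L-strand synthesis (alpha) for genes on the
## O_L -> O_H arc, and shrinks with the opposite-direction distance
## (beta) elsewhere, where it is scored as alpha - beta. Deamination
## (A -> hypoxanthine, read G; C -> U, read T) accumulates in exposed
## single strands, so long-exposed tRNA loci are expected to carry more
## G+T at their mutation-sensitive anticodon positions.

#' Replication origin map of a genome
#'
#' Locates the two origins as point coordinates: `o_l` from the
#' midpoint of an annotated L-strand replication origin, or -- when the
#' annotation is absent -- imputed at the midpoint of the gap between
#' tRNA-Asn and tRNA-Cys (the WANCY region, where O_L resides in
#' vertebrates); `o_h` from an annotated H-strand origin midpoint, or
#' the control region's H-strand reference as fallback. L-strand
#' synthesis is taken to run in increasing coordinates (the orientation
#' in which, for the typical order, Cys through Pro lie downstream of
#' O_L).
#'
#' @param rec An `mt_genome`.
#' @return List of class `replication_map`: `o_l`, `o_h`, `o_l_source`,
#'   `o_h_source`, `genome_length`.
#' @export
replication_map <- function(rec) {
  L <- rec$length_bp
  ol_feat <- features_of(rec, kind = "rep_origin_L")
  if (length(ol_feat)) {
    iv <- ol_feat[[1]]$intervals
    o_l <- .circ_midpoint(iv[1, 1], iv[nrow(iv), 2], L)
    o_l_source <- "annotated"
  } else {
    asn <- features_of(rec, kind = "tRNA", label = "Asn")
    cys <- features_of(rec, kind = "tRNA", label = "Cys")
    if (!length(asn) || !length(cys))
      stop("record '", rec$accession, "' has no L-strand replication ",
           "origin and lacks tRNA-Asn/Cys for WANCY imputation; ",
           "deamination analyses are unavailable")
    a_end <- max(asn[[1]]$intervals)
    c_start <- min(cys[[1]]$intervals)
    o_l <- .circ_midpoint(a_end + 1L, c_start - 1L, L)
    o_l_source <- "imputed_wancy"
  }
  oh_feat <- features_of(rec, kind = "rep_origin_H")
  if (length(oh_feat)) {
    iv <- oh_feat[[1]]$intervals
    o_h <- .circ_midpoint(iv[1, 1], iv[nrow(iv), 2], L)
    o_h_source <- "annotated"
  } else {
    o_h <- cr_reference_points(rec)$h_ref
    o_h_source <- "cr_reference"
  }
  if (o_l == o_h) stop("degenerate replication map: o_l == o_h")
  structure(list(o_l = as.integer(o_l), o_h = as.integer(o_h),
                 o_l_source = o_l_source, o_h_source = o_h_source,
                 genome_length = L),
            class = "replication_map")
}

# midpoint of the circular arc from a to b walked in increasing
# coordinates
.circ_midpoint <- function(a, b, L) {
  span <- (b - a) %% L
  (((a - 1L) + span %/% 2L) %% L) + 1L
}

#' Classify tRNAs by replication arc
#'
#' A tRNA is `between_origins` iff its reference point (5' end of the
#' coding strand) lies on the arc from O_L to O_H walked in the
#' direction of L-strand synthesis; otherwise `outside`. In the human
#' genome the between-origins group is the 13 genes Cys, Tyr, Ser1,
#' Asp, Lys, Gly, Arg, His, Ser2, Leu2, Glu, Thr, Pro.
#'
#' @param rec An `mt_genome`.
#' @param map A `replication_map`; computed if missing.
#' @return Named character vector (tRNA label -> group).
#' @export
classify_replication_group <- function(rec, map = NULL) {
  if (is.null(map)) map <- replication_map(rec)
  feats <- features_of(rec, kind = "tRNA")
  L <- map$genome_length
  arc <- (map$o_h - map$o_l) %% L
  grp <- vapply(feats, function(f) {
    ref <- feature_5prime(f)
    a <- (ref - map$o_l) %% L
    if (a > 0 && a <= arc) "between_origins" else "outside"
  }, character(1))
  names(grp) <- vapply(feats, `[[`, "", "label")
  grp
}

#' Single-strand exposure durations
#'
#' For each tRNA, alpha is the distance (bp) from O_L along the
#' L-synthesis direction to the gene's reference point, beta the
#' distance along the opposite direction (alpha + beta equals the
#' genome length), and the exposure score is alpha for the
#' between-origins group and alpha - beta for the rest. The G+T count
#' of the two scored anticodon positions is attached when the
#' anticodon is known.
#'
#' @param rec An `mt_genome`.
#' @param map A `replication_map`; computed if missing.
#' @param convention Anticodon scoring convention, see
#'   [anticodon_gt_count()].
#' @return Data frame: `trna`, `group`, `alpha`, `beta`, `exposure`,
#'   `anticodon`, `gt_count`.
#' @export
exposure_durations <- function(rec, map = NULL,
                               convention = c("codon12_pairing",
                                              "first_two_5to3")) {
  convention <- match.arg(convention)
  if (is.null(map)) map <- replication_map(rec)
  grp <- classify_replication_group(rec, map)
  feats <- features_of(rec, kind = "tRNA")
  L <- map$genome_length
  rows <- lapply(feats, function(f) {
    alpha <- (feature_5prime(f) - map$o_l) %% L
    beta <- L - alpha
    g <- grp[[f$label]]
    ac <- f$anticodon
    if (is.na(ac) && f$label %in% names(canonical_anticodons()))
      ac <- unname(canonical_anticodons()[f$label])
    gt <- if (is.na(ac)) NA_integer_
          else anticodon_gt_count(ac, convention)
    data.frame(trna = f$label, group = g, alpha = alpha, beta = beta,
               exposure = if (g == "between_origins") alpha
                          else alpha - beta,
               anticodon = ac, gt_count = gt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' G+T count at the scored anticodon positions
#'
#' Counts G and T bases on the tRNA gene's coding strand at the two
#' anticodon positions selected by the convention:
#' `codon12_pairing` scores the bases pairing with codon positions 1
#' and 2 (structural anticodon positions 36 and 35 -- the
#' non-degenerate, mutation-sensitive sites; the default), while
#' `first_two_5to3` scores the first two anticodon bases read 5' to 3'
#' (structural positions 34 and 35, including the wobble base).
#'
#' @param anticodon Anticodon triplet(s), DNA alphabet, coding strand,
#'   5' to 3' (structural positions 34-36), or a tRNA `mt_feature`.
#' @param convention `"codon12_pairing"` or `"first_two_5to3"`.
#' @return Integer count(s) in 0..2.
#' @export
anticodon_gt_count <- function(anticodon,
                               convention = c("codon12_pairing",
                                              "first_two_5to3")) {
  convention <- match.arg(convention)
  if (inherits(anticodon, "mt_feature")) {
    if (is.na(anticodon$anticodon))
      stop("tRNA '", anticodon$label, "' has no anticodon")
    anticodon <- anticodon$anticodon
  }
  anticodon <- toupper(anticodon)
  if (any(!grepl("^[ACGT]{3}$", anticodon)))
    stop("anticodon must be an ACGT triplet")
  idx <- if (convention == "first_two_5to3") c(1L, 2L) else c(3L, 2L)
  vapply(anticodon, function(a) {
    b <- strsplit(a, "")[[1]][idx]
    sum(b %in% c("G", "T"))
  }, integer(1), USE.NAMES = FALSE)
}

#' Correlate exposure with anticodon G+T content
#'
#' One-tailed (positive) Pearson correlation between single-strand
#' exposure and the G+T count of the scored anticodon positions,
#' either within the between-origins group (exposure = alpha) or over
#' all 22 tRNAs (mixed alpha / alpha - beta scores).
#'
#' @param records Data frame from [exposure_durations()].
#' @param subset `"all"` or `"between_origins_only"`.
#' @return A `cor_result`.
#' @export
exposure_gt_correlation <- function(records,
                                    subset = c("all",
                                               "between_origins_only")) {
  subset <- match.arg(subset)
  if (subset == "between_origins_only")
    records <- records[records$group == "between_origins", , drop = FALSE]
  records <- records[!is.na(records$gt_count), , drop = FALSE]
  if (nrow(records) < 3L) stop("fewer than 3 usable exposure records")
  pearson_one_tailed(records$exposure, records$gt_count,
                     tail = "positive")
}
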