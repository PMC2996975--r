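## Reading and writing annotated mitochondrial genomes as GenBank flat
## files, normalized into the package's data model. The reader covers
## the subset of the format that annotated mt-genome records use:
## single- and multi-record files, join/complement locations (wraps
## around the circular origin), multi-line qualifiers, anticodon
## qualifiers, and D-loop / replication-origin misc features.

# --- tRNA product canonicalization -----------------------------------

.aa3_to_label <- c(Phe = "Phe", Val = "Val", Ile = "Ile", Met = "Met",
                   Trp = "Trp", Ala = "Ala", Asn = "Asn", Cys = "Cys",
                   Tyr = "Tyr", Asp = "Asp", Lys = "Lys", Gly = "Gly",
                   Arg = "Arg", His = "His", Glu = "Glu", Thr = "Thr",
                   Pro = "Pro", Gln = "Gln")

.anticodon_to_isotype <- c(TAA = "Leu1", TAG = "Leu2",
                           TGA = "Ser1", GCT = "Ser2")

#' Canonicalize a tRNA product name
#'
#' Maps free-text tRNA product names (e.g. `"tRNA-Phe"`,
#' `"tRNA-Leu (UUR)"`) to the 22 canonical labels. The two leucine and
#' two serine isoacceptors are resolved by the anticodon (TAA -> Leu1,
#' TAG -> Leu2, TGA -> Ser1, GCT -> Ser2) or by a codon-family note
#' (UUR/CUN/UCN/AGY) embedded in the product text; a Leu or Ser with
#' neither is an error.
#'
#' @param product_text Product or gene qualifier text.
#' @param anticodon Optional anticodon triplet (DNA, coding strand).
#' @return One of the 22 canonical labels.
#' @export
canonical_trna_label <- function(product_text, anticodon = NA_character_) {
  txt <- product_text
  m <- regmatches(txt, regexpr("tRNA[- ]?([A-Za-z]{3})", txt))
  if (!length(m)) stop("not a tRNA product: '", product_text, "'")
  aa <- sub("tRNA[- ]?", "", m)
  aa <- paste0(toupper(substr(aa, 1, 1)), tolower(substr(aa, 2, 3)))
  if (aa %in% names(.aa3_to_label)) return(unname(.aa3_to_label[aa]))
  if (!aa %in% c("Leu", "Ser"))
    stop("unknown tRNA amino acid '", aa, "' in '", product_text, "'")
  up <- toupper(txt)
  if (aa == "Leu") {
    if (grepl("UUR|TTR", up)) return("Leu1")
    if (grepl("CUN|CTN", up)) return("Leu2")
  } else {
    if (grepl("UCN|TCN", up)) return("Ser1")
    if (grepl("AGY|AGC|AGN", up)) return("Ser2")
  }
  ac <- toupper(anticodon)
  if (!is.na(ac) && ac %in% names(.anticodon_to_isotype))
    return(unname(.anticodon_to_isotype[ac]))
  stop("ambiguous ", aa, " tRNA '", product_text,
       "': no anticodon and no codon-family note")
}

# CDS gene-name normalization (common GenBank spellings)
.normalize_cds_label <- function(txt) {
  up <- toupper(gsub("[ _-]", "", txt))
  map <- c(ND1 = "ND1", ND2 = "ND2", ND3 = "ND3", ND4 = "ND4",
           ND4L = "ND4L", ND5 = "ND5", ND6 = "ND6",
           NADH1 = "ND1", NADH2 = "ND2", NADH3 = "ND3", NADH4 = "ND4",
           NADH4L = "ND4L", NADH5 = "ND5", NADH6 = "ND6",
           COX1 = "COX1", COX2 = "COX2", COX3 = "COX3",
           COI = "COX1", COII = "COX2", COIII = "COX3",
           CO1 = "COX1", CO2 = "COX2", CO3 = "COX3",
           ATP6 = "ATP6", ATP8 = "ATP8", ATPASE6 = "ATP6",
           ATPASE8 = "ATP8", CYTB = "CYTB", COB = "CYTB", CYB = "CYTB")
  if (up %in% names(map)) unname(map[up]) else txt
}

.normalize_rrna_label <- function(txt) {
  up <- toupper(txt)
  if (grepl("12S|SMALL|S-RRNA|RRNS", up)) "rrnS"
  else if (grepl("16S|LARGE|L-RRNA|RRNL", up)) "rrnL"
  else txt
}

# --- location strings ------------------------------------------------

.parse_location <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "H"
  while (grepl("^complement\\(", loc)) {
    strand <- if (strand == "H") "L" else "H"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  iv <- t(vapply(parts, function(p) {
    nums <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    if (anyNA(nums)) stop("cannot parse location part '", p, "'")
    nums
  }, integer(2)))
  dimnames(iv) <- NULL
  list(strand = strand, intervals = iv)
}

.format_location <- function(f) {
  parts <- apply(f$intervals, 1, function(p) paste0(p[1], "..", p[2]))
  loc <- if (length(parts) > 1L)
    paste0("join(", paste(parts, collapse = ","), ")") else parts
  if (f$strand == "L") paste0("complement(", loc, ")") else loc
}

# --- reader ----------------------------------------------------------

#' Read GenBank flat files into genome records
#'
#' Parses one or more GenBank records from a flat file, normalizing
#' features into the data model: D-loop / control-region misc features
#' become `control_region`, replication origins become `rep_origin_L`
#' or `rep_origin_H` (by their note), tRNA product names and anticodon
#' qualifiers are canonicalized, and CDS/rRNA gene names are mapped to
#' canonical labels. Records without a control region load but are
#' flagged geometry-incapable.
#'
#' @param path Path to a GenBank flat file (>= 1 record).
#' @return List of `mt_genome` records.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(grep("^LOCUS", lines))) stop("no LOCUS line in ", path)
  rec_breaks <- c(grep("^LOCUS", lines), length(lines) + 1L)
  lapply(seq_len(length(rec_breaks) - 1L), function(i) {
    .parse_genbank_record(lines[rec_breaks[i]:(rec_breaks[i + 1L] - 1L)])
  })
}

.parse_genbank_record <- function(lines) {
  locus <- lines[1]
  len <- regmatches(locus, regexpr("[0-9]+(?= bp)", locus, perl = TRUE))
  if (!length(len)) stop("LOCUS line lacks a length: ", locus)
  length_bp <- as.integer(len)
  name <- strsplit(trimws(sub("^LOCUS", "", locus)), "[[:space:]]+")[[1]][1]
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line))
    strsplit(trimws(sub("^ACCESSION", "", acc_line[1])),
             "[[:space:]]+")[[1]][1] else name
  org_line <- grep("^[[:space:]]*ORGANISM", lines, value = TRUE)
  taxon <- if (length(org_line)) trimws(sub(".*ORGANISM", "", org_line[1]))
           else accession

  fstart <- grep("^FEATURES", lines)
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  feats <- list()
  if (length(fstart)) {
    fend <- if (length(fend)) min(fend[fend > fstart[1]]) else length(lines) + 1L
    block <- lines[(fstart[1] + 1L):(fend - 1L)]
    feats <- .parse_feature_block(block, length_bp)
  }
  seq <- NULL
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart)) {
    oend <- grep("^//", lines)
    oend <- if (length(oend)) min(oend[oend > ostart[1]]) else length(lines) + 1L
    if (oend > ostart[1] + 1L) {
      raw <- lines[(ostart[1] + 1L):(oend - 1L)]
      seq <- toupper(gsub("[^acgtnACGTN]", "", paste(raw, collapse = "")))
      if (!nzchar(seq)) seq <- NULL
    }
  }
  rec <- mt_genome(accession, taxon = taxon, length_bp = length_bp,
                   features = feats, sequence = seq)
  if (!rec$geometry_capable)
    message("record ", accession, ": no control region annotated; ",
            "flagged geometry-incapable")
  rec
}

.parse_feature_block <- function(block, length_bp) {
  # split into entries: a new entry starts with a key in columns 6-20
  key_idx <- grep("^ {2,10}[A-Za-z_'-]+ +\\S", block)
  key_idx <- key_idx[!grepl("^ {21}", block[key_idx])]
  if (!length(key_idx)) return(list())
  ends <- c(key_idx[-1L] - 1L, length(block))
  feats <- list()
  for (j in seq_along(key_idx)) {
    entry <- block[key_idx[j]:ends[j]]
    header <- entry[1]
    key <- sub("^ +", "", substr(header, 1, 20))
    key <- strsplit(key, "[[:space:]]+")[[1]][1]
    rest <- trimws(substr(header, 22, nchar(header)))
    body <- if (length(entry) > 1L) trimws(entry[-1L]) else character(0)
    # location continuation lines (before first qualifier)
    qual_at <- grep("^/", body)
    loc_extra <- if (length(qual_at)) body[seq_len(min(qual_at) - 1L)]
                 else body
    loc <- paste(c(rest, loc_extra), collapse = "")
    quals <- .parse_qualifiers(if (length(qual_at))
      body[min(qual_at):length(body)] else character(0))
    f <- .normalize_feature(key, loc, quals)
    if (!is.null(f)) feats[[length(feats) + 1L]] <- f
  }
  feats
}

.parse_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  starts <- grep("^/", lines)
  ends <- c(starts[-1L] - 1L, length(lines))
  quals <- list()
  for (j in seq_along(starts)) {
    q <- paste(lines[starts[j]:ends[j]], collapse = " ")
    name <- sub("^/([A-Za-z_]+).*", "\\1", q)
    val <- if (grepl("=", q, fixed = TRUE))
      sub("^/[A-Za-z_]+=", "", q) else ""
    quals[[name]] <- gsub('^"|"$', "", val)
  }
  quals
}

.normalize_feature <- function(key, loc, quals) {
  parsed <- .parse_location(loc)
  note <- toupper(paste(quals$note %||% "", quals$product %||% "",
                        quals$standard_name %||% ""))
  if (key %in% c("D-loop", "D_loop")) {
    return(mt_feature("control_region", "CR", parsed$strand,
                      parsed$intervals))
  }
  if (key == "misc_feature" && grepl("CONTROL REGION|D-LOOP", note)) {
    return(mt_feature("control_region", "CR", parsed$strand,
                      parsed$intervals))
  }
  if (key == "rep_origin") {
    is_h <- grepl("H-STRAND|HEAVY", note)
    return(mt_feature(if (is_h) "rep_origin_H" else "rep_origin_L",
                      if (is_h) "OH" else "OL",
                      parsed$strand, parsed$intervals))
  }
  if (key == "tRNA") {
    ac <- NA_character_
    ac_q <- quals$anticodon
    if (!is.null(ac_q)) {
      m <- regmatches(ac_q, regexpr("seq:[acgtACGT]{3}", ac_q))
      if (length(m)) ac <- toupper(sub("seq:", "", m))
      else if (grepl("^[acgtACGT]{3}$", ac_q)) ac <- toupper(ac_q)
    }
    prod <- quals$product %||% quals$gene %||%
      stop("tRNA feature without product/gene qualifier at ", loc)
    label <- canonical_trna_label(prod, ac)
    if (is.na(ac)) ac <- unname(canonical_anticodons()[label])
    return(mt_feature("tRNA", label, parsed$strand, parsed$intervals,
                      anticodon = ac))
  }
  if (key == "CDS") {
    g <- quals$gene %||% quals$product %||%
      stop("CDS feature without gene/product qualifier at ", loc)
    return(mt_feature("CDS", .normalize_cds_label(g), parsed$strand,
                      parsed$intervals))
  }
  if (key == "rRNA") {
    g <- quals$product %||% quals$gene %||% "rRNA"
    return(mt_feature("rRNA", .normalize_rrna_label(g), parsed$strand,
                      parsed$intervals))
  }
  NULL  # source, gene, misc features etc. are not modelled
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- writer ----------------------------------------------------------

.gb_product <- function(f) {
  switch(f$kind,
         tRNA = {
           aa <- trna_amino_acid(f$label)
           fam <- switch(f$label, Leu1 = " (UUR)", Leu2 = " (CUN)",
                         Ser1 = " (UCN)", Ser2 = " (AGY)", "")
           paste0("tRNA-", aa, fam)
         },
         rRNA = if (f$label == "rrnS") "12S ribosomal RNA"
                else "16S ribosomal RNA",
         f$label)
}

#' Write genome records as GenBank flat files
#'
#' Emits one `<accession>.gb` flat file per record, readable back by
#' [read_genbank()] with feature-for-feature fidelity (the round trip
#' is the identity on the data model).
#'
#' @param records List of `mt_genome` records (or a single record).
#' @param directory Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_fixture_genbank <- function(records, directory) {
  if (inherits(records, "mt_genome")) records <- list(records)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(records, function(rec) {
    path <- file.path(directory, paste0(rec$accession, ".gb"))
    writeLines(.format_genbank_record(rec), path)
    path
  }, character(1))
  invisible(paths)
}

.format_genbank_record <- function(rec) {
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     circular     %s",
            rec$accession, rec$length_bp, format(Sys.Date(), "%d-%b-%Y")),
    sprintf("DEFINITION  %s mitochondrion, complete genome.", rec$taxon),
    sprintf("ACCESSION   %s", rec$accession),
    "  ORGANISM  " %p% rec$taxon,
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", rec$length_bp),
    sprintf("                     /organism=\"%s\"", rec$taxon))
  for (f in rec$features) {
    key <- switch(f$kind, control_region = "D-loop",
                  rep_origin_L = "rep_origin", rep_origin_H = "rep_origin",
                  f$kind)
    out <- c(out, sprintf("     %-15s %s", key, .format_location(f)))
    if (f$kind == "tRNA") {
      out <- c(out, sprintf("                     /product=\"%s\"",
                            .gb_product(f)))
      if (!is.na(f$anticodon))
        out <- c(out, sprintf("                     /anticodon=\"(seq:%s)\"",
                              tolower(f$anticodon)))
    } else if (f$kind == "CDS") {
      out <- c(out, sprintf("                     /gene=\"%s\"", f$label))
    } else if (f$kind == "rRNA") {
      out <- c(out, sprintf("                     /product=\"%s\"",
                            .gb_product(f)))
    } else if (f$kind == "rep_origin_L") {
      out <- c(out,
               "                     /note=\"origin of L-strand replication\"")
    } else if (f$kind == "rep_origin_H") {
      out <- c(out,
               "                     /note=\"origin of H-strand replication\"")
    }
  }
  if (!is.null(rec$sequence)) {
    out <- c(out, "ORIGIN")
    s <- tolower(rec$sequence)
    pos <- seq(1L, nchar(s), by = 60L)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59L, nchar(s)))
      groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, by = 10L),
                               nchar(chunk)))
      out <- c(out, sprintf("%9d %s", p, paste(groups, collapse = " ")))
    }
  }
  c(out, "//")
}

`%p%` <- function(a, b) paste0(a, b)

#' Export a normalized feature table
#'
#' @param records List of `mt_genome` records.
#' @param path TSV output path (accession, label, kind, strand, start,
#'   end, anticodon; one row per interval).
#' @return The table, invisibly.
#' @export
write_feature_tsv <- function(records, path) {
  if (inherits(records, "mt_genome")) records <- list(records)
  rows <- do.call(rbind, lapply(records, function(rec) {
    do.call(rbind, lapply(rec$features, function(f) {
      data.frame(accession = rec$accession, label = f$label,
                 kind = f$kind, strand = f$strand,
                 start = f$intervals[, 1], end = f$intervals[, 2],
                 anticodon = f$anticodon, stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(rows)
}
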