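test_that("tRNA product names canonicalize, isoacceptors resolved", {
  expect_identical(canonical_trna_label("tRNA-Phe"), "Phe")
  expect_identical(canonical_trna_label("tRNA-Leu", "TAG"), "Leu2")
  expect_identical(canonical_trna_label("tRNA-Leu", "TAA"), "Leu1")
  expect_identical(canonical_trna_label("tRNA-Leu (UUR)"), "Leu1")
  expect_identical(canonical_trna_label("tRNA-Ser (AGY)"), "Ser2")
  expect_identical(canonical_trna_label("tRNA-Ser", "TGA"), "Ser1")
  expect_error(canonical_trna_label("tRNA-Leu"), "ambiguous")
  expect_error(canonical_trna_label("rRNA 12S"), "not a tRNA")
  # all 22 canonical anticodons map to 22 distinct labels
  ac <- canonical_anticodons()
  got <- vapply(names(ac), function(l) {
    aa <- trna_amino_acid(l)
    canonical_trna_label(paste0("tRNA-", aa), ac[[l]])
  }, character(1))
  expect_identical(unname(got), names(ac))
})

test_that("record validation enforces the data-model invariants", {
  expect_error(mt_genome("X", length_bp = 0L), "positive")
  f <- mt_feature("tRNA", "Phe", "H", c(1L, 70L))
  expect_error(mt_genome("X", length_bp = 50L, features = list(f)),
               "exceeds")
  dup <- list(f, mt_feature("tRNA", "Phe", "H", c(100L, 170L)))
  expect_error(mt_genome("X", length_bp = 500L, features = dup),
               "duplicate.*Phe")
  expect_error(mt_feature("tRNA", "Phe", "H", c(70L, 1L)), "end < start")
  # no control region: loads, flagged geometry-incapable
  rec <- mt_genome("X", length_bp = 500L, features = list(f))
  expect_false(rec$geometry_capable)
  expect_error(cr_reference_points(rec), "control_region")
  # zero features is fine
  empty <- mt_genome("E", length_bp = 100L)
  expect_length(empty$features, 0L)
  expect_false(empty$geometry_capable)
})

test_that("simulated records round-trip through GenBank exactly", {
  g <- sim_record(seed = 421L)
  dir <- withr::local_tempdir()
  paths <- write_fixture_genbank(g$record, dir)
  back <- read_genbank(paths[[1L]])
  expect_length(back, 1L)
  b <- back[[1L]]
  a <- g$record
  expect_identical(b$accession, a$accession)
  expect_identical(b$length_bp, a$length_bp)
  expect_identical(b$sequence, a$sequence)
  expect_identical(length(b$features), length(a$features))
  for (i in seq_along(a$features)) {
    fa <- a$features[[i]]; fb <- b$features[[i]]
    expect_identical(fb$kind, fa$kind, info = i)
    expect_identical(fb$label, fa$label, info = i)
    expect_identical(fb$strand, fa$strand, info = i)
    expect_identical(fb$intervals, fa$intervals, info = i)
    expect_identical(is.na(fb$anticodon), is.na(fa$anticodon))
    if (!is.na(fa$anticodon))
      expect_identical(fb$anticodon, fa$anticodon, info = i)
  }
})

test_that("a database-style flat file parses, including wraps and joins", {
  txt <- c(
    "LOCUS       TEST0001            1000 bp    DNA     circular VRT 01-JAN-2000",
    "DEFINITION  Testus exemplaris mitochondrion, complete genome.",
    "ACCESSION   TEST0001",
    "  ORGANISM  Testus exemplaris",
    "FEATURES             Location/Qualifiers",
    "     source          1..1000",
    "                     /organism=\"Testus exemplaris\"",
    "     D-loop          join(951..1000,1..50)",
    "     tRNA            51..120",
    "                     /product=\"tRNA-Phe\"",
    "     tRNA            complement(121..190)",
    "                     /product=\"tRNA-Ser\"",
    "                     /anticodon=(pos:complement(151..153),aa:Ser,",
    "                     seq:tga)",
    "     CDS             200..301",
    "                     /gene=\"COI\"",
    "     rRNA            400..500",
    "                     /product=\"12S ribosomal RNA\"",
    "     rep_origin      complement(600..640)",
    "                     /note=\"origin of L-strand replication\"",
    "     misc_feature    700..720",
    "                     /note=\"repeat region\"",
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(txt, path)
  expect_error(recs <- read_genbank(path), NA)
  rec <- recs[[1L]]
  expect_identical(rec$length_bp, 1000L)
  expect_identical(rec$taxon, "Testus exemplaris")
  kinds <- vapply(rec$features, `[[`, "", "kind")
  expect_identical(sum(kinds == "control_region"), 1L)
  cr <- rec$features[[which(kinds == "control_region")[1]]]
  expect_identical(nrow(cr$intervals), 2L)
  expect_identical(cr$intervals[1L, ], c(951L, 1000L))
  ser <- Filter(function(f) f$kind == "tRNA" && f$label == "Ser1",
                rec$features)
  expect_length(ser, 1L)
  expect_identical(ser[[1L]]$strand, "L")
  expect_identical(ser[[1L]]$anticodon, "TGA")
  cds <- Filter(function(f) f$kind == "CDS", rec$features)
  expect_identical(cds[[1L]]$label, "COX1")
  ol <- Filter(function(f) f$kind == "rep_origin_L", rec$features)
  expect_length(ol, 1L)
})

test_that("multi-record files split and parse errors are caught", {
  g1 <- sim_record(seed = 77L)
  g2 <- sim_record(seed = 78L)
  rec2 <- g2$record; rec2$accession <- "SYNB"
  dir <- withr::local_tempdir()
  write_fixture_genbank(list(g1$record, rec2), dir)
  joint <- file.path(dir, "both.gb")
  writeLines(c(readLines(file.path(dir, "SYN001.gb")),
               readLines(file.path(dir, "SYNB.gb"))), joint)
  both <- read_genbank(joint)
  expect_length(both, 2L)
  expect_identical(vapply(both, `[[`, "", "accession"),
                   c("SYN001", "SYNB"))
  bad <- withr::local_tempfile(fileext = ".gb")
  writeLines("LOCUS       NOLEN", bad)
  expect_error(read_genbank(bad), "length")
})

test_that("typical-order check flags swapped genes and passes human", {
  h <- human_mt_genome()
  expect_true(check_typical_order(h)$match)
  # swap Gln and Ile coordinates
  idx <- which(vapply(h$features, `[[`, "", "label") %in% c("Gln", "Ile"))
  tmp <- h$features[[idx[1]]]$intervals
  h$features[[idx[1]]]$intervals <- h$features[[idx[2]]]$intervals
  h$features[[idx[2]]]$intervals <- tmp
  rep <- check_typical_order(h)
  expect_false(rep$match)
  expect_setequal(rep$mismatches$observed, c("Gln", "Ile"))
})

test_that("feature tables export one row per interval", {
  h <- human_mt_genome()
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- write_feature_tsv(h, path)
  expect_true(file.exists(path))
  expect_identical(nrow(tab), 40L)  # 39 features, CR has two intervals
  expect_identical(sum(tab$label == "CR"), 2L)
})
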