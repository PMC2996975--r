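test_that("human replication geometry reproduces the 13/9 split", {
  h <- human_mt_genome()
  map <- replication_map(h)
  expect_identical(map$o_l_source, "annotated")
  grp <- classify_replication_group(h, map)
  expect_identical(sum(grp == "between_origins") +
                     sum(grp == "outside"), 22L)
  expect_setequal(names(grp)[grp == "between_origins"],
                  c("Cys", "Tyr", "Ser1", "Asp", "Lys", "Gly", "Arg",
                    "His", "Ser2", "Leu2", "Glu", "Thr", "Pro"))
  expect_setequal(names(grp)[grp == "outside"],
                  c("Asn", "Ala", "Trp", "Met", "Gln", "Ile", "Leu1",
                    "Val", "Phe"))
})

test_that("alpha + beta equals the genome length for every tRNA", {
  for (seed in c(501L, 502L)) {
    g <- sim_record(seed = seed)
    tab <- exposure_durations(g$record)
    expect_true(all(tab$alpha + tab$beta == g$record$length_bp))
    expect_identical(nrow(tab), 22L)
    between <- tab$group == "between_origins"
    expect_true(all(tab$exposure[between] == tab$alpha[between]))
    expect_true(all(tab$exposure[!between] ==
                      tab$alpha[!between] - tab$beta[!between]))
  }
  h <- exposure_durations(human_mt_genome())
  expect_true(all(h$alpha + h$beta == 16569L))
})

test_that("alpha matches a stepwise walk from the L-strand origin", {
  g <- sim_record(seed = 503L)
  rec <- g$record
  map <- replication_map(rec)
  tab <- exposure_durations(rec, map)
  L <- rec$length_bp
  for (i in sample(nrow(tab), 5L)) {
    f <- Filter(function(x) x$kind == "tRNA" && x$label == tab$trna[i],
                rec$features)[[1L]]
    target <- if (f$strand == "H") f$intervals[1L, 1L]
              else f$intervals[nrow(f$intervals), 2L]
    pos <- map$o_l; n <- 0L
    while (pos != target) {
      pos <- (pos %% L) + 1L
      n <- n + 1L
    }
    expect_identical(tab$alpha[i], n, info = tab$trna[i])
  }
})

test_that("exposures are rotation-invariant; boundary gene is between", {
  h <- human_mt_genome()
  t0 <- exposure_durations(h)
  t1 <- exposure_durations(rotate_genome(h, 4321L))
  m <- merge(t0, t1, by = "trna")
  expect_identical(m$alpha.x, m$alpha.y)
  expect_identical(m$exposure.x, m$exposure.y)
  expect_identical(m$group.x, m$group.y)
  # a gene starting right after o_l belongs to the between group
  feats <- list(mt_feature("control_region", "CR", "H", c(9001L, 10000L)),
                mt_feature("rep_origin_L", "OL", "L", c(3000L, 3000L)),
                mt_feature("tRNA", "Cys", "L", c(3001L, 3070L)))
  rec <- mt_genome("B", length_bp = 10000L, features = feats)
  grp <- classify_replication_group(rec)
  expect_identical(unname(grp[["Cys"]]), "between_origins")
})

test_that("WANCY imputation stands in for a missing origin annotation", {
  g <- sim_record(seed = 504L)
  rec <- g$record
  keep <- vapply(rec$features, function(f) f$kind != "rep_origin_L",
                 logical(1))
  rec$features <- rec$features[keep]
  rec <- validate_mt_genome(rec)
  map <- replication_map(rec)
  expect_identical(map$o_l_source, "imputed_wancy")
  # the imputed origin sits in the Asn-Cys gap
  asn <- Filter(function(f) f$kind == "tRNA" && f$label == "Asn",
                rec$features)[[1L]]
  cys <- Filter(function(f) f$kind == "tRNA" && f$label == "Cys",
                rec$features)[[1L]]
  a <- max(asn$intervals); c_ <- min(cys$intervals); L <- rec$length_bp
  span <- (c_ - 1L - a - 1L) %% L
  off <- (map$o_l - (a + 1L)) %% L
  expect_lte(off, span)
  # with neither annotation nor Asn/Cys, the analysis refuses
  rec2 <- rec
  rec2$features <- Filter(function(f)
    !(f$kind == "tRNA" && f$label %in% c("Asn", "Cys")), rec2$features)
  rec2 <- validate_mt_genome(rec2)
  expect_error(replication_map(rec2), "WANCY")
})

test_that("anticodon G+T counting honors both conventions", {
  expect_identical(anticodon_gt_count("GTA", "first_two_5to3"), 2L)
  expect_identical(anticodon_gt_count("GTA", "codon12_pairing"), 1L)
  expect_identical(anticodon_gt_count("CAA", "first_two_5to3"), 0L)
  expect_identical(anticodon_gt_count("CAA", "codon12_pairing"), 0L)
  expect_identical(anticodon_gt_count("TTT"), 2L)
  expect_error(anticodon_gt_count("GT"), "triplet")
  expect_error(anticodon_gt_count("GTX"), "triplet")
  # all canonical anticodons give counts in 0..2 under both conventions
  for (conv in c("codon12_pairing", "first_two_5to3")) {
    counts <- anticodon_gt_count(unname(canonical_anticodons()), conv)
    expect_true(all(counts %in% 0:2))
  }
})

test_that("degenerate G+T input yields an undefined-correlation error", {
  tab <- data.frame(trna = c("Phe", "Val", "Leu1"),
                    group = "between_origins",
                    alpha = c(100, 200, 300), beta = c(900, 800, 700),
                    exposure = c(100, 200, 300),
                    anticodon = "GAA", gt_count = 1L)
  expect_error(exposure_gt_correlation(tab, "all"), "zero variance")
})

test_that("a simulated gradient is recovered; slope zero stays null", {
  g <- typical_genome()
  map <- replication_map(g$record)
  cfg0 <- sim_config(n_species = 2L, deamination_slope = 0, seed = 1L)
  cfg_big <- sim_config(n_species = 2L, deamination_slope = 5 / 10000,
                        seed = 1L)
  r0 <- rbig <- numeric(30L)
  for (i in 1:30) {
    s0 <- simulate_anticodon_gradient(cfg0, g$record, map,
                                      seed = 7000L + i)
    sb <- simulate_anticodon_gradient(cfg_big, g$record, map,
                                      seed = 7100L + i)
    t0 <- exposure_durations(s0$record, map)
    tb <- exposure_durations(sb$record, map)
    r0[i] <- exposure_gt_correlation(t0, "all")$r
    rbig[i] <- exposure_gt_correlation(tb, "all")$r
    # the generator's own G+T draw matches what the analysis reads back
    expect_identical(stats::setNames(tb$gt_count, tb$trna)[sb$truth$trna],
                     stats::setNames(sb$truth$gt_count, sb$truth$trna))
  }
  expect_lt(abs(mean(r0)), 0.15)         # centred on zero
  expect_true(all(rbig > 0))             # strong gradient dominates
  expect_gt(mean(rbig), 0.4)
})
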