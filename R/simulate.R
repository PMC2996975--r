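## Seeded synthetic-data generator: trees, correlated tip data, and
## fully annotated circular genomes with sequences, so that every
## analysis stage can be exercised against known ground truth.
##
## The generator emulates the statistical structure the analyses
## assume -- per-family codon usage and CR distance co-evolving under
## correlated Brownian motion on a phylogeny, and an exposure-dependent
## G+T gradient at anticodon positions -- not sequence evolution:
## genomes are independent draws given their tip parameters.

#' Simulation configuration
#'
#' Bundles the generator's parameters. Defaults describe the study
#' conditions the package's analyses target: a cohort of 47 vertebrate
#' mt-genomes of about 16.5 kb; a usage-position correlation of -0.4
#' (the strength of the translational-constraint signal once outlier
#' families are excluded); Brownian scales of 0.15 log10 units per
#' unit branch (about 1.4-fold change between sister taxa) for both
#' log usage and log distance; and a deamination gradient of 0.5 logit
#' per 10 kb of exposure with even (logit 0) baseline G+T odds.
#'
#' @param n_species Number of tips / genomes.
#' @param genome_length Genome length in bp.
#' @param gene_order `"typical"` or `"permuted"` (tRNA root positions
#'   shuffled with `permutation_seed`).
#' @param permutation_seed Seed for the permuted gene order.
#' @param rho_usage_position Brownian cross-correlation between log10
#'   usage and log10 distance, in (-1, 1).
#' @param bm_sigma_usage,bm_sigma_position Brownian standard deviations
#'   (log10 scale, per unit branch length).
#' @param deamination_slope Logit G+T probability per bp of exposure.
#' @param deamination_intercept Logit G+T probability at zero exposure.
#' @param seed Mandatory integer seed; all generator randomness derives
#'   from it (no hidden global state).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_species = 47L, genome_length = 16500L,
                       gene_order = c("typical", "permuted"),
                       permutation_seed = 1L,
                       rho_usage_position = -0.4,
                       bm_sigma_usage = 0.15, bm_sigma_position = 0.15,
                       deamination_slope = 0.5 / 10000,
                       deamination_intercept = 0, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  gene_order <- match.arg(gene_order)
  stopifnot(n_species >= 2L, genome_length >= 4000L,
            abs(rho_usage_position) < 1,
            bm_sigma_usage > 0, bm_sigma_position > 0)
  structure(list(n_species = as.integer(n_species),
                 genome_length = as.integer(genome_length),
                 gene_order = gene_order,
                 permutation_seed = as.integer(permutation_seed),
                 rho_usage_position = rho_usage_position,
                 bm_sigma_usage = bm_sigma_usage,
                 bm_sigma_position = bm_sigma_position,
                 deamination_slope = deamination_slope,
                 deamination_intercept = deamination_intercept,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a Yule tree
#'
#' Pure-birth topology: starting from a cherry, a uniformly chosen
#' extant tip splits until `n_species` tips exist. All branch lengths
#' are 1 (the same convention the contrasts use for composite trees
#' without rate estimates). Deterministic given the seed.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A rooted binary `phylo` tree with tip labels `s1..sn`.
#' @export
simulate_tree <- function(n_species, seed) {
  if (n_species < 2L) stop("need at least 2 species")
  set.seed(seed)
  kids <- vector("list", 2L * n_species - 1L)
  tips <- c(2L, 3L)
  next_id <- 4L
  kids[[1L]] <- c(2L, 3L)
  while (length(tips) < n_species) {
    pick <- tips[sample.int(length(tips), 1L)]
    kids[[pick]] <- c(next_id, next_id + 1L)
    tips <- c(setdiff(tips, pick), next_id, next_id + 1L)
    next_id <- next_id + 2L
  }
  label <- integer(0)
  nwk <- function(node) {
    ch <- kids[[node]]
    if (is.null(ch)) {
      label <<- c(label, node)
      paste0("s", length(label))
    } else {
      paste0("(", nwk(ch[1L]), ":1,", nwk(ch[2L]), ":1)")
    }
  }
  tree <- ape::read.tree(text = paste0(nwk(1L), ";"))
  tree
}

#' Simulate correlated Brownian tip values
#'
#' Evolves a bivariate Brownian process along a rooted tree: each
#' branch adds independent bivariate normal increments with standard
#' deviations `sigma_x * sqrt(b)`, `sigma_y * sqrt(b)` and correlation
#' `rho`. The building block of the tip-data generator, also useful
#' directly for calibration studies of the contrasts machinery.
#'
#' @param tree Rooted binary `phylo`; missing branch lengths default
#'   to 1.
#' @param root_x,root_y Root values.
#' @param sigma_x,sigma_y Per-unit-branch standard deviations.
#' @param rho Cross-correlation of the increments, in (-1, 1).
#' @param seed Optional integer seed (set before drawing when given).
#' @return Matrix (tips x 2, columns `x`, `y`) of tip values, rows in
#'   `tree$tip.label` order.
#' @export
simulate_bm_tips <- function(tree, root_x = 0, root_y = 0,
                             sigma_x = 1, sigma_y = 1, rho = 0,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- .simulate_bm_pair(tree, root_x, root_y, sigma_x, sigma_y, rho)
  rownames(out) <- tree$tip.label
  out
}

# Correlated bivariate Brownian motion along a tree; returns a
# (tips x 2) matrix of tip values. Caller manages the RNG seed.
.simulate_bm_pair <- function(tree, root_x, root_y, sigma_x, sigma_y, rho) {
  ntip <- length(tree$tip.label)
  bl <- tree$edge.length
  if (is.null(bl)) bl <- rep(1, nrow(tree$edge))
  ord <- ape::reorder.phylo(tree, "postorder")
  e <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]  # preorder
  blp <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  if (is.null(blp)) blp <- rep(1, nrow(e))
  vx <- vy <- rep(NA_real_, ntip + tree$Nnode)
  vx[ntip + 1L] <- root_x; vy[ntip + 1L] <- root_y
  z1 <- stats::rnorm(nrow(e)); z2 <- stats::rnorm(nrow(e))
  for (i in seq_len(nrow(e))) {
    par <- e[i, 1L]; ch <- e[i, 2L]; s <- sqrt(blp[i])
    dx <- sigma_x * s * z1[i]
    dy <- sigma_y * s * (rho * z1[i] + sqrt(1 - rho^2) * z2[i])
    vx[ch] <- vx[par] + dx
    vy[ch] <- vy[par] + dy
  }
  cbind(x = vx[seq_len(ntip)], y = vy[seq_len(ntip)])
}

# typical L-strand tRNAs (all others are H)
.l_strand_trnas <- c("Gln", "Ala", "Asn", "Cys", "Tyr", "Ser1", "Glu",
                     "Pro")

# Root log10 distances: the typical-order distances of the human
# genome, rescaled to the configured genome length.
.root_distances <- function(config) {
  d <- trna_distance(human_mt_genome())
  dist <- stats::setNames(d$distance_bp, d$trna)[trna_labels()]
  dist <- pmax(1, round(dist * config$genome_length / 16569))
  if (config$gene_order == "permuted") {
    prev <- .Random.seed
    set.seed(config$permutation_seed)
    dist <- stats::setNames(sample(dist), names(dist))
    .Random.seed <<- prev
  }
  dist
}

#' Simulate co-evolving usage and positions on a tree
#'
#' For each of the 22 tRNA families, evolves (log10 usage score, log10
#' CR distance) under correlated Brownian motion with cross-correlation
#' `rho_usage_position` along the tree. Usage scores are exponentiated
#' and renormalized per species to relative frequencies summing to 1;
#' distances are exponentiated to bp. Root usage is uniform (1/22);
#' root distances follow the typical vertebrate arrangement (or a
#' seeded permutation of it).
#'
#' @param config A [sim_config()].
#' @param tree Optional `phylo`; simulated from the config seed when
#'   missing.
#' @return List: `tree`, `usage` (species x 22 relative frequencies),
#'   `distance_bp` (species x 22, real-valued), `strand` (named
#'   vector), `truth` (latent log10 matrices and parameters).
#' @export
simulate_usage_and_positions <- function(config, tree = NULL) {
  set.seed(config$seed)
  if (is.null(tree)) tree <- simulate_tree(config$n_species, config$seed)
  labels <- trna_labels()
  root_d <- log10(.root_distances(config))
  root_u <- rep(log10(1 / 22), 22L)
  ntip <- length(tree$tip.label)
  u <- d <- matrix(NA_real_, nrow = ntip, ncol = 22L,
                   dimnames = list(tree$tip.label, labels))
  for (j in seq_len(22L)) {
    tv <- .simulate_bm_pair(tree, root_u[j], root_d[j],
                            config$bm_sigma_usage,
                            config$bm_sigma_position,
                            config$rho_usage_position)
    u[, j] <- tv[, "x"]
    d[, j] <- tv[, "y"]
  }
  usage <- 10^u
  usage <- usage / rowSums(usage)
  strand <- stats::setNames(ifelse(labels %in% .l_strand_trnas, "L", "H"),
                            labels)
  list(tree = tree, usage = usage, distance_bp = 10^d, strand = strand,
       truth = list(log_usage = u, log_distance = d,
                    rho = config$rho_usage_position,
                    root_distance = root_d))
}

#' Realize one annotated genome from tip data
#'
#' Builds a full `mt_genome` (with sequence) whose tRNA genes sit at
#' the given CR distances and whose 13 protein-coding genes carry a
#' multinomial draw of codons matching the given family usage. tRNAs
#' are placed at their rounded target distances (minimum 1 bp spacing,
#' later genes shifted downstream on collision); the remaining gaps are
#' filled, in genomic order, with the 2 rRNA and 13 CDS blocks of the
#' typical arrangement. Counting codons on the emitted record
#' reproduces the returned `codon_counts` exactly, and the realized
#' distances are exactly recoverable by [trna_distance()].
#'
#' @param config A [sim_config()].
#' @param usage Named numeric vector of 22 relative family frequencies.
#' @param distance_bp Named numeric vector of 22 target distances (bp).
#' @param accession,taxon Record identifiers.
#' @param seed Integer seed for the codon draw and background sequence.
#' @return List: `record` (an `mt_genome`), `codon_counts` (named
#'   integer vector, intended = realized), `distances` (realized, bp).
#' @export
realize_genome <- function(config, usage, distance_bp, accession,
                           taxon = accession, seed) {
  set.seed(seed)
  L <- config$genome_length
  labels <- trna_labels()
  stopifnot(all(labels %in% names(usage)),
            all(labels %in% names(distance_bp)))
  cr_len <- 1100L
  l_ref <- L - cr_len + 1L          # CR occupies [l_ref, L]
  h_ref <- L
  region_end <- l_ref - 1L
  trna_len <- 70L
  strand <- ifelse(labels %in% .l_strand_trnas, "L", "H")
  # desired genomic start of each tRNA gene body
  d <- pmin(pmax(as.integer(round(unname(distance_bp[labels]))), 1L),
            region_end - trna_len)
  start <- ifelse(strand == "H", d, l_ref - d - trna_len + 1L)
  start <- pmin(pmax(start, 1L), region_end - trna_len + 1L)
  ord <- order(start)
  placed <- integer(22L)
  prev_end <- 0L
  for (k in ord) {
    s <- max(start[k], prev_end + 2L)
    placed[k] <- s
    prev_end <- s + trna_len - 1L
  }
  # backward pass: distances clamped at the far end stack up beyond the
  # usable region; compress them leftward preserving order and spacing
  if (placed[ord[22L]] + trna_len - 1L > region_end) {
    nxt <- region_end + 2L
    for (k in rev(ord)) {
      placed[k] <- min(placed[k], nxt - trna_len - 1L)
      nxt <- placed[k]
    }
    if (placed[ord[1L]] < 1L)
      stop("layout infeasible: tRNA genes exceed the genome length")
  }
  trna_iv <- cbind(placed, placed + trna_len - 1L)
  # gaps between placed tRNAs (and the CR) host the rRNA and CDS
  # blocks; a large gap takes several blocks, as between consecutive
  # tRNAs of the typical arrangement
  occ <- trna_iv[order(trna_iv[, 1L]), , drop = FALSE]
  gaps <- cbind(c(1L, occ[, 2L] + 2L), c(occ[, 1L] - 2L, region_end - 1L))
  gaps <- gaps[gaps[, 2L] >= gaps[, 1L], , drop = FALSE]
  scale <- L / 16569
  targets <- c(rrnL = as.integer(round(1550 * scale)),
               rrnS = as.integer(round(950 * scale)),
               stats::setNames(rep(903L, 13L), .cds_labels))
  blocks <- matrix(0L, nrow = 15L, ncol = 2L)
  bkind <- character(15L)
  glist <- lapply(seq_len(nrow(gaps)), function(i) gaps[i, ])
  for (b in seq_along(targets)) {
    sizes <- vapply(glist, function(g) g[2L] - g[1L] + 1L, integer(1))
    gi <- which.max(sizes)
    len <- as.integer(min(targets[b], sizes[gi]))
    if (len < 36L)
      stop("layout infeasible: no room left for rRNA/CDS blocks")
    s <- glist[[gi]][1L]
    blocks[b, ] <- c(s, s + len - 1L)
    bkind[b] <- if (names(targets)[b] %in% c("rrnS", "rrnL"))
      "rRNA" else "CDS"
    glist[[gi]] <- c(s + len + 1L, glist[[gi]][2L])
    if (glist[[gi]][1L] > glist[[gi]][2L]) glist[[gi]] <- c(1L, 0L)
  }
  # relabel by genomic order: rRNAs become rrnS then rrnL, CDS take the
  # typical-order labels
  ordb <- order(blocks[, 1L])
  blocks <- blocks[ordb, , drop = FALSE]
  kind <- bkind[ordb]
  lab <- character(15L)
  lab[kind == "rRNA"] <- c("rrnS", "rrnL")
  lab[kind == "CDS"] <- c("ND1", "ND2", "COX1", "COX2", "ATP8", "ATP6",
                          "COX3", "ND3", "ND4L", "ND4", "ND5", "ND6",
                          "CYTB")
  # codon capacity of each CDS (room for codons + one stop)
  cds_rows <- which(kind == "CDS")
  cap <- (blocks[cds_rows, 2L] - blocks[cds_rows, 1L] + 1L) %/% 3L - 1L
  M <- sum(cap)
  fam_counts <- stats::rmultinom(1L, M, prob = unname(usage[labels]))[, 1L]
  names(fam_counts) <- labels
  pool <- unlist(lapply(labels, function(l) {
    cods <- trna_codon_family(l)
    k <- fam_counts[[l]]
    base <- k %/% length(cods); extra <- k %% length(cods)
    rep(cods, times = base + (seq_along(cods) <= extra))
  }), use.names = FALSE)
  pool <- sample(pool)
  # background sequence, then write features into it
  genome <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  feats <- list(mt_feature("control_region", "CR", "H", c(l_ref, L)))
  anticodons <- canonical_anticodons()
  for (k in seq_len(22L)) {
    s <- trna_iv[k, 1L]; e <- trna_iv[k, 2L]
    coding <- sample(c("A", "C", "G", "T"), trna_len, replace = TRUE)
    coding[31:33] <- strsplit(anticodons[[labels[k]]], "")[[1L]]
    genomic <- if (strand[k] == "L")
      rev(chartr("ACGT", "TGCA", coding)) else coding
    genome[s:e] <- genomic
    feats[[length(feats) + 1L]] <-
      mt_feature("tRNA", labels[k], strand[k], c(s, e),
                 anticodon = anticodons[[labels[k]]])
  }
  used <- 0L
  ci <- 0L
  for (b in seq_len(15L)) {
    s <- blocks[b, 1L]
    if (kind[b] == "rRNA") {
      feats[[length(feats) + 1L]] <-
        mt_feature("rRNA", lab[b], "H", c(s, blocks[b, 2L]))
      next
    }
    ci <- ci + 1L
    k <- cap[ci]
    codons <- pool[(used + 1L):(used + k)]
    used <- used + k
    coding <- c(unlist(strsplit(codons, ""), use.names = FALSE),
                c("T", "A", "A"))
    e <- s + length(coding) - 1L
    cds_strand <- if (lab[b] == "ND6") "L" else "H"
    genomic <- if (cds_strand == "L")
      rev(chartr("ACGT", "TGCA", coding)) else coding
    genome[s:e] <- genomic
    feats[[length(feats) + 1L]] <-
      mt_feature("CDS", lab[b], cds_strand, c(s, e))
  }
  # the WANCY-side replication origin, between Asn and Cys when the
  # typical neighbourhood exists, otherwise next to the first L tRNA
  asn_i <- which(labels == "Asn"); cys_i <- which(labels == "Cys")
  ol_mid <- .circ_midpoint(trna_iv[asn_i, 2L] + 1L,
                           trna_iv[cys_i, 1L] - 1L, L)
  feats[[length(feats) + 1L]] <-
    mt_feature("rep_origin_L", "OL", "L", c(ol_mid, ol_mid))
  rec <- mt_genome(accession, taxon = taxon, length_bp = L,
                   features = feats,
                   sequence = paste(genome, collapse = ""))
  realized <- ifelse(strand == "H", trna_iv[, 1L],
                     l_ref - trna_iv[, 2L])
  intended <- table(factor(pool, levels = names(.codon_family_table)))
  list(record = rec,
       codon_counts = stats::setNames(as.integer(intended),
                                      names(intended)),
       distances = stats::setNames(as.integer(realized), labels))
}

#' Simulate a full annotated cohort
#'
#' Tree, co-evolving tip data, and one realized genome per species.
#'
#' @param config A [sim_config()].
#' @return List: `config`, `tree`, `tips` (from
#'   [simulate_usage_and_positions()]), `genomes` (list of
#'   [realize_genome()] results, one per species; accessions `SYN...`
#'   matching tip labels in order).
#' @export
simulate_cohort <- function(config) {
  tips <- simulate_usage_and_positions(config)
  species <- tips$tree$tip.label
  genomes <- lapply(seq_along(species), function(i) {
    realize_genome(config,
                   usage = tips$usage[i, ],
                   distance_bp = tips$distance_bp[i, ],
                   accession = sprintf("SYN%03d", i),
                   taxon = species[i],
                   seed = config$seed + 1000L + i)
  })
  names(genomes) <- species
  list(config = config, tree = tips$tree, tips = tips, genomes = genomes)
}

#' Simulate an exposure-dependent anticodon G+T gradient
#'
#' Replaces each tRNA's anticodon annotation with a random draw in
#' which each of the two scored positions is G or T with probability
#' plogis(intercept + slope * exposure), G vs T (and A vs C) chosen
#' evenly; the unscored position is drawn uniformly. The record's
#' feature annotation is updated (the analysis reads anticodons from
#' the annotation; the nucleotide sequence, if any, is untouched).
#'
#' @param config A [sim_config()] (supplies slope and intercept).
#' @param rec An `mt_genome` with exposure-computable geometry.
#' @param map Optional `replication_map`.
#' @param convention Scored-position convention, as in
#'   [anticodon_gt_count()].
#' @param seed Integer seed.
#' @return List: `record` (annotation updated), `truth` (data frame
#'   with `trna`, `exposure`, `p_gt`, `gt_count`).
#' @export
simulate_anticodon_gradient <- function(config, rec, map = NULL,
                                        convention = c("codon12_pairing",
                                                       "first_two_5to3"),
                                        seed) {
  convention <- match.arg(convention)
  set.seed(seed)
  if (is.null(map)) map <- replication_map(rec)
  exp_tab <- exposure_durations(rec, map, convention)
  p <- stats::plogis(config$deamination_intercept +
                       config$deamination_slope * exp_tab$exposure)
  gt_count <- integer(nrow(exp_tab))
  new_ac <- character(nrow(exp_tab))
  scored <- if (convention == "first_two_5to3") c(1L, 2L) else c(3L, 2L)
  for (i in seq_len(nrow(exp_tab))) {
    draw_gt <- stats::runif(2L) < p[i]
    bases <- ifelse(draw_gt,
                    sample(c("G", "T"), 2L, replace = TRUE),
                    sample(c("A", "C"), 2L, replace = TRUE))
    ac <- sample(c("A", "C", "G", "T"), 3L, replace = TRUE)
    ac[scored] <- bases
    new_ac[i] <- paste(ac, collapse = "")
    gt_count[i] <- sum(draw_gt)
  }
  ## write the drawn anticodons back into the feature annotation; the
  ## unscored position is overwritten too, so the other convention sees
  ## pure noise there
  idx <- which(vapply(rec$features, `[[`, "", "kind") == "tRNA")
  feat_labels <- vapply(rec$features[idx], `[[`, "", "label")
  for (i in seq_len(nrow(exp_tab))) {
    j <- idx[match(exp_tab$trna[i], feat_labels)]
    rec$features[[j]]$anticodon <- new_ac[i]
  }
  list(record = rec,
       truth = data.frame(trna = exp_tab$trna,
                          exposure = exp_tab$exposure,
                          p_gt = p, gt_count = gt_count,
                          stringsAsFactors = FALSE))
}
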