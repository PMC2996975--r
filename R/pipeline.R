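## End-to-end orchestration: each exported run_* stage reproduces one
## analysis of the pipeline on a cohort of records plus a tree, and
## run_pipeline() chains them, writing TSV tables and a JSON summary.
## Stages communicate through plain data frames, so any stage can be
## rerun from saved intermediates.

#' Analysis configuration
#'
#' @param records List of `mt_genome` records (with sequences for the
#'   usage stages), or a directory of GenBank files to read.
#' @param tree Rooted binary `phylo` tree (or newick path) whose tip
#'   labels match the records' taxa (or accessions).
#' @param groups Optional named character vector mapping each record's
#'   taxon to `"stable"` or `"rearranged"` (editorial assignment).
#' @param exclude_taxa,exclude_trnas Optional labels dropped in the
#'   corresponding sensitivity reruns (e.g. rearranged-within-stable
#'   taxa; outlier tRNA families such as Leu2 and Thr).
#' @param offsets Transcription-start offsets for
#'   [offset_sensitivity()].
#' @param convention Anticodon scoring convention (both are always
#'   reported by [run_deamination()]; this picks the headline).
#' @param tail Predicted direction for usage-position correlations.
#' @param seed Seed for any stage that randomizes (none do by default;
#'   kept for reproducibility of configs).
#' @return List of class `mt_config`.
#' @export
mt_config <- function(records, tree = NULL, groups = NULL,
                      exclude_taxa = character(0),
                      exclude_trnas = c("Leu2", "Thr"),
                      offsets = c(0L, 150L, -150L, 500L, -500L),
                      convention = c("codon12_pairing", "first_two_5to3"),
                      tail = "negative", seed = 1L) {
  convention <- match.arg(convention)
  if (is.character(records) && length(records) == 1L && dir.exists(records)) {
    files <- list.files(records, pattern = "\\.gbk?$", full.names = TRUE)
    records <- unlist(lapply(files, read_genbank), recursive = FALSE)
  }
  if (inherits(records, "mt_genome")) records <- list(records)
  if (is.character(tree)) tree <- ape::read.tree(tree)
  taxa <- vapply(records, `[[`, "", "taxon")
  names(records) <- taxa
  if (!is.null(groups)) {
    missing <- setdiff(taxa, names(groups))
    if (length(missing))
      stop("taxa without a stable/rearranged group label: ",
           paste(missing, collapse = ", "))
  }
  structure(list(records = records, tree = tree, groups = groups,
                 exclude_taxa = exclude_taxa,
                 exclude_trnas = exclude_trnas, offsets = offsets,
                 convention = convention, tail = tail,
                 seed = as.integer(seed)),
            class = "mt_config")
}

#' Hydropathy rank test per genome
#'
#' For each geometry-capable genome, tests whether the tRNAs of
#' hydrophobic amino acids lie closer to the control region than those
#' of hydrophilic ones (Mann-Whitney U on the CR distances of the
#' 10-vs-12 split). Genomes with missing tRNAs are skipped with a
#' warning.
#'
#' @param config An `mt_config` (or a list of records).
#' @return List: `tables` (per-genome distance tables) and `tests`
#'   (data frame of U and p per genome).
#' @export
run_hydropathy_test <- function(config) {
  records <- if (inherits(config, "mt_config")) config$records else config
  tables <- list(); rows <- list()
  for (rec in records) {
    if (!isTRUE(rec$geometry_capable)) {
      warning("skipping ", rec$accession, ": no control region")
      next
    }
    present <- vapply(features_of(rec, kind = "tRNA"), `[[`, "", "label")
    absent <- setdiff(trna_labels(), present)
    if (length(absent)) {
      warning("skipping ", rec$accession, ": missing tRNA gene(s) ",
              paste(absent, collapse = ", "))
      next
    }
    tab <- tryCatch(hydropathy_table(rec), error = function(e) {
      warning("skipping ", rec$accession, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(tab)) next
    u <- mann_whitney_u(tab$distance_bp[tab$class == "hydrophobic"],
                        tab$distance_bp[tab$class == "hydrophilic"])
    tables[[rec$accession]] <- tab
    rows[[rec$accession]] <-
      data.frame(accession = rec$accession, taxon = rec$taxon,
                 U = u$U, n1 = u$n1, n2 = u$n2,
                 p_one_tailed = u$p_one_tailed,
                 p_two_tailed = u$p_two_tailed, method = u$method,
                 stringsAsFactors = FALSE)
  }
  tests <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
  list(tables = tables, tests = tests)
}

# per-species per-family log10 usage and log10 distance matrices
.usage_distance_matrices <- function(records) {
  labels <- trna_labels()
  taxa <- vapply(records, `[[`, "", "taxon")
  u <- d <- matrix(NA_real_, nrow = length(records), ncol = 22L,
                   dimnames = list(taxa, labels))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    counts <- count_codons(rec)
    usage <- trna_usage(counts)
    pseudo <- 0.5 / counts$total_sense
    u[i, usage$trna] <- log_transform(stats::setNames(usage$rel_freq,
                                                      usage$trna),
                                      pseudocount = pseudo)
    dist <- trna_distance(rec)
    d[i, dist$trna] <- log10(dist$distance_bp)
  }
  list(log_usage = u, log_distance = d)
}

# contrasts for one family over the species subset where both
# variables are available
.family_contrasts <- function(tree, log_u, log_d, family) {
  ok <- !is.na(log_u[, family]) & !is.na(log_d[, family])
  species <- rownames(log_u)[ok]
  if (length(species) < 4L) return(NULL)
  sub <- ape::keep.tip(tree, intersect(tree$tip.label, species))
  if (length(sub$tip.label) < 4L) return(NULL)
  x <- stats::setNames(log_u[sub$tip.label, family], sub$tip.label)
  y <- stats::setNames(log_d[sub$tip.label, family], sub$tip.label)
  cp <- independent_contrasts(sub, x, y)
  cp$trna <- family
  cp
}

#' Usage-position contrast correlations
#'
#' The central translational-constraint analysis: per tRNA family,
#' standardized contrasts of log10 relative usage (x) against log10 CR
#' distance (y) on the phylogeny; pooled through-origin correlations
#' over the configured taxon groups (all / stable / rearranged), with
#' reruns excluding the configured outlier tRNA families and taxa; and
#' the cross-taxon means analysis (per-family mean usage vs mean
#' distance, ordinary one-tailed Pearson over the 22 families, with
#' and without the outliers).
#'
#' @param config An `mt_config` with records (sequences required) and
#'   a tree.
#' @return List: `contrasts` (pooled data frame with `trna` column),
#'   `pooled` (named list of `cor_result`), `means` (the per-family
#'   means analyses plus the mean table).
#' @export
run_contrast_correlations <- function(config) {
  stopifnot(inherits(config, "mt_config"))
  if (is.null(config$tree)) stop("config has no tree")
  tree <- config$tree
  missing <- setdiff(names(config$records), tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  mats <- .usage_distance_matrices(config$records)
  labels <- trna_labels()

  subset_records <- function(taxa) {
    m <- list(log_usage = mats$log_usage[taxa, , drop = FALSE],
              log_distance = mats$log_distance[taxa, , drop = FALSE])
    m
  }
  group_sets <- list(all = names(config$records))
  if (!is.null(config$groups)) {
    group_sets$stable <-
      names(config$records)[config$groups[names(config$records)] == "stable"]
    group_sets$rearranged <-
      names(config$records)[config$groups[names(config$records)] == "rearranged"]
  }
  if (length(config$exclude_taxa))
    group_sets$excluding_taxa <-
      setdiff(names(config$records), config$exclude_taxa)

  pooled <- list(); all_pairs <- list()
  for (g in names(group_sets)) {
    taxa <- group_sets[[g]]
    if (length(taxa) < 4L) next
    m <- subset_records(taxa)
    sub_tree <- ape::keep.tip(tree, intersect(tree$tip.label, taxa))
    fams <- lapply(labels, function(f)
      .family_contrasts(sub_tree, m$log_usage, m$log_distance, f))
    pairs <- do.call(rbind, fams)
    if (is.null(pairs) || nrow(pairs) < 3L) next
    all_pairs[[g]] <- pairs
    pooled[[g]] <- contrast_correlation(pairs, tail = config$tail)
    if (length(config$exclude_trnas)) {
      kept <- pairs[!pairs$trna %in% config$exclude_trnas, , drop = FALSE]
      if (nrow(kept) >= 3L)
        pooled[[paste0(g, "_excl_outlier_trnas")]] <-
          contrast_correlation(kept, tail = config$tail)
    }
  }

  mean_u <- colMeans(mats$log_usage, na.rm = TRUE)
  mean_d <- colMeans(mats$log_distance, na.rm = TRUE)
  means <- list(table = data.frame(trna = labels,
                                   mean_log_usage = unname(mean_u[labels]),
                                   mean_log_distance = unname(mean_d[labels])),
                all = pearson_one_tailed(mean_u, mean_d,
                                         tail = config$tail))
  keep <- setdiff(labels, config$exclude_trnas)
  if (length(keep) >= 3L)
    means$excl_outlier_trnas <-
      pearson_one_tailed(mean_u[keep], mean_d[keep], tail = config$tail)

  list(contrasts = all_pairs, pooled = pooled, means = means)
}

#' Per-family meta-analysis of contrast correlations
#'
#' Correlates each tRNA family's contrasts separately and combines the
#' 22 family results with [combine_correlations()] (weighted Fisher r,
#' unweighted Stouffer Z).
#'
#' @param config An `mt_config`.
#' @return List: `per_family` (data frame) and `meta` (`meta_result`).
#' @export
run_meta <- function(config) {
  stopifnot(inherits(config, "mt_config"))
  mats <- .usage_distance_matrices(config$records)
  rows <- list()
  for (f in trna_labels()) {
    cp <- .family_contrasts(config$tree, mats$log_usage,
                            mats$log_distance, f)
    if (is.null(cp) || nrow(cp) < 3L) next
    res <- tryCatch(contrast_correlation(cp, tail = config$tail),
                    error = function(e) NULL)
    if (is.null(res)) next
    rows[[f]] <- data.frame(label = f, r = res$r, n = res$n,
                            p_one_tailed = res$p_one_tailed,
                            stringsAsFactors = FALSE)
  }
  if (length(rows) < 2L)
    stop("fewer than 2 tRNA families with usable contrasts")
  per_family <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(per_family = per_family,
       meta = combine_correlations(per_family))
}

#' Deamination analysis of one genome
#'
#' Exposure table and exposure-vs-G+T correlations (between-origins
#' group and all tRNAs) under both anticodon conventions.
#'
#' @param rec An `mt_genome` with a locatable L-strand origin.
#' @return List: per convention, the exposure table and the two
#'   `cor_result`s.
#' @export
run_deamination <- function(rec) {
  map <- replication_map(rec)
  out <- list()
  for (conv in c("codon12_pairing", "first_two_5to3")) {
    tab <- exposure_durations(rec, map, convention = conv)
    out[[conv]] <- list(
      table = tab,
      between_origins = exposure_gt_correlation(tab, "between_origins_only"),
      all = exposure_gt_correlation(tab, "all"))
  }
  out$map <- map
  out
}

.cor_row <- function(x) {
  c(r = x$r, n = x$n, df = x$df, t = x$t, p_one_tailed = x$p_one_tailed)
}

#' Run the full pipeline
#'
#' Chains the hydropathy test, offset sensitivity, contrast
#' correlations, the per-family meta-analysis and the deamination
#' analysis, optionally writing TSV tables and a JSON summary. With a
#' fixed-seed synthetic cohort the outputs are bit-reproducible.
#'
#' @param config An `mt_config`.
#' @param outdir Optional output directory for TSV/JSON files.
#' @param stages Character subset of
#'   `c("hydropathy", "offsets", "contrasts", "meta", "deamination")`.
#' @return Named list of stage results (invisible when `outdir` given).
#' @export
run_pipeline <- function(config, outdir = NULL,
                         stages = c("hydropathy", "offsets", "contrasts",
                                    "meta", "deamination")) {
  stopifnot(inherits(config, "mt_config"))
  res <- list()
  if ("hydropathy" %in% stages)
    res$hydropathy <- run_hydropathy_test(config)
  if ("offsets" %in% stages)
    res$offsets <- lapply(config$records, offset_sensitivity,
                          offsets = config$offsets)
  if ("contrasts" %in% stages)
    res$contrasts <- run_contrast_correlations(config)
  if ("meta" %in% stages)
    res$meta <- run_meta(config)
  if ("deamination" %in% stages)
    res$deamination <- lapply(config$records, function(rec)
      tryCatch(run_deamination(rec), error = function(e) {
        warning("deamination analysis skipped for ", rec$accession,
                ": ", conditionMessage(e))
        NULL
      }))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(res$hydropathy$tests))
      utils::write.table(res$hydropathy$tests,
                         file.path(outdir, "hydropathy_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$contrasts)) {
      pooled <- do.call(rbind, lapply(names(res$contrasts$pooled),
        function(g) data.frame(analysis = g,
                               t(.cor_row(res$contrasts$pooled[[g]])))))
      utils::write.table(pooled, file.path(outdir, "pooled_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$meta))
      utils::write.table(res$meta$per_family,
                         file.path(outdir, "per_family_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- list()
    if (!is.null(res$hydropathy$tests))
      summary$hydropathy <- res$hydropathy$tests
    if (!is.null(res$contrasts))
      summary$pooled <- lapply(res$contrasts$pooled, .cor_row)
    if (!is.null(res$meta))
      summary$meta <- list(r_weighted = res$meta$meta$r_weighted,
                           Z_stouffer = res$meta$meta$Z_stouffer,
                           p_combined = res$meta$meta$p_combined,
                           k = res$meta$meta$k)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}
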