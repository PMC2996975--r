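## Phylogenetically independent contrasts for two variables on a rooted
## binary tree, the comparative engine behind the usage-vs-position
## correlations. Implements the classic pruning recursion: at an
## internal node with daughter values x_i, x_j on (tie-adjusted) branch
## lengths b_i, b_j, the standardized contrast is
## (x_i - x_j) / sqrt(b_i + b_j), the nodal estimate is the
## branch-length-weighted mean, and the parent branch is lengthened by
## b_i b_j / (b_i + b_j).

#' Log-transform tip values
#'
#' Elementwise log10, with an optional pseudocount substituted for
#' zeros so that zero-usage families stay in the analysis. Values that
#' are negative, or zero without a pseudocount, are an error.
#'
#' @param values Named numeric vector (species -> positive value).
#' @param pseudocount Optional replacement for exact zeros.
#' @return Named numeric vector of log10 values, with attribute
#'   `n_pseudocount` giving the number of substituted zeros.
#' @export
log_transform <- function(values, pseudocount = NULL) {
  if (any(values < 0)) stop("negative values cannot be log-transformed")
  zero <- values == 0
  if (any(zero)) {
    if (is.null(pseudocount))
      stop(sum(zero), " zero value(s); supply a pseudocount")
    values[zero] <- pseudocount
  }
  out <- log10(values)
  attr(out, "n_pseudocount") <- sum(zero)
  out
}

# Binary rooted check that tolerates trees read without branch lengths.
.check_binary <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  tab <- tabulate(tree$edge[, 1])
  if (any(tab[tab > 0] != 2L))
    stop("tree has polytomies (or unifurcations); resolve them before ",
         "computing contrasts")
}

#' Independent contrasts for two variables
#'
#' @param tree Rooted binary `phylo` tree. Missing branch lengths
#'   default to 1 (the convention for composite literature trees
#'   without rate estimates).
#' @param x,y Named numeric vectors of tip values; names must match the
#'   tip labels exactly (any order).
#' @return Data frame with one row per internal node: `node`,
#'   `contrast_x`, `contrast_y` (standardized), and `sd` (the square
#'   root of the summed adjusted branch lengths used to standardize).
#'   Pairs are sign-oriented so `contrast_x >= 0`, with `contrast_y`
#'   negated accordingly.
#' @export
independent_contrasts <- function(tree, x, y) {
  .check_binary(tree)
  tips <- tree$tip.label
  for (v in list(x = x, y = y)) {
    if (is.null(names(v))) stop("tip values must be named")
  }
  dx <- setdiff(tips, names(x)); ex <- setdiff(names(x), tips)
  dy <- setdiff(tips, names(y)); ey <- setdiff(names(y), tips)
  if (length(c(dx, ex, dy, ey)))
    stop("tip labels and value names differ: missing [",
         paste(unique(c(dx, dy)), collapse = ", "), "], extra [",
         paste(unique(c(ex, ey)), collapse = ", "), "]")
  ntip <- length(tips)
  nnode <- tree$Nnode
  bl <- tree$edge.length
  if (is.null(bl)) bl <- rep(1, nrow(tree$edge))
  if (any(bl <= 0)) stop("branch lengths must be positive")

  nv_x <- c(unname(x[tips]), rep(NA_real_, nnode))
  nv_y <- c(unname(y[tips]), rep(NA_real_, nnode))
  blen <- rep(NA_real_, ntip + nnode)
  blen[tree$edge[, 2]] <- bl

  ord <- ape::reorder.phylo(tree, "postorder")
  res <- matrix(NA_real_, nrow = nnode, ncol = 4,
                dimnames = list(NULL, c("node", "contrast_x",
                                        "contrast_y", "sd")))
  row <- 0L
  e <- ord$edge
  for (i in seq(1, nrow(e), by = 2)) {
    node <- e[i, 1]
    if (e[i + 1, 1] != node)
      stop("internal error: postorder edges not paired at node ", node)
    ch <- e[c(i, i + 1), 2]
    b <- blen[ch]
    s <- sqrt(sum(b))
    cx <- (nv_x[ch[1]] - nv_x[ch[2]]) / s
    cy <- (nv_y[ch[1]] - nv_y[ch[2]]) / s
    if (cx < 0 || (cx == 0 && cy < 0)) { cx <- -cx; cy <- -cy }
    row <- row + 1L
    res[row, ] <- c(node, cx, cy, s)
    w <- 1 / b
    nv_x[node] <- sum(w * nv_x[ch]) / sum(w)
    nv_y[node] <- sum(w * nv_y[ch]) / sum(w)
    blen[node] <- blen[node] + prod(b) / sum(b)  # NA at root stays NA
    if (is.na(blen[node]) && node != ntip + 1L)
      stop("internal error: missing branch length above node ", node)
  }
  as.data.frame(res)
}

#' Correlate contrast pairs
#'
#' Through-origin correlation of standardized contrasts (contrasts have
#' zero expectation and arbitrary sign, so no intercept is fitted and
#' the degrees of freedom are n - 1). In pooled mode the caller
#' concatenates pairs across tRNA families before calling; per-family
#' results feed [combine_correlations()].
#'
#' @param pairs Data frame from [independent_contrasts()] (or any frame
#'   with `contrast_x`, `contrast_y`), or a concatenation of several.
#' @param method `"pearson_through_origin"` (default) or `"spearman"`
#'   (midranked, ordinary correlation -- a robustness check only).
#' @param tail Predicted direction of the correlation.
#' @return A `cor_result`.
#' @export
contrast_correlation <- function(pairs,
                                 method = c("pearson_through_origin",
                                            "spearman"),
                                 tail = c("negative", "positive")) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  if (nrow(pairs) < 3L) stop("need at least 3 contrast pairs")
  if (method == "pearson_through_origin")
    origin_correlation(pairs$contrast_x, pairs$contrast_y, tail)
  else
    spearman_one_tailed(pairs$contrast_x, pairs$contrast_y, tail)
}
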