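#' Neighbor-joining tree for one window
#'
#' Builds a tree over individuals from the matrix of pairwise genotype
#' distances (expected allele mismatch per jointly genotyped site, see
#' [pair_distance()]) by neighbor joining, clamps any negative branch
#' lengths to zero, and roots the tree on the individuals of the declared
#' outgroup taxon.
#'
#' @param gm a [genotype_matrix()].
#' @param window one-row window data frame (0-based half-open).
#' @param outgroup outgroup taxon label whose individuals root the tree;
#'   `NULL` for an unrooted tree.
#' @param min_genotyped per-site minimum genotyped individuals over the
#'   whole sample (default 1: any genotyped site contributes).
#' @return An [ape::phylo] object, or `NULL` (with a warning) when some
#'   pair of individuals shares no genotyped site in the window.
#' @export
window_tree <- function(gm, window, outgroup = NULL, min_genotyped = 1) {
  ind <- names(gm$taxon_map)
  if (length(ind) < 4) stop("need at least 4 individuals with data")
  sites <- gm_window_sites(gm, window$chrom, window$start, window$end)
  D <- gm$gt[sites, ind, drop = FALSE]
  n_geno <- rowSums(!is.na(D))
  D <- D[n_geno >= min_genotyped, , drop = FALSE]
  mm <- mismatch_matrices(D)
  if (any(mm$J[upper.tri(mm$J)] == 0)) {
    warning("window ", window$chrom, ":", window$start, "-", window$end,
            " skipped: a pair of individuals shares no genotyped site")
    return(NULL)
  }
  dist_mat <- mm$M / mm$J
  diag(dist_mat) <- 0
  dimnames(dist_mat) <- list(ind, ind)
  tr <- ape::nj(as.dist(dist_mat))
  tr$edge.length[tr$edge.length < 0] <- 0
  if (!is.null(outgroup)) tr <- root_on_outgroup(tr, gm_individuals(gm, outgroup))
  tr
}

# Root on the outgroup individuals; if they are not monophyletic in the
# unrooted tree, fall back to rooting on the first outgroup tip and flag.
root_on_outgroup <- function(tr, out_tips) {
  out_tips <- intersect(out_tips, tr$tip.label)
  if (!length(out_tips)) stop("no outgroup tips present in tree")
  if (length(out_tips) == 1 || ape::is.monophyletic(tr, out_tips)) {
    ape::root(tr, outgroup = out_tips, resolve.root = TRUE)
  } else {
    rooted <- ape::root(tr, outgroup = out_tips[1], resolve.root = TRUE)
    attr(rooted, "outgroup_nonmonophyletic") <- TRUE
    rooted
  }
}

#' Concordance between a window tree and the genome tree
#'
#' Pearson correlation of the lower triangles of the two tip-to-tip
#' patristic (cophenetic) distance matrices, aligned on tip labels. A
#' value of 1 means identical shapes up to a linear rescaling of branch
#' lengths; lower values indicate increasing topological or branch-length
#' discordance.
#'
#' @param window_tree,genome_tree [ape::phylo] trees over identical tip
#'   sets.
#' @return Correlation in `[-1, 1]`, or `NA` when either distance matrix
#'   has zero variance (e.g. a star tree).
#' @export
concordance_score <- function(window_tree, genome_tree) {
  if (!setequal(window_tree$tip.label, genome_tree$tip.label)) {
    stop("tip sets differ between window tree and genome tree")
  }
  dw <- ape::cophenetic.phylo(window_tree)
  dg <- ape::cophenetic.phylo(genome_tree)
  dg <- dg[rownames(dw), colnames(dw)]
  lw <- dw[lower.tri(dw)]
  lg <- dg[lower.tri(dg)]
  if (sd(lw) == 0 || sd(lg) == 0) return(NA_real_)
  cor(lw, lg)
}

#' Clade recovery fraction over a set of window trees
#'
#' Fraction of window trees (rooted on the outgroup) in which the given
#' set of tips is monophyletic — how often a node of the genome-wide tree
#' is recovered along the genome.
#'
#' @param tree_set list of rooted [ape::phylo] trees (`NULL` entries, from
#'   skipped windows, are ignored).
#' @param clade character vector of at least two tip labels; must not
#'   contain outgroup tips.
#' @param outgroup_tips optional character vector of outgroup tip labels
#'   used to validate `clade`.
#' @return Named numeric `c(fraction, n_trees)`.
#' @export
clade_recovery <- function(tree_set, clade, outgroup_tips = NULL) {
  if (length(clade) < 2) stop("clade must contain at least 2 tips")
  if (!is.null(outgroup_tips) && length(intersect(clade, outgroup_tips))) {
    stop("clade must not contain outgroup tips")
  }
  tree_set <- Filter(Negate(is.null), tree_set)
  if (!length(tree_set)) stop("no trees in set")
  hits <- vapply(tree_set, function(tr) {
    if (!all(clade %in% tr$tip.label)) stop("clade tip absent from a tree")
    ape::is.monophyletic(tr, clade)
  }, logical(1))
  c(fraction = mean(hits), n_trees = length(tree_set))
}

#' Concordance scores for every window
#'
#' Convenience wrapper building one neighbor-joining tree per window and
#' scoring each against the genome tree.
#'
#' @inheritParams window_tree
#' @param windows data frame from [make_windows()].
#' @param genome_tree reference tree over the same individuals.
#' @return `windows` with columns `score` and a list-column-free parallel
#'   list of trees in `attr(, "trees")`.
#' @export
window_concordance <- function(gm, windows, genome_tree, outgroup = NULL) {
  trees <- lapply(seq_len(nrow(windows)), function(i) {
    window_tree(gm, windows[i, ], outgroup = outgroup)
  })
  windows$score <- vapply(trees, function(tr) {
    if (is.null(tr)) NA_real_ else concordance_score(tr, genome_tree)
  }, numeric(1))
  attr(windows, "trees") <- trees
  windows
}
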