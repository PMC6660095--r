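#' Diploid genotype matrix with taxon assignments
#'
#' The central container for multi-sample genotype data: an ordered set of
#' sites (variant and invariant) on one or more contigs, with one diploid
#' genotype per site and individual, stored as the count of alternate
#' alleles (0, 1, 2) or `NA` for missing. Invariant sites carry `NA` in
#' `alt` and dosage 0 wherever genotyped. Only biallelic or invariant sites
#' are admitted, so the dosage encoding is lossless up to phase, which none
#' of the statistics in this package use.
#'
#' @param chrom character vector of contig identifiers, one per site.
#' @param pos integer vector of 1-based site positions, strictly increasing
#'   within each contig.
#' @param ref,alt character vectors of reference/alternate alleles; `alt`
#'   is `NA` at invariant sites.
#' @param gt integer matrix, sites x individuals, of alternate-allele
#'   dosages (0/1/2) with `NA` for missing calls. Column names are the
#'   individual identifiers.
#' @param taxon_map named character vector mapping every individual (names)
#'   to its taxon label (values).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, gt, taxon_map) {
  if (!is.matrix(gt)) stop("`gt` must be a matrix")
  storage.mode(gt) <- "integer"
  n_sites <- nrow(gt)
  individuals <- colnames(gt)
  if (is.null(individuals)) stop("`gt` must have individual ids as colnames")
  stopifnot(
    length(chrom) == n_sites, length(pos) == n_sites,
    length(ref) == n_sites, length(alt) == n_sites
  )
  if (anyDuplicated(individuals)) stop("duplicated individual ids")
  missing_map <- setdiff(individuals, names(taxon_map))
  if (length(missing_map)) {
    stop("individuals absent from taxon map: ", paste(missing_map, collapse = ", "))
  }
  for (ctg in unique(chrom)) {
    p <- pos[chrom == ctg]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions not strictly increasing on contig ", ctg)
    }
  }
  bad <- gt[!is.na(gt)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  structure(
    list(
      chrom = as.character(chrom), pos = as.integer(pos),
      ref = as.character(ref), alt = as.character(alt),
      gt = gt, individuals = individuals,
      taxon_map = taxon_map[individuals]
    ),
    class = "genotype_matrix"
  )
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  n_var <- sum(!is.na(x$alt))
  cat(sprintf(
    "genotype_matrix: %d sites (%d variant) x %d individuals, %d taxa, %d contig(s)\n",
    nrow(x$gt), n_var, ncol(x$gt), length(unique(x$taxon_map)),
    length(unique(x$chrom))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$gt)

#' Subset a genotype matrix by site index
#'
#' @param gm a [genotype_matrix()].
#' @param idx logical or integer site index.
#' @return A `genotype_matrix` restricted to the selected sites.
#' @export
gm_subset_sites <- function(gm, idx) {
  gm$chrom <- gm$chrom[idx]
  gm$pos <- gm$pos[idx]
  gm$ref <- gm$ref[idx]
  gm$alt <- gm$alt[idx]
  gm$gt <- gm$gt[idx, , drop = FALSE]
  gm
}

#' Taxa represented in a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return Character vector of taxon labels, in order of first appearance.
#' @export
gm_taxa <- function(gm) unique(unname(gm$taxon_map))

#' Individuals belonging to a taxon
#' @param gm a [genotype_matrix()].
#' @param taxon a taxon label present in the taxon map.
#' @return Character vector of individual ids.
#' @export
gm_individuals <- function(gm, taxon) {
  out <- names(gm$taxon_map)[gm$taxon_map == taxon]
  if (!length(out)) stop("no individuals for taxon ", taxon)
  out
}

# site index of gm falling in window [start, end) (0-based half-open)
gm_window_sites <- function(gm, chrom, start, end) {
  which(gm$chrom == chrom & gm$pos - 1L >= start & gm$pos - 1L < end)
}
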