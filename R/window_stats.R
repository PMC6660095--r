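#' Expected allele mismatch between two diploid genotype vectors
#'
#' The distance between two diploid genotypes at one site is the expected
#' mismatch when one allele is drawn at random from each individual:
#' identical homozygotes score 0, opposite homozygotes 1, and any
#' comparison involving a heterozygote 0.5. Sites where either call is
#' missing are excluded from both numerator and denominator, which is the
#' per-pair missing-data correction used throughout this package.
#'
#' @param calls_i,calls_j equal-length integer vectors of alternate-allele
#'   dosages (0/1/2, `NA` missing) over the sites of one window.
#' @return Named numeric vector `c(mismatch, joint)`: the summed expected
#'   mismatch and the number of jointly genotyped sites. `(0, 0)` when no
#'   site is jointly genotyped.
#' @export
pair_distance <- function(calls_i, calls_j) {
  stopifnot(length(calls_i) == length(calls_j))
  ok <- !is.na(calls_i) & !is.na(calls_j)
  pi_ <- calls_i[ok] / 2
  pj <- calls_j[ok] / 2
  c(mismatch = sum(pi_ * (1 - pj) + pj * (1 - pi_)), joint = sum(ok))
}

# Pairwise mismatch/joint-site matrices for a dosage matrix D (sites x ind).
# M[i, j] = summed expected allele mismatch between individuals i and j over
# jointly genotyped sites, J[i, j] = count of such sites. One crossprod each.
mismatch_matrices <- function(D) {
  G <- !is.na(D)
  storage.mode(G) <- "double"
  Q <- D / 2
  Q[is.na(Q)] <- 0
  QG <- crossprod(Q, G)
  M <- QG + t(QG) - 2 * crossprod(Q)
  J <- crossprod(G)
  list(M = M, J = J)
}

# Mean pairwise distance over a set of (i, j) index pairs, each pair's
# distance being mismatch / joint sites; pairs with no joint sites dropped.
# `total_sites`, when given, overrides the per-pair denominator (complete
# data whose invariant sites are not stored explicitly, e.g. simulator
# output where every bp of the window is genotyped).
mean_pair_ratio <- function(M, J, pairs, total_sites = NULL) {
  m <- M[pairs]
  j <- if (is.null(total_sites)) J[pairs] else rep(total_sites, nrow(pairs))
  ok <- j > 0
  if (!any(ok)) return(c(value = NA_real_, n_pairs = 0))
  c(value = mean(m[ok] / j[ok]), n_pairs = sum(ok))
}

within_pairs <- function(idx) {
  if (length(idx) < 2) return(matrix(integer(0), ncol = 2))
  t(combn(idx, 2))
}

between_pairs <- function(idx_a, idx_b) {
  as.matrix(expand.grid(idx_a, idx_b))
}

# Restrict a window's dosage matrix to sites passing the per-taxon
# genotyping filter. `min_by_taxon`: named vector of minimum genotyped
# individuals per taxon (only the taxa named are checked).
filter_sites <- function(D, taxon_of_col, min_by_taxon) {
  keep <- rep(TRUE, nrow(D))
  for (tx in names(min_by_taxon)) {
    cols <- which(taxon_of_col == tx)
    n_geno <- rowSums(!is.na(D[, cols, drop = FALSE]))
    keep <- keep & n_geno >= min_by_taxon[[tx]]
  }
  D[keep, , drop = FALSE]
}

#' Nucleotide diversity in one window
#'
#' Mean over all unordered pairs of distinct individuals of a taxon of the
#' per-pair mismatch ratio (expected allele mismatches divided by jointly
#' genotyped sites, variant and invariant). Sites genotyped in fewer than
#' `min_genotyped` individuals of the taxon are excluded first; pairs
#' sharing no genotyped site are dropped from the mean.
#'
#' @param gm a [genotype_matrix()].
#' @param taxon taxon label.
#' @param window one-row data frame (`chrom`, `start`, `end`, 0-based
#'   half-open), e.g. a row of [make_windows()].
#' @param min_genotyped per-site minimum number of genotyped individuals in
#'   the taxon (default 3).
#' @return Named numeric `c(pi, n_sites)`; `pi` is `NA` when fewer than two
#'   individuals have data.
#' @export
pi_window <- function(gm, taxon, window, min_genotyped = 3) {
  ind <- gm_individuals(gm, taxon)
  sites <- gm_window_sites(gm, window$chrom, window$start, window$end)
  D <- gm$gt[sites, ind, drop = FALSE]
  D <- filter_sites(D, gm$taxon_map[ind], setNames(min_genotyped, taxon))
  if (length(ind) < 2) return(c(pi = NA_real_, n_sites = nrow(D)))
  mm <- mismatch_matrices(D)
  r <- mean_pair_ratio(mm$M, mm$J, within_pairs(seq_along(ind)))
  c(pi = unname(r["value"]), n_sites = nrow(D))
}

#' Absolute divergence between two taxa in one window
#'
#' Mean over all between-taxon pairs of individuals of the per-pair
#' mismatch ratio. Sites must be genotyped in at least `min_genotyped[a]`
#' individuals of taxon a and `min_genotyped[b]` of taxon b.
#'
#' @inheritParams pi_window
#' @param taxon_a,taxon_b taxon labels.
#' @param min_genotyped length-1 or length-2 per-taxon site filter.
#' @return Named numeric `c(dxy, n_sites)`.
#' @export
dxy_window <- function(gm, taxon_a, taxon_b, window, min_genotyped = 3) {
  ind_a <- gm_individuals(gm, taxon_a)
  ind_b <- gm_individuals(gm, taxon_b)
  min2 <- rep_len(min_genotyped, 2)
  sites <- gm_window_sites(gm, window$chrom, window$start, window$end)
  D <- gm$gt[sites, c(ind_a, ind_b), drop = FALSE]
  D <- filter_sites(D, gm$taxon_map[c(ind_a, ind_b)],
                    setNames(min2, c(taxon_a, taxon_b)))
  mm <- mismatch_matrices(D)
  pairs <- between_pairs(seq_along(ind_a), length(ind_a) + seq_along(ind_b))
  r <- mean_pair_ratio(mm$M, mm$J, pairs)
  c(dxy = unname(r["value"]), n_sites = nrow(D))
}

#' Kst-family differentiation between two taxa in one window
#'
#' `Fst = 1 - Ks / Kt`, where `Ks` is the mean within-taxon pairwise
#' distance pooled over both taxa (equivalently, the weighted mean of the
#' two taxon means with weights proportional to their pair counts) and
#' `Kt` the mean pairwise distance over all pairs in the pooled sample.
#' Every pairwise distance uses the per-pair missing-data denominator of
#' [pair_distance()]. On complete data from well-differentiated taxa the
#' value is close to the Hudson form `1 - mean(pi) / dxy`.
#'
#' @inheritParams dxy_window
#' @param total_sites optional scalar overriding the per-pair denominators
#'   (complete-data fast path; see [run_scenario()]).
#' @return Named numeric `c(fst, n_sites)`; `NA` when the pooled sample has
#'   no variation (`Kt = 0`).
#' @export
fst_window <- function(gm, taxon_a, taxon_b, window, min_genotyped = 3,
                       total_sites = NULL) {
  ind_a <- gm_individuals(gm, taxon_a)
  ind_b <- gm_individuals(gm, taxon_b)
  min2 <- rep_len(min_genotyped, 2)
  sites <- gm_window_sites(gm, window$chrom, window$start, window$end)
  D <- gm$gt[sites, c(ind_a, ind_b), drop = FALSE]
  if (is.null(total_sites)) {
    D <- filter_sites(D, gm$taxon_map[c(ind_a, ind_b)],
                      setNames(min2, c(taxon_a, taxon_b)))
  }
  kst_from_matrices(mismatch_matrices(D), length(ind_a), length(ind_b),
                    n_sites = nrow(D), total_sites = total_sites)
}

# Kst combination shared by the VCF path and the simulator fast path.
kst_from_matrices <- function(mm, n_a, n_b, n_sites, total_sites = NULL) {
  ia <- seq_len(n_a)
  ib <- n_a + seq_len(n_b)
  pw <- rbind(within_pairs(ia), within_pairs(ib))
  pt <- rbind(pw, between_pairs(ia, ib))
  ks <- mean_pair_ratio(mm$M, mm$J, pw, total_sites)
  kt <- mean_pair_ratio(mm$M, mm$J, pt, total_sites)
  # Ks as implemented is the pooled mean over all valid within-taxon pairs,
  # i.e. taxon means weighted by their (valid) pair counts.
  if (is.na(kt["value"]) || kt["value"] == 0) {
    return(c(fst = NA_real_, n_sites = n_sites))
  }
  c(fst = unname(1 - ks["value"] / kt["value"]), n_sites = n_sites)
}

#' Net divergence between two taxa
#'
#' `da = dxy - (pi_a + pi_b) / 2`, computed from genome-wide means taken
#' over a common window set. Net divergence corrects `dxy` for the
#' variation already present in the common ancestor and is used as a proxy
#' for time since the population split.
#'
#' @param dxy_mean genome-wide mean `dxy` of the pair.
#' @param pi_a,pi_b genome-wide mean diversity of each taxon.
#' @return `da` (may be slightly negative for very recent splits).
#' @export
da_pair <- function(dxy_mean, pi_a, pi_b) {
  dxy_mean - (pi_a + pi_b) / 2
}

#' Z-transform a landscape
#'
#' Centers and scales a window series to mean 0, SD 1 over its non-missing
#' windows, so that landscapes of different magnitude can be compared and
#' summarized jointly. By convention the population (divide-by-n) SD is
#' used: this is a normalization, not an inference.
#'
#' @param x numeric window series (may contain `NA`).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @param label series name used in error messages.
#' @return `x` standardized; `NA`s propagated.
#' @export
z_transform <- function(x, sd_type = c("population", "sample"), label = "series") {
  sd_type <- match.arg(sd_type)
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("fewer than 2 non-missing values in ", label)
  n <- sum(ok)
  s <- sd(x[ok])
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  if (!is.finite(s) || s == 0) stop("zero standard deviation in ", label)
  (x - mean(x[ok])) / s
}

#' Window statistics for all taxa and taxon pairs
#'
#' Computes per-window nucleotide diversity for every taxon and `dxy`/`Fst`
#' for every unordered taxon pair, applying the per-site genotyping filter
#' independently for each comparison (a lower threshold is used for
#' comparisons involving the outgroup, whose sample size is typically
#' smaller).
#'
#' @param gm a [genotype_matrix()].
#' @param windows data frame from [make_windows()].
#' @param min_genotyped per-site minimum genotyped individuals per taxon
#'   (default 3).
#' @param outgroup optional outgroup taxon label.
#' @param min_genotyped_outgroup filter applied to the outgroup taxon in
#'   comparisons that involve it (default 2).
#' @return List with `windows` and window-by-variable matrices `pi`
#'   (columns taxa), `dxy` and `fst` (columns `"a|b"` pairs).
#' @export
window_statistics <- function(gm, windows, min_genotyped = 3, outgroup = NULL,
                              min_genotyped_outgroup = 2) {
  taxa <- gm_taxa(gm)
  prs <- t(combn(taxa, 2))
  pair_names <- paste(prs[, 1], prs[, 2], sep = "|")
  min_of <- function(tx) {
    if (!is.null(outgroup) && tx == outgroup) min_genotyped_outgroup else min_genotyped
  }
  W <- nrow(windows)
  pi_mat <- matrix(NA_real_, W, length(taxa), dimnames = list(NULL, taxa))
  dxy_mat <- matrix(NA_real_, W, nrow(prs), dimnames = list(NULL, pair_names))
  fst_mat <- dxy_mat
  for (w in seq_len(W)) {
    win <- windows[w, ]
    for (tx in taxa) {
      pi_mat[w, tx] <- pi_window(gm, tx, win, min_genotyped = min_of(tx))["pi"]
    }
    for (p in seq_len(nrow(prs))) {
      a <- prs[p, 1]; b <- prs[p, 2]
      mg <- c(min_of(a), min_of(b))
      dxy_mat[w, p] <- dxy_window(gm, a, b, win, min_genotyped = mg)["dxy"]
      fst_mat[w, p] <- fst_window(gm, a, b, win, min_genotyped = mg)["fst"]
    }
  }
  list(windows = windows, pi = pi_mat, dxy = dxy_mat, fst = fst_mat,
       pairs = data.frame(a = prs[, 1], b = prs[, 2], name = pair_names))
}
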