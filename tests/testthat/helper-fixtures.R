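# Shared fixtures and independent oracles for the statistic kernels.

# Build a genotype_matrix from a dosage matrix (sites x individuals).
make_gm <- function(gt, taxon_map, chrom = "chr1", pos = NULL,
                    alt = NULL) {
  storage.mode(gt) <- "integer"
  n <- nrow(gt)
  if (is.null(pos)) pos <- seq_len(n)
  if (is.null(alt)) {
    # invariant where every genotyped call is homozygous reference
    variant <- apply(gt, 1, function(r) any(r > 0, na.rm = TRUE))
    alt <- ifelse(variant, "T", NA_character_)
  }
  genotype_matrix(chrom = rep(chrom, n), pos = pos,
                  ref = rep("A", n), alt = alt, gt = gt,
                  taxon_map = taxon_map)
}

window_all <- function(gm) {
  data.frame(chrom = gm$chrom[1], start = 0, end = max(gm$pos))
}

# --- independent direct-enumeration oracles ------------------------------
# Diploid pair distance by exhaustive enumeration of the 4 allele pairings
# per site (dosage -> explicit allele pair), nothing shared with the
# package's crossprod kernel.
oracle_pair <- function(g1, g2) {
  alleles <- function(d) switch(as.character(d), "0" = c(0, 0),
                                "1" = c(0, 1), "2" = c(1, 1))
  mm <- 0
  joint <- 0
  for (s in seq_along(g1)) {
    if (is.na(g1[s]) || is.na(g2[s])) next
    a <- alleles(g1[s])
    b <- alleles(g2[s])
    mm <- mm + mean(outer(a, b, "!="))
    joint <- joint + 1
  }
  c(mismatch = mm, joint = joint)
}

oracle_sites_pass <- function(D, taxon_of_col, mins) {
  keep <- rep(TRUE, nrow(D))
  for (tx in names(mins)) {
    cols <- taxon_of_col == tx
    keep <- keep & rowSums(!is.na(D[, cols, drop = FALSE])) >= mins[[tx]]
  }
  keep
}

oracle_mean_pairs <- function(D, pairs) {
  vals <- apply(pairs, 1, function(p) {
    r <- oracle_pair(D[, p[1]], D[, p[2]])
    if (r["joint"] == 0) return(NA_real_)
    r["mismatch"] / r["joint"]
  })
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

oracle_pi <- function(gm, taxon, min_genotyped) {
  ind <- names(gm$taxon_map)[gm$taxon_map == taxon]
  D <- gm$gt[, ind, drop = FALSE]
  D <- D[oracle_sites_pass(D, gm$taxon_map[ind],
                           setNames(min_genotyped, taxon)), , drop = FALSE]
  oracle_mean_pairs(D, t(combn(seq_along(ind), 2)))
}

oracle_dxy <- function(gm, ta, tb, min_genotyped) {
  ia <- names(gm$taxon_map)[gm$taxon_map == ta]
  ib <- names(gm$taxon_map)[gm$taxon_map == tb]
  D <- gm$gt[, c(ia, ib), drop = FALSE]
  D <- D[oracle_sites_pass(D, gm$taxon_map[c(ia, ib)],
                           setNames(rep(min_genotyped, 2), c(ta, tb))), ,
         drop = FALSE]
  oracle_mean_pairs(D, as.matrix(expand.grid(seq_along(ia),
                                             length(ia) + seq_along(ib))))
}

oracle_fst <- function(gm, ta, tb, min_genotyped) {
  ia <- names(gm$taxon_map)[gm$taxon_map == ta]
  ib <- names(gm$taxon_map)[gm$taxon_map == tb]
  D <- gm$gt[, c(ia, ib), drop = FALSE]
  D <- D[oracle_sites_pass(D, gm$taxon_map[c(ia, ib)],
                           setNames(rep(min_genotyped, 2), c(ta, tb))), ,
         drop = FALSE]
  na <- length(ia); nb <- length(ib)
  pw <- rbind(t(combn(seq_len(na), 2)), t(combn(na + seq_len(nb), 2)))
  pt <- rbind(pw, as.matrix(expand.grid(seq_len(na), na + seq_len(nb))))
  ks <- oracle_mean_pairs(D, pw)
  kt <- oracle_mean_pairs(D, pt)
  if (is.na(kt) || kt == 0) return(NA_real_)
  1 - ks / kt
}

# Random genotype matrix: two taxa, biallelic + invariant sites, missing.
random_gm <- function(n_sites, n_a, n_b, miss, seed) {
  set.seed(seed)
  n <- n_a + n_b
  p <- runif(n_sites, 0.1, 0.9)
  gt <- sapply(seq_len(n), function(i) rbinom(n_sites, 2, p))
  gt[runif(length(gt)) < miss] <- NA
  gt <- matrix(as.integer(gt), n_sites, n,
               dimnames = list(NULL, c(paste0("a", seq_len(n_a)),
                                       paste0("b", seq_len(n_b)))))
  make_gm(gt, setNames(rep(c("ta", "tb"), c(n_a, n_b)), colnames(gt)))
}

# Polarized-frequency table from explicit columns (for D-statistic tests).
make_freqs <- function(p1, p2, p3, pos = NULL, chrom = "chr1") {
  n <- length(p1)
  if (is.null(pos)) pos <- seq_len(n)
  structure(data.frame(chrom = rep(chrom, n), pos = pos,
                       p1 = p1, p2 = p2, p3 = p3),
            class = c("polarized_freqs", "data.frame"))
}
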