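#' Polarize sites against a fixed outgroup
#'
#' For a four-taxon test (((P1, P2), P3), O), retains the biallelic sites
#' at which the outgroup is fixed for one allele (any site where the
#' outgroup is polymorphic or entirely missing is dropped), calls the
#' outgroup allele ancestral, and returns the derived-allele frequency of
#' each ingroup taxon computed from genotyped alleles only.
#'
#' @param gm a [genotype_matrix()].
#' @param p1,p2,p3,outgroup taxon labels present in the taxon map.
#' @param min_genotyped minimum genotyped individuals per ingroup taxon at
#'   a retained site (default 2); the outgroup additionally needs at least
#'   2 genotyped individuals.
#' @return Object of class `polarized_freqs`: data frame with `chrom`,
#'   `pos`, `p1`, `p2`, `p3` (derived frequencies) plus the taxon labels
#'   as attributes.
#' @export
polarize_sites <- function(gm, p1, p2, p3, outgroup, min_genotyped = 2) {
  taxa <- c(p1 = p1, p2 = p2, p3 = p3, o = outgroup)
  for (tx in taxa) gm_individuals(gm, tx)  # errors on unknown label
  variant <- !is.na(gm$alt)
  D <- gm$gt[variant, , drop = FALSE]
  freq_of <- function(tx) {
    cols <- gm_individuals(gm, tx)
    sub <- D[, cols, drop = FALSE]
    n_geno <- rowSums(!is.na(sub))
    list(freq = rowSums(sub, na.rm = TRUE) / (2 * n_geno), n = n_geno)
  }
  fo <- freq_of(outgroup)
  out_fixed <- fo$n >= 2 & (fo$freq == 0 | fo$freq == 1)
  f1 <- freq_of(p1); f2 <- freq_of(p2); f3 <- freq_of(p3)
  keep <- out_fixed & f1$n >= min_genotyped & f2$n >= min_genotyped &
    f3$n >= min_genotyped
  # derived allele = the allele absent from the outgroup
  derived <- function(f) ifelse(fo$freq[keep] == 0, f$freq[keep], 1 - f$freq[keep])
  structure(
    data.frame(
      chrom = gm$chrom[variant][keep], pos = gm$pos[variant][keep],
      p1 = derived(f1), p2 = derived(f2), p3 = derived(f3)
    ),
    labels = taxa, class = c("polarized_freqs", "data.frame")
  )
}

# ABBA/BABA site weights from derived frequencies (outgroup ancestral).
site_patterns <- function(p1, p2, p3) {
  list(abba = (1 - p1) * p2 * p3, baba = p1 * (1 - p2) * p3)
}

#' Patterson's D from polarized frequencies
#'
#' With per-site derived frequencies and an ancestral outgroup, the
#' frequency-weighted pattern counts are `ABBA = (1 - p1) p2 p3` and
#' `BABA = p1 (1 - p2) p3`; `D = (sum ABBA - sum BABA) / (sum ABBA + sum
#' BABA)`. Per-site terms are retained for the block jackknife and fd.
#'
#' @param freqs a [polarize_sites()] result (or any data frame with
#'   columns `p1`, `p2`, `p3` and positions).
#' @return List with `D`, `n_sites`, and per-site `abba`/`baba` vectors.
#'   `D` is `NA` when no site carries pattern weight.
#' @export
patterson_d <- function(freqs) {
  if (!nrow(freqs)) stop("no informative sites")
  pat <- site_patterns(freqs$p1, freqs$p2, freqs$p3)
  s_abba <- sum(pat$abba); s_baba <- sum(pat$baba)
  d <- if (s_abba + s_baba == 0) NA_real_ else (s_abba - s_baba) / (s_abba + s_baba)
  list(D = d, n_sites = nrow(freqs), abba = pat$abba, baba = pat$baba)
}

#' Weighted block jackknife for Patterson's D
#'
#' Splits the genome into contiguous blocks of `block_bp`, recomputes D
#' with each non-empty block deleted, and uses the weighted delete-one
#' jackknife (block weights proportional to each block's share of the
#' total pattern weight) to obtain a standard error; `Z = D / SE` and a
#' two-sided normal p-value follow. Blocks make the standard error robust
#' to linkage between nearby sites.
#'
#' @param d a [patterson_d()] result.
#' @param freqs the [polarize_sites()] result it was computed from.
#' @param block_bp block size in bp (default 500 kb).
#' @return List with `SE`, `Z`, `p`, `n_blocks`. When all blocks give the
#'   same estimate, `SE = 0` and `Z`/`p` are `NA` with a flag.
#' @export
block_jackknife <- function(d, freqs, block_bp = 5e5) {
  block <- paste(freqs$chrom, (freqs$pos - 1) %/% block_bp)
  w <- d$abba + d$baba  # per-site pattern weight
  tot_num <- sum(d$abba) - sum(d$baba)
  tot_den <- sum(w)
  num_b <- tapply(d$abba - d$baba, block, sum)
  den_b <- tapply(w, block, sum)
  keep <- den_b > 0
  num_b <- num_b[keep]; den_b <- den_b[keep]
  g <- length(den_b)
  if (g < 10) stop("fewer than 10 non-empty blocks; enlarge the data or shrink block_bp")
  theta <- tot_num / tot_den
  theta_del <- (tot_num - num_b) / (tot_den - den_b)
  h <- tot_den / den_b  # inverse block weights
  # weighted delete-one jackknife (pseudovalue form)
  theta_j <- g * theta - sum((1 - den_b / tot_den) * theta_del)
  pseudo <- h * theta - (h - 1) * theta_del
  var_j <- mean((pseudo - theta_j)^2 / (h - 1))
  se <- sqrt(var_j)
  if (se == 0) {
    return(list(SE = 0, Z = NA_real_, p = NA_real_, n_blocks = g,
                degenerate = TRUE))
  }
  z <- theta / se
  list(SE = se, Z = z, p = 2 * pnorm(-abs(z)), n_blocks = g, degenerate = FALSE)
}

#' Genome-wide admixture proportion f
#'
#' Compares the observed ABBA excess `S(P1, P2, P3)` to the excess
#' expected under complete admixture, obtained by splitting the P3
#' individuals into two random halves P3a/P3b and letting one half stand
#' in for P2: `f = S(P1, P2, P3) / S(P1, P3a, P3b)`. The split is drawn
#' once, from the supplied seed.
#'
#' @param gm the [genotype_matrix()] the test is computed from.
#' @param freqs the [polarize_sites()] result for (P1, P2, P3, O).
#' @param seed integer seed for the P3 split.
#' @param min_genotyped passed to the internal re-polarization of the
#'   P3a/P3b comparison (default 1, as the halves are small).
#' @return List with `f`, the half memberships, and the numerator and
#'   denominator sums. `f` is `NA` (flagged) when the denominator is not
#'   positive.
#' @export
admixture_fraction_f <- function(gm, freqs, seed = 1, min_genotyped = 1) {
  labels <- attr(freqs, "labels")
  p3_ind <- gm_individuals(gm, labels[["p3"]])
  if (length(p3_ind) < 2) stop("need at least 2 P3 individuals to split")
  set.seed(seed)
  half <- sample(p3_ind, floor(length(p3_ind) / 2))
  other <- setdiff(p3_ind, half)
  # frequencies of the two halves at the already-polarized sites
  site_key <- paste(freqs$chrom, freqs$pos)
  variant <- !is.na(gm$alt)
  key_all <- paste(gm$chrom[variant], gm$pos[variant])
  rows <- match(site_key, key_all)
  D <- gm$gt[variant, , drop = FALSE]
  half_freq <- function(cols) {
    sub <- D[rows, cols, drop = FALSE]
    n_geno <- rowSums(!is.na(sub))
    raw <- rowSums(sub, na.rm = TRUE) / (2 * n_geno)
    ok <- n_geno >= min_genotyped
    list(freq = raw, ok = ok)
  }
  fa <- half_freq(half)
  fb <- half_freq(other)
  # orient to derived allele exactly as in the parent polarization
  p3_derived <- freqs$p3
  # derived orientation flag recovered from any taxon is not stored; the
  # halves must be oriented the same way, so recompute from the outgroup
  out_ind <- gm_individuals(gm, labels[["o"]])
  sub_o <- D[rows, out_ind, drop = FALSE]
  o_freq <- rowSums(sub_o, na.rm = TRUE) / (2 * rowSums(!is.na(sub_o)))
  orient <- function(f) ifelse(o_freq == 0, f, 1 - f)
  ok <- fa$ok & fb$ok
  p3a <- orient(fa$freq)[ok]
  p3b <- orient(fb$freq)[ok]
  s <- function(p1, p2, p3) {
    pat <- site_patterns(p1, p2, p3)
    sum(pat$abba) - sum(pat$baba)
  }
  numerator <- s(freqs$p1, freqs$p2, freqs$p3)
  denominator <- s(freqs$p1[ok], p3a, p3b)
  f <- if (denominator <= 0) NA_real_ else numerator / denominator
  list(f = f, numerator = numerator, denominator = denominator,
       p3a = half, p3b = other, degenerate = denominator <= 0)
}

#' Window-based admixture proportion fd
#'
#' The dynamic-donor window statistic: per window, `fd = S(P1, P2, P3) /
#' S(P1, PD, PD)` where at each site the donor PD is whichever of P2, P3
#' carries the higher derived-allele frequency. fd is designed for an
#' excess of ABBA (gene flow from P3 into P2), so when the genome-wide D
#' of the test is negative, P1 and P2 must be swapped before calling this
#' function (see [four_taxon_test()]). Windows whose numerator is
#' negative or denominator non-positive are reported `NA`: the statistic
#' is undefined there.
#'
#' @param freqs a [polarize_sites()] result (P1/P2 already ordered so that
#'   genome-wide D is non-negative).
#' @param windows data frame of non-overlapping windows from
#'   [make_windows()].
#' @return Numeric vector of fd per window (`NA` where undefined).
#' @export
fd_windows <- function(freqs, windows) {
  pd <- pmax(freqs$p2, freqs$p3)
  num_terms <- site_patterns(freqs$p1, freqs$p2, freqs$p3)
  den_terms <- site_patterns(freqs$p1, pd, pd)
  vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    in_w <- freqs$chrom == w$chrom & freqs$pos - 1 >= w$start & freqs$pos - 1 < w$end
    if (!any(in_w)) return(NA_real_)
    num <- sum(num_terms$abba[in_w]) - sum(num_terms$baba[in_w])
    den <- sum(den_terms$abba[in_w]) - sum(den_terms$baba[in_w])
    if (num < 0 || den <= 0) NA_real_ else num / den
  }, numeric(1))
}

#' Run one complete four-taxon introgression test
#'
#' Polarizes sites, computes genome-wide Patterson's D with its block
#' jackknife, the admixture proportion f, and the per-window fd track.
#' If genome-wide D is negative, P1 and P2 are swapped (recorded in
#' `swapped`) before fd is computed, as fd detects ABBA excess only.
#'
#' @inheritParams polarize_sites
#' @param windows non-overlapping window grid for fd.
#' @param block_bp jackknife block size (default 500 kb).
#' @param seed seed for the P3 split of f.
#' @return List of class `four_taxon_result` with `labels`, `D`, `SE`,
#'   `Z`, `p`, `f`, `fd` (per window), `swapped`, `n_sites`.
#' @export
four_taxon_test <- function(gm, p1, p2, p3, outgroup, windows,
                            min_genotyped = 2, block_bp = 5e5, seed = 1) {
  freqs <- polarize_sites(gm, p1, p2, p3, outgroup, min_genotyped)
  d <- patterson_d(freqs)
  jk <- block_jackknife(d, freqs, block_bp)
  f <- admixture_fraction_f(gm, freqs, seed = seed)
  swapped <- FALSE
  if (!is.na(d$D) && d$D < 0) {
    swapped <- TRUE
    freqs_fd <- freqs
    freqs_fd$p1 <- freqs$p2
    freqs_fd$p2 <- freqs$p1
  } else {
    freqs_fd <- freqs
  }
  structure(list(
    labels = c(P1 = p1, P2 = p2, P3 = p3, O = outgroup),
    D = d$D, SE = jk$SE, Z = jk$Z, p = jk$p, n_blocks = jk$n_blocks,
    f = f$f, fd = fd_windows(freqs_fd, windows),
    swapped = swapped, n_sites = d$n_sites
  ), class = "four_taxon_result")
}

#' @method print four_taxon_result
#' @export
print.four_taxon_result <- function(x, ...) {
  cat(sprintf(
    "four_taxon_test (((%s, %s), %s), %s)%s: D = %.4f, Z = %.2f, f = %s, %d sites\n",
    x$labels["P1"], x$labels["P2"], x$labels["P3"], x$labels["O"],
    if (x$swapped) " [P1/P2 swapped for fd]" else "",
    x$D, x$Z, format(x$f, digits = 3), x$n_sites
  ))
  invisible(x)
}

#' Mean and maximum fd across many four-taxon tests
#'
#' Per-window reduction over the fd tracks of several tests, skipping
#' missing values; a window missing in every test stays missing.
#'
#' @param tracks list of `four_taxon_result` objects (or a list of plain
#'   numeric fd vectors) on a common window grid.
#' @return Data frame with `mean_fd`, `max_fd`, `n_tests` per window.
#' @export
fd_summary <- function(tracks) {
  vecs <- lapply(tracks, function(t) if (inherits(t, "four_taxon_result")) t$fd else t)
  if (length(unique(lengths(vecs))) != 1) stop("fd tracks differ in window grid")
  m <- do.call(cbind, vecs)
  n_tests <- rowSums(!is.na(m))
  mean_fd <- ifelse(n_tests > 0, rowMeans(m, na.rm = TRUE), NA_real_)
  max_fd <- apply(m, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  data.frame(mean_fd = mean_fd, max_fd = max_fd, n_tests = n_tests)
}
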