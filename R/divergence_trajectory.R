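#' Landscape/covariate correlations for every taxon pair
#'
#' For each unordered taxon pair, computes the Pearson correlations that
#' track genomic-landscape evolution with divergence time: mean pair
#' diversity vs gene count, mean pair diversity vs recombination rate,
#' `Fst` vs gene count, `Fst` vs recombination rate, `dxy` vs mean pair
#' diversity, and `Fst` vs mean pair diversity. Mean pair diversity is
#' `(pi_a + pi_b) / 2` computed per window. Each pair is annotated with
#' its net divergence `da`, the proxy for time since the split.
#'
#' @param stats list from [window_statistics()].
#' @param gene_count,recomb_rate per-window covariate vectors aligned with
#'   `stats$windows` (either may be `NULL` to skip those columns).
#' @param min_windows minimum complete windows per correlation (default
#'   10); below it the value is `NA` with a warning.
#' @return Data frame, one row per pair: `pair`, `a`, `b`, `da`,
#'   `r_pi_genes`, `r_pi_recomb`, `r_fst_genes`, `r_fst_recomb`,
#'   `r_dxy_pi`, `r_fst_pi`, `n_windows`.
#' @export
pair_correlations <- function(stats, gene_count = NULL, recomb_rate = NULL,
                              min_windows = 10) {
  guarded_cor <- function(x, y) {
    if (is.null(x) || is.null(y)) return(NA_real_)
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_windows) {
      warning("fewer than ", min_windows, " complete windows for a correlation")
      return(NA_real_)
    }
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])
  }
  out <- lapply(seq_len(nrow(stats$pairs)), function(p) {
    a <- stats$pairs$a[p]; b <- stats$pairs$b[p]
    nm <- stats$pairs$name[p]
    pi_mean <- (stats$pi[, a] + stats$pi[, b]) / 2
    fst <- stats$fst[, nm]
    dxy <- stats$dxy[, nm]
    da <- da_pair(mean(dxy, na.rm = TRUE),
                  mean(stats$pi[, a], na.rm = TRUE),
                  mean(stats$pi[, b], na.rm = TRUE))
    data.frame(
      pair = nm, a = a, b = b, da = da,
      r_pi_genes = guarded_cor(pi_mean, gene_count),
      r_pi_recomb = guarded_cor(pi_mean, recomb_rate),
      r_fst_genes = guarded_cor(fst, gene_count),
      r_fst_recomb = guarded_cor(fst, recomb_rate),
      r_dxy_pi = guarded_cor(dxy, pi_mean),
      r_fst_pi = guarded_cor(fst, pi_mean),
      n_windows = sum(!is.na(fst) & !is.na(pi_mean))
    )
  })
  do.call(rbind, out)
}

#' Phylogenetic correction for pairwise comparisons
#'
#' Pairwise statistics between n taxa are phylogenetically non-independent
#' because pairs share internal branches. The correction for pairwise data
#' reduces the C(n, 2) pair values to n - 1 independent points: every pair
#' maps to the internal node that is the most recent common ancestor of
#' its two taxa, and each node contributes the (unweighted) mean of its
#' pairs' values. Regressions downstream are fitted to these node means
#' only.
#'
#' @param pair_values named numeric vector of per-pair values, names
#'   `"a|b"` as produced by [window_statistics()].
#' @param topology rooted, fully resolved [ape::phylo] tree whose tips are
#'   the taxa.
#' @return Data frame with one row per internal node: `node`, `value`,
#'   `n_pairs`.
#' @export
independent_contrasts <- function(pair_values, topology) {
  if (!ape::is.rooted(topology)) stop("topology must be rooted")
  if (!ape::is.binary(topology)) {
    deg <- tabulate(topology$edge[, 1])
    poly <- which(deg > 2)
    stop("unresolved polytomy at node ", poly[1])
  }
  prs <- strsplit(names(pair_values), "|", fixed = TRUE)
  if (any(lengths(prs) != 2)) stop("pair names must be of the form 'a|b'")
  node <- vapply(prs, function(p) {
    if (!all(p %in% topology$tip.label)) {
      stop("taxon absent from topology: ", paste(setdiff(p, topology$tip.label), collapse = ", "))
    }
    ape::getMRCA(topology, p)
  }, integer(1))
  agg <- tapply(pair_values, node, mean)
  counts <- tapply(pair_values, node, length)
  out <- data.frame(node = as.integer(names(agg)),
                    value = as.numeric(agg),
                    n_pairs = as.integer(counts))
  n_taxa <- length(topology$tip.label)
  if (nrow(out) != n_taxa - 1) {
    stop("expected ", n_taxa - 1, " contrasts for ", n_taxa,
         " taxa, got ", nrow(out), "; supply values for all pairs")
  }
  out
}

#' Convert net divergence to a divergence time
#'
#' `T = da / (2 mu)` generations, converted to years with the supplied
#' generation time. Negative `da` (a small-sample artifact of very recent
#' splits) is clamped to zero with a warning.
#'
#' @param da net divergence (proportion of sites).
#' @param mu per-bp per-generation mutation rate (default 1.5e-8).
#' @param generation_time_years years per generation (default 2).
#' @return List with `T_generations`, `T_years`, `mu`, `generation_time`.
#' @export
divergence_time <- function(da, mu = 1.5e-8, generation_time_years = 2) {
  stopifnot(mu > 0)
  if (da < 0) {
    warning("negative da clamped to 0")
    da <- 0
  }
  t_gen <- da / (2 * mu)
  list(T_generations = t_gen, T_years = t_gen * generation_time_years,
       mu = mu, generation_time = generation_time_years)
}
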