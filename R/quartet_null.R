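#' Independent polarized sites under a no-migration quartet coalescent
#'
#' Samples polarized derived-allele frequencies for a four-taxon test
#' (((P1, P2), P3), O) under the multispecies coalescent with no gene
#' flow, one independent genealogy per site (the infinite-sites,
#' one-mutation-per-locus limit). Sites where the outgroup is polymorphic
#' or the ingroup invariant are rejected and redrawn. Because per-site
#' ABBA/BABA terms are then independent, this is the sampling regime in
#' which the block-jackknife D test should be well calibrated; it is used
#' for null-calibration experiments of [patterson_d()] and
#' [block_jackknife()].
#'
#' @param n_sites number of retained sites.
#' @param n_hap haploid sample sizes, a length-4 vector (P1, P2, P3, O).
#' @param ne diploid population size of every branch.
#' @param split_times generations ago of the P1-P2, (P1,P2)-P3 and
#'   ingroup-outgroup splits (increasing).
#' @param total_bp genome length over which the sites are spread evenly
#'   (determines how many sites fall in each jackknife block).
#' @param seed integer seed.
#' @return A data frame with columns `chrom`, `pos`, `p1`, `p2`, `p3`,
#'   compatible with [patterson_d()] and [block_jackknife()].
#' @export
simulate_quartet_sites <- function(n_sites, n_hap = c(8, 8, 8, 4),
                                   ne = 1e5,
                                   split_times = c(4e4, 8e4, 1.6e5),
                                   total_bp = 25e6, seed = 1) {
  stopifnot(length(n_hap) == 4, length(split_times) == 3,
            !is.unsorted(split_times))
  freqs <- .quartet_sites_cpp(n_hap[1], n_hap[2], n_hap[3], n_hap[4],
                              ne, split_times[1], split_times[2],
                              split_times[3], n_sites, as.integer(seed))
  data.frame(
    chrom = "sim", pos = as.integer(round(seq(1, total_bp, length.out = n_sites))),
    p1 = freqs[, 1], p2 = freqs[, 2], p3 = freqs[, 3]
  )
}
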