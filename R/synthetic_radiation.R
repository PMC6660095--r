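#' Default 9-taxon species tree of the synthetic radiation
#'
#' An ultrametric tree (branch lengths in generations) mirroring the
#' structure of a recent radiation: an outgroup (`clv`), a nested ingroup,
#' and one very recent split pair (`pun_red`/`pun_yel`), so the window
#' statistics are exercised across both shallow and deep net-divergence
#' regimes.
#'
#' @return An [ape::phylo] tree with 9 tips.
#' @export
radiation_topology <- function() {
  ape::read.tree(text = paste0(
    "(clv:500000,((ari:200000,gra:200000):150000,((aur:200000,par:200000):100000,",
    "((lon:120000,cal:120000):100000,(pun_red:20000,pun_yel:20000):200000):80000)",
    ":50000):150000);"
  ))
}

#' Configuration of the synthetic radiation generator
#'
#' Bundles all parameters of [generate_radiation()]. Windows are laid out
#' on a regular grid (`window_bp` tiles over `n_chrom` contigs) and each
#' window carries an independently simulated coalescent locus of
#' `locus_bp` contiguous sites. Per-window diversity is modulated by the
#' local-Ne multiplier `lambda_w = 1 / (1 + alpha * g_w / (rho_w + eps))`
#' computed from the gene-density and recombination tracks: gene-dense,
#' low-recombination windows get proportionally smaller population sizes,
#' the phenomenological signature of linked selection.
#'
#' @param topology dated species tree ([ape::phylo], branch lengths in
#'   generations); tips are the taxon labels.
#' @param outgroup outgroup taxon label.
#' @param n_per_taxon diploid individuals sampled per ingroup taxon.
#' @param n_outgroup diploid individuals sampled from the outgroup.
#' @param ne_base baseline diploid effective size of every branch.
#' @param mu per-bp per-generation mutation rate.
#' @param n_windows,n_chrom,window_bp,locus_bp window grid layout.
#' @param alpha,eps landscape suppression coefficients (see above);
#'   `alpha = 0` gives a flat landscape.
#' @param smoothness moving-average span of the covariate tracks.
#' @param cross_cor generate negatively correlated gene-density and
#'   recombination tracks (as observed in real genomes).
#' @param admixture_events data frame with columns `donor`, `recipient`,
#'   `time` (generations), `fraction`, and `prop_windows` (share of
#'   windows affected, drawn once per event).
#' @param missing_rate i.i.d. genotype missingness.
#' @param emit_invariant keep invariant-site records (needed for
#'   absolute-scale pi/dxy denominators).
#' @param keep_trees store the realized genealogy of each window in the
#'   ground truth.
#' @param seed integer seed.
#' @return A list of class `radiation_config`.
#' @export
radiation_config <- function(topology = radiation_topology(),
                             outgroup = "clv",
                             n_per_taxon = 4, n_outgroup = 3,
                             ne_base = 1.25e5, mu = 5e-8,
                             n_windows = 400, n_chrom = 2,
                             window_bp = 5e5, locus_bp = 500,
                             alpha = 0.12, eps = 0.5,
                             smoothness = 8, cross_cor = TRUE,
                             admixture_events = NULL,
                             missing_rate = 0.1,
                             emit_invariant = TRUE,
                             keep_trees = FALSE,
                             seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate < 1, ne_base > 0, mu > 0,
            n_windows >= 10, locus_bp >= 10, window_bp >= locus_bp)
  structure(as.list(environment()), class = "radiation_config")
}

#' Spatially autocorrelated covariate tracks
#'
#' Generates positive, spatially autocorrelated gene-density and
#' recombination-rate tracks as moving averages of i.i.d. draws over a
#' shared (optionally anti-correlated) latent field. `smoothness` is the
#' moving-average span in windows: 1 gives i.i.d. tracks, larger values
#' increasingly smooth landscapes (lag-1 autocorrelation about
#' `(k - 1) / k`).
#'
#' @param n_windows number of windows (>= 10).
#' @param smoothness moving-average span (>= 1).
#' @param seed integer seed.
#' @param cross_cor if `TRUE`, gene-dense windows get lower recombination.
#' @return List with integer `gene_count`, numeric `recomb_rate` (cM/Mbp)
#'   and the latent field `latent`.
#' @export
generate_landscape_tracks <- function(n_windows, smoothness, seed = 1,
                                      cross_cor = TRUE) {
  if (n_windows < 10) stop("n_windows must be at least 10")
  if (smoothness < 1) stop("smoothness must be at least 1")
  set.seed(seed)
  k <- as.integer(smoothness)
  smooth <- function(x) {
    s <- stats::filter(x, rep(1 / k, k), sides = 2, circular = TRUE)
    as.numeric(scale(as.numeric(s)))
  }
  z <- smooth(rnorm(n_windows))
  z2 <- if (cross_cor) z else smooth(rnorm(n_windows))
  gene_count <- pmax(0L, as.integer(round(6 + 3 * z + rnorm(n_windows, 0, 0.7))))
  recomb_rate <- pmax(0.05, 1.5 - 0.8 * z2 + rnorm(n_windows, 0, 0.25))
  list(gene_count = gene_count, recomb_rate = recomb_rate, latent = z)
}

#' Generate a synthetic radiation dataset
#'
#' Simulates every window of the grid as an independent multispecies-
#' coalescent locus under the configured species tree, with all branch
#' population sizes scaled by the window's landscape multiplier
#' `lambda_w`, admixture pulses applied to their affected windows as
#' backward lineage reassignment, diploid genotypes assembled from paired
#' lineages, and genotypes masked missing i.i.d. The returned ground
#' truth aligns 1:1 with the emitted windows and supports
#' parameter-recovery tests of every downstream statistic.
#'
#' @param config a [radiation_config()].
#' @return List with `gm` (a [genotype_matrix()]), `windows` (the grid),
#'   `tracks` (`gene_count`, `recomb_rate`), `truth` (data frame with
#'   `lambda`, `admixed`, `admix_fraction`, `expected_pi`, `n_variant`),
#'   `trees` (realized genealogies if `keep_trees`), `config`.
#' @export
generate_radiation <- function(config) {
  stopifnot(inherits(config, "radiation_config"))
  set.seed(config$seed)
  plan <- species_tree_plan(config$topology)
  taxa <- config$topology$tip.label
  n_ind <- ifelse(taxa == config$outgroup, config$n_outgroup, config$n_per_taxon)
  names(n_ind) <- taxa
  individuals <- unlist(lapply(taxa, function(tx) {
    paste0(tx, "_", seq_len(n_ind[[tx]]))
  }))
  taxon_map <- setNames(rep(taxa, times = n_ind), individuals)
  tip_pop <- rep(plan$tip_of[taxa], times = 2 * n_ind)  # 2 lineages/indiv
  lineage_ind <- rep(seq_along(individuals), each = 2)

  # window grid
  per_chrom <- ceiling(config$n_windows / config$n_chrom)
  contig_lengths <- setNames(
    rep(per_chrom * config$window_bp, config$n_chrom),
    paste0("chr", seq_len(config$n_chrom))
  )
  windows <- make_windows(contig_lengths, config$window_bp)
  windows <- windows[seq_len(config$n_windows), ]
  w_n <- nrow(windows)

  tracks <- generate_landscape_tracks(w_n, config$smoothness,
                                      seed = config$seed + 1L,
                                      cross_cor = config$cross_cor)
  lambda <- 1 / (1 + config$alpha * tracks$gene_count /
                   (tracks$recomb_rate + config$eps))

  # admixture pulses: per event, draw its affected window set once
  admixed <- rep(FALSE, w_n)
  admix_fraction <- rep(0, w_n)
  pulses_by_window <- vector("list", w_n)
  ev <- config$admixture_events
  if (!is.null(ev) && nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      mrca <- ape::getMRCA(config$topology, c(ev$donor[i], ev$recipient[i]))
      t_mrca <- plan$time[mrca]
      if (ev$time[i] >= t_mrca) {
        stop("admixture event ", i, " older than donor/recipient divergence")
      }
      affected <- which(runif(w_n) < ev$prop_windows[i])
      pulse <- data.frame(
        time = ev$time[i],
        from_pop = pop_at_time(plan, ev$recipient[i], ev$time[i]),
        to_pop = pop_at_time(plan, ev$donor[i], ev$time[i]),
        fraction = ev$fraction[i]
      )
      for (w in affected) {
        pulses_by_window[[w]] <- rbind(pulses_by_window[[w]], pulse)
        admixed[w] <- TRUE
        admix_fraction[w] <- 1 - (1 - admix_fraction[w]) * (1 - ev$fraction[i])
      }
    }
  }
  base_events <- msc_events(plan)

  ne_nodes <- rep(config$ne_base, length(plan$time))
  n_lin <- length(tip_pop)
  trees <- if (config$keep_trees) vector("list", w_n) else NULL

  chrom_out <- character(0)
  pos_out <- integer(0)
  alt_out <- character(0)
  gt_list <- vector("list", w_n)
  meta_list <- vector("list", w_n)
  n_variant <- integer(w_n)
  for (w in seq_len(w_n)) {
    events <- if (is.null(pulses_by_window[[w]])) base_events else
      msc_events(plan, pulses_by_window[[w]])
    gen <- msc_genealogy(plan, tip_pop, ne_nodes * lambda[w], events)
    mut <- genealogy_mutations(gen, config$mu, config$locus_bp)
    n_variant[w] <- length(mut$pos)
    if (config$keep_trees) {
      lin_labels <- paste0(individuals[lineage_ind], c("_a", "_b"))
      trees[[w]] <- genealogy_to_phylo(gen, lin_labels)
    }
    # diploid dosages: paired lineages per individual
    if (length(mut$pos)) {
      carr <- mut$carriers
      dos <- carr[, seq(1, n_lin, by = 2), drop = FALSE] +
        carr[, seq(2, n_lin, by = 2), drop = FALSE]
    } else {
      dos <- matrix(0L, 0, length(individuals))
    }
    if (config$emit_invariant) {
      full <- matrix(0L, config$locus_bp, length(individuals))
      if (length(mut$pos)) full[mut$pos + 1L, ] <- dos
      site_pos <- seq_len(config$locus_bp) - 1L
      is_var <- seq_len(config$locus_bp) %in% (mut$pos + 1L)
    } else {
      full <- dos
      site_pos <- mut$pos
      is_var <- rep(TRUE, length(mut$pos))
    }
    storage.mode(full) <- "integer"
    gt_list[[w]] <- full
    meta_list[[w]] <- list(
      chrom = rep(windows$chrom[w], nrow(full)),
      pos = windows$start[w] + site_pos + 1L,  # 1-based
      alt = ifelse(is_var, "T", NA_character_)
    )
  }
  gt <- do.call(rbind, gt_list)
  colnames(gt) <- individuals
  if (config$missing_rate > 0) {
    gt[runif(length(gt)) < config$missing_rate] <- NA_integer_
  }
  gm <- genotype_matrix(
    chrom = unlist(lapply(meta_list, `[[`, "chrom")),
    pos = unlist(lapply(meta_list, `[[`, "pos")),
    ref = rep("A", nrow(gt)),
    alt = unlist(lapply(meta_list, `[[`, "alt")),
    gt = gt, taxon_map = taxon_map
  )
  truth <- data.frame(
    chrom = windows$chrom, start = windows$start, end = windows$end,
    lambda = lambda, admixed = admixed, admix_fraction = admix_fraction,
    expected_pi = 4 * config$ne_base * lambda * config$mu,
    n_variant = n_variant
  )
  list(gm = gm, windows = windows, tracks = tracks, truth = truth,
       trees = trees, config = config)
}

#' Write a synthetic radiation dataset to disk
#'
#' Emits the plain-text files a real analysis would start from: a VCF
#' with variant and invariant sites, the taxon map TSV, a BED of gene
#' features consistent with the gene-count track, a genetic-map TSV
#' consistent with the recombination track (markers every
#' `window_bp / 5`), the window ground truth as TSV, and (when present)
#' the realized window genealogies as newick.
#'
#' @param rad a [generate_radiation()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
radiation_write <- function(rad, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- rad$config
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    taxa = file.path(dir, "taxon_map.tsv"),
    genes = file.path(dir, "genes.bed"),
    map = file.path(dir, "genetic_map.tsv"),
    truth = file.path(dir, "truth.tsv"),
    trees = file.path(dir, "window_trees.nwk")
  )
  write_vcf(rad$gm, paths["vcf"])
  write.table(data.frame(names(rad$gm$taxon_map), unname(rad$gm$taxon_map)),
              paths["taxa"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # gene features: gene_count[w] intervals placed wholly inside window w
  genes <- do.call(rbind, lapply(seq_len(nrow(rad$windows)), function(w) {
    g <- rad$tracks$gene_count[w]
    if (g == 0) return(NULL)
    width <- 2000
    starts <- rad$windows$start[w] +
      sort(sample.int(rad$windows$end[w] - rad$windows$start[w] - width, g))
    data.frame(chrom = rad$windows$chrom[w], start = starts, end = starts + width)
  }))
  write.table(genes, paths["genes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # genetic map: 5 intervals per window, each at the window's rate
  map <- do.call(rbind, lapply(split(seq_len(nrow(rad$windows)),
                                     rad$windows$chrom), function(idx) {
    step <- cfg$window_bp / 5
    bp <- seq(rad$windows$start[idx[1]],
              rad$windows$end[idx[length(idx)]], by = step)
    rate_of_bp <- rad$tracks$recomb_rate[idx][
      pmin(length(idx), findInterval(bp[-length(bp)], rad$windows$start[idx]))]
    cm <- cumsum(c(0, rate_of_bp * step / 1e6))
    data.frame(marker = paste0(rad$windows$chrom[idx[1]], "_m", seq_along(bp)),
               chrom = rad$windows$chrom[idx[1]], bp = bp + 1L, cM = cm)
  }))
  write.table(map, paths["map"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(rad$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(rad$trees)) {
    writeLines(vapply(rad$trees, ape::write.tree, character(1)), paths["trees"])
  } else {
    paths <- paths[names(paths) != "trees"]
  }
  invisible(paths)
}
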