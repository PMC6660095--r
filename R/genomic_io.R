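#' Read a taxon map
#'
#' A taxon map is a two-column, tab-separated file `sample<TAB>taxon` with
#' no header, assigning each sequenced individual to a taxon.
#'
#' @param path path to the TSV file.
#' @return Named character vector: names are samples, values taxon labels.
#' @export
read_taxon_map <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("sample", "taxon"))
  if (anyDuplicated(tab$sample)) stop("duplicated sample in taxon map")
  setNames(as.character(tab$taxon), tab$sample)
}

#' Load genotypes from a VCF file
#'
#' Reads a VCF 4.x file containing variant and invariant records (the
#' all-sites output of a genotype caller) into a [genotype_matrix()].
#' Multiallelic sites are dropped, invariant sites (missing ALT) are
#' retained, and half-called diploid genotypes are treated as missing.
#'
#' @param path path to a VCF (optionally bgzipped) with per-sample GT.
#' @param taxon_map named character vector as returned by
#'   [read_taxon_map()]; must cover every sample in the VCF.
#' @param verbose passed to [vcfR::read.vcfR()].
#' @return A [genotype_matrix()].
#' @export
load_genotypes <- function(path, taxon_map, verbose = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = verbose)
  fix <- vcfR::getFIX(vcf)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_raw)
  absent <- setdiff(samples, names(taxon_map))
  if (length(absent)) {
    stop("VCF samples absent from taxon map: ", paste(absent, collapse = ", "))
  }
  alt <- fix[, "ALT"]
  alt[alt %in% c(".", "")] <- NA_character_
  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  keep <- !multi
  gm <- genotype_matrix(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = fix[keep, "REF"],
    alt = alt[keep],
    gt = parse_gt_dosage(gt_raw[keep, , drop = FALSE]),
    taxon_map = taxon_map
  )
  gm
}

# GT strings ("0/0", "0|1", "./.", "./1", ...) -> dosage; half calls -> NA
parse_gt_dosage <- function(gt_raw) {
  lut <- c(
    "0/0" = 0L, "0|0" = 0L, "0" = 0L,
    "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
    "1/1" = 2L, "1|1" = 2L, "1" = 1L
  )
  out <- matrix(unname(lut[gt_raw]), nrow = nrow(gt_raw),
                dimnames = list(NULL, colnames(gt_raw)))
  storage.mode(out) <- "integer"
  out
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal, valid VCF 4.2 with GT-only genotype fields, suitable
#' for round-tripping through [load_genotypes()]. Invariant sites are
#' written with `ALT = .`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  n <- ncol(gm$gt)
  gt_chr <- matrix(c("0/0", "0/1", "1/1")[gm$gt + 1L], nrow = nrow(gm$gt))
  gt_chr[is.na(gm$gt)] <- "./."
  alt <- ifelse(is.na(gm$alt), ".", gm$alt)
  body <- paste(
    gm$chrom, gm$pos, ".", gm$ref, alt, ".", "PASS", ".", "GT",
    apply(gt_chr, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mimland",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gm$gt)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Define a window grid over contigs
#'
#' Windows are half-open intervals `[start, end)` in 0-based coordinates,
#' with every start a multiple of `step` and the last window truncated at
#' the contig end. `step = size` gives non-overlapping tiles; `step < size`
#' a sliding grid. A contig shorter than `size` yields a single window
#' covering the whole contig.
#'
#' @param contig_lengths named numeric vector of contig lengths in bp.
#' @param size window size in bp.
#' @param step step between window starts in bp; must not exceed `size`.
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open). Use [windows_report()] for 1-based inclusive output.
#' @export
make_windows <- function(contig_lengths, size, step = size) {
  stopifnot(size > 0, step > 0, step <= size)
  if (is.null(names(contig_lengths))) stop("contig_lengths must be named")
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    if (len <= size) {
      starts <- 0
    } else {
      full <- seq(0, len - size, by = step)
      # truncated tail window, if the full windows do not reach the end
      if (max(full) + size < len) full <- c(full, max(full) + step)
      starts <- full
    }
    data.frame(chrom = ctg, start = starts,
               end = pmin(starts + size, len))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Convert internal window coordinates to 1-based inclusive reports
#'
#' @param windows data frame from [make_windows()].
#' @return The same data frame with `start`/`end` 1-based inclusive.
#' @export
windows_report <- function(windows) {
  windows$start <- windows$start + 1
  windows
}

#' Per-window recombination rate from a genetic map
#'
#' Interval rates (delta-cM / delta-Mbp) are computed between all pairs of
#' adjacent markers on each contig; the top 5% of rates genome-wide are
#' discarded as implausibly high; and the window value is the mean rate of
#' the surviving intervals overlapping the window. Windows overlapped by
#' fewer than `min_intervals` surviving intervals are reported `NA`.
#'
#' @param genetic_map data frame with columns `marker`, `chrom`, `bp`
#'   (1-based physical position) and `cM`, sorted by `bp` within `chrom`.
#' @param windows data frame from [make_windows()].
#' @param drop_top fraction of the highest interval rates to discard
#'   genome-wide before averaging (default 0.05).
#' @param min_intervals minimum number of surviving intervals overlapping a
#'   window for a rate to be reported (default 3).
#' @return Numeric vector of cM/Mbp per window (`NA` where undefined).
#' @export
window_recombination <- function(genetic_map, windows, drop_top = 0.05,
                                 min_intervals = 3) {
  ivs <- lapply(split(genetic_map, genetic_map$chrom), function(gm_chr) {
    gm_chr <- gm_chr[order(gm_chr$bp), ]
    n <- nrow(gm_chr)
    if (n < 2) return(NULL)
    dbp <- diff(gm_chr$bp)
    dcm <- diff(gm_chr$cM)
    zero <- dbp == 0
    if (any(zero)) {
      warning("skipping ", sum(zero), " marker interval(s) with zero physical distance")
    }
    data.frame(
      chrom = gm_chr$chrom[1], start = gm_chr$bp[-n] - 1L, end = gm_chr$bp[-1] - 1L,
      rate = dcm / (dbp / 1e6)
    )[!zero, ]
  })
  ivs <- do.call(rbind, ivs)
  if (is.null(ivs) || !nrow(ivs)) return(rep(NA_real_, nrow(windows)))
  n_drop <- floor(nrow(ivs) * drop_top)
  if (n_drop > 0) {
    ivs <- ivs[order(ivs$rate, decreasing = TRUE), ][-seq_len(n_drop), ]
  }
  vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    ov <- ivs$chrom == w$chrom & ivs$start < w$end & ivs$end > w$start
    if (sum(ov) < min_intervals) NA_real_ else mean(ivs$rate[ov])
  }, numeric(1))
}

#' Per-window gene counts from an annotation
#'
#' A gene increments the count of every window its interval overlaps by at
#' least 1 bp, so genes spanning a window boundary are counted in both
#' windows.
#'
#' @param features data frame of gene records with columns `chrom`,
#'   `start`, `end`.
#' @param windows data frame from [make_windows()].
#' @param coords coordinate dialect of `features`: `"gff"` for 1-based
#'   inclusive (GFF3) or `"bed"` for 0-based half-open (BED).
#' @return Integer vector of gene counts per window.
#' @export
window_gene_count <- function(features, windows, coords = c("gff", "bed")) {
  coords <- match.arg(coords)
  if (nrow(features)) {
    if (coords == "gff") {
      features$start <- features$start - 1
    }
    unknown <- !(features$chrom %in% windows$chrom)
    if (any(unknown)) {
      warning("skipping ", sum(unknown), " feature(s) on contigs absent from the window grid")
      features <- features[!unknown, , drop = FALSE]
    }
  }
  vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sum(features$chrom == w$chrom & features$start < w$end & features$end > w$start)
  }, integer(1))
}
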