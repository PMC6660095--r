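#' Summarize many landscapes by their first principal component
#'
#' Correlation-matrix PCA of a window-by-variable matrix (variables are
#' taxa for diversity, taxon pairs for divergence/differentiation).
#' Windows with any missing variable are dropped (listwise deletion; the
#' count is reported). The PC1 sign is fixed so that the mean loading is
#' non-negative, making "high PC1 = high statistic". When the landscapes
#' share most of their topography, PC1 is effectively the per-window mean
#' across variables; the row mean is returned for that consistency check.
#'
#' @param x numeric matrix, windows x variables, possibly with `NA`.
#' @return List of class `landscape_pca`: `scores` (PC1 per retained
#'   window), `scores_z` (Z-transformed PC1), `loadings` (per variable),
#'   `variance_explained` (fraction per component), `row_mean` (per-window
#'   mean of the standardized variables), `complete` (logical index of
#'   retained windows), `n_dropped`.
#' @export
landscape_pca <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 variables")
  complete <- stats::complete.cases(x)
  if (sum(complete) < 3) stop("fewer than 3 complete windows")
  xc <- x[complete, , drop = FALSE]
  p <- prcomp(xc, center = TRUE, scale. = TRUE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  flip <- if (mean(p$rotation[, 1]) < 0) -1 else 1
  scores1 <- flip * p$x[, 1]
  # loadings on the correlation scale: eigenvector * sdev, |loading| <= 1
  loadings1 <- flip * p$rotation[, 1] * p$sdev[1]
  structure(list(
    scores = scores1,
    scores_z = z_transform(scores1, label = "PC1 scores"),
    loadings = loadings1,
    rotation = p$rotation, sdev = p$sdev, center = p$center, scale = p$scale,
    variance_explained = ve,
    row_mean = rowMeans(scale(xc)),
    complete = complete,
    n_dropped = sum(!complete)
  ), class = "landscape_pca")
}

#' @method print landscape_pca
#' @export
print.landscape_pca <- function(x, ...) {
  cat(sprintf(
    "landscape_pca: %d windows (%d dropped), %d variables; PC1 explains %.1f%%\n",
    length(x$scores), x$n_dropped, nrow(x$rotation),
    100 * x$variance_explained[1]
  ))
  invisible(x)
}

#' Permutation test for spatial autocorrelation of a window series
#'
#' For each linkage group, the observed statistic is the Pearson
#' correlation between the series and itself shifted by `k` windows, where
#' `k = round(lag_bp / grid step)`. The null distribution is obtained by
#' jointly permuting the genome-wide values across all window positions
#' and recomputing the per-LG coefficient; the one-sided p-value (with the
#' +1 correction) asks whether values cluster more than expected at random.
#'
#' @param values numeric series on a regular window grid.
#' @param windows data frame from [make_windows()] aligned with `values`.
#' @param lag_bp physical lag in bp (default 2 Mbp).
#' @param n_perm number of permutations (default 1000, minimum 100).
#' @param seed optional integer seed for the permutations.
#' @return Data frame with one row per linkage group: `lg`, `coeff`, `p`,
#'   `k`, `n_windows`. LGs with fewer than `k + 2` windows get `NA`.
#' @export
autocorrelation_test <- function(values, windows, lag_bp = 2e6,
                                 n_perm = 1000, seed = NULL) {
  stopifnot(length(values) == nrow(windows), n_perm >= 100)
  if (!is.null(seed)) set.seed(seed)
  step <- window_grid_step(windows)
  k <- max(1L, as.integer(round(lag_bp / step)))
  ok <- !is.na(values)
  if (sd(values[ok]) == 0) stop("constant series: autocorrelation undefined")
  lgs <- unique(windows$chrom)
  by_lg <- lapply(lgs, function(lg) which(windows$chrom == lg))
  lag_cor <- function(v, idx) {
    x <- v[idx]
    n <- length(x)
    if (n < k + 2) return(NA_real_)
    a <- x[seq_len(n - k)]
    b <- x[seq_len(n - k) + k]
    keep <- !is.na(a) & !is.na(b)
    if (sum(keep) < 3 || sd(a[keep]) == 0 || sd(b[keep]) == 0) return(NA_real_)
    cor(a[keep], b[keep])
  }
  obs <- vapply(by_lg, function(idx) lag_cor(values, idx), numeric(1))
  null_mat <- matrix(NA_real_, n_perm, length(lgs))
  for (b in seq_len(n_perm)) {
    perm <- sample(values)
    null_mat[b, ] <- vapply(by_lg, function(idx) lag_cor(perm, idx), numeric(1))
  }
  p <- vapply(seq_along(lgs), function(j) {
    if (is.na(obs[j])) return(NA_real_)
    nz <- null_mat[, j]
    nz <- nz[!is.na(nz)]
    (sum(nz >= obs[j]) + 1) / (length(nz) + 1)
  }, numeric(1))
  data.frame(lg = lgs, coeff = obs, p = p, k = k,
             n_windows = lengths(by_lg))
}

# Infer the step of a regular window grid (bp between consecutive starts).
window_grid_step <- function(windows) {
  steps <- unlist(lapply(split(windows$start, windows$chrom), diff))
  steps <- steps[steps > 0]
  if (!length(steps)) return(windows$end[1] - windows$start[1])
  as.numeric(stats::median(steps))
}

#' Lineage-specific deviation of one pair's landscape from PC1
#'
#' Per-window difference, in SD units, between one pair's Z-transformed
#' differentiation landscape and the Z-transformed PC1 landscape. Loci
#' under lineage-specific positive selection appear as windows strongly
#' elevated above the shared pattern; the return value carries the rank of
#' each window (1 = largest positive deviation).
#'
#' @param z_pair Z-transformed window series for one taxon pair.
#' @param pc1_z Z-transformed PC1 series on the same window grid.
#' @return Data frame with `deviation` and `rank` per window.
#' @export
outlier_deviation <- function(z_pair, pc1_z) {
  if (length(z_pair) != length(pc1_z)) {
    stop("window grids differ between the pair series and PC1")
  }
  dev <- z_pair - pc1_z
  data.frame(deviation = dev, rank = rank(-dev, ties.method = "min",
                                          na.last = "keep"))
}
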