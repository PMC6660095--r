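test_that("make_windows tiles contigs with multiples-of-step starts", {
  w <- make_windows(c(chr1 = 1e6), size = 5e5, step = 5e5)
  expect_equal(nrow(w), 2)
  expect_equal(w$start, c(0, 5e5))
  w2 <- make_windows(c(chr1 = 1e6), size = 5e5, step = 5e4)
  expect_equal(nrow(w2), 11)
  expect_equal(w2$start, seq(0, 5e5, by = 5e4))
  expect_true(all(w2$end - w2$start == 5e5))
  # short contig: single truncated window
  w3 <- make_windows(c(c1 = 120000), size = 5e5)
  expect_equal(nrow(w3), 1)
  expect_equal(c(w3$start, w3$end), c(0, 120000))
  # non-multiple length: truncated tail window still tiles the contig
  w4 <- make_windows(c(c1 = 1.03e6), size = 5e5, step = 5e4)
  expect_equal(max(w4$end), 1.03e6)
  expect_true(all(w4$start %% 5e4 == 0))
  # 1-based report round-trip
  expect_equal(windows_report(w3)$start, 1)
})

test_that("window_recombination filters the top 5% and needs 3 intervals", {
  # single interval: rate = 1.5 cM / 1 Mbp
  gmap <- data.frame(marker = c("m1", "m2"), chrom = "chr1",
                     bp = c(1, 1e6 + 1), cM = c(0, 1.5))
  w <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  # only 1 interval overlapping -> below the 3-interval minimum
  expect_true(is.na(window_recombination(gmap, w)))
  expect_equal(window_recombination(gmap, w, min_intervals = 1), 1.5)
  # 100 intervals, top 5 rates removed genome-wide
  set.seed(3)
  rates <- runif(101, 0.5, 3)
  gmap2 <- data.frame(marker = paste0("m", 1:101), chrom = "chr1",
                      bp = seq(1, by = 1e5, length.out = 101),
                      cM = cumsum(c(0, rates[-1] * 0.1)))
  w2 <- data.frame(chrom = "chr1", start = 0, end = 101e5)
  got <- window_recombination(gmap2, w2, min_intervals = 1)
  iv_rates <- diff(gmap2$cM) / 0.1
  kept <- sort(iv_rates)[1:95]
  expect_equal(got, mean(kept), tolerance = 1e-10)
  # zero physical distance -> interval skipped with warning
  gmap3 <- data.frame(marker = c("a", "b", "c"), chrom = "chr1",
                      bp = c(1, 1, 2e6), cM = c(0, 0.1, 1))
  expect_warning(window_recombination(gmap3, w, min_intervals = 1),
                 "zero physical")
})

test_that("window_gene_count counts boundary-spanning genes in both windows", {
  wins <- make_windows(c(chr1 = 1e6), 5e5, 5e5)
  genes <- data.frame(chrom = "chr1", start = 490000, end = 510000)
  expect_equal(window_gene_count(genes, wins, coords = "gff"), c(1L, 1L))
  # empty set and wholly-contained genes
  expect_equal(window_gene_count(genes[0, ], wins), c(0L, 0L))
  many <- data.frame(chrom = "chr1", start = seq(1000, 10000, 1000),
                     end = seq(1500, 10500, 1000))
  expect_equal(window_gene_count(many, wins, coords = "gff"), c(10L, 0L))
  # BED dialect: a feature ending exactly at a boundary stays in window 1
  bed <- data.frame(chrom = "chr1", start = 499000, end = 500000)
  expect_equal(window_gene_count(bed, wins, coords = "bed"), c(1L, 0L))
  # unknown contig skipped with a warning
  expect_warning(
    got <- window_gene_count(data.frame(chrom = "chrX", start = 1, end = 10),
                             wins, coords = "gff"),
    "absent")
  expect_equal(got, c(0L, 0L))
})

test_that("VCF loading filters multiallelic sites and half calls", {
  vcf <- file.path(tempdir(), "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\t.\tC\tG,T\t.\tPASS\t.\tGT\t0/1\t1/2",
    "chr1\t300\t.\tG\t.\t.\tPASS\t.\tGT\t0/0\t./.",
    "chr1\t400\t.\tT\tC\t.\tPASS\t.\tGT\t./1\t1|1"
  ), vcf)
  tm <- c(s1 = "ta", s2 = "tb")
  gm <- load_genotypes(vcf, tm)
  expect_equal(nrow(gm$gt), 3)  # triallelic site dropped
  expect_equal(gm$pos, c(100L, 300L, 400L))
  expect_true(is.na(gm$alt[2]))                 # invariant retained
  expect_true(is.na(gm$gt[2, "s2"]))            # ./. missing
  expect_true(is.na(gm$gt[3, "s1"]))            # half call -> missing
  expect_equal(unname(gm$gt[3, "s2"]), 2L)      # phased genotype parsed
  expect_error(load_genotypes(vcf, c(s1 = "ta")), "absent from taxon map")
})

test_that("synthetic VCF round-trips through write and load", {
  cfg <- radiation_config(n_windows = 10, locus_bp = 60, seed = 9,
                          missing_rate = 0.15)
  rad <- generate_radiation(cfg)
  path <- file.path(tempdir(), "rt.vcf")
  write_vcf(rad$gm, path)
  tm <- rad$gm$taxon_map
  back <- load_genotypes(path, tm)
  expect_identical(back$gt, rad$gm$gt)
  expect_identical(back$pos, rad$gm$pos)
  expect_identical(back$chrom, rad$gm$chrom)
  expect_identical(is.na(back$alt), is.na(rad$gm$alt))
})

test_that("genotype_matrix validates its invariants", {
  gt <- matrix(0L, 2, 2, dimnames = list(NULL, c("s1", "s2")))
  expect_error(
    genotype_matrix(chrom = c("c", "c"), pos = c(5L, 2L), ref = c("A", "A"),
                    alt = c("T", NA), gt = gt, taxon_map = c(s1 = "x", s2 = "y")),
    "strictly increasing")
  expect_error(
    genotype_matrix(chrom = c("c", "c"), pos = c(1L, 2L), ref = c("A", "A"),
                    alt = c("T", NA), gt = gt, taxon_map = c(s1 = "x")),
    "absent from taxon map")
})
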