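test_that("pair_distance enumerates diploid allele pairings", {
  expect_equal(pair_distance(0L, 1L), c(mismatch = 0.5, joint = 1))
  expect_equal(pair_distance(0L, 2L), c(mismatch = 1, joint = 1))
  expect_equal(pair_distance(1L, 1L), c(mismatch = 0.5, joint = 1))
  # identical homozygous vectors: no mismatch
  expect_equal(pair_distance(c(0L, 2L, 0L), c(0L, 2L, 0L)),
               c(mismatch = 0, joint = 3))
  # missing sites excluded from both numerator and denominator
  expect_equal(pair_distance(c(0L, NA, 2L), c(1L, 1L, NA)),
               c(mismatch = 0.5, joint = 1))
  expect_equal(pair_distance(NA_integer_, 1L), c(mismatch = 0, joint = 0))
  # random 5-site pairs equal the exhaustive allele-pairing oracle
  set.seed(42)
  for (i in 1:20) {
    g1 <- sample(c(0:2, NA), 5, replace = TRUE)
    g2 <- sample(c(0:2, NA), 5, replace = TRUE)
    expect_equal(unname(pair_distance(g1, g2)), unname(oracle_pair(g1, g2)))
  }
})

test_that("pi_window matches hand enumeration and handles missing pairs", {
  # 2 individuals, A/A vs T/T at 1 variant site, 9 invariant joint sites
  gt <- cbind(x1 = c(0L, rep(0L, 9)), x2 = c(2L, rep(0L, 9)))
  gm <- make_gm(gt, c(x1 = "tx", x2 = "tx"))
  res <- pi_window(gm, "tx", window_all(gm), min_genotyped = 2)
  expect_equal(unname(res["pi"]), 0.1)
  # identical homozygotes: pi = 0
  gt0 <- cbind(x1 = rep(2L, 5), x2 = rep(2L, 5), x3 = rep(2L, 5))
  gm0 <- make_gm(gt0, setNames(rep("tx", 3), colnames(gt0)), alt = rep("T", 5))
  expect_equal(unname(pi_window(gm0, "tx", window_all(gm0),
                                min_genotyped = 1)["pi"]), 0)
  # a pair sharing no genotyped site is dropped from the mean
  gt2 <- cbind(x1 = c(0L, NA), x2 = c(NA, 0L), x3 = c(2L, 2L))
  gm2 <- make_gm(gt2, setNames(rep("tx", 3), colnames(gt2)))
  res2 <- pi_window(gm2, "tx", window_all(gm2), min_genotyped = 1)
  # pairs (x1,x3): 1 mismatch / 1 site; (x2,x3): 1/1; (x1,x2) dropped
  expect_equal(unname(res2["pi"]), 1)
})

test_that("dxy_window matches hand enumeration", {
  # taxa fixed for different alleles at 1 of 10 sites
  gt <- cbind(a1 = c(0L, rep(0L, 9)), a2 = c(0L, rep(0L, 9)),
              b1 = c(2L, rep(0L, 9)), b2 = c(2L, rep(0L, 9)))
  gm <- make_gm(gt, setNames(c("ta", "ta", "tb", "tb"), colnames(gt)))
  expect_equal(unname(dxy_window(gm, "ta", "tb", window_all(gm),
                                 min_genotyped = 2)["dxy"]), 0.1)
  # single shared polymorphism at frequency 0.5 in both taxa, 1 of 10 sites:
  # heterozygous individuals everywhere -> expected mismatch 0.5 per pair
  gt2 <- cbind(a1 = c(1L, rep(0L, 9)), a2 = c(1L, rep(0L, 9)),
               b1 = c(1L, rep(0L, 9)), b2 = c(1L, rep(0L, 9)))
  gm2 <- make_gm(gt2, setNames(c("ta", "ta", "tb", "tb"), colnames(gt2)))
  expect_equal(unname(dxy_window(gm2, "ta", "tb", window_all(gm2),
                                 min_genotyped = 2)["dxy"]), 0.05)
  # identical monomorphic taxa: dxy = 0
  gt3 <- matrix(0L, 10, 4, dimnames = list(NULL, colnames(gt)))
  gm3 <- make_gm(gt3, setNames(c("ta", "ta", "tb", "tb"), colnames(gt3)))
  expect_equal(unname(dxy_window(gm3, "ta", "tb", window_all(gm3),
                                 min_genotyped = 2)["dxy"]), 0)
})

test_that("fst boundary cases are exact", {
  # reciprocally fixed taxa -> Fst = 1
  gt <- cbind(a1 = rep(0L, 6), a2 = rep(0L, 6), a3 = rep(0L, 6),
              b1 = rep(2L, 6), b2 = rep(2L, 6), b3 = rep(2L, 6))
  gm <- make_gm(gt, setNames(rep(c("ta", "tb"), each = 3), colnames(gt)))
  expect_equal(unname(fst_window(gm, "ta", "tb", window_all(gm),
                                 min_genotyped = 2)["fst"]), 1,
               tolerance = 1e-12)
  # identical taxa (every individual the same genotype vector, with
  # heterozygous sites so Kt > 0) -> Fst = 0 exactly
  gt2 <- matrix(rep(c(1L, 0L, 2L, 1L, 0L, 1L), 6), 6, 6)
  colnames(gt2) <- c(paste0("a", 1:3), paste0("b", 1:3))
  gm2 <- make_gm(gt2, setNames(rep(c("ta", "tb"), each = 3), colnames(gt2)))
  expect_equal(unname(fst_window(gm2, "ta", "tb", window_all(gm2),
                                 min_genotyped = 2)["fst"]), 0,
               tolerance = 1e-12)
  # no variation at all -> Kt = 0 -> missing
  gt3 <- matrix(0L, 4, 4, dimnames = list(NULL, colnames(gt)[1:4]))
  gm3 <- make_gm(gt3, setNames(rep(c("ta", "tb"), each = 2), colnames(gt3)))
  expect_true(is.na(fst_window(gm3, "ta", "tb", window_all(gm3),
                               min_genotyped = 2)["fst"]))
})

test_that("pi, dxy and Kst Fst match the direct-enumeration oracle", {
  for (i in 1:60) {
    gm <- random_gm(n_sites = sample(2:6, 1), n_a = sample(2:5, 1),
                    n_b = sample(2:5, 1), miss = 0.3, seed = 1000 + i)
    w <- window_all(gm)
    mg <- sample(1:2, 1)
    expect_equal(unname(pi_window(gm, "ta", w, mg)["pi"]),
                 oracle_pi(gm, "ta", mg), tolerance = 1e-12)
    expect_equal(unname(dxy_window(gm, "ta", "tb", w, mg)["dxy"]),
                 oracle_dxy(gm, "ta", "tb", mg), tolerance = 1e-12)
    f_pkg <- unname(fst_window(gm, "ta", "tb", w, mg)["fst"])
    f_ora <- oracle_fst(gm, "ta", "tb", mg)
    if (is.na(f_ora)) expect_true(is.na(f_pkg)) else
      expect_equal(f_pkg, f_ora, tolerance = 1e-12)
  }
})

test_that("dxy and Fst are symmetric and bounded", {
  for (i in 1:15) {
    gm <- random_gm(6, 4, 3, miss = 0.2, seed = 2000 + i)
    w <- window_all(gm)
    expect_equal(dxy_window(gm, "ta", "tb", w, 2)["dxy"],
                 dxy_window(gm, "tb", "ta", w, 2)["dxy"])
    expect_equal(fst_window(gm, "ta", "tb", w, 2)["fst"],
                 fst_window(gm, "tb", "ta", w, 2)["fst"])
    pi_v <- pi_window(gm, "ta", w, 2)["pi"]
    dxy_v <- dxy_window(gm, "ta", "tb", w, 2)["dxy"]
    fst_v <- fst_window(gm, "ta", "tb", w, 2)["fst"]
    expect_true(is.na(pi_v) || (pi_v >= 0 && pi_v <= 1))
    expect_true(is.na(dxy_v) || (dxy_v >= 0 && dxy_v <= 1))
    expect_true(is.na(fst_v) || fst_v <= 1)
  }
})

test_that("Kst Fst approaches the Hudson form on diverged complete data", {
  # strongly diverged pair, complete data: Fst ~ 1 - mean(pi)/dxy
  set.seed(11)
  n <- 200
  pa <- runif(n, 0, 0.15); pb <- runif(n, 0.85, 1)
  gt <- cbind(sapply(1:5, function(i) rbinom(n, 2, pa)),
              sapply(1:5, function(i) rbinom(n, 2, pb)))
  colnames(gt) <- c(paste0("a", 1:5), paste0("b", 1:5))
  storage.mode(gt) <- "integer"
  gm <- make_gm(gt, setNames(rep(c("ta", "tb"), each = 5), colnames(gt)))
  w <- window_all(gm)
  fst_v <- fst_window(gm, "ta", "tb", w, 2)["fst"]
  pi_m <- (pi_window(gm, "ta", w, 2)["pi"] + pi_window(gm, "tb", w, 2)["pi"]) / 2
  dxy_v <- dxy_window(gm, "ta", "tb", w, 2)["dxy"]
  hudson <- 1 - pi_m / dxy_v
  expect_lt(abs(fst_v - hudson), 0.1)
  expect_gt(fst_v, 0.5)
})

test_that("da_pair and z_transform follow their definitions", {
  expect_equal(da_pair(0.016, 0.003, 0.003), 0.013)
  expect_equal(da_pair(0.01, 0.01, 0.01), 0)
  expect_equal(da_pair(0.02, 0, 0), 0.02)
  # population-SD convention: sd = sqrt(2/3), so scores are +-sqrt(3/2)
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1) * sqrt(3 / 2))
  expect_equal(z_transform(c(1, 2, 3), sd_type = "sample"), c(-1, 0, 1))
  x <- c(4, NA, 8, 1, 7)
  z <- z_transform(x)
  expect_true(is.na(z[2]))
  expect_equal(mean(z, na.rm = TRUE), 0)
  ok <- !is.na(z)
  expect_equal(sqrt(mean(z[ok]^2)), 1)
  expect_error(z_transform(rep(2, 5), label = "flat"), "zero standard deviation")
  expect_error(z_transform(c(1, NA, NA)), "fewer than 2")
})
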