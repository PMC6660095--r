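# Independent patristic distances via igraph shortest paths, so the
# concordance checks do not lean on the same ape code path.
igraph_patristic <- function(tr) {
  g <- igraph::graph_from_edgelist(apply(tr$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tr$edge.length
  d <- igraph::distances(g)
  tips <- as.character(seq_along(tr$tip.label))
  d <- d[tips, tips]
  dimnames(d) <- list(tr$tip.label, tr$tip.label)
  d
}

test_that("window_tree recovers an additive topology by neighbor joining", {
  # two cherries: ((a1,a2),(b1,b2)) with taxa fixed for different alleles
  gt <- cbind(a1 = rep(0L, 20), a2 = rep(0L, 20),
              b1 = rep(2L, 20), b2 = rep(2L, 20))
  gt[1, "a2"] <- 1L  # a little within-cherry variation
  gt[2, "b2"] <- 1L
  gm <- make_gm(gt, setNames(c("ta", "ta", "tb", "tb"), colnames(gt)))
  tr <- window_tree(gm, window_all(gm))
  expect_s3_class(tr, "phylo")
  expect_true(ape::is.monophyletic(tr, c("a1", "a2")))
  expect_true(all(tr$edge.length >= 0))
  # a pair sharing no genotyped sites skips the window
  gt2 <- cbind(a1 = c(0L, NA), a2 = c(0L, 1L), b1 = c(NA, 2L), b2 = c(2L, 2L))
  gm2 <- make_gm(gt2, setNames(c("ta", "ta", "tb", "tb"), colnames(gt2)))
  expect_warning(tr2 <- window_tree(gm2, window_all(gm2)), "no genotyped site")
  expect_null(tr2)
})

test_that("concordance_score is 1 for a tree against itself and scale-invariant", {
  set.seed(7)
  tr <- ape::rtree(12)
  expect_equal(concordance_score(tr, tr), 1)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 2
  expect_equal(concordance_score(tr2, tr), 1)
  # star tree has zero cophenetic variance -> missing
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_true(is.na(concordance_score(star, star)))
  expect_error(concordance_score(ape::rtree(5), ape::rtree(6)), "tip sets")
})

test_that("concordance_score equals the direct cophenetic correlation", {
  cat8 <- ape::read.tree(text = "(((((((a:1,b:1):1,c:1):1,d:1):1,e:1):1,f:1):1,g:1):1,h:1);")
  bal8 <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);")
  expected <- {
    dw <- igraph_patristic(cat8)
    dg <- igraph_patristic(bal8)[rownames(dw), colnames(dw)]
    cor(dw[lower.tri(dw)], dg[lower.tri(dg)])
  }
  expect_equal(concordance_score(cat8, bal8), expected)
  expect_lt(expected, 1)
})

test_that("concordance decreases monotonically with distance-matrix noise", {
  set.seed(31)
  ref <- ape::rtree(10)
  d0 <- ape::cophenetic.phylo(ref)
  score_at_noise <- function(eps) {
    median(replicate(60, {
      noise <- matrix(rnorm(100, 0, eps), 10, 10)
      noise <- abs(noise + t(noise))
      diag(noise) <- 0
      tr <- ape::nj(as.dist(d0 + noise))
      tr$edge.length[tr$edge.length < 0] <- 0
      concordance_score(tr, ref)
    }))
  }
  meds <- vapply(c(0.05, 0.4, 1.5), score_at_noise, numeric(1))
  expect_true(all(diff(meds) <= 0))
})

test_that("clade_recovery counts monophyly across window trees", {
  t1 <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,o:1);")
  t2 <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,o:1);")
  t3 <- ape::read.tree(text = "(((a:1,c:1):1,b:1):1,o:1);")
  t4 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,o:1):1);")
  res <- clade_recovery(list(t1, t2, t3, t4), c("a", "b"))
  expect_equal(unname(res["fraction"]), 0.75)
  expect_equal(unname(res["n_trees"]), 4)
  # replicated genome tree -> every ingroup clade recovered always
  res2 <- clade_recovery(list(t1, t1, t1), c("a", "b", "c"),
                         outgroup_tips = "o")
  expect_equal(unname(res2["fraction"]), 1)
  expect_error(clade_recovery(list(t1), "a"), "at least 2")
  expect_error(clade_recovery(list(t1), c("a", "o"), outgroup_tips = "o"),
               "outgroup")
})

test_that("window trees from the generator are concordant with the species history", {
  cfg <- radiation_config(n_windows = 12, locus_bp = 400, missing_rate = 0.05,
                          seed = 17)
  rad <- generate_radiation(cfg)
  # genome tree: NJ over all sites of the first contig
  genome_tree <- window_tree(rad$gm, data.frame(chrom = rad$windows$chrom[1],
                                                start = 0, end = max(rad$gm$pos)))
  conc <- window_concordance(rad$gm, rad$windows, genome_tree, outgroup = "clv")
  expect_true(all(conc$score > 0.3, na.rm = TRUE))
  expect_gt(mean(conc$score, na.rm = TRUE), 0.6)
  # outgroup individuals cluster away from the recent-split pair
  trees <- attr(conc, "trees")
  ok <- !vapply(trees, is.null, logical(1))
  expect_true(any(ok))
})
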