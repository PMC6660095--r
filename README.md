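# mimland

Window-based speciation genomics for multi-taxon radiations: the
genomic landscapes of diversity (π), divergence (d<sub>xy</sub>) and
differentiation (F<sub>ST</sub>), what shapes them, and how they evolve
with time since a population split.

## The problem

Closely related taxa in a rapid radiation — for example the bush
monkeyflowers, nine taxa spanning roughly a million years of
divergence — show strikingly similar "landscapes" of genome-wide
variation: π, d<sub>xy</sub> and F<sub>ST</sub> peak and dip in the
same windows in nearly every pairwise comparison, and the shared
topography tracks the local density of genes and the recombination
rate. Interpreting that pattern requires a chain of analyses that this
package implements end to end:

* **Window statistics.** π, d<sub>xy</sub> and K<sub>ST</sub>-family
  F<sub>ST</sub> (`Fst = 1 − Ks/Kt`) in tiling or sliding windows, from
  an all-sites VCF (variant + invariant records). Every pairwise
  distance uses a per-pair missing-data denominator: the expected
  allele mismatch between two diploid genotypes, divided by the sites
  genotyped in both individuals. Net divergence
  `da = dxy − mean(π)` orders taxon pairs by split time, and
  `T = da/(2µ)` converts it to generations.
* **Window trees.** Neighbor-joining trees per window, a concordance
  score (Pearson correlation of cophenetic matrices against the genome
  tree), and per-clade recovery fractions.
* **Landscape PCA and spatial tests.** PC1 across the 36 pairwise
  landscapes as the shared pattern; a permutation test for spatial
  autocorrelation of any window series; and a Z-F<sub>ST</sub>
  deviation-from-PC1 scan for lineage-specific sweeps.
* **Divergence trajectories.** Landscape/covariate correlations for all
  pairs against d<sub>a</sub>, reduced to n − 1 phylogenetically
  independent node means (8 contrasts for 9 taxa).
* **Introgression.** Patterson's D from polarized allele frequencies
  (`ABBA = (1−p1)p2p3`, `BABA = p1(1−p2)p3`) with a weighted 500-kb
  block jackknife, the admixture proportion f via a random P3 split,
  and the window statistic f<sub>d</sub> with a dynamic donor.
* **Forward simulation.** A compiled Wright–Fisher engine for six
  divergence scenarios (neutral, background selection, BDM
  incompatibilities, positive selection, both, local adaptation) on a
  three-part chromosome whose distal thirds carry selected mutations,
  with population rescaling for desk-scale runs.
* **Synthetic data.** A multispecies-coalescent generator of a 9-taxon
  radiation with gene-density/recombination-driven diversity
  suppression, admixture pulses, missing genotypes and exported ground
  truth, so the whole pipeline is testable offline.

## A worked example

```r
library(mimland)

# a synthetic radiation: 120 windows, 9 taxa, missing genotypes
cfg <- radiation_config(n_windows = 120, locus_bp = 400, seed = 1)
rad <- generate_radiation(cfg)
rad$gm
#> genotype_matrix: 48000 sites (19482 variant) x 35 individuals, 9 taxa, 2 contig(s)

# window statistics for all taxa and the 36 pairs
st <- window_statistics(rad$gm, rad$windows, outgroup = "clv")
round(mean(st$pi, na.rm = TRUE), 4)
#> [1] 0.0181

# shared landscape: PC1 of the 36 Fst landscapes
p <- landscape_pca(st$fst)
p
#> landscape_pca: 120 windows (0 dropped), 36 variables; PC1 explains 30.4%
cor(p$scores, p$row_mean)^2
#> [1] 0.9928

# divergence-time trajectory with the phylogenetic correction
pc <- pair_correlations(st, gene_count = rad$tracks$gene_count,
                        recomb_rate = rad$tracks$recomb_rate)
ct <- independent_contrasts(setNames(pc$r_fst_pi, pc$pair), radiation_topology())
nrow(ct)
#> [1] 8
divergence_time(max(pc$da), mu = 5e-8)$T_generations  # generator scale
#> [1] 485660

# a four-taxon introgression test
tt <- four_taxon_test(rad$gm, "pun_yel", "pun_red", "par", "clv", rad$windows)
tt
#> four_taxon_test (((pun_yel, pun_red), par), clv) [P1/P2 swapped for fd]: D = -0.0554, Z = -0.48, f = -0.00424, 16697 sites
```

The numbers above are from this exact script (seed 1): mean window π
matches the generator's θ-scale, PC1 behaves as the mean landscape
(r² > 0.99), nine taxa reduce to eight independent contrasts, and an
un-admixed quartet shows D ≈ 0 with a non-significant Z.

Simulating landscape evolution:

```r
cfg <- rescale(sim_scenario("positive", L = 2.1e6, window_bp = 5e4), Q = 20)
out <- run_scenario(cfg, reps = 2)
subset(out$correlations, replicate == 1 & timepoint %in% c(0, 5000))
#>    replicate timepoint   r_dxy_pi    r_fst_pi
#> 1          1         0  0.9997052 -0.02318669
#> 11         1      5000 -0.1229292 -0.98532942
```

At the split d<sub>xy</sub> mirrors ancestral π almost perfectly; ten
(scaled) N generations of tail-targeted positive selection later the
correlation has collapsed and F<sub>ST</sub> is strongly
anti-correlated with diversity — the signature that distinguishes
adaptation-driven landscapes from background selection alone.

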