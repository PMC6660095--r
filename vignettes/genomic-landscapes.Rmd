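---
title: "Genomic landscapes of diversity, divergence and introgression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic landscapes of diversity, divergence and introgression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mimland)
```

# The problem

In a recent radiation — a group of closely related taxa such as the bush
monkeyflowers, spanning less than about a million years of divergence —
patterns of genome-wide variation tend to be strikingly similar across
taxa: diversity (π), divergence (d~xy~) and differentiation (F~ST~) rise
and fall in the same genomic regions in almost every comparison. The
shared topography reflects heterogeneous *indirect* selection: wherever
functional density is high and recombination low, directional selection
at linked sites removes variation, which depresses π, depresses
ancestral d~xy~, and inflates F~ST~. `mimland` implements the full
analytical chain used to characterize and interpret such landscapes:

1. window statistics with explicit missing-data handling
   (`window_statistics()`, `pi_window()`, `dxy_window()`, `fst_window()`);
2. per-window phylogenies and their concordance with the genome tree
   (`window_tree()`, `concordance_score()`, `clade_recovery()`);
3. PCA summaries of many landscapes and a permutation test for spatial
   autocorrelation (`landscape_pca()`, `autocorrelation_test()`,
   `outlier_deviation()`);
4. the divergence-time trajectory of landscape/covariate correlations
   with a phylogenetic correction for pairwise data
   (`pair_correlations()`, `independent_contrasts()`, `divergence_time()`);
5. ABBA-BABA introgression statistics (`four_taxon_test()`:
   Patterson's D with a weighted block jackknife, the genome-wide
   admixture proportion f, and the window statistic f~d~);
6. a forward Wright–Fisher simulator of six divergence scenarios
   (`sim_scenario()`, `rescale()`, `run_scenario()`); and
7. a multispecies-coalescent generator of synthetic radiation data with
   exported ground truth (`radiation_config()`, `generate_radiation()`),
   so that every stage of the pipeline is testable without any download.

# Window statistics and missing data

All estimators are built from one primitive, `pair_distance()`: the
distance between two diploid genotypes at a site is the expected
mismatch when one allele is drawn at random from each individual (0 for
identical homozygotes, 1 for opposite homozygotes, 0.5 whenever a
heterozygote is involved). For each pair of individuals the per-pair
ratio is (summed expected mismatches) / (sites genotyped in *both*
individuals), with invariant sites counting toward the denominator.
Missing data therefore shrink a pair's denominator rather than biasing
its numerator, and pairs that share no genotyped site are dropped from
the averaging instead of contributing a spurious zero.

* π is the mean per-pair ratio over all unordered pairs of distinct
  individuals within a taxon. Within-individual heterozygosity is not
  itself treated as a "pair".
* d~xy~ is the mean per-pair ratio over all between-taxon pairs.
* F~ST~ follows the K~ST~ family: `Fst = 1 − Ks/Kt`, where K~s~ is the
  mean within-taxon pairwise distance pooled over both taxa
  (equivalently, the two taxon means weighted by their pair counts — the
  published form of K~ST~ does not restate its weights under unequal,
  site-varying sample sizes, so the pair-count weighting is exposed as
  this package's documented reading) and K~t~ is the mean distance over
  all pairs in the pooled sample. On complete data from
  well-differentiated taxa this is close to the Hudson form
  `1 − mean(π)/d_xy`; exact agreement is not expected, as these are
  different estimator families.

Per-site genotyping filters are applied independently for every
comparison: by default a site must be genotyped in at least 3
individuals of each taxon involved, relaxed to 2 for the outgroup
(whose sample is typically smaller). Net divergence is
`da = dxy − (πa + πb)/2`, and `T = da/(2µ)` converts it to generations
(default µ = 1.5×10⁻⁸ per bp per generation; years via a 2-year
generation time).

Landscapes are compared after Z-transformation. The default uses the
population (divide-by-n) standard deviation: this is a normalization of
a fixed set of windows, not an inference about a larger population of
windows; the sample convention is available via `sd_type`.

# Window trees and concordance

Phylogenetic discordance along the genome is scored against a reference
genome tree. Per-window trees are built by neighbor joining from the
matrix of per-pair genotype distances (the same `pair_distance()`
ratios), negative NJ branch lengths clamped to zero, rooted on the
outgroup individuals. The concordance score is the Pearson correlation
between the lower triangles of the two tip-to-tip patristic
(branch-length) distance matrices. Patristic rather than purely
topological distances were chosen because the score should respond to
branch-length as well as branching-order discordance; the choice is
configurable by supplying externally built trees (any newick trees over
the same tips can be scored). If the outgroup is not monophyletic in a
window, the tree is rooted on the first outgroup tip and flagged.
`clade_recovery()` reports how often each node of the genome tree is
monophyletic across window trees.

# Landscape PCA, autocorrelation, outlier scan

`landscape_pca()` performs correlation-matrix PCA of the
window-by-variable matrix (taxa for π; taxon pairs for d~xy~/F~ST~),
with listwise deletion of windows containing missing values (the count
is reported; no imputation is attempted). The PC1 sign is fixed so that
the mean loading is non-negative — "high PC1 = high statistic". When
landscapes share most of their topography, PC1 is nearly the per-window
mean of the standardized variables; the row mean is returned so that
this consistency can be checked (r² is typically > 0.99 on
strong-shared-signal data).

`autocorrelation_test()` measures, per linkage group, the Pearson
correlation between the window series and itself shifted by
`k = round(lag_bp / grid step)` windows (the default 2-Mbp lag gives
k = 4 on a 500-kb non-overlapping grid). The null distribution permutes
the genome-wide values jointly across positions and recomputes the
per-LG coefficient; the p-value is one-sided (clustering means positive
autocorrelation) with the +1 correction so p is never exactly zero.

`outlier_deviation()` subtracts the Z-transformed PC1 landscape from one
pair's Z-F~ST~ landscape and ranks windows by the deviation, the scan
that exposes lineage-specific selective sweeps (such as a large-effect
flower-color locus) as sharp positive departures from the shared
pattern. No multiple-testing machinery is attached: the scan is
descriptive and rank-based.

# Divergence-time trajectories and the phylogenetic correction

`pair_correlations()` computes, for every taxon pair, the correlations
that diagnose landscape evolution — mean pair π vs gene count, mean
pair π vs recombination rate, F~ST~ vs both covariates, d~xy~ vs π and
F~ST~ vs π — and attaches each pair's net divergence d~a~ as its time
proxy. Pairwise comparisons among n taxa are not independent (they
share internal branches), so `independent_contrasts()` applies the
correction for pairwise data: every pair maps to the internal node that
is the MRCA of its two taxa, and each node contributes the unweighted
mean of its pairs' values — n − 1 independent points for n taxa (8 for
9). Pairs are not weighted by window count within a node; the node mean
is a summary of comparisons, not a meta-analysis, and the unweighted
form keeps the points exchangeable. Trend lines through the contrasts
are plain least squares.

# Introgression statistics

`polarize_sites()` keeps biallelic sites at which the outgroup is fixed
(at least two genotyped outgroup individuals, frequency exactly 0 or 1)
and calls the non-outgroup allele derived. With derived frequencies p1,
p2, p3 and an ancestral outgroup, the frequency-weighted pattern counts
are `ABBA = (1 − p1) p2 p3` and `BABA = p1 (1 − p2) p3`, and
`D = (ΣABBA − ΣBABA)/(ΣABBA + ΣBABA)`.

Significance uses a weighted delete-one block jackknife over contiguous
500-kb blocks: block weights are each block's share of the total pattern
weight, the variance is the pseudovalue form for unequal block sizes,
and `Z = D/SE` is referred to the normal. The genome-wide admixture
proportion compares the observed excess to the excess expected under
complete admixture, estimated by splitting the P3 sample into two
random halves (one half standing in for P2): `f = S(P1, P2, P3)/S(P1,
P3a, P3b)`. The split is drawn once from a recorded seed; with an odd
P3 sample the halves differ by one individual.

The window statistic f~d~ uses the dynamic donor: at each site the
donor is whichever of P2/P3 has the higher derived frequency. f~d~ is
designed for ABBA excess, so tests with negative genome-wide D have P1
and P2 swapped (and flagged) before windowing; windows with a negative
numerator or non-positive denominator are reported missing — the
statistic is undefined there, and reporting zero would bias window
summaries toward no admixture. `fd_summary()` reduces many tests to
per-window mean and maximum with missing-skip semantics. The set of
four-taxon tests is an explicit input: the package does not guess which
quartets are "appropriate" for a given tree.

`simulate_quartet_sites()` supports calibration experiments: it samples
polarized site frequencies under a no-migration quartet coalescent with
one independent genealogy per site (the infinite-sites,
one-mutation-per-locus limit). In that regime per-site pattern terms are
independent and the block-jackknife test should reject at its nominal
rate; the acceptance suite verifies a two-sided 5% test rejects in
3.5–6.5% of 1,000 replicates. The default design (8/8/8/4 haploid
samples, Ne = 10⁵, splits at 40/80/160 thousand generations, 5,000
sites over fifty 500-kb blocks) was chosen so that a few hundred sites
carry pattern weight in every block; with far fewer weighted sites per
block the jackknife standard error is estimated from heavy-tailed block
sums and the normal reference becomes anti-conservative — a property of
the test, documented here, not corrected away.

# The forward Wright–Fisher simulator

`run_scenario()` drives a discrete-generation, diploid Wright–Fisher
engine (compiled code): multiplicative fitness across sites with
codominance (h = 0.5, the convention of standard forward simulators;
dominance is not otherwise specified by the model), Poisson mutation
and crossover counts on a finite integer-coordinate chromosome with
collision resampling (sites currently segregating cannot be hit again,
and substituted sites stay blocked, keeping every site biallelic with a
known ancestral state). An ancestral population of N diploids evolves
for 10N generations, splits into two daughters of size N, and diverges
for another 10N generations. Selected mutations arise only in the two
distal thirds of the chromosome; the central third is always neutral,
so the chromosome carries a built-in contrast between constrained tails
and an unconstrained center. The six scenarios are: neutral; background
selection (tail mutations deleterious with probability `prop_neg`,
s = −Ns/N); BDM incompatibilities (background selection in the
ancestor — disablable via `ancestral_selection` — and, after the split,
each new selected tail mutation deleterious in one randomly chosen
population and neutral in the other, with symmetric migration);
positive selection; background + positive selection; and local
adaptation (beneficial in one population only, with migration, plus
recruitment of standing neutral tail variation at the split, each
segregating neutral tail mutation becoming locally beneficial with
probability `prop_pos` — the recruitment probability is this package's
concrete reading of "some of the standing variation", recorded in the
configuration). Scenario defaults follow the canonical parameter set
(Ns = 100 for both mutation classes; prop 0.1 for background selection,
0.05 for BDMI with Nm = 0.1, 0.001 for positive selection, 0.1/0.005
for the combined model, 0.001 with Nm = 0.1 for local adaptation).

Statistics are sampled at the split (time 0) and at 10 equally spaced
times during divergence from `n_sample` individuals per population, and
are computed by the same pairwise-mismatch kernel as the empirical
pipeline, with the window length as denominator (the simulated sample
is complete, and every bp is a genotyped site). Neutral variation is
simulated directly in the forward engine rather than overlaid on
recorded genealogies: the overlay is an efficiency device, and the
contract here is on output distributions, which the test suite checks
against coalescent expectations.

`rescale()` applies standard population rescaling (N′ = N/Q, times /Q,
per-bp rates ×Q), preserving θ = 4Nµ, ρ = 4Nr, Ns and Nm while the
per-mutation coefficient grows as s′ = sQ; it warns above s′ = 0.1 and
refuses above 0.5. The desk-scale profile used throughout the tests is
Q = 20 (N′ = 500, 5,000-generation burn-in and divergence), a 2.1-Mbp
chromosome in 50-kb windows — 42 windows, the same window resolution as
a 21-Mbp chromosome in 500-kb windows — and 20 sampled individuals per
population. At this scale a neutral burn-in reproduces π = 4N′µ′ within
a few percent, the split-time F~ST~ is ≈ 0, background selection leaves
the center third a few percent more diverse than the tails, and
positive selection generates strong tail-concentrated differentiation
with r(F~ST~, π) < 0 and a decaying r(d~xy~, π).

# The synthetic radiation generator

`generate_radiation()` emulates the statistical structure the analysis
assumes, not any particular dataset. Windows are simulated as
independent multispecies-coalescent loci under a dated 9-taxon species
tree (an outgroup, a nested ingroup, one very recent split pair —
`radiation_topology()`), with three deliberate idealizations:

* **Independent windows.** There is no linkage disequilibrium between
  windows; spatial structure is injected through the smooth landscape
  tracks instead. This is sufficient for testing every downstream
  window statistic and orders of magnitude cheaper than whole-genome
  simulation; it does *not* emulate within-window LD decay or
  cross-window genealogical correlation, so passing tests say nothing
  about methods that depend on those features.
* **Phenomenological linked selection.** Diversity suppression enters as
  a local-Ne multiplier `λ_w = 1/(1 + α g_w/(ρ_w + ε))` built from the
  gene-density and recombination tracks — gene-dense, low-recombination
  windows coalesce faster. The mechanism-level simulator lives in the
  forward engine; the generator only needs the signature (negative
  π/gene-count and positive π/recombination correlations propagating
  into d~xy~ and F~ST~).
* **I.i.d. missingness.** Genotypes are masked at a flat rate (default
  10%); real missingness is structured by depth and mapping quality.

Admixture events are lineage-reassignment pulses (donor, recipient,
time, fraction) restricted to a window subset drawn once per event;
the ground truth records each window's λ, admixture status and realized
fraction, and (optionally) its genealogy. Defaults: 4 diploids per
ingroup taxon and 3 for the outgroup; Ne = 1.25×10⁵ and µ = 5×10⁻⁸ per
bp, giving θ ≈ 0.025/bp so a 500-bp locus yields ~50–60 segregating
sites over the 70-lineage sample — enough signal per window for
parameter-recovery tests at a few hundred windows. Absolute values of
π here are an order of magnitude above typical empirical values by
design (compressed loci); no attempt is made to match any real
dataset's absolute numbers. `radiation_write()` emits the plain-text
files a real analysis would start from (all-sites VCF, taxon map, gene
BED, genetic-map TSV, truth table, newick genealogies), and the
generated VCF round-trips bit-identically through `load_genotypes()`.

# Numerical and design choices

* Coordinates are 0-based half-open internally; all reports are 1-based
  inclusive (`windows_report()`).
* The top-5% recombination-interval filter is applied genome-wide across
  all interval estimates before window averaging, as a single
  operation; a per-chromosome variant would change window values only
  on chromosomes with atypical rate distributions. Windows overlapped
  by fewer than 3 surviving intervals are missing.
* Genes spanning a window boundary are counted in every window they
  overlap by ≥ 1 bp.
* Invariant sites are explicit records, not an accessible-sites mask,
  which keeps every denominator auditable.
* Half-called diploid genotypes are treated as missing (conservative).
* Multiallelic sites are dropped on load.
* `z_transform()` errors on zero-SD input naming the offending series;
  `landscape_pca()` requires ≥ 3 complete windows; LGs shorter than
  lag + 2 windows return missing autocorrelation.
* Negative d~a~ (possible for very recent splits under sampling noise)
  is clamped to zero with a warning in `divergence_time()`.
* Negative NJ branch lengths are clamped to zero; ties in the outlier
  ranking share the minimum rank.

# Limitations

The K~ST~ weighting under extreme per-site sample-size variation is one
defensible reading of the estimator family and is deliberately isolated
in `kst_from_matrices()`. The f estimator's P3-split makes f mildly
noisy for small P3 samples; the acceptance experiment uses 1,600
independent windows to keep the Monte-Carlo error of f well inside the
recovery band. The simulator is limited to two demes and fixed
selection coefficients per mutation class (no distribution of fitness
effects), and the generator's independence-of-windows assumption rules
out LD-based analyses. None of the numerical results quoted above are
claims about real monkeyflower data; each is computed by the test suite
or the acceptance script from data the package itself generates.
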