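---
title: "Methods: SNP-based population genetics of polymorphic Batesian mimicry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP-based population genetics of polymorphic Batesian mimicry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In several swallowtail butterflies only a fraction of females carry the
mimetic wing pattern that protects against avian predators, even though
mimicry is beneficial. Under negative frequency-dependent selection (NFDS)
the benefit of resembling an unpalatable model species shrinks as mimics
become common relative to the model, so the mimic ratio (MR — the fraction
of mimetic females) is expected to equilibrate at a level set by the local
abundance of the model species rather than by neutral processes. The
competing neutral explanation is isolation by distance: nearby island
populations are genetically closer and should then have similar MRs
regardless of model abundance.

Telling these apart requires (i) neutral genetic distances between island
populations estimated from many nuclear markers, (ii) per-island MR and an
"advantage index" (AI) summarizing model abundance, and (iii) matrix
permutation tests that can ask whether MR differences track AI differences
*after controlling for* genetic (or geographic) distance. `polymimic`
implements that full chain for diploid biallelic SNP matrices, plus a
simulator that generates island metapopulations in which the answer is
known, so every stage of the pipeline is testable without field data.

## Genotype filtering

Reduced-representation genotyping of low-quantity DNA yields patchy
matrices, so filtering is staged and order matters:

1. keep sites with missing fraction strictly below 20% over all
   individuals;
2. drop individuals with strictly more than 30% missing calls over the
   kept sites;
3. recompute site missingness over the remaining individuals and apply the
   20% rule again.

Both thresholds are strict inequalities (a site at exactly 20% missing is
removed), and `FilterReport` records every removal so the counts reconcile
pass by pass. A consequence worth knowing: with the 20% rule, a third-pass
removal can only occur when at least `ceiling(n - m/0.2)` individuals were
dropped in pass 2 (for example, with 20 individuals at least 5), because
the missing count of a kept site must jump from below 20% of the old
denominator to at least 20% of the new one.

Each remaining site is then tested for Hardy–Weinberg equilibrium
separately within every island, with a plain 1-df chi-squared
goodness-of-fit test on the three genotype classes (no continuity
correction, no minimum-expected-count rule, monomorphic samples give
p = 1 by convention). A site is removed if p < 0.05 in *any one* island —
deliberately without multiple-testing correction, since the filter is an
artifact screen, not an inference. Note the power floor: with only three
diploids the largest attainable chi-squared is 3.44 (p = .064), so islands
with fewer than four genotyped individuals can never trigger this filter.

When a sequencing locus carries several SNP sites,
`select_one_snp_per_locus()` retains one uniformly at random, because all
downstream statistics treat sites as unlinked.

## Diversity and divergence statistics

All estimators work on allele frequencies with pairwise deletion of
missing calls; nothing is imputed. Per island:

* observed heterozygosity per polymorphic site (fraction of heterozygotes
  among non-missing individuals), and the small-sample unbiased expected
  heterozygosity `2n/(2n-1) * 2pq`;
* average gene diversity over "usable" loci (within-island missingness
  strictly below 5%): `h = 2N/(2N-1) * (1 - sum p_a^2)` with `2N` allele
  copies, i.e. the probability that two randomly chosen distinct copies
  differ; monomorphic loci contribute 0;
* counts of polymorphic sites and of sites where the island carries an
  allele seen nowhere else.

Reported spreads are population SDs (divisor n) across sites or loci.

Between islands X and Y, the average number of pairwise differences is
`pi_XY = sum_sites [p_X(1-p_Y) + p_Y(1-p_X)]`, in units of differing SNP
sites (a per-site variant sits behind `per_site = TRUE`). Net divergence is
`D_A = pi_XY - (pi_X + pi_Y)/2`, with the within-island terms computed over
the pair's shared site set so that pairwise deletion cannot push `D_A`
above `pi_XY`. Differentiation is `Phi_ST = D_A / pi_XY`, which for these
allele-frequency estimators coincides with the Hudson-style F_ST ratio;
`slatkin_fst()` exposes the same quantity with an optional divergence-time
linearization `F/(1-F)`. Negative estimates are reported as computed —
small negative values are ordinary sampling outcomes, not errors.

## Trees

The individual-level tree treats each diploid as an unphased pair of
allele copies: `concatenate_random_alleles()` emits the two copies per
site in random order (phase is unknown for unlinked loci, so any fixed
order would be arbitrary), and distances between the resulting 0/1
pseudo-sequences use Kimura's two-parameter formula
`d = -1/2 ln[(1-2P-Q) sqrt(1-2Q)]` over pairwise-complete positions.
Because the matrix stores allele counts rather than nucleotides, each
site's transition/transversion class is carried as metadata when known
(the VCF reader derives it from REF/ALT; the simulator assigns classes
with the usual ~2:1 transition bias); without classes every difference is
treated as a transition, which makes the distance a monotone transform of
the p-distance but saturates sooner (`1-2P <= 0`). Saturation raises an
error rather than returning a number; during bootstrapping such replicates
are dropped and counted. With a few hundred sites at realistic allele
frequencies saturation is rare; it becomes likely only for very short
concatenations of intermediate-frequency sites.

Neighbor joining is implemented canonically (Q-criterion, standard branch
lengths, exact on additive matrices) with one documented determinism rule:
ties in Q are broken by the smallest (row, column) pair in the current
node order. Negative branch lengths are kept unless `clamp_negative` is
set. The population-level tree is built from the `D_A` matrix; the
individual-level tree from K2P distances. Bootstrap support resamples SNP
sites (columns) with replacement — resampling individuals would break the
population-sample structure — and annotates each internal bipartition of
the point-estimate tree with its replicate frequency; a consensus tree is
deliberately not the default display.

## Mimicry indices

`MR = mimics / (mimics + nonmimics)` over female counts;
`AI = models / (mimics + models)`, and the stricter variant
`AI_U = models / (mimics + nonmimics + models)` that keeps nonmimetic
females in the denominator (`AI >= AI_U` always). Pairwise island
contrasts enter the Mantel machinery as absolute differences
(`difference_matrix()`); a signed version is excluded because Mantel tests
need distances.

## Mantel and partial Mantel tests

The statistic is the Pearson correlation over the n(n-1)/2 upper
off-diagonal entries. The simple test permutes rows and columns of the
second matrix; the partial test uses the first-order partial correlation
`r_AB.C` and permutes the *raw* entries of A while B and C stay fixed,
recomputing the full statistic each draw (the raw-data permutation scheme;
residual-permutation variants are intentionally not implemented). Design
choices, all surfaced in `TestResult`:

* For `n <= 7` labels all `n!` permutations are enumerated and the p-value
  is the exact fraction of permutations (identity included) at least as
  extreme as the observed statistic — at n = 5 islands there are only 120
  relabelings, so Monte-Carlo sampling would add noise for no benefit.
  In Monte-Carlo mode `p = (1 + #extreme)/(1 + n_perm)`, which cannot
  return 0.
* Ties with the observed statistic count as extreme.
* The default alternative is one-sided "greater", because the NFDS
  prediction (MR differences track AI differences) and isolation by
  distance are directional; two-sided inference is available.

A practical floor follows from exactness: with five labels the smallest
attainable p is 1/120 ≈ 0.0083, and rejection at 0.05 requires the
observed statistic to rank in the top six relabelings.

## The simulator

`simulate_metapopulation()` is a forward Wright–Fisher model chosen for
transparency at desk scale: unlinked biallelic loci, `n_islands` demes of
diploid size N on a one-dimensional chain, per-generation migration
`m_ij = migration_rate_per_km / d_ij`, symmetric mutation, binomial drift,
and a final hypergeometric sample of individuals without replacement.
Defaults emulate the study design the package targets: five islands at
positions 0, 150, 450, 750, 765 km (a north–south chain whose last two
islands are close neighbors), samples of 11/46/12/14/12 diploids, 240
loci, N = 100, migration 0.5 per km per generation (nearest-neighbor
migration fractions 0.003–0.03, hence Nm of order 0.3–3), and 400
generations — long enough for migration–drift balance, so genetic distance
increases with geographic distance rather than with run-length artifacts.
Missingness defaults place a heavy-dropout minority (30% rate at every
10th locus, 45% for two individuals) on a light background (3% / 2%),
which is what the staged filter is designed to digest.

Phenotypes are layered on top, not genetically encoded (no mimicry locus,
no selection on genotypes): each island's equilibrium MR solves the
self-consistent relation `qlogis(MR) = qlogis(AI) + e` with
`AI = M/(F·MR + M)` the advantage index the analysis itself recomputes
from counts, and `e ~ N(0, 0.1)` on the logit scale; mimic counts are then
Binomial(females, MR). Model abundance is deliberately *non-monotone*
along the island chain (default 350, 10, 40, 300, 150) — mirroring systems
where the model species colonized a mid-chain island — so mimic-ratio
differences are orthogonal to geography and to the neutral genetic
structure. This makes the MR–AI association the recoverable truth while
the SNPs evolve neutrally: exactly the configuration the partial Mantel
test is supposed to detect (and the simple MR–genetics test is supposed
*not* to detect).
Ancestral allele frequencies start at 0.5 by default (maximally
informative for filter and estimator tests); `ancestral_freq = "beta"`
draws Beta(0.8, 0.8) starts instead, giving the U-shaped site-frequency
spectrum and lower heterozygosity typical of real SNP panels — the tree
and bootstrap examples use it because short concatenations of
frequency-0.5 sites sit close to the K2P saturation boundary.

What the simulator does *not* emulate: linkage, sequencing error,
ascertainment bias, selection on genotypes, two-dimensional geography.
Passing tests therefore certify the statistical machinery under the stated
generative model, not the biology of any particular archipelago.

## Numerical conventions and degenerate inputs

* Monomorphic HWE input: chi2 = 0, p = 1. `Phi_ST` with `pi_XY = 0`
  (identical monomorphic populations): 0 by convention.
* `F_ST = 1` under linearization returns `Inf` with a warning.
* K2P saturation and all-replicate bootstrap failure raise errors; partial
  Mantel with a control correlation of magnitude 1 is refused as
  degenerate.
* All stochastic steps take explicit seeds; a fixed seed reproduces every
  output bit-for-bit, and the pipeline derives per-stage seeds from one
  master seed.

## Problem sizes used in the test suite

The suite exercises the estimators against brute-force enumeration on
6-individual × 10-locus toys (1,000 draws), neighbor joining against 100
random additive matrices (n ≤ 8), permutation tests against full
enumeration at n ≤ 5 and a 1,000-pair size calibration at n = 5 with 999
permutations, and the end-to-end mimicry pattern on 100 simulated
five-island datasets at the default conditions, with two-deme bootstrap
experiments (200 loci, F_ST ≈ 0.5) for clade support. These sizes were
chosen to make each check statistically meaningful while keeping the whole
suite runnable on a laptop in minutes.

## Known limitations

Exact agreement with published tables from any particular field study is
out of reach by design: those numbers depend on raw-read processing and on
software-specific estimator variants (e.g. AMOVA-based F_ST) that are not
part of this package's scope. The K2P transition/transversion default is a
convention, not an inference; and the one-sided default alternative should
be switched to two-sided when the direction of an association is not
predicted in advance.
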