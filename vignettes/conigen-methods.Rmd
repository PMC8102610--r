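---
title: "Methods and design notes for conigen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for conigen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conigen)
```

`conigen` analyses biallelic SNP panels of strongly structured,
declining species. This vignette records the statistical models the
package implements, the defaults and why they were chosen, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where the underlying methods literature leaves choices
open.

## The genotype substrate

Everything operates on a sample × locus matrix of alternate-allele
dosages (0/1/2, `NA` missing) with per-locus scaffold and 1-based
position annotations (`genotype_matrix`). VCF input is restricted to
biallelic SNPs; dosages are counts of the alternate allele in the `GT`
field. Population structure is supplied as a map of individual →
population → region (lineage) with decimal-degree coordinates.

## Filter cascade

`filter_snps()` applies five stages in a fixed order; stage counts are
order-dependent, so the order is part of the contract and is recorded in
the report: (1) locus call rate < 0.80 removed; (2) minor allele count
< 3; (3) observed heterozygosity > 0.5 (a guard against collapsed
paralogs); (4) LD pruning; (5) samples missing > 25% of calls.

LD pruning follows a windowed scan within each scaffold: for every pair
of retained loci closer than 100 kb whose dosage correlation exceeds the
threshold, one locus is dropped. Three open choices were fixed as
follows:

* **r, not r²** — the threshold 0.5 applies to |r| by default
  (`ld_stat = "r2"` switches), matching the usual phrasing "correlation
  of > 0.5"; the report logs which rule ran.
* **Tie-breaking** — the member with more missing data is dropped,
  ties by later position. Deterministic, and favours completeness.
* **Missing data** — correlations use pairwise-complete observations;
  pairs sharing < 10 samples are not tested (too noisy to act on).

A consequence worth knowing for simulated data: the generator's loci
are unlinked, so pruning removes only chance- and *structure*-correlated
pairs. With strong hierarchical structure many unlinked loci correlate
through lineage membership, so pruning thins divergent loci noticeably —
a real property of LD pruning on structured samples, not an artefact.
`n_dup_loci` plants perfectly duplicated loci when an unambiguous
pruning target is needed.

## Diversity and differentiation

Per-population statistics are computed per locus on genotyped samples
and averaged: *A*, *A*~E~ = 1/Σp², *H*~O~, unbiased
*H*~E~ = (2n/(2n−1))·2pq, *P*~E~ = 2pq, and *F*~IS~ = 1 − *H*~O~/*H*~E~
averaged over polymorphic loci only (monomorphic loci have no defined
*F*~IS~). Populations below 6 individuals are excluded by default — the
usual inclusion rule for tables of this kind.

Pairwise differentiation uses the Nei–Chesser small-sample corrections
with harmonic-mean sample size ñ and heterozygosity correction:

$$\hat H_S = \frac{\tilde n}{\tilde n - 1}\Big(1 - \overline{\sum_a p_{ia}^2} - \frac{H_O}{2\tilde n}\Big), \qquad
\hat H_T = 1 - \sum_a \bar p_a^2 + \frac{\hat H_S}{k\tilde n} - \frac{H_O}{2k\tilde n}$$

followed by Nei's finite-deme correction
$D'_{ST} = \frac{k}{k-1}(\hat H_T - \hat H_S)$ and
$\hat H'_T = \hat H_S + D'_{ST}$ with *k* = 2. The multilocus estimate
is the **ratio of sums**, $F_{ST} = 1 - \sum_l \hat H_S / \sum_l \hat
H'_T$: per-locus ratios are unstable when diversity is low. The
finite-deme correction matters: under a two-deme drift model with
divergence *f*, the corrected estimator recovers *f* itself, whereas
the uncorrected ratio converges to *f*/(2−*f*) — parameter-recovery
tests in the suite check exactly this. Hedrick's standardisation
$G''_{ST} = \frac{k(\hat H'_T - \hat H_S)}{(k\hat H'_T - \hat H_S)(1 - \hat H_S)}$
is applied to the locus-averaged components, so populations fixed for
alternative alleles give exactly 1. Negative estimates near zero are
reported unclamped; clamping is a display decision, not a statistical
one. Significance comes from permuting individuals between the pair
(default 1000 permutations, so the smallest attainable p is 1/1001,
sufficient to report "P ≤ 0.001").

## Kinship

One dosage-based estimator is implemented rather than several: the
allele-matching rate $M_{jk} = \overline{(x y + (2-x)(2-y))/4}$ centred
on the mean within-population sharing,
$\beta_{jk} = (M_{jk} - \bar M)/(1 - \bar M)$ (Weir–Goudet style). On
the kinship scale this gives ≈ 0.25 for parent–offspring and ≈ 0.5 for
duplicates relative to an unrelated baseline. The default flag
threshold 0.125 sits halfway between the second- and third-degree
expectations; both threshold and the derived greedy kin-pruned sample
list (drop the higher-missingness member of each flagged pair) feed the
robustness re-run that `run_pipeline()` performs automatically. With
many close kin in one small population the within-population mean
$\bar M$ is itself inflated, biasing estimates slightly downward; the
planted-kin tests quantify that this stays well clear of the threshold
at realistic kin densities.

## Ordination and spatial autocorrelation

PCoA is classical metric scaling of either Nei (1972) standard
distances between populations, $D = -\ln(J_{xy}/\sqrt{J_x J_y})$, or
Prevosti distances between individuals (mean |dosage difference|/2 over
shared loci). Negative eigenvalues are excluded from the
variance-explained denominator and logged.

The correlogram implements the Smouse–Peakall multivariate coefficient:
squared Prevosti distances are double-centred,
$c_{ij} = -\tfrac12 (d^2_{ij} - \bar d^2_{i\cdot} - \bar d^2_{\cdot j} + \bar d^2_{\cdot\cdot})$,
and for distance class *k*,
$r_k = \sum_{(i,j) \in k} c_{ij} \big/ \sum_{i \in \text{pairs}(k)} c_{ii}$,
with each participating individual counted once in the denominator.
The null permutes whole genotypes across locations (999 permutations by
default) and the envelope is the 2.5/97.5 percentile per class;
p-values are rank-based and two-tailed. Default class edges
{0, 1, 5, 10, 50, 100, 500, 1000} km are log-spaced to resolve both a
short-range (< 5 km) decay and long-range (> 100 km) persistence; real
analyses should set edges from their sampling design. The analysis is
usually restricted to one lineage (`region =`), since lineage-level
divergence otherwise dominates every class.

## The diversity cascade

Per locus, Rao's quadratic entropy with unit mismatch distance between
distinct alleles collapses to $Q_l = 1 - \sum_a p_a^2$; the effective
diversity is $D_l = 1/(1-Q_l)$. Aggregation happens in effective-
diversity space: a stratum's *D* is the arithmetic mean of $D_l$ over
loci and its $Q = 1 - 1/D$. The hierarchical partition is
multiplicative:

$$D_{GT} = D_{AR} \times \overline{D_{WR}}, \qquad
  D_{WR}(r) = D_{AP}(r) \times \overline{D_\alpha(p)},$$

with stratum means weighted by sample size by default
(`weighted = FALSE` gives unweighted means; both modes are exercised in
the tests because the published descriptions of cascade software do not
pin this down — it is the largest reconstruction risk in the package
and is therefore config-switchable and asserted by partition-identity
tests to 1e-9 on every run). δ and β then follow as $1 - 1/D_{AR}$ and
$1 - 1/D_{AP}$. The cascade requires complete data;
`complete_case_panel()` drops any locus with a missing call first.
Bartlett's test compares the per-locus $D_l$ distributions between
regions; because these are far from Gaussian a label-permutation
alternative (`beta_permutation_test`) is provided for the
among-population components.

Sampling bias note: stratum frequencies are used uncorrected, so finite
samples leave a small positive floor under δ even when regions are
identical (≈ 0.002 at 20 individuals per population); tests of the
"identical regions ⇒ δ ≈ 0" property use that scale.

## Rarefaction and prioritisation

Rarefied allelic richness standardises to *g* = 8 gene copies by
hypergeometric rarefaction,
$AR = \sum_a \big(1 - \binom{N - N_a}{g}/\binom{N}{g}\big)$, computed
with log-binomials for stability and verified against exhaustive
enumeration of all subsamples for every configuration with N ≤ 12. Loci
where any group holds fewer than *g* copies are excluded for all groups
(listwise default) so every group's value shares one locus panel;
per-group skipping is available. The leave-one-out contribution
$C_i = (AR(t) - AR(-i))/(AR(t) - 1)$ is the proportional loss of
standardised richness if group *i* were lost; the formula is read with
the full numerator difference, the only precedence that yields a
bounded proportional loss. Negative contributions are meaningful: a
depauperate group can raise pooled rarefied richness when removed.

The reserve-selection analysis solves maximum coverage of alleles
exactly: with ≤ ~10 candidate groups and unit costs, all
$\binom{G}{b}$ subsets are enumerated per budget *b* — no heuristic
solver is needed and the optimum is certified by construction (a
brute-force oracle re-checks it in the tests). Each of 100 iterations
resamples 4 individuals per group, so selection frequencies across
iterations express sampling robustness; ties on coverage are broken by
the rarefied richness of the selected union and then lexicographically,
never randomly, so frequency splits reflect resampling variation only.
Small populations should be merged into one group beforehand via a
`group` column in the map, mirroring the usual practice of pooling
under-sampled localities within a region.

## Niche hypervolumes

Environmental tables (five continuous variables: annual rainfall,
maximum temperature of the hottest month, minimum temperature of the
coldest month, elevation, ruggedness) are standardised to pooled
z-scores; each group's occupied region is modelled by a one-class SVM
(radial kernel, ν = 0.1). The kernel bandwidth defaults to 0.4 × the
median pairwise distance. This scaling of the median heuristic was
calibrated once against a known-volume benchmark — a uniform hypercube
sample, where the raw median bandwidth lets the boundary spill far
beyond the data (≈ +60% volume) while 0.4× recovers the true volume
within a few percent — and is configurable along with ν.

Volumes are Monte-Carlo estimates: uniform points in the group's
bounding box inflated by 50% of each dimension's range, volume = box
volume × inclusion fraction, with a reported standard error (default
10⁵ points). Each group's volume uses its *own* box: when niches are
disjoint, a pooled box would leave too few points inside a tight niche
to resolve it at all. Overlap statistics instead classify one shared
point set over the union of the two boxes, so the box volume cancels in
Jaccard = V∩/V∪ and Sørensen = 2V∩/(V₁+V₂), identical boundaries
overlap exactly, and an empty sampled intersection gives exactly zero.
Absolute volumes depend on estimator internals (kernel, ν, margin) and
are comparable only within one configuration; ratios and the
zero/nonzero overlap outcome are the robust quantities.

## The synthetic-data generator

`simulate_dataset()` draws, per locus, a folded ancestral minor-allele
frequency uniform on [0.05, 0.5], then Balding–Nichols Beta-drifted
regional frequencies (parameter `f_region`), population frequencies
within regions (`f_pop`), and Hardy–Weinberg genotypes. Under this
hierarchy the expected differentiation between populations of different
regions compounds as $1 - (1-f_{region})(1-f_{pop})$ (`expected_fst()`),
which the corrected F~ST~ estimator recovers. Defaults emulate a
strongly structured declining mammal: two lineages, four populations of
15/10/6/11 individuals, 10⁴ SNPs, `f_region = 0.5` and `f_pop = 0.05`
(between-lineage F~ST~ ≫ within-lineage), 2% missing calls, lineages
~600 km apart with populations ~100 km apart and 2 km within-population
scatter (the within-population spatial scale is a free choice, set so
the shortest correlogram classes are populated), and Gaussian regional
environments whose means are ≥ 6 pooled SDs apart in at least one
dimension — disjoint niches — with later regions given progressively
narrower envelopes to emulate insular lineages confined to restricted
conditions.

Kin planting replaces the third member of a trio with a Mendelian
offspring of the first two, keeping population sizes as configured;
duplicated loci are exact copies placed half a spacing away for pruning
tests. Loci are unlinked and positions synthetic, so LD pruning on
simulated data removes only chance- and structure-correlated pairs (see
above); there is no sequence-level simulation, no selection, and no
isolation-by-distance migration — the generator reproduces
allele-frequency structure, which is all the downstream statistics
consume. Passing tests on these data therefore validates the statistics
and their contracts, not read-level artefacts (allele dropout, depth
variation, batch effects) that real reduced-representation data add
upstream of this package's inputs.

Problem sizes in the test-suite simulations (10³–10⁴ loci, tens of
individuals, 10²–10³ permutations) match the scale of the emulated
study design while keeping the whole suite runnable in well under half
an hour on one core.

## Degenerate inputs and numerical choices

* Empty filter output raises an explicit "empty panel" error, never a
  silent success; filtering is idempotent.
* All-zero distance matrices yield a flagged degenerate ordination.
* A single region collapses the cascade (γ = σ, δ = 0); a
  single-population region has undefined β, reported as `NA`.
* Monomorphic panels make leave-one-out contributions undefined
  (explicit error, since AR(t) = 1).
* Binomial coefficients in rarefaction are computed via `lchoose`
  differences to avoid overflow at large copy numbers.
* Zero-variance environmental dimensions are dropped with a warning
  before SVM fitting.
* Seeds: every stochastic routine either takes a `seed` argument or
  respects the caller's RNG state; `run_pipeline()` derives fixed
  offsets from its single global seed, so a config re-run is
  byte-identical.

## Known limitations

* The cascade's locus-aggregation and stratum-weighting conventions are
  a reconstruction (documented above); other software may aggregate
  differently, so cross-package numeric equality is not guaranteed —
  the partition identities and limiting cases are the tested contract.
* The kinship screen is a flagging device, not a pedigree estimator;
  its baseline shifts with the relatedness composition of each
  population.
* Hypervolume volumes are estimator-relative; only ratios and overlap
  verdicts travel across analyses.
* The permutation F~ST~ test assumes exchangeable individuals under the
  null and is one-sided toward differentiation.
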