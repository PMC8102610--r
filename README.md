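# conigen

Conservation genomics of fragmented, declining mammal populations: a
reproducible post-genotyping pipeline for reduced-representation
(e.g. ddRAD) SNP panels.

Many threatened species persist as a handful of isolated populations,
often split across deeply diverged lineages (for example a mainland
lineage and insular relicts). Managers then face two linked questions:
*where does the species' genetic diversity reside*, and *which
populations must be protected to retain most of it*? `conigen`
implements the full analysis chain used to answer both from a biallelic
SNP matrix, a population map (individual → population → region/lineage,
with coordinates) and a per-sample table of environmental conditions.

## What it computes

* **Filter cascade** (`filter_snps`) — locus call rate ≥ 0.80, minor
  allele count ≥ 3, observed heterozygosity ≤ 0.5, windowed LD pruning
  (|r| > 0.5 within 100 kb), then samples with > 25% missing calls;
  every stage is counted in a `filter_report`.
* **Diversity** (`diversity_table`) — per population: alleles *A*,
  effective alleles *A*<sub>E</sub> = 1/Σp², *H*<sub>O</sub>, unbiased
  *H*<sub>E</sub> = (2n/(2n−1))·2pq, *F*<sub>IS</sub> = 1 −
  *H*<sub>O</sub>/*H*<sub>E</sub>, polymorphic index *P*<sub>E</sub>.
* **Differentiation** (`pairwise_fst`) — Nei (1987) pairwise
  *F*<sub>ST</sub> on Nei–Chesser-corrected gene diversities with the
  k/(k−1) correction on *D*<sub>ST</sub> (so a two-deme drift model with
  divergence *f* is recovered as *F*<sub>ST</sub> ≈ *f*), Hedrick's
  standardised *G″*<sub>ST</sub>, and permutation p-values.
* **Kinship screening** (`kinship_screen`) — dosage allele-sharing
  kinship centred on the within-population mean (parent–offspring ≈
  0.25, duplicates ≈ 0.5), with a deterministic kin-pruned sample list
  for robustness re-analysis.
* **Ordination** (`pcoa`) — classical PCoA of Nei (1972) standard
  distances between populations or Prevosti distances between
  individuals.
* **Spatial autocorrelation** (`autocorrelation`) — the Smouse–Peakall
  multilocus coefficient *r* per geographic distance class with a
  999-permutation null envelope.
* **Diversity cascade** (`cascade`) — Rao-quadratic-entropy diversity
  (per locus *Q* = 1 − Σp², effective diversity *D* = 1/(1−*Q*))
  partitioned multiplicatively into grand-total γ, among-region δ,
  within-region σ, among-population β and within-population α, plus
  Bartlett's test of within-region homogeneity.
* **Prioritisation** (`rarefied_ar`, `loo_contributions`,
  `max_coverage`) — hypergeometric rarefied allelic richness at g = 8
  gene copies, leave-one-out contributions
  (AR(t) − AR(−i))/(AR(t) − 1), and an exact (subset-enumeration)
  maximum-coverage reserve-selection analysis over 100 resampled
  4-individual subsets per population, for budgets of 1–5 populations.
* **Niche hypervolumes** (`niche_hypervolumes`) — one-class-SVM
  occupancy models of 5 environmental dimensions per lineage, with
  Monte-Carlo volume estimates and Jaccard/Sørensen overlap.
* **Simulator** (`simulate_dataset`) — a hierarchical Balding–Nichols
  generator (regions then populations, Beta-drifted allele frequencies,
  Hardy–Weinberg genotypes, plantable kin pairs, duplicated loci,
  missing calls, regional environmental niches) so the entire pipeline
  is testable without restricted field data.

`run_pipeline()` chains all stages with one seed and writes one CSV per
result table plus a run log.

## Worked example

```r
library(conigen)
sim  <- simulate_dataset(sim_config(n_loci = 5000, seed = 11))
filt <- filter_snps(sim$genotypes)
print(filt$report)
#> SNP/sample filter cascade
#>               stage   unit n_in n_removed n_retained
#>     locus_call_rate  locus 5000         0       5000
#>  minor_allele_count  locus 5000      1279       3721
#>        observed_het  locus 3721        79       3642
#>          ld_pruning  locus 3642      1497       2145
#>      sample_missing sample   42         0         42
#> final panel: 42 samples x 2145 loci; 1.52% missing

g <- filt$genotypes
set.seed(11)
pairwise_fst(g, sim$popmap, n_perm = 200)
#> Pairwise Nei F_ST (lower) / Hedrick G''_ST (upper):
#>       pop1  pop2  pop3  pop4
#> pop1 0.000 0.130 0.662 0.652
#> pop2 0.051 0.000 0.660 0.652
#> pop3 0.338 0.337 0.000 0.140
#> pop4 0.331 0.331 0.057 0.000
```

The synthetic design has two lineages (pop1–pop2 vs pop3–pop4): the
between-lineage *F*<sub>ST</sub> (~0.33) dwarfs the within-lineage
values (~0.05), exactly the pattern a drift-fragmented species shows.
The cascade tells the same story in diversity units — about a quarter of
total diversity (γ = 0.345) lies among lineages (δ = 0.088), far more
than among populations within lineages (β ≈ 0.012):

```r
cascade(g, sim$popmap)
#>  parameter  region population      Q
#>      gamma                    0.3447
#>      delta                    0.0883
#>      sigma region1            0.2899
#>      sigma region2            0.2680
#>       beta region1            0.0118
#>       beta region2            0.0130
#>      alpha region1       pop1 0.2815  ...
#> Bartlett within-region homogeneity: P = 0.693

max_coverage(g, sim$popmap, budgets = 1:4, seed = 11)$coverage
#>  budget mean_coverage min_coverage max_coverage mean_AR
#>       1         0.814        0.807        0.820   1.606
#>       2         0.951        0.947        0.955   1.737
#>       3         0.982        0.979        0.985   1.738
#>       4         1.000        1.000        1.000   1.742
```

Protecting one population retains ~81% of detected alleles; adding one
population from the *other* lineage lifts that to ~95% — the classic
diminishing-returns curve that makes the two-lineage minimum explicit.
The niche analysis closes the loop: the two lineages' environmental
hypervolumes do not overlap at all (Jaccard = Sørensen = 0), so neither
population set can stand in for the other ecologically.

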