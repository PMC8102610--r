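Package: conigen
Title: Conservation Genomics of Fragmented Mammal Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reproducible post-genotyping analysis pipeline for
    conservation genomics of declining, fragmented mammal populations.
    Implements SNP and sample filtering of biallelic genotype panels,
    per-population diversity statistics, pairwise Nei F_ST and Hedrick
    G''_ST differentiation with permutation tests, dosage-based kinship
    screening, principal coordinate ordinations, multilocus spatial
    autocorrelation correlograms, a hierarchical diversity cascade
    derived from Rao's quadratic entropy, rarefied allelic richness with
    leave-one-out population contributions, exact maximum-coverage
    prioritisation of populations for allele conservation, and
    environmental niche-hypervolume overlap. A hierarchical
    Balding-Nichols simulator generates synthetic genotype, population
    map and environmental datasets with realistic two-lineage structure
    so that every stage of the pipeline can be exercised and tested
    without access to restricted field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR,
    e1071,
    geosphere
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
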