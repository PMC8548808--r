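Package: ecoploid
Title: Mixed-Ploidy Population Genomics for Parallel Ecotype Divergence
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating parallel ecotype emergence from parallel
    introgression in mixed-ploidy (diploid/polyploid) SNP data sets such as
    ddRADseq panels from autotetraploid fishes. Implements per-individual
    ploidy model selection from allele-balance Gaussian mixtures, Bayesian
    dosage genotyping under arbitrary even ploidy, the Hind/He
    Mendelian-consistency filter with simulation-derived thresholds,
    ploidy-aware differentiation statistics (gene diversity, G_ST-form F_ST,
    Jost's D, D_XY), four-taxon Patterson's D and f4-ratio admixture tests
    with block-jackknife uncertainty, and a locus-partitioned population-tree
    analysis (D_XY-ratio and F_ST-bin partitions with neighbor-joining trees)
    that classifies replicated highland/lowland ecotype pairs into
    secondary-contact, de-novo-emergence, or standing-variation/adaptive-
    introgression scenarios. A scenario simulator built on hierarchical
    Balding-Nichols drift provides ground-truth data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
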