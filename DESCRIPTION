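Package: transmeta
Title: Trans-Ethnic Meta-Regression of GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aggregates genome-wide association study (GWAS) summary
    statistics across genetically diverse populations by meta-regression of
    allelic effects on axes of genetic variation. Axes are derived by
    multi-dimensional scaling of mean pairwise allele-frequency distances
    between studies; per-variant inverse-variance weighted regression
    partitions effect heterogeneity into an ancestry-correlated component and
    a residual component, and yields approximate Bayes' factors for
    fine-mapping with 99% credible sets. Includes fixed-effects
    inverse-variance meta-analysis with Cochran's Q as a comparator, genomic
    control, readers and harmonisers for per-study summary-statistic files,
    and a seeded simulation engine (hierarchical Balding-Nichols allele
    frequencies, Hardy-Weinberg case-control genotypes with
    population-specific odds ratios, mosaic locus haplotypes with
    population-specific linkage disequilibrium) for power, type-I-error and
    fine-mapping calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
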