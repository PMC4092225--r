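Package: cpscan
Title: Common Population-Specific Variant Catalogues, Window Enrichment
    Scans and Selection Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Catalogues variants private to a single population from phased
    multi-population VCF data, locates genomic clusters of common
    population-specific (CPS) variants with non-overlapping 50-SNP and 5-kb
    window scans under a cumulative hypergeometric model, and interrogates
    the enriched regions with haplotype-based (EHH/iHH/iHS, window-level
    iES) and allele-frequency-based (Weir-Cockerham FST, population branch
    statistic) selection scans plus recombination hotspot/coldspot
    enrichment tests. Includes a multi-population Balding-Nichols genotype
    simulator with planted private variants, clusters, sweeps and
    recombination-rate heterogeneity so every stage is testable against a
    known truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
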