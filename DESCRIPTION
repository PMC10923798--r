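Package: contiscan
Title: Speciation-Continuum Genome Scans for Microbial Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed population-genomic scans and gene-flow statistics for
    placing closely related microbial lineages along the speciation continuum.
    Implements sliding-window nucleotide diversity, Watterson's theta,
    Tajima's D, Fu's F(S), absolute divergence (D_XY) and Hudson's F_ST from
    multi-sample SNP data; dual-percentile detection of divergence-outlier
    regions; per-gene McDonald-Kreitman tests with neutrality indices;
    recombination-based gene-flow fractions, per-strain r/m and rho/theta,
    and divergence-probability staging of lineage pairs; and
    isolation-by-distance/environment statistics (Mantel tests, Blomberg's K,
    Pagel's lambda, Kruskal-Wallis with Dunn's post hoc test, ANI clustering).
    A coalescent-based simulator generates complete synthetic datasets with a
    machine-readable truth set for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    phytools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
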