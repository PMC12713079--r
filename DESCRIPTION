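Package: emsburden
Title: Gene-Level Association Mapping for Indexed EMS Mutant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-genetics toolkit for sequenced (indexed) EMS mutant
    libraries, in which every line carries thousands of ultra-rare induced
    point mutations. Reads SnpEff-annotated multi-sample VCFs, applies
    quality and permutation-calibrated population-frequency filters,
    collapses per-site mutations into gene-level burden matrices, and runs a
    dual-pathway genotype-phenotype association: a reverse-genetics
    chi-square enrichment of gene carriers among phenotypically deviant
    lines, and a forward-genetics burden regression, cross-validated by
    top-K intersection with family-wise permutation significance
    thresholds and expression-based candidate prioritisation. Also provides
    spikelet-trajectory geometry typing (quartic fits, 21-node profiles,
    four-region I/N/D spike-type codes) and gene-level pairwise epistasis
    scans with network centrality and node-removal robustness simulation.
    A synthetic EMS-population generator with known ground truth makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
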