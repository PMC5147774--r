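Package: denovotrio
Title: De Novo Mutation Calling, Rate Estimation and Cluster Analysis for
    Parent-Offspring Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing germline de novo mutations from whole-genome
    sequenced parent-offspring trios. Implements seven-criterion trio filtering
    of candidate de novo single-nucleotide variants and short indels,
    probabilistic per-site callability for rate denominators, per-generation
    and per-year mutation rate estimation with Wilson confidence intervals,
    parental-age regression, multi-nucleotide mutation (MNM) cluster detection
    with simulation and permutation null models, strand-collapsed mutational
    spectra and sequence-context motif tests, and association tests of the
    mutation rate with replication timing and meiotic recombination. A fully
    synthetic trio-cohort generator (genome, families, truth mutations,
    read-level observations, covariate tracks) allows every pipeline stage to
    be exercised end to end without access to restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
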