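Package: mtrelapse
Title: Mitochondrial Variant Dynamics in Matched Normal, Primary and Relapse Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of mitochondrial (mt) genome variant dynamics across
    matched normal / primary tumor / relapse sample triplets. Applies
    coverage and heteroplasmy-abundance filters to per-sample mt variant
    tables, classifies variants as germline or tumor-specific with
    occurrence patterns, tests for gain of tumor-specific and loss of
    germline variants with Monte Carlo nulls built from uniform draws on
    the observed count range, reconstructs Neighbor-Joining phylogenies of
    multi-relapse patients from binarized heteroplasmy profiles under
    Jukes-Cantor (optionally gamma-corrected) distances with site-bootstrap
    support, and computes reference-normalized 96-trinucleotide-context
    mutation spectra. A synthetic cohort generator with planted dynamics
    makes every pipeline stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    vcfR,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
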