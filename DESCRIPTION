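Package: alloanchor
Title: Candidate-Gene Mapping for Erythrocyte Alloantigen Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for tracing a serologically defined red-blood-cell
    alloantigen system to its causative gene, modelled on the strategy used for
    the chicken D blood system (CD99). Stages: pooled-DNA genome-wide association
    by regression of serology-expected allele counts on SNP-array intensities, a
    confirmation trend-test scan on individual genotypes, candidate-gene
    screening by variant impact class, membrane annotation and line-consistency,
    homozygote-anchored Clark-parsimony haplotype phasing over a marker panel,
    and haplotype-to-serological-allele assignment by anchoring and
    co-segregation with a concordance audit. Ships the published 8-marker CD99
    PACE panel and its 11 haplotypes as a fixture, and a synthetic-data
    generator (pedigrees, DNA pools, intensities, serology with
    heterozygote-only error, annotated variant tables) so every stage is
    testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
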