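Package: mitodemix
Title: Probabilistic Deconvolution of Mitochondrial DNA Mixtures from
    Amplicon Sequencing Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for resolving mixtures of human mitochondrial DNA in
    massively parallel amplicon sequencing data. Implements paired-read
    error correction, primer trimming and removal of nuclear
    mitochondrial segment (NUMT) reads by differential Levenshtein
    alignment; joint estimation of contributor haplogroups and mixture
    proportions by expectation maximization over phylotree-derived read
    likelihoods; augmentation of the candidate set with known contributor
    haplotypes; diagnostic-SNP reporting with partial haplotypes; and a
    fully seeded in-silico amplicon mixture generator with truth
    manifests for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    S4Vectors,
    jsonlite,
    yaml,
    optparse,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
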