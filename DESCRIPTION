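Package: ebsrmap
Title: Bulked-Segregant RNA-Seq Mapping of EMS-Induced Recessive Mutants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps EMS-induced recessive mutations from bulked-segregant
    RNA-seq experiments. Reads pooled variant calls (VCF with per-sample
    allele depths) for a mutant bulk and its wild-type sibling bulk,
    applies high-confidence SNP filters (per-pool coverage, detection in
    both pools, cross-line blacklist), computes per-site SNP indices and
    their difference (D-value), localizes the linked chromosome, and calls
    candidate genes carrying large-effect variants. Includes a Monte Carlo
    calibration of the D-value threshold under binomial genotype sampling,
    Poisson sequencing depth and Gaussian technical noise, an EMS
    mutation-spectrum diagnostic, and a synthetic-experiment generator
    that emulates the segregation structure of selfed M2 ears for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
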