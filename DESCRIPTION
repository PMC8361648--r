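Package: mutmapr
Title: MutMap Bulked-Segregant Candidate Gene Mapping for EMS-Induced Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate causal genes for recessive EMS-induced
    mutants in selfing crops by the MutMap bulked-segregant strategy.
    Computes the per-site SNP index (mutant-allele read fraction) in an F2
    mutant-phenotype bulk from parental and bulk variant calls, runs a
    sliding-window genome scan, and applies the filter cascade used in
    practice (homozygous parental difference, low-index removal, SNP index
    of one, EMS transition typicality, large-effect annotation). Also
    provides Mendelian segregation chi-square tests with Yates continuity
    correction, a KASP-style genotype-phenotype co-segregation check,
    2^-ddCt relative expression, a simple differential-expression threshold
    filter, and a full synthetic EMS/F2-bulk simulator (genome, gene
    models, mutation spectrum, meiosis with Haldane crossovers, depth
    sampling) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
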