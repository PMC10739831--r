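Package: probesnpaudit
Title: Probe-SNP Auditing and Ancestry-Bias Diagnostics for DNA Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Audits Illumina-style CpG methylation array probes for population
    variants falling inside their hybridization footprint. Designates the 51-bp
    genomic probe region for each CpG assay (handling targeted strand, Infinium
    chemistry type and the single-base-extension position), cross-references the
    regions with biallelic SNPs read from VCF together with a population panel,
    quantifies allele-frequency differentiation of probe SNPs with the
    Weir-Cockerham per-site Fst estimator, and diagnoses technical bias in
    methylation quantitative trait locus (meQTL) results via group comparisons
    and distance-dependent polynomial regression with sequential F-test model
    selection. Ships a Balding-Nichols two-population simulator so the whole
    pipeline is testable without external downloads, and a command-line
    front-end for each stage plus an end-to-end audit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
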