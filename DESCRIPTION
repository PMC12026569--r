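Package: cftrio
Title: Fetal Variant and Copy-Number Inference from Maternal Plasma cfDNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive prenatal screening analysis from maternal-plasma
    cell-free DNA (cfDNA). Implements a binomial mixture model over plasma
    allele counts to estimate the fetal fraction and call fetal genotypes
    against the maternal background, fragment-size-informed maximum-likelihood
    copy-number calling on targeted bins against reference control bins,
    artifact filtering and trio-based classification of paternally inherited
    and de novo variants, and concordance statistics between plasma and
    child/fetus callsets. A seeded synthetic trio-cohort simulator generates
    genotypes, plasma allele counts, cfDNA fragment lengths and bin depths so
    the whole pipeline runs and is tested at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    vcfR,
    GenomicRanges,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
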