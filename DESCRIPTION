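Package: barleyGP
Title: Genomic Prediction of Seed Quality Traits in Barley Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: GBLUP genomic prediction for advanced barley breeding lines:
    VanRaden genomic relationship matrix from SNP chip genotypes, marker and
    line quality control, average-information REML estimation of a
    four-component mixed model (additive genomic, residual line,
    genotype-by-environment and plot residual variance), line-mean
    heritability with delta-method standard errors, and the cross-validation
    designs used to assess prediction accuracy in breeding populations
    (leave-one-out, leave-set-out, leave-family-out, and reduced
    training-population and reduced-marker experiments). Includes a
    breeding-program simulator (biparental crosses, recurrent selfing with
    recombination, replicated multi-environment field trials) so the whole
    pipeline can be exercised and validated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
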