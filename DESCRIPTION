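Package: linecross
Title: QTL Fine-Mapping and Candidate-Gene Dissection in F2 Line Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interval mapping of quantitative trait loci (QTL) in F2 crosses
    between divergent founder lines, in the regression framework of
    line-origin (Haley-Knott) coefficients.  Computes breed-line-origin
    probabilities from multi-allelic marker data, scans chromosomes with
    nested-model F ratios, calibrates significance by permutation and
    localisation by bootstrap, and dissects candidate genes under the QTL
    with standard, marker-assisted and F-drop association tests, pedigree
    haplotype phasing and haplotype-copy regression.  Includes a forward
    simulator of a three-generation pig intercross (pedigree, meiosis,
    microsatellite and SNP genotypes, polygenic and residual variation)
    so that every stage of the pipeline can be validated against known
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    methods,
    Matrix,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
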