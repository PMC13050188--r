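Package: famvar
Title: Genetic Variance from Direct, Indirect Parental, Imprinting and
    Sibling Effects under Random and Assortative Mating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Closed-form single-locus and multilocus genetic variances for
    traits shaped jointly by direct effects, indirect maternal and paternal
    effects, parent-of-origin (imprinting) effects and indirect sibling
    effects, under random and assortative mating, together with the exact
    parent-offspring mating-table enumeration that underlies the formulas.
    Includes a forward-in-time family simulator with phased transmission,
    scenario-based effect sampling and phenotype-ordering assortative mating;
    variance-component decompositions that compare simulation against theory;
    and genomic-relationship analyses of the phenotypic correlation between
    pairs of relatives, including sibling-difference designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
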