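Package: culturekin
Title: Kin Networks, Cultural Trait Assortment and Reproductive Skew
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the adoption of out-group cultural traits in
    co-residing ethnic groups from census data with pedigree links. Builds
    additive-relatedness matrices from mother/father records, assembles
    ego-centric biological- and affinal-kin networks among surveyed
    individuals, tests trait assortment on those networks with node-label
    permutation tests, estimates multinomial reproductive-skew indices
    (Nonacs' B and a normalized M index) with Dirichlet posterior draws and
    group contrasts, and tabulates trait proportions with Pearson chi-square
    comparisons. A synthetic census generator with controllable kinship
    structure, kin-correlated trait adoption and male fertility
    heterogeneity provides ground-truth data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
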