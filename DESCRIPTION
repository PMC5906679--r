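Package: gmcqtl
Title: QTL Mapping and Favorable-Haplotype Exploration for Grain
    Mineral Concentrations in Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the genetics of grain mineral
    concentrations (Fe, Zn, Cd, Mn, Cu, Se) in milled rice grain from
    structured germplasm panels.  Provides a mixed linear model
    genome-wide association scan with VanRaden kinship and principal
    component covariates (EMMA-style restricted maximum likelihood,
    P3D testing), dual-threshold QTL locus calling with interval
    merging and cadmium-locus clustering, comparative-mapping support
    annotation against linkage and literature QTL, candidate-gene
    haplotype construction with Duncan's multiple range test and
    favorable-haplotype classification, a two-subset panel simulator
    with planted causal haplotypes, and an end-to-end reproducible
    pipeline with Manhattan, distribution and haplotype-effect plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
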