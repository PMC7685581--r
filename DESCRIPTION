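Package: pathpls
Title: Pathway Completeness and Geochemistry Coupling in Hot-Spring
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for 16S rRNA surveys of hydrothermal oil-seep
    ("oil site") microbial communities: alpha-diversity of OTU tables,
    taxonomy-driven KEGG-pathway completeness (the ratio of detected to
    required KEGG orthologs per pathway), and two-block partial least
    squares (co-inertia) association between a geochemical block and
    either taxonomic composition or pathway-completeness profiles, with
    permutation significance. Includes readers for OTU, geochemistry,
    annotation and pathway-catalog tables (with below-detection-limit
    semantics and the ICP-MS detection-limit formula) and a seeded
    generator of coupled synthetic datasets with known ground truth so
    the whole chain is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
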