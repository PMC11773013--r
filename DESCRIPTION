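Package: rarewoods
Title: Rarity, Protection Status and Timber Availability from Cluster-Plot
    Forest Inventories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing woody-species rarity and commonness
    (Rabinowitz's eight categories), range/habitat/abundance rarity indices,
    protected-area coverage (protection index), nonparametric species
    richness (bias-corrected Chao1 and ACE), beta-diversity partitioned into
    turnover and nestedness components, and commercial timber availability,
    all from nested cluster-plot forest inventories in which small stems are
    recorded only in a subplot and expanded by design weights. Includes a
    synthetic inventory generator with known ground truth for end-to-end
    validation, and a pipeline that produces per-species assessment tables
    and summary reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
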