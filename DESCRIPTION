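Package: restoscape
Title: Restoration Hotspot Mapping for Savannah Mosaic Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for prioritizing ecosystem restoration across
    heterogeneous savannah-dominated regions. Assigns a potential
    restoration vegetation type (grassland, savannah, woodland and
    forest) to pasture cells from historical and neighbouring native
    landcover, models potential plant species richness with stacked
    presence-background species distribution models evaluated by the
    continuous Boyce index, estimates net total biomass gain from
    localized aboveground-biomass stocks and root:shoot ratios,
    computes moving-window native-vegetation connectivity, and combines
    the metrics into Box-Cox normalized, equally weighted restoration
    hotspot scores. Includes a synthetic landscape generator with known
    ground truth so the full pipeline is testable end-to-end, and a
    separate maximum-surface-temperature climate-risk layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
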