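Package: coastvuln
Title: Integrated Assessment of Coastal Exposure and Social Vulnerability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for integrated, index-based assessment of vulnerability to
    coastal change. Ranks biophysical variables (relief, wave and wind
    exposure, surge potential, natural habitats, shoreline change rates) into
    five exposure classes and combines them into a geometric-mean index of
    exposure (IE) along a sampled coastline; evaluates habitat-loss scenarios
    for coral reefs, mangroves and seagrasses; counts population within a
    buffer of higher-exposure shoreline; builds a census-based social
    vulnerability index (SVI) by log transformation, z-score normalisation
    and quintile ranking; sums SVI and mean IE into an index of vulnerability
    to coastal change (IVCC) with priority/critical classification; and
    validates the indices against hazard-event inventories with Mann-Whitney
    U tests and Spearman rank correlations. A seeded synthetic-region
    generator produces complete coastline, habitat, population, census and
    event data so the full pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
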