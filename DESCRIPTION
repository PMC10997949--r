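Package: swsshrt
Title: Hydraulic Retention Time Modelling for Secondary Water Supply Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models plug-flow hydraulic retention time (HRT) of tap water in
    high-rise buildings served by secondary water supply systems (SWSS):
    storage tanks, pumped risers, gravity down-feed zones and on-floor
    horizontal supply lines. Provides a validated building-topology data
    model, an analytic per-tap HRT calculation with component breakdown, an
    independent plug-flow parcel-tracking oracle, a seeded generator of
    synthetic per-tap water-quality observations (16S rRNA gene copies, Fe,
    Zn, Cu) with calibrated HRT dependence, permutation-based correlation
    analysis, and a configuration-driven command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
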