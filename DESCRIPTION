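Package: wbcure
Title: Curation Toolkit for Multi-Station Whole-Body MRI Sessions
Version: 0.9.0
Authors@R: person("wbcure", "Maintainers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Audit and repair of geometric defects introduced when vendor
    software "composes" multi-station whole-body MRI into a single volume
    (slice overlap and underlap, per-station in-plane offsets, misordered
    stations), detection and correction of Dixon fat-water label swaps,
    harmonisation of imaging sessions onto a common grid with NIfTI export,
    stratified subject-level allocation to study phases by disease category,
    disease-pattern coding and count aggregation, and self-documenting QA
    run records.  Ships a synthetic multi-station Dixon+DWI phantom
    generator with ground-truth defect injection so every detector and
    repair step is verifiable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
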