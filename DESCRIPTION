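Package: splitmem
Title: Split-Membrane Model Toolkit for All-Atom Lipid Bilayers
Version: 0.1.0
Authors@R: person("splitmem", "developers", role = c("aut", "cre"),
    email = "splitmem@example.org")
Description: Transforms all-atom phospholipid bilayer systems into a split
    head/tail representation in which each lipid is cut at the glycerol
    backbone into two independent molecules capped by massless virtual
    sites, held together by flat-bottomed layer restraints. Provides the
    inverse reunification (merge) with nearest-head matching under periodic
    boundaries, readers and writers for GRO, PDB, TOP/ITP and NDX files,
    a validation-analysis battery (lateral diffusion via the Einstein
    relation, acyl-chain order parameters, density profiles, P-N angle,
    area per lipid, bilayer thickness, radial distribution functions),
    and deterministic synthetic bilayer and Brownian-trajectory generators
    so the whole pipeline is testable without running molecular dynamics.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
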