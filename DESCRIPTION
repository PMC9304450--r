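Package: ataamark
Title: Geometric and Biofluidic Biomarkers for Ascending Thoracic Aortic Aneurysm
Version: 0.1.0
Authors@R: person("ataamark", "developers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for a mouse-specific ascending thoracic aortic aneurysm
    (ATAA) biomarker pipeline: Holzapfel-Gasser-Ogden (HGO) constitutive
    fitting of biaxial vessel-wall mechanics, lumped three-element Windkessel
    outlet pressures, Carreau-Yasuda shear-thinning rheology, wall-shear-stress
    derived biomarkers (TAWSS, OSI, Reynolds and Womersley numbers), centerline
    geometry (aortic tortuosity index, maximum diameter), and right-censored
    Tobit regression of biomarkers against lifespan with a pseudo-r-squared.
    Includes seeded synthetic-data generators that emulate biaxial test
    protocols, wall-shear-stress fields, tortuous aneurysmal vessels, inflow
    waveforms, and censored lifespan cohorts, so every pipeline stage can be
    exercised and validated without imaging data or a 3D fluid-structure
    solver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
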