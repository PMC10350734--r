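Package: graftflow
Title: Pulsatile Hemodynamics and Wall Shear Stress Analysis for Femoral
    Endografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale computational hemodynamics of the femoral
    bifurcation in the setting of superficial femoral artery endografts.
    Provides parametric two-dimensional bifurcation geometries with stenosis,
    patch-angioplasty widening and endograft annotations plus a virtual
    angioplasty operator; synthesis and Fourier analysis of duplex-like
    centerline velocity waveforms; closed-form Womersley solutions (tube and
    planar channel) for converting centerline velocity to volumetric flow and
    for inlet velocity profiles; three-element Windkessel (RCR) outlet models
    with parameter tuning; a stabilized finite-element solver for pulsatile
    incompressible Newtonian flow run to cycle periodicity; and wall shear
    stress post-processing including time-averaged wall shear stress (TAWSS)
    maps, low-shear threshold reports and pre/post-intervention comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
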