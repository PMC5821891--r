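Package: pivcflow
Title: Desk-Scale Hemodynamics of Peripheral Intravenous Catheters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reduced-order computational study of saline infusion through a
    peripheral intravenous catheter (PIVC) into an idealized cephalic vein.
    Enumerates clinically relevant catheter configurations (gauge, insertion
    angle, tip position, infusion rate), solves steady incompressible
    two-component blood/saline flow on a 2-D mid-plane domain with a masked
    finite-volume projection scheme, transports blood mass fraction and
    residence time as passive scalars, and computes wall shear stress,
    power-law hemolysis (blood damage), residence-time and venous stasis
    metrics normalized to the patent vein. Includes quadratic wall-shear
    surrogate models over infusion rate with critical-threshold inversion,
    fractional-factorial ANOVA with generalized eta-squared effect sizes,
    analytic flow fixtures for verification, and a study pipeline that runs
    the full parameter sweep and reports tidy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
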