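Package: nephrosim
Title: Steady-State Epithelial Solute and Water Transport Along a Human Nephron
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell-based steady-state simulator of water and solute transport
    along a superficial human nephron, from Bowman space to the papillary tip.
    Fifteen solutes plus protein are tracked through a compliant proximal
    tubule, the loop of Henle, distal segments and coalescing collecting
    ducts. Membrane transport combines Kedem-Katchalsky volume fluxes,
    Goldman-Hodgkin-Katz electrodiffusion, kinetic SGLT2 and NKCC2 carrier
    models, and saturable pump/cotransporter forms; acid-base chemistry uses
    four equilibrium buffer pairs. The package ships a reference parameter
    fixture and reproduces SNGFR-variation, SGLT2-inhibition and
    NKCC2-inhibition experiments, with axial profile tables and urine
    composition reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
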