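Package: ccoflash
Title: Flow-Flash Kinetics of Cytochrome c Oxidase Under a Membrane
    Potential
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models and analyzes the oxidative phase of the cytochrome c
    oxidase catalytic cycle in energized membranes.  Provides a sequential
    first-order reaction scheme (R -> A -> P_R -> F -> F_R -> O) with
    proton-motive-force-dependent rate scaling, a Beer-Lambert observable
    model mapping state occupancies to absorbance changes at 445 and 605
    nm, separable (variable-projection style) multi-exponential trace
    fitting, Nernst-equation calibration of potentiometric dye responses,
    respiratory-control-ratio utilities, and a fully seeded synthetic-data
    generator emulating flow-flash experiments on sub-mitochondrial
    particles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
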