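Package: pcosdyn
Title: Compartmental Dynamics of Infertility Treatment under Polycystic
    Ovary Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the SIT1T2R compartmental model of infertility
    treatment in women with polycystic ovary syndrome: the six-equation
    vector field with conservation and divergence diagnostics, the basic
    reproduction number via next-generation matrices, closed-form free and
    endemic equilibria with residual-based validation, local stability
    classification through Routh-Hurwitz minors, a qualitative (sign)
    stability tester based on the Quirk-Ruppert/Jeffries graph conditions,
    a fixed-step classical Runge-Kutta integrator, and scenario presets
    with end-to-end report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
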