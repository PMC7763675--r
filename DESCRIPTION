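Package: relkin
Title: Release-Kinetics Modelling for Nanocarrier Drug Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of cumulative drug-release curves from spherical
    nanocarriers. Implements the exact sphere-diffusion (desorption) series
    solution, its single-exponential approximation, and a bimodal
    two-population first-order release model; fits all three to time-release
    tables by bounded multi-start least squares scored with a root-mean-square
    deviation statistic over non-trivial (release < 99%) points; converts
    fitted rate constants to surface diffusivities via the linear driving
    force relation K = 15 D / r^2; provides closed-form formulation metrics
    (Solomon-Ciuta intrinsic viscosity, Mark-Houwink-Sakurada molecular
    weight, weight loss, yield, drug loading, entrapment efficiency); screens
    whether a triaxial-ellipsoid guest can traverse metal-organic-framework
    pore windows; and generates seeded synthetic release curves for validating
    the fitting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
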