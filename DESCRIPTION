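Package: treatSIRS
Title: SIRS Epidemic Model with Saturated Incidence and Constant Treatment
Version: 1.0.0
Authors@R: person("treatSIRS", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for a planar SIRS epidemic model with saturated
    incidence beta*S*I/(1 + alpha*I^2), a constant-capacity treatment term, and
    constant immigration of susceptible and infective individuals. Provides
    endemic-equilibrium computation via the model cubic, local classification
    from the Jacobian, global-stability certification through a Dulac function,
    Hopf-bifurcation diagnostics with the first Lyapunov (focal) number, an
    adaptive Dormand-Prince ODE integrator for the full and reduced systems,
    and Poincare return-map detection of unstable periodic orbits by
    backward-time integration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
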