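# treatSIRS

Analysis toolkit for a planar SIRS epidemic model that combines **saturated
incidence** `beta*S*I/(1 + alpha*I^2)`, a **constant-capacity treatment**
term `h(I) = k` (for `I > 0`), and **constant immigration** of both
susceptible (`(1-p)A`) and infective (`pA`) individuals. It is aimed at
epidemic modellers studying how a fixed treatment budget interacts with
behavioral saturation of transmission: the threshold quantity here is

```
R0 = k / (p*A)
```

— treatment capacity over infective inflow (not the classical basic
reproduction number). On the invariant plane `S = N0 - I - R` (`N0 = A/d`)
the model reduces to

```
I' = pA - k + beta*I*(N0 - I - R)/(1 + alpha*I^2) - (d + m)*I
R' = m*I - (d + gamma)*R + k
```

and endemic equilibria are the in-domain positive roots of the cubic

```
f(I) = alpha*(d+m)*I^3 + [beta*(d+gamma+m)/(d+gamma) + (k - pA)*alpha]*I^2
       + [d + m + beta*k/(d+gamma) - beta*N0]*I + (k - pA)
```

mapped through the nullcline `R = (m*I + k)/(d + gamma)`.

The package provides:

* equilibrium finding via the cubic (companion-matrix roots, Vieta
  residual guards, domain filtering, multiplicity-aware tangency handling);
* local classification from the Jacobian and a Dulac-function certificate
  for global stability below threshold, reported honestly as "certified on
  grid";
* Hopf diagnostics: trace-zero condition, the discriminant-like quantity
  `delta`, the closed-form first Lyapunov (focal) number
  `sigma = (1/16) * (2*alpha*(d+gamma)/(beta*I*) - 6*alpha*(d+m))`, a
  numerical focal-value cross-check, and a correct first-Lyapunov
  coefficient for genuine Hopf points (`det J > 0`);
* an adaptive Dormand–Prince 5(4) integrator (Rcpp) for the full 3-D,
  reduced, and time-rescaled systems;
* unstable-limit-cycle detection by backward-time integration with a
  Poincaré return map;
* YAML/JSON configs, JSON reports, CSV trajectories, a CLI
  (`inst/cli/treatSIRS.R`), and a seeded random-parameter generator for
  property tests.

A headline finding, established by the test suite rather than assumed: for
the widely quoted example parameter set bundled with the package, the
trace-zero "Hopf" point is actually a **saddle** (`det J < 0`; the quoted
condition `delta > 0` certifies real eigenvalues `±sqrt(delta)`), so no
periodic orbit exists there at all. The determinant identity
`det J = (d+gamma) * f'(I_e) / (1 + alpha*I_e^2)` makes the smaller of two
endemic equilibria a saddle *always*. Genuine (subcritical) Hopf points do
exist elsewhere in parameter space; a synthetic set with a verified
unstable cycle ships as `cycle_example_params()`. See the vignette
(`vignettes/saturated-treatment-sirs.Rmd`) for the full analysis.

## Worked example

```r
library(treatSIRS)
pr <- example_params()          # A=4.4236, d=k=gamma=0.1, beta=0.01,
                                # m=0.1, alpha=0.3995, p=0.01
find_equilibria(pr)
#> Endemic equilibria (R0 = 2.2606, regime: one_or_two_endemic)
#>           I         R  residual_f residual_rhs in_domain multiplicity
#> 1 -2.067063 -0.533532 5.89806e-16  2.22045e-16     FALSE            1
#> 2  0.250011  0.625006 7.63278e-17  7.63278e-17      TRUE            1
#> 3  1.350497  1.175249 1.17961e-16  5.55112e-17      TRUE            1

eqs <- endemic_equilibria(pr)
hopf_condition(eqs[[1]], pr)
#> Hopf diagnostics at (I*, R*) = (0.250011, 0.625006)
#>   a11 = 0.204988  a12 = -0.00250011  a21 = 0.102497  a22 = -0.204994
#>   trace = -6.44e-06 (residual 6.44e-06), det = -0.041765
#>   delta = 0.0417664 (condition TRUE), omega = 0.204368
#>   sigma = 3.96486 (subcritical)
#>   hopf_point (trace-zero + delta condition): TRUE
#>   genuine_hopf (trace-zero + det > 0): FALSE
```

`R0 = 2.2606`, the equilibria `(0.25, 0.625)` and `(1.3505, 1.1752)`, and
`sigma = 3.965` (4 s.f.) reproduce the reference values; `det < 0` at the
trace-zero point is why no cycle can encircle it. On the synthetic set the
cycle machinery closes the loop:

```r
pc <- cycle_example_params()
find_unstable_cycle(pc, endemic_equilibria(pc)[[2]])
#> Periodic-orbit search (backward-time Poincare return map)
#>   found: TRUE (return map converged)
#>   period = 1.2253051, amplitude_I = 2.4922
#>   section point (I, R) = (0.54234987, 261.14838), residual = 4.68e-08
#>   winding number about (1.28845, 261.148): 1
```

The period is in the model's time units; `residual` is the distance
between successive same-direction crossings of the section `R = R_e`
(convergence threshold `1e-7`).

## Command line

```sh
Rscript inst/cli/treatSIRS.R equilibria --config inst/extdata/bifurcation_example.yaml
Rscript inst/cli/treatSIRS.R cycle --config inst/extdata/cycle_synthetic.yaml --equilibrium-index 2
Rscript inst/cli/treatSIRS.R demo --out report.json
```

Exit codes: 0 ok, 1 analysis failure (e.g. no cycle found), 2 bad input.

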