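---
title: "An SIRS model with saturated incidence and constant treatment: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An SIRS model with saturated incidence and constant treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treatSIRS)
```

## The model

treatSIRS analyses a planar SIRS epidemic model in which three mechanisms
interact:

* **Saturated incidence** $\beta S I / (1 + \alpha I^2)$. The numerator is
  mass-action transmission; the denominator models behavioral inhibition —
  as prevalence $I$ grows, contact behavior changes and the per-capita
  infection force falls off. $\alpha$ (units 1/individuals$^2$) sets how
  quickly inhibition kicks in.
* **Constant-capacity treatment** $h(I) = k$ for $I > 0$, $h(0) = 0$. A
  community treats at its full fixed capacity $k$ (individuals/time)
  whenever any infectives are present, rather than at a rate proportional
  to $I$.
* **Immigration into both classes**: recruitment $A$ splits into $(1-p)A$
  susceptibles and $pA$ infectives, $0 < p < 1$, so the disease is
  continually reseeded.

With natural death rate $d$, recovery rate $m$ and immunity-loss rate
$\gamma$, the full system is

$$S' = (1-p)A - \frac{\beta I S}{1+\alpha I^2} - dS + \gamma R, \qquad
  I' = pA + \frac{\beta I S}{1+\alpha I^2} - (d+m)I - h(I), \qquad
  R' = mI - (d+\gamma)R + h(I).$$

Total population obeys $N' = A - dN$, so $N \to N_0 = A/d$ and the dynamics
of interest live on the plane $S = N_0 - I - R$, giving the reduced planar
system (`rhs_reduced()`)

$$I' = pA - k + \frac{\beta I (N_0 - I - R)}{1+\alpha I^2} - (d+m)I, \qquad
  R' = mI - (d+\gamma)R + k,$$

studied on $D = \{(I,R): I>0,\ R>0,\ I+R<N_0\}$. Multiplying the field by
the positive factor $1+\alpha I^2$ gives an orbitally equivalent polynomial
system (`rhs_rescaled()`): same orbits and equilibria, reparametrized time.

The central dimensionless quantity is
$$R_0 = \frac{k}{pA},$$
the ratio of treatment capacity to infective inflow (`compute_R0()`). It is
*not* the classical basic reproduction number; it controls the equilibrium
structure through the constant term of the equilibrium cubic below.

## Equilibria

Substituting the $R$-nullcline $R = (mI+k)/(d+\gamma)$ into the $I$
equation yields the cubic (`cubic_coefficients()`)

$$f(I) = \alpha(d+m)I^3
  + \Big[\tfrac{\beta(d+\gamma+m)}{d+\gamma} + (k-pA)\alpha\Big]I^2
  + \Big[d+m+\tfrac{\beta k}{d+\gamma} - \beta N_0\Big]I + (k - pA).$$

Endemic equilibria are its positive roots mapped through the nullcline and
filtered by membership in $D$ (`find_equilibria()`). Since
$f(0) = pA(R_0-1)$ and $f(N_0) > 0$ always (provable by regrouping the
terms), $R_0 < 1$ forces at least one root in $(0, N_0)$; across all random
parameter sets we have sampled, that root is unique. For $R_0 > 1$ the
count of in-domain equilibria is **zero, one or two** — zero is generic
under weak transmission, where the cubic factors in the $\beta \to 0$ limit
as $(\alpha I^2+1)\big((d+m)I + (k-pA)\big)$ with no positive root. A claim
sometimes attached to this model, that $R_0 > 1$ always leaves one or two
endemic states, is therefore incorrect; the corresponding acceptance
expectation in our suite is deliberately left failing (see *Where the
reference analysis fails recomputation*).

A structural identity worth recording, since it decides everything that
follows: differentiating $f$ along the nullcline shows

$$\det J(E) = \frac{(d+\gamma)\, f'(I_e)}{1+\alpha I_e^2},$$

where $J$ is the Jacobian of the reduced system at an equilibrium. When two
endemic equilibria exist, $f$ crosses zero downward at the smaller root and
upward at the larger, so **the smaller equilibrium is always a saddle** and
only the larger one can carry complex eigenvalues. This identity is
property-tested against the root pattern of $f$.

## Local and global stability

`jacobian_reduced()` evaluates the closed-form Jacobian (cross-checked
everywhere against central differences of the field) and
`classify_local()` applies the standard trace–determinant classification
with a relative nonhyperbolicity tolerance of $10^{-7}(1+|\det|)$. For
$R_0 < 1$ the unique equilibrium always satisfies $\operatorname{tr} J < 0$,
$\det J > 0$ (all terms of $J_{11}$ are negative there), which the suite
verifies over hundreds of random sets.

For global stability the package uses the Dulac function
$D(I,R) = (1+\alpha I^2)/I$. The divergence of the multiplied field is, in
closed form (`dulac_divergence()`),

$$-\beta - 2\alpha(d+m)I - \frac{pA(1-R_0)}{I^2} + \alpha pA(1-R_0)
  - \frac{d+\gamma}{I} - \alpha I(d+\gamma).$$

**Caveat.** For $R_0 < 1$ five of the six terms are negative, but the
fourth, $+\alpha pA(1-R_0)$, is positive and *can dominate* when $\alpha$
is large relative to the rates: the suite pins a concrete counterexample
with divergence $+0.53$ inside $D$. So the Dulac certificate does not close
for all of the valid parameter space; where the sampled maximum of the
divergence is negative, `global_stability_verdict()` reports global
stability "certified on grid" (a $50\times50$ log-spaced sweep reaching
within $10^{-6}N_0$ of the boundary — a regression guard, not a proof);
where it is not, the verdict is honest `FALSE` even though local stability
still holds and forward simulation still converges in every case we
sampled. Nothing in the package claims a limit cycle exists below
threshold; only the certificate fails.

## Hopf analysis

At an equilibrium of the rescaled system the linearization entries are
(`linearization_entries()`, validated against finite differences)

$$a_{11} = \beta(N_0 - 2I_* - R_*) - (d+m)(1+3\alpha I_*^2)
  - 2pA\alpha(R_0-1)I_*, \quad a_{12} = -\beta I_*,$$
$$a_{21} = m(1+\alpha I_*^2), \qquad a_{22} = -(d+\gamma)(1+\alpha I_*^2).$$

The trace-zero condition is $a_{11} = (d+\gamma)(1+\alpha I_*^2)$.
`hopf_condition()` reports the trace residual together with

$$\delta = (d+\gamma)^2(1+\alpha I_*^2)^2 - m\beta I_*(1+\alpha I_*^2)$$

and the classical gate $\delta > 0$ that is sometimes quoted with this
model. That gate has the sign backwards: at trace zero,
$\delta = -\det J$, so $\delta > 0$ certifies a **hyperbolic saddle** with
eigenvalues $\pm\sqrt\delta$ — not a center. Transforming to the
prescribed normal-form chart ($x = I - I_*$, $X = x$,
$Y = a_{11}x + a_{12}y$, $u = -X$, $v = Y/\sqrt\delta$) and measuring the
linear part numerically confirms it is the symmetric form
$(-\sqrt\delta\, v,\ -\sqrt\delta\, u)$, not the rotation
$(-\sqrt\delta\, v,\ \sqrt\delta\, u)$ a Hopf normal form requires. A
genuine Hopf point needs $\det J > 0$, i.e. $\delta < 0$; `hopf_condition()`
exposes both booleans (`hopf_point` for the quoted conditions,
`genuine_hopf` for trace zero with positive determinant) rather than
silently repairing the condition.

The first Lyapunov (focal) number is kept in its quoted closed form
(`lyapunov_sigma()`),

$$\sigma = \frac{1}{16}\left[\frac{2\alpha(d+\gamma)}{\beta I_*}
  - 6\alpha(d+m)\right],$$

because it reproduces the published value on the example set
($\sigma = 3.965$) and is the normative quantity our acceptance targets
report. Two numerical companions quantify its standing:

* `focal_value_crosscheck()` evaluates the general second/third-partial
  focal-value combination on the transformed field by central differences.
  On the example set it agrees with the closed form **in sign only**
  (estimate $\approx 0.17$ versus $3.965$); the gap is structural, since
  the chart is built around a hyperbolic point where the focal-value
  formula has no dynamical meaning. The test suite freezes the measured
  value instead of widening a tolerance until it "passes".
* `first_lyapunov_coefficient()` computes the standard first Lyapunov
  coefficient in a genuinely rotational chart ($\omega = \sqrt{\det J}$)
  and is the tool to use at a `genuine_hopf` point.

## Cycle detection

An unstable (repelling) limit cycle is attracting for the time-reversed
flow, so `find_unstable_cycle()` integrates backward from a small
displacement off the supplied equilibrium (default $10^{-2}(1,0)$),
monitors crossings of the Poincaré section $\{R = R_e\}$ in a fixed
direction, and declares convergence when successive same-direction section
crossings differ by less than $10^{-7}$ in $I$; the period is the elapsed
time between them. Crossings are refined by cubic Hermite interpolation
between dense samples (interval $5\times10^{-3}$), using the model field
itself for the endpoint derivatives, so crossing times carry
$O(\Delta t^4)$ error and halving the integrator tolerances moves the
detected period by less than $10^{-4}$ relative (tested). Orbits that
leave $D$, collapse onto an equilibrium, or fail to converge within
bounded returns and time produce `found = FALSE` with a diagnostic, never
an exception.

## The example sets

Two parameter sets ship with the package:

* `example_params()` (file `bifurcation_example.yaml`):
  $\beta=0.01$, $m=0.1$, $A=4.4236$, $d=k=\gamma=0.1$, $\alpha=0.3995$,
  $p=0.01$. It has $R_0 = 2.2606$ and endemic equilibria
  $E_1 = (0.25, 0.625)$, $E_2 = (1.3505, 1.1752)$. The value of $A$ was
  evidently tuned to put the trace at $E_1$ on zero (residual
  $\sim 6\times10^{-6}$), and the quoted conditions (`hopf_point`) do hold
  there — but $\det J(E_1) = -0.0398 < 0$, so $E_1$ is a saddle and by
  index theory no periodic orbit can encircle it. Backward integration
  from either equilibrium leaves $D$ or diverges; there is **no limit
  cycle at all** for this set. $E_2$ is a stable focus
  ($\operatorname{tr} = -0.370$, $\det = +0.0348$).
* `cycle_example_params()` (file `cycle_synthetic.yaml`, labelled
  synthetic because it was constructed by numerical search rather than
  taken from any published table): $A=2.88$, $d=0.0108$, $\beta=2.82$,
  $m=8.83$, $\gamma=0.058$, $\alpha=0.00102$, $p=0.916$, $k=6.59$. Its
  larger equilibrium undergoes a genuine subcritical Hopf bifurcation at
  $\gamma^* \approx 0.0539$ (trace zero, $\det > 0$, first Lyapunov
  coefficient $+0.31$); at the shipped $\gamma = 0.058$ the focus is
  stable and encircled by an unstable cycle of period $\approx 1.225$,
  which `find_unstable_cycle()` recovers with return-map residual below
  $10^{-7}$ and winding number 1, and whose two-sided stability (forward
  orbits spiral in from inside, depart outside) is verified by
  simulation.

## Where the reference analysis fails recomputation

The example set arrives with four claims. Recomputation (all of it in the
test suite, none of it assumed) sorts them as follows:

| claim | recomputed status |
|---|---|
| $R_0 = 2.2606$; $E_1=(0.25,0.625)$, $E_2=(1.3505,1.1752)$; $\sigma = 3.965$ | reproduced to printed precision |
| trace-zero and $\delta$ conditions hold at $E_1$ | reproduced (they do hold as formulas) |
| $E_2$ is an unstable saddle | false — $E_2$ is a stable focus; the saddle is $E_1$ |
| an unstable periodic orbit encircles $E_1$ | false — $E_1$ is a saddle; no cycle exists for this set |

Likewise the blanket claims that $R_0>1$ yields one-or-two endemic
equilibria, that the Dulac divergence is negative whenever $R_0<1$, and
that $D$ is positively invariant (for $R_0 > 1$ the reduced field has
$I' = pA - k < 0$ along $I = 0^+$, so orbits below the saddle's stable
manifold exit) all fail on explicit counterexamples kept in the suite.
The acceptance tests assert the original claims at their stated tolerances
and are left **failing deliberately**; weakening them to pass would hide
exactly the findings this package establishes.

## Numerical choices

* **Cubic roots** via companion-matrix eigenvalues, not the closed-form
  solution: stable near double roots. A root is treated as real when
  $|\mathrm{Im}| \le 10^{-9}(1+|\mathrm{Re}|)$; real roots closer than
  $10^{-7}N_0$ are merged and reported with multiplicity 2 (saddle-node
  tangency). Domain filtering applies the strict inequalities of $D$ with
  $10^{-12}\max(1,N_0)$ slack so boundary-grazing roots are not lost to
  round-off. Two exact Vieta identities, evaluated from the raw rates
  rather than the solved coefficients, guard the solver (residuals below
  $10^{-8}$ on well-scaled inputs).
* **Integration** by an in-package Dormand–Prince 5(4) stepper (Rcpp) with
  embedded error control, FSAL, and defaults rtol $10^{-9}$, atol
  $10^{-12}$; no suitable ODE package is available in the supported
  dependency set, and the stepper is validated against the closed form
  $N(t) = N_0 + (N(0)-N_0)e^{-dt}$, time-reversal consistency, and
  tolerance-halving robustness. Step-size collapse raises an explicit
  error with the last valid time. The full system's treatment term is
  discontinuous at $I=0$; when $k > pA$ that face becomes a Filippov
  sliding boundary which a smooth integrator cannot cross — the failure is
  detected (persistent micro-steps) and reported, and sliding-mode
  continuation is out of scope.
* **Hopf tolerance** default $10^{-3}$ relative on the trace residual: the
  example's bifurcation parameter is printed to five digits, which lands
  the trace within about $10^{-4}$ of zero.
* **Random parameter sets** (`random_params()`) draw each rate log-uniform
  on $[10^{-3}, 10]$, $p$ uniform inside $(0,1)$, reject $N_0 > 10^4$, and
  resample $k$ until the requested $R_0$ regime holds. The range spans
  slow/fast rate ratios of $10^4$, wide enough to expose the large-$\alpha$
  Dulac failure and the zero-equilibrium regime; it does not emulate any
  particular disease, and a green property test establishes the algebraic
  facts over this distribution only. All stochastic choices take explicit
  seeds (default 20131121) and restore the caller's RNG state.

## Known limitations

No continuation of the Hopf curve or saddle-node surface in parameter
space; no Floquet multipliers; no center-manifold computation beyond the
first focal value; no sliding-mode (Filippov) dynamics on the $I=0$ face;
grid certification of the Dulac sign is a regression guard, not a proof;
stochastic and age-structured variants are out of scope.
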