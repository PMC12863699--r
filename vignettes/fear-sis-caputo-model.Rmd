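---
title: "A Caputo fractional-order predator-prey model with fear effect and SIS disease in prey"
author: "fearsis authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Caputo fractional-order predator-prey model with fear effect and SIS disease in prey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearsis)
```

## The model

`fearsis` analyzes an eco-epidemiological system with three compartments:
susceptible prey $S$, infected prey $I$, and a predator $P$ that feeds only
on infected prey (pathogen-induced morbidity makes infected individuals the
accessible target). The disease has SIS structure — infected prey recover at
rate $\omega$ back into the susceptible class and can be reinfected — and
predator presence suppresses prey recruitment through a fear factor. Time
evolution uses the Caputo fractional derivative of order
$\alpha \in (0, 1]$, so the rate of change of each population is a weighted
average of its whole history (a memory effect):

$$
\begin{aligned}
{}^{C}\!D^{\alpha}_t S &= \frac{\Lambda}{1+kP} - \mu S - \beta S I + \omega I,\\
{}^{C}\!D^{\alpha}_t I &= \beta S I - (\delta+\omega) I - \frac{m I P}{1+aI},\\
{}^{C}\!D^{\alpha}_t P &= \frac{n I P}{1+aI} - d P.
\end{aligned}
$$

All rates are expressed in the rescaled fractional time unit
(per time$^\alpha$); the package works exclusively in these rescaled
parameters, because every analytical and numerical result of interest is
stated in them. The eleven parameters, their units and the default values
used throughout the numerical experiments (`table2_params()`) are:

| parameter | meaning | units | default |
|---|---|---|---|
| `Lambda` | recruitment of susceptible prey | density/time$^\alpha$ | 10 |
| `k` | fear level | 1/density | 0.4 |
| `mu` | susceptible-prey mortality | 1/time$^\alpha$ | 0.5 |
| `beta` | infection rate | 1/(density·time$^\alpha$) | 1.5 |
| `omega` | recovery rate | 1/time$^\alpha$ | 0.5 |
| `delta` | infected-prey mortality | 1/time$^\alpha$ | 0.5 |
| `m` | predation rate (saturated) | 1/time$^\alpha$ | 4 |
| `a` | half-saturation constant | 1/density | 1 |
| `n` | predator conversion rate | 1/time$^\alpha$ | 1 |
| `d` | predator mortality | 1/time$^\alpha$ | 0.5 |
| `alpha` | Caputo order (memory index) | — | 0.95 |

The defaults are the hypothetical configuration of the published numerical
experiments for this model family; they are not fitted to any particular
species.

## Equilibria and the basic reproduction number

Setting the right-hand side to zero yields three equilibria:

* **PDPF** $(\Lambda/\mu, 0, 0)$ — disease and predator extinct; always
  exists.
* **PFP** $\bigl(\Lambda/(\mu R_0),\, (R_0-1)\Lambda/(\delta R_0),\, 0\bigr)$
  — predator extinct; exists iff the basic reproduction number
  $R_0 = \beta\Lambda / ((\delta+\omega)\mu)$ exceeds 1. At $R_0 = 1$
  exactly it coincides with the PDPF and the package reports it as
  absent-degenerate rather than duplicating the PDPF.
* **CEP** $(\eta, \sigma, \kappa)$ — all three populations positive. The
  predator equation pins $\sigma = d/(n - ad)$ (requiring $n > ad$);
  eliminating $S$ through the infected-prey steady state and substituting
  into the susceptible-prey steady state (multiplied by $1+kP$) gives a
  quadratic $\zeta_1 P^2 + \zeta_2 P + \zeta_3 = 0$ whose coefficients
  `cep_coefficients()` computes symbolically:
  $\zeta_1 = C_1 k$, $\zeta_2 = C_1 + C_0 k$, $\zeta_3 = C_0 - \Lambda$ with
  $C_0 = (\mu+\beta\sigma)(\delta+\omega)/\beta - \omega\sigma$ and
  $C_1 = (\mu+\beta\sigma)\, m /(\beta(1+a\sigma))$.

The $\zeta$ coefficients were **rederived** from the steady-state equations
rather than transcribed, because the typeset fractions of the published
versions are ambiguous. The rederivation is validated by the two anchored
interior equilibria of the default configuration, which it reproduces to all
printed digits:

```{r}
eq_cep(update_params(table2_params(), beta = 0.06))  # published: (18.39, 1, 0.05)
eq_cep(update_params(table2_params(), beta = 0.6))   # published: (6.3, 1, 1.39)
```

One consequence of the rederivation deserves emphasis. Since
$\zeta_1, \zeta_2 > 0$ always, a positive root exists iff $\zeta_3 < 0$,
which works out to $\Lambda > \delta\sigma$ **and**
$R_0 > \Lambda/(\Lambda-\delta\sigma)$. The published existence statement
for this family prints the inequality in the opposite direction
($R_0 < \Lambda/(\Lambda-\delta\sigma)$) and admits $\sigma > \Lambda/\delta$;
both contradict the published numerics themselves (the interior point exists
at $\beta = 0.06$, where $R_0 = 1.2 > 20/19$). The implemented direction is
the one consistent with the algebra and with every anchored coordinate.
Likewise $\eta$ is recovered from the infected-prey steady state as
$\eta = [(\delta+\omega)(1+a\sigma) + m\kappa]/(\beta(1+a\sigma))$, the
parenthesization that reproduces the printed values. The root itself is
computed in the cancellation-free form $\kappa = \zeta_3/q$ with
$q = -(\zeta_2 + \sqrt{\zeta_2^2 - 4\zeta_1\zeta_3})/2$; for $k=0$ the
quadratic degenerates to a linear equation, handled separately.

## Local stability: Matignon cone and fractional Routh-Hurwitz

For a Caputo system the eigenvalues $\lambda_j$ of the Jacobian at an
equilibrium decide stability through their *arguments*, not their real
parts: the equilibrium is locally asymptotically stable iff
$|\arg \lambda_j| > \alpha\pi/2$ for all $j$. The package reports the margin
$m(\alpha) = \alpha\pi/2 - \min_j |\arg\lambda_j|$; a zero crossing of the
margin is the fractional Hopf point.

Classification semantics (`classify_matignon()`): all eigenvalues outside
the cone is `"LAS"`; all inside is `"unstable"`; a complex-conjugate pair
inside the cone with a real eigenvalue outside is also reported
`"unstable"`, because it is the spiral (Hopf-type) instability that feeds a
limit cycle and it is what the literature for this model calls unstable; a
*real* eigenvalue inside with others outside is `"saddle"` (the mixed
hyperbolic structure seen at the PDPF and PFP past their forward
bifurcations). Eigenvalues within `1e-6` rad of the cone boundary, or of
modulus below `1e-10`, make the verdict `"marginal"`.

Equilibrium Jacobians are always evaluated from the general-state analytic
Jacobian (`model_jacobian()`), never from per-equilibrium simplified
formulas: the published simplified characteristic coefficients for the
interior point drop factors, so they serve only as cross-check test cases.
The fractional Routh-Hurwitz criterion (`routh_hurwitz_fractional()`)
provides an independent route to the same verdicts via the characteristic
coefficients and discriminant; the test suite checks the two routes agree on
hundreds of random parameter draws whenever both are decisive.

The predator-invasion eigenvalue of the PFP is reported explicitly as
$\lambda_1 = n\hat I/(1+a\hat I) - d$, read directly from the decoupled
third Jacobian row (the published compound-fraction version of this quantity
is typeset ambiguously; the tests assert the equivalence of the two
readings).

## Global stability predicates

The three Lyapunov-derived sufficient conditions are implemented exactly as
final inequalities (`global_pdpf_condition()`, `global_pfp_condition()`,
`global_cep_condition()`); the Lyapunov function constructions themselves are
out of scope. Because they are sufficient conditions only, a `FALSE` result
means "inconclusive for global stability", never "not globally stable" —
several configurations that simulate as globally attracting fail the
inequalities. The region bound $\gamma$ of the interior-point condition
defaults to $1.01\,\Lambda/\theta$ with $\theta = \min(\mu, \delta, d)$
(the largest admissible decay rate, giving the tightest dissipative bound;
the 1% headroom plays the role of the arbitrary $\varepsilon > 0$ in the
bound, which the source material leaves unspecified). The $\gamma_2$ term
mixes a density with the region bound exactly as published; the dimensional
oddity is retained because the predicate is only sufficient.

## The fractional integrator

`fde_solve()` implements the full-memory Adams-Bashforth-Moulton
predictor-corrector for Caputo initial-value problems: a fractional
rectangle-rule predictor followed by a trapezoid-weight corrector, both over
the entire solution history ($O(N^2)$ work, implemented in C++). No
short-memory truncation is offered in the default path: truncation changes
the effective memory kernel and measurably shifts Hopf thresholds. Weight
tables are precomputed once per integration in the stabilized difference
form $(\ell+1)^\alpha-\ell^\alpha$ and
$(\ell+2)^{\alpha+1}+\ell^{\alpha+1}-2(\ell+1)^{\alpha+1}$, which avoids
cancellation at large lag $\ell$.

Validation is oracle-based:

* at $\alpha = 1$ the scheme reproduces $e^{-t}$ for the linear test
  equation;
* for $\alpha < 1$ it reproduces $E_\alpha(-t^\alpha)$, with
  `mittag_leffler()` as the independent closed form;
* the global-error order estimated by `estimate_convergence_order()` is
  about $\min(2, 1+\alpha)$ (measured as the max-norm error over shared
  grid points against the finest solution — the *endpoint* error
  superconverges and is not a useful order probe);
* at $\alpha = 0.999$ trajectories agree with a stiff classical solver
  (`deSolve::lsoda`) for the same vector field to $10^{-2}$.

`mittag_leffler()` sums the defining power series where the alternating-sum
cancellation stays near $10^{-11}$ (estimated from the largest term
$x^{j^\ast}/\Gamma(\alpha j^\ast + 1)$ at $j^\ast \approx x^{1/\alpha}/\alpha$)
and otherwise switches to the complete-monotonicity spectral integral, with
the quadrature split around the sharp spectral peak that develops as
$\alpha \to 1$. Accuracy is better than $10^{-10}$ for $|z| \le 50$,
verified against 40-digit reference values.

Numerical settings the source material does not specify are fixed as
package defaults: step $h = 0.05$, horizon $t_{\text{end}} = 2000$ for
attractor classification (fractional relaxation is algebraic, so weakly
damped equilibria need long horizons before transients drop below the cycle
tolerance), one corrector pass. Initial conditions for reproducing the
published phase portraits are likewise unspecified there; the package
default perturbs the most interior existing equilibrium by +5% per
component, which suppresses transients, and records every resolved setting
in the run log. States are never clamped inside the vector field; tiny
negative excursions from discretization are tolerated up to $10^{-6}$ by the
non-negativity check. Note that the Holling term has a pole at $I = -1/a$
just below the admissible region: a step too coarse for a fast predation
plunge can overshoot into it and blow up, which the solver reports as an
integration failure carrying the partial trajectory (tests use $h = 0.01$
for stiff random-draw transients).

## Bifurcation analysis

Two routes are provided and cross-checked:

* **Eigenvalue route** (default, deterministic and step-size-free):
  `forward_threshold_beta()` and `predator_invasion_threshold_beta()` are
  closed forms ($R_0 = 1$ and the interior-existence boundary
  $R_0 = \Lambda/(\Lambda-\delta\sigma)$); `find_hopf_threshold()` bisects
  the Matignon margin of the interior equilibrium in any parameter
  (including $\alpha$) to $10^{-6}$, verifies the Hopf eigenvalue structure
  (negative real eigenvalue plus complex pair) at the root, and checks
  transversality by the numerical sign of the margin derivative. When the
  bisected parameter is $\alpha$ itself the closed form
  $\alpha^\ast = (2/\pi)\arctan(\omega_I/\theta_R)$ of the eigenpair
  $\theta_R \pm i\omega_I$ is attached as a cross-check.
* **Simulation route**: `sweep_parameter()` integrates along a monotone
  grid with warm-started continuation, discards the first half of each
  trajectory (`transient_fraction = 0.5`), and classifies cycle versus
  equilibrium by the tail's relative amplitude against
  `amplitude_tol = 1e-2`. Warm starts are floored at $10^{-3}$ per
  component because $S$, $I$, $P = 0$ are invariant planes: a state that has
  decayed onto one could never show invasion as the parameter grows.

On the default configuration the two routes agree: the infection-rate scan
classifies equilibrium/equilibrium/equilibrium/cycle at
$\beta \in \{0.04, 0.052, 0.06, 0.6\}$ and the sweep's equilibrium-to-cycle
transition brackets the bisected Hopf point near $\beta \approx 0.065$
within one grid cell.

### Reference battery and known discrepancies

`reference_report()` recomputes every published reference quantity for the
default configuration and tabulates the comparison. Eleven anchors (the
reproduction numbers, all equilibrium coordinates, the forward and invasion
thresholds, and the infection-rate Hopf point) reproduce to their printed
precision. Three do not and are reported with notes rather than asserted:

* the upper infection-rate Hopf point: the eigenvalue computation gives
  $\approx 1.797$ against a published $\approx 1.8367$ (about 2%);
* the fear-level and memory-index Hopf points: the published values
  ($\approx 2.3165$ and $\approx 0.7367$) cannot be reconciled with an
  independent eigenvalue recomputation under the stated configuration — the
  package finds the fear-level crossing near $k \approx 0.68$ and the order
  crossing at $\alpha^\ast \approx 0.911$ — suggesting a
  caption/configuration mismatch in the source. The package reports its own
  values; they are excluded from the anchored comparisons.

## What the synthetic scenarios do and do not show

All inputs are generated in code (`builtin_scenarios()`): there is no
observational data anywhere in the pipeline. The scenarios emulate the
published numerical experiments — an infection-rate scan crossing every
bifurcation of the model, a fear-level scan, and a memory-index scan — under
hypothetical parameters chosen for their dynamical structure, not fitted to
a real predator-prey system. Passing tests therefore demonstrate internal
mathematical consistency (equilibria annihilate the vector field, eigenvalue
and simulation routes agree, the integrator converges at its theoretical
order), not ecological realism: no demographic stochasticity, no
seasonality, no spatial structure, and no observation error are modeled.

## Problem sizes and tolerances used by the test suite

Property-style tests run on fixed-seed random draws (200-1000 parameter
sets for the existence and residual scans, 500 for the
Routh-Hurwitz/Matignon agreement scan), and simulation-based checks use
$h = 0.05$ with horizons of 200-2000 time units (long horizons only where
attractor classification demands them). Equilibrium residuals are held to
$10^{-8}$ relative, integrator-versus-closed-form errors to $10^{-3}$,
empirical orders to $\pm 0.3$, and printed-value comparisons to the
precision each reference value is stated with. These sizes resolve every
assertion comfortably on a single CPU.

## Known limitations

* Only the Caputo operator is supported (no Caputo-Fabrizio or
  Atangana-Baleanu kernels), no adaptive stepping, and no delay terms.
* The limit cycle itself is not continued (no Floquet analysis, no
  two-parameter bifurcation surfaces).
* Global-stability predicates are sufficient-only, and noticeably
  conservative for this model.
* $R_0$ is the hard-coded closed form for this compartment structure, not a
  general next-generation-matrix engine.
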