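---
title: "The SIT1T2R model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SIT1T2R model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcosdyn)
```

## The model

`pcosdyn` implements a compartmental model of the treatment pathway of
women attending an infertility clinic with polycystic ovary syndrome
(PCOS).  The population attending the clinic is split into susceptible
newcomers $S$, diagnosed patients $I$, a drug-treatment arm $T_1$
(clomiphene citrate + gonadotropin), an IVF arm $T_2$, and recovered
patients $R$; the total $N = S + I + T_1 + T_2 + R$ carries its own rate
equation.  The dynamics are

$$
\begin{aligned}
S'   &= \gamma N - \alpha S - \beta S(\eta T_1 + \zeta T_2) \\
I'   &= -\lambda I - \alpha I + \beta S(\eta T_1 + \zeta T_2) \\
T_1' &= -\mu_1 T_1 - \alpha T_1 + \lambda b I \\
T_2' &= -\mu_2 T_2 - \alpha T_2 + (1-u_1)\mu_1 T_1 + (1-b)\lambda I \\
R'   &= -\alpha R + u_1\mu_1 T_1 + u_2\mu_2 T_2 \\
N'   &= \gamma N - (1-u_2)\mu_2 T_2 - \alpha N
\end{aligned}
$$

Patients arrive at rate $\gamma$ and drop out untreated at rate
$\alpha$; $\beta S(\eta T_1 + \zeta T_2)$ is the relapse force —
treated women returning to the disease (after abortion or ovarian
hyperstimulation) recruit susceptible women into the patient class at a
rate proportional to the treatment speeds $\eta$, $\zeta$ of the two
arms.  Diagnosed patients are assigned to treatment at rate $\lambda$,
a fraction $b$ to the drug arm; the drug arm resolves at rate $\mu_1$
with cure fraction $u_1$ (the remainder progressing to IVF), the IVF
arm at rate $\mu_2$ with cure fraction $u_2$.

### Parameters

| name | meaning | unit | fig7 | fig8 | fig9 |
|------|---------|------|------|------|------|
| `alpha` | drop-out rate | 1/time | 0.3 | 0.16 | 0.16 |
| `gamma` | arrival rate | 1/time | 0.5 | 0.23 | 0.23 |
| `beta`  | relapse rate | 1/(count·time) | 0.05 | 0.05 | 0.05 |
| `lam`   | treatment assignment | 1/time | 0.47 | 0.47 | 0.47 |
| `b`     | drug-arm fraction | — | 0.34 | 0.34 | 0.34 |
| `eta`   | drug-arm speed | 1/time | 0.47 | 0.47 | 0.47 |
| `zeta`  | IVF-arm speed | 1/time | 0.16 | 0.16 | 0.08 |
| `mu1`   | drug-arm resolution | 1/time | 0.9 | 0.9 | 0.9 |
| `mu2`   | IVF-arm resolution | 1/time | 0.92 | 0.92 | 0.96 |
| `u1`    | drug-arm cure fraction | — | 0.04 | 0.04 | 0.04 |
| `u2`    | IVF-arm cure fraction | — | 0.29 | 0.29 | 0.19 |

The three scenario presets correspond to patient strata: `fig7` ages
20–25 and `fig8` ages 25–30, both with ovarian reserve above 3.5
(`fig8` halves the turnover rates $\alpha, \gamma$), and `fig9`
ovarian reserve below 3.5 (slower IVF arm, lower IVF cure fraction).
All three share the initial state $(S, I, T_1, T_2, N, R) =
(15, 30, 27, 12, 104, 20)$, which satisfies the bookkeeping identity
exactly: $15 + 30 + 27 + 12 + 20 = 104$.

**The relapse rate `beta = 0.05` is a package choice.**  The scenario
captions state ten of the eleven parameters and omit $\beta$ entirely.
We fixed it once, on qualitative grounds: over a grid of candidate
values $\beta \in [0.005, 1]$ and horizons $T \in [5, 50]$, the
combination $\beta = 0.05$ with horizon $[0, 25]$ is the only one in
which all three scenarios show interior minima of the treated and
recovered compartments, the `fig7` treatment arms are rising at the end
of the cycle, and no compartment goes negative — the qualitative shape
the scenario narratives describe.  The value was not tuned against any
quantitative target and is a config knob (`beta` in any scenario file).

**The integration horizon is $[0, 25]$ with $M = 50$ steps.**  $M = 50$
is the stated grid size; the horizon endpoints are nowhere stated.  We
chose $t \in [0, 25]$ by the same qualitative criterion as $\beta$
above (at a horizon of 10, for instance, the slower `fig8`/`fig9`
scenarios have not yet turned around, so their minima sit on the grid
endpoint and no interior-minimum comparison is possible for any
$\beta$).  Every report states the horizon it used, and it is
overridable (`t_end`, `M`).

## Structural diagnostics

Summing the five class equations and subtracting the $N$ equation gives
$$ (S'+I'+T_1'+T_2'+R') - N' = \alpha\,\bigl(N - (S+I+T_1+T_2+R)\bigr), $$
i.e. the redundancy of $N$ is exactly preserved by the flow: the
consistency defect obeys $\delta' = -\alpha\,\delta$ and stays zero if
it starts zero.  Rather than eliminating $N$, the package integrates
all six equations and exposes `conservation_residual()` as a free
accuracy check — along a consistent trajectory it should stay at
round-off, and the tests require $\le 10^{-6} N_0$ along all scenario
runs.  A state is accepted as consistent when
$|N - \Sigma| \le 10^{-8}\max(1, N)$ — the identity is exact
analytically, so the slack covers only float drift.

The divergence of the field is
$-6\alpha - \beta(\eta T_1 + \zeta T_2) - \lambda - \mu_1 - \mu_2 + \gamma$
(`sitr_divergence()`, equal to the Jacobian trace by construction and
cross-checked against finite differences in the tests).  The
closed-orbit (Dulac/Stokes) argument for this model is usually run with
the shorter coefficient
$-6\alpha - \beta(\eta T_1 + \zeta T_2) - \mu_1 - \mu_2$, which omits
the $-\lambda$ and $+\gamma$ terms; `divergence_dulac()` exposes it
separately, and we deliberately take no position on which expression
was intended — for all three presets both are negative on the whole
orthant ($\gamma < 6\alpha + \lambda + \mu_1 + \mu_2$), which is what
the no-recurrence conclusion needs.

## Reproduction number and local stability

At the disease-free population ($S = N = S_0$) the infected subsystem
$(I, T_1, T_2)$ linearizes into a relapse part $F$ and a transition
part $K$ (lower triangular with diagonal $\alpha+\lambda$,
$\alpha+\mu_1$, $\alpha+\mu_2$), and
$R_0 = \operatorname{Trace}(F K^{-1})$.  `next_generation()` carries
both the closed-form $K^{-1}$ and a numeric inverse, and the tests
require them to agree to $10^{-10}$ and the closed-form scalar $H$ to
equal the numeric trace to $10^{-12}$ over random parameter sets.

The free equilibrium $Q_0 = (S_0, 0, 0, 0, S_0)$ — mapped into six
compartments with $R = 0$ — is an exact fixed point only when
$\gamma = \alpha$; otherwise the field leaves the residual
$(\gamma-\alpha)S_0$ in the $S$ and $N$ components.  We implement
$Q_0$ as given and surface that residual instead of reinterpreting the
equilibrium.  Its linearization factors into the explicit eigenvalues
$-\alpha$ and $\gamma-\alpha$ and a cubic
$\lambda^3 + a_1\lambda^2 + a_2\lambda + a_3$ whose coefficients
`cubic_coefficients()` evaluates from their closed forms (validated in
the tests against the characteristic polynomial of the
$(I, T_1, T_2)$ Jacobian block).  Under $R_0 < 1$ the Hurwitz minors
$\Delta_2 = a_1a_2 - a_0a_3$ and $\Delta_3 = a_3\Delta_2$ are positive
— this is a theorem, and the property tests confirm it over random
draws — so the classification of `classify_free_equilibrium()` is
driven entirely by the sign of $\gamma - \alpha$: positive gives
"locally stable but not asymptotically stable" (arrivals outpace
drop-outs; treatment is worth attending), zero gives "unstable", and
negative gives "locally asymptotically stable".  The sign test is an
exact comparison, because the parameters are user-specified literals,
and the numeric eigenvalues are reported alongside but never override
the rule.  When $R_0 \ge 1$ the rule's hypothesis fails and the verdict
is `NOT_APPLICABLE`.

## The endemic equilibrium: verbatim transcription plus an oracle

`endemic_equilibrium()` evaluates the published closed-form chain for
$Q^* = (S^*, I^*, T_1^*, T_2^*, N^*)$ literally, including its two
apparent typos: the intermediate scalar $E$ divides by
$\gamma - \alpha$ while $N^*$ divides by $\lambda - \alpha$, and the
$E$ numerator's second term looks dimensionally short of a
$\gamma\lambda b$ factor.  We deliberately do not "correct" the
formulas.  Instead:

* $R^*$, for which no formula is given, is reconstructed from
  $R' = 0$ as $(u_1\mu_1 T_1^* + u_2\mu_2 T_2^*)/\alpha$ (forced);
* the max-norm of the field at the reconstructed point is returned as
  `residual_norm`.  For the presets the $I$, $T_1$, $T_2$, $R$
  equations are satisfied exactly — the component ratios are internally
  consistent — and the defect concentrates in the $S$ and $N$
  equations (`fig7`: 48.04 and 3.61), which is precisely where the two
  suspect denominators enter;
* `solve_equilibrium()` (damped Newton on the analytic Jacobian,
  halving steps up to 50 times, 200 iterations, relative tolerance
  $10^{-10}$ — ordinary robust defaults) is the independent audit.
  Seeded at the closed form for `fig7` it converges to a genuine root
  with negative components, i.e. the printed chain does not correspond
  to an interior fixed point for these parameter values.

Feasibility of $Q^*$ is the verbatim pair of published conditions
($\lambda > \alpha$ plus the displayed product inequality), evaluated
as printed.

## Qualitative (sign) stability

Biological rate constants are error-prone, so it matters when stability
is a consequence of the *sign structure* alone.  `is_sign_stable()`
implements the five-part Quirk–Ruppert/Jeffries test on the sign
pattern of a matrix: nonpositive diagonal; no mutually reinforcing
off-diagonal pair; no directed cycle of length $\ge 3$; in the
undirected pattern graph, the only admissible black/white coloring
(diagonal vertices black, no black vertex with exactly one white
neighbour, every white vertex with a white neighbour) is all-black; and
a pairwise-disjoint edge set covering every zero-diagonal vertex.  Two
printed-source ambiguities are resolved to the field's standard
definitions and flagged here rather than silently fixed: the first
condition is implemented as *diagonal* nonpositivity ($a_{ii} \le 0$;
the stated "for all $i, j$" would reject matrices the source's own
worked example accepts on other grounds), and the directed and
undirected pattern graphs use edge sets
$\{(i,j): a_{ij} \ne 0\}$ and $\{\{i,j\}: a_{ij} \ne 0 \ne a_{ji}\}$
(the printed definitions of the two graphs are typographically
identical, an apparent copy error).

All three combinatorial conditions are decided by exhaustive
enumeration (simple-cycle DFS, $2^{|V - R_A|}$ colorings, recursive
matching search) with a hard cap at $n = 20$ — correctness over scale;
the model needs $n = 5$.  Verdicts depend only on the pattern, and a
Monte-Carlo soundness oracle (`sign_stability_soundness()`: magnitudes
resampled uniformly on $[0.1, 10]$) backs every acceptance in the test
suite.

At the endemic point with $\gamma > \alpha$, the $(5,5)$ entry of the
$(S, I, T_1, T_2, N)$ community matrix is $\gamma - \alpha > 0$, so
the first condition fails and the equilibrium is not sign stable —
clinically a good thing, since structurally locked-in relapse dynamics
would mean a permanently infertile subpopulation.
`qstar_reference_pattern()` ships the published 5×5 reference pattern;
it differs from the computed Jacobian pattern in the single entry
$(2,1)$, where $\partial I'/\partial S = \beta(\eta T_1^* + \zeta
T_2^*) > 0$ but the reference records 0.  The verdict and the diagonal
witness are unaffected; the tests pin down exactly this one-entry
difference.

## Numerical integration

The solver is the classical fixed-step fourth-order Runge–Kutta scheme,
applied to all six components simultaneously (the staged increments
$K_1 \ldots K_4$ with weights $\tfrac16(1,2,2,1)$; the printed stage
notation "$K_{1,i} = h_i(\ldots)$" is read as $h\,f_i(\ldots)$, the
only reading consistent with the update rule).  Design choices:

* **No clipping.**  Negative excursions are reported (first crossing
  time per compartment) and returned as computed; silent projection
  would mask step-size or parameter pathologies.
* **Determinism.**  Identical inputs give bit-identical trajectories;
  report CSVs are written with 12 significant digits so fixtures
  reproduce exactly.
* **Accuracy.**  The tests verify textbook order-4 behaviour — one step
  on $y' = -y$ equals the degree-4 Taylor polynomial, global error
  shrinks ~16× per halving on both the scalar problem and the full
  system against an $M = 10000$ reference — plus agreement with an
  adaptive reference integrator (`deSolve::lsoda` at $10^{-10}$
  tolerances) and exact preservation of the $N$-bookkeeping identity
  along all scenario runs.  On the default grid ($h = 0.5$) the
  trajectories are resolved but not over-resolved; halving the step at
  horizon 10 moves the final state by less than $10^{-5}$ relative.

Problem sizes throughout the suite (1000-draw property loops, a single
$M = 10^4$ reference trajectory, 500-sample eigenvalue oracles) were
chosen so the whole suite is a half-minute run while still exercising
every branch.

## What the scenarios do and do not show

The presets emulate the clinic strata the model was built around:
deterministic, continuous counts, closed parameter values, a shared
printed initial state.  They do not emulate demographic stochasticity,
measurement error, time-varying rates, or any fitting to patient
records (the model has no estimation component, which is why the
package's model object has no `residuals()` method).  Passing tests
therefore certify the mathematics — algebraic identities, stability
classifications, convergence orders — not any predictive claim about
clinic data.

One reported figure-to-figure comparison deserves a caveat.  At the
default conditions the `fig8`/`fig7` ratio of $T_2$ minima computes to
0.44, matching the narrative "half"; the ratio of $R$ minima computes
to 0.90, far from the narrative "approximately 0.25", and a scan of
horizons $[5, 50]$ at the default $\beta$ never brings it below 0.82.
Mechanistically the direction is forced: `fig8` *halves* the drop-out
rate $\alpha$, so its recovered class decays more slowly and its
minimum is *higher*.  The 0.25 claim is reproducible only near
$\beta \approx 0.01$ with a horizon near 33 — a corner in which no
scenario has an interior minimum at the default horizon and the $T_2$
ratio collapses to 0.025, contradicting the other narrative claim.  The
comparison machinery (`compare_scenarios()`) reports whatever the
conditions give; we did not move the conditions to chase either number.

## Known limitations

* The closed-form $Q^*$ chain is transcribed with its inconsistencies;
  users wanting an actual interior equilibrium should treat
  `solve_equilibrium()` as primary and the closed form as provenance.
* The sign-stability tester is exponential by design and refuses
  $n > 20$.
* No adaptive stepping, stiff solvers, or event detection; no
  stochastic (CTMC/SDE) variant; no parameter estimation.
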