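---
title: "Multilevel muscle fatigue simulation: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel muscle fatigue simulation: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatiguesim)
```

`fatiguesim` couples three model layers to predict individual muscle forces
and localized fatigue during high-intensity elbow tasks: rigid-tendon
Hill-type musculotendon mechanics, the revised three-compartment controller
(3CCr) fatigue model, and load-sharing optimization of the muscle redundancy
problem. This vignette is the package's account of those models: what is
assumed, which parameters matter, how the numerics are set up, and what the
synthetic-data tests do and do not demonstrate.

## Musculotendon mechanics

Each muscle is a Hill-type actuator with maximum isometric force $F_0^M$,
optimal fiber length $l_0^M$, tendon slack length $l_S^T$ and pennation
angle $\alpha_0$. The tendon is rigid, so fiber length and velocity follow
directly from the musculotendon geometry at the current elbow angle:
$l^M \cos\alpha = l^{MT} - l_S^T$ with a constant-thickness pennation model
($l^M \sin\alpha = l_0^M \sin\alpha_0$), and $v^M = v^{MT}\cos\alpha$.
Excitation equals activation throughout: there are no activation dynamics
anywhere in the package, so the only state carried through time is the
fatigue compartment state.

The force along the tendon is
$F^{MT} = (F^M_{CE} + F^M_{PE})\cos\alpha$ with
$F^M_{CE} = F_0^M \, a \, f_l(l^M) f_v(v^M)$ and
$F^M_{PE} = F_0^M f_{PE}(l^M)$. Setting $a = 0$ and $a = 1$ gives the
physiological force bounds used by the load-sharing solver,

$$F^{Min} = f_{PE}\,F_0^M \cos\alpha, \qquad
  F^{Max} = (f_l f_v + f_{PE})\,F_0^M \cos\alpha .$$

The dimensionless curves are standard smooth forms chosen by this package
(the modeling literature specifies their qualitative shape, not one
canonical formula); all shape constants live in
`hill_curve_defaults()` and can be overridden per model:

* **Active force-length**: Gaussian $f_l = \exp(-((l/l_0^M - 1)/\gamma)^2)$
  with width $\gamma = 0.45$ — unit value at the optimum, symmetric.
* **Force-velocity**: Hill hyperbola on the shortening side,
  $f_v = (1 + \tilde v)/(1 - \tilde v / k)$ with shape $k = 0.25$, where
  $\tilde v$ is fiber velocity normalized by the maximum shortening
  velocity; zero at maximal shortening, one isometrically, and a smooth
  rise to an eccentric plateau of 1.4 during lengthening.
* **Passive force-length**: zero at and below $l_0^M$, exponential above
  it, reaching $F_0^M$ at a passive strain of 0.6.

The maximum shortening velocity is $10\,l_0^M$ per second per muscle. The
velocity sign convention is lengthening-positive. Because the sources the
musculotendon literature provides differ in these details, numerical
agreement with any particular third-party implementation is not expected;
all qualitative constraints (bounds, monotonicity, symmetry) are enforced
by tests.

## The 3CCr fatigue model

Each muscle's motor-unit pool is split into active ($M_a$), resting
($M_r$) and fatigued ($M_f$) compartments in percent of the pool, so
$M_a + M_r + M_f = 100$ identically. A feedback controller $C(t)$ moves
units between rest and activity to track a target load $TL$ (% of
maximum):

$$C = \begin{cases}
TL - M_a & M_a < TL,\ M_r > TL - M_a\\
M_r & M_a < TL,\ M_r \le TL - M_a\\
TL - M_a & M_a > TL \quad(\text{deactivating})
\end{cases}$$

and the compartments evolve as

$$\dot M_a = C - F M_a,\qquad
  \dot M_f = F M_a - R\,r\,M_f,\qquad
  \dot M_r = -C + R\,r\,M_f,$$

with fatigue rate $F$ (1/s), recovery rate $R$ (1/s) and a rest multiplier
$r$ that equals 1 while $TL > 0$ and `r_rest` ($\ge 1$) during rest.
Printed variants of this model family sometimes carry $R$ instead of $F$
in the active-compartment drain and omit $r$ from one of the recovery
terms; those forms do not conserve the motor-unit pool, which the model
definition requires, so the conservation-consistent equations above are
used and the variants treated as typos.

Two derived quantities close the loop with the mechanics. The residual
force capacity is $100 - M_f$ (% of baseline), and a sustained maximal
effort converges to the closed-form asymptote
$100/(F/R + 1)$ — the balance point of fatigue outflow and recovery
inflow, reproduced by `endurance_asymptote()` and verified against long
simulations. Fatigue lowers only the contractile ceiling:

$$F^{Max}_{fat} = \left(f_l f_v \frac{100 - M_f}{100} + f_{PE}\right)
  F_0^M \cos\alpha ,$$

leaving the passive term untouched.

Reference parameter values: the slow, fatigue-resistant fiber group
(type I + IIa, "group A") uses $F = 0.004$, $R = 0.01$, $r = 1$, a set
constructed so that a 120-s sustained maximal effort costs roughly a
quarter of the force capacity; integrating the model exactly gives a
23.1% decline at 120 s, consistent with that rounded design target (the
acceptance script recomputes this number). The fast-glycolytic group B
fixes $R_B = 0.001$ (anaerobic metabolism, poor recovery during effort)
while $F_B$ and $r_B$ are subject-specific fit targets.

## Load sharing

At each instant the net flexion torque $Q$ from inverse dynamics must be
reproduced by the muscle forces through their signed moment arms $J_i$:

$$\min \sum_i (w_i F_i^{MT})^2 \quad \text{s.t.} \quad
  \sum_i J_i F_i^{MT} = Q,\quad F_i^{Min} \le F_i^{MT} \le F_i^{Max}.$$

With unit weights this is the classical minimum sum-of-squared-forces
criterion; with $w_i$ set to each muscle's fatigue rate $F_i$ (used as a
dimensionless multiplier — units cancel in the argmin) the criterion
prefers fatigue-resistant fibers, reproducing the Henneman size-principle
recruitment order across fiber-type groups. The reported objective uses
the weight-inside-the-square form.

This problem is a separable box-constrained quadratic program with a
single equality constraint. Its KKT conditions give
$F_i(\lambda) = \mathrm{clamp}(\lambda J_i / 2w_i^2,\ F_i^{Min},
F_i^{Max})$ with the achieved torque piecewise linear and non-decreasing
in $\lambda$, so the package solves it *exactly* by sorting the bound
breakpoints and solving the one linear segment that brackets $Q$ — no
iterative solver, no tolerance, and a deterministic unique solution
(strict convexity). No installed package offers this structure-exploiting
solve, hence it is written in-house; tests cross-check it against the
Lagrange closed form (inactive bounds) and a dense grid search (active
bounds).

If $Q$ exceeds what the fatigue-modified ceilings allow, the solver
returns the bound-clamped maximal-torque solution and reports the deficit
as `torque_residual`; no reserve actuator ("hand of God") is added,
because an artificial reserve would silently erase exactly the capacity
deficit the fatigue model is supposed to expose. Sessions continue
through such deficits and log them as failure events. Extensor passive
torque enters the equality constraint through the extensors' own force
variables, whose optimum sits at the passive minimum under pure flexion
demand.

## The coupled session loop

`simulate_protocol()` executes a task protocol (MVCs, static holds, curl
sets, rests) with an explicit one-step coupling: at step $k$ the
load-sharing problem is solved under ceilings from the current compartment
states, activations are back-computed against the fatigue-adjusted
contractile capacity ($a = 1$ means "all non-fatigued units recruited"),
and the per-muscle target loads $TL_i = 100\,a_i$ advance the compartments
to step $k+1$. The one-step lag mirrors the feedback structure of the
modeled system; at the default `dt = 0.01` s its error is negligible
relative to the compartment time constants (hundreds of seconds).

During MVC segments the agonist target loads are forced to 100%
(maximal efforts bypass the redundancy problem) and the available maximal
flexion moment — flexors at their fatigued ceilings, extensors at their
passive minimum — is recorded as the simulated gauge signal. Failure of a
static hold is the first instant this available moment drops below the
demand, linearly interpolated between steps. Cyclic protocols tag their
cycles; the simulator reports equilibrium when every muscle's fatigued
share changes by less than 0.01 percentage points of motor units between
consecutive cycle ends, the balance point at which such work-rest
schedules could continue indefinitely.

## Calibration

Four subject-specific procedures are provided:

* **Length scaling** multiplies $l_0^M$ and $l_S^T$ by the ratio of
  subject to reference musculotendon length with outstretched arm.
* **Moment-arm scale $k_1$**: if the moment arms were correct, the
  actuator-level maximum isometric force extracted from maximal efforts,
  $F_0 = Q^*_{max} / (J_{flex}(f_l f_v + f_{PE}))$, would be identical at
  every posture. $k_1$ rescales the *variation* of every muscle's moment
  arm about its full-extension value,
  $J^*(\varphi) = k_1 (J(\varphi) - J(0°)) + J(0°)$, minimizing the
  standard deviation of the per-trial estimates. The map is anchored at
  extension deliberately: a plain multiplicative rescale cannot change the
  relative spread of the estimates at all (every estimate divides by the
  same factor), which would make the SD objective degenerate — it would
  decrease without bound as the scale grows. The anchored one-parameter
  map is the minimal non-degenerate reading, and $k_1 = 1$ is always in
  the search space, so calibration can never worsen the spread. The
  optimizer is a coarse log-spaced scan followed by golden-section
  refinement in the bracketing subinterval, which is robust to the
  penalty plateaus that appear when extreme $k_1$ values drive estimates
  negative.
* **Force scale $k_2$**: during an MVC the flexors are assumed fully
  active and the extensors passive, so $k_2(t) = Q(t)/Q_{max,flex}(t)$
  pointwise and every muscle's $F_0^M$ (extensors included) is scaled by
  $\max_t k_2$. Recomputing $k_2$ on the scaled model returns 1.
* **Fatigue-parameter fitting**: box-constrained least squares
  (`nlminb`, bounds $F, R \in [10^{-5}, 1]$, $r \in [1, 50]$, fixed
  initial guesses, tolerances $10^{-10}$ — fully deterministic) of the
  forward-simulated active compartment against normalized force measured
  during a sustained maximal effort and a post-rest probe, with
  $TL = 100$ during efforts (maximal efforts recruit everything) and 0
  between them. The group-B variant freezes $R_B$ and fits
  $(F_B, r_B)$ with the fixed group-A contribution included in the
  forward model; a zero group-B force share makes the problem
  unidentifiable and is flagged rather than fit.

The `%decay` statistic that apportions force between fiber groups is
estimated from 0.5-s local linear fits evaluated at the window edges
(plateau start and trace end). A plain window mean would be biased low by
half a window's worth of slope on a steadily decaying trace; the edge fit
is exact for linear decay and retains the noise averaging of the window.
90% of the measured decay is attributed to group B, so
$F_{0,A}^M = F_0^M (100 - 0.9\,\%decay)/100$ and
$F_{0,B}^M = F_0^M \cdot 0.9\,\%decay/100$; the two parts always sum to
the original force exactly. The same force split is applied to all
muscles — per-muscle distributions are representable but there is no
principled way to measure them at joint level.

## Model variants

* **7M**: individual muscles (the reference configuration; the toy
  generator's 4 flexors + 3 extensors mirror the elbow's main actuators).
* **2M**: one flexor and one extensor actuator; parameters are side means
  except $F_0^M$, which sums, and geometry is averaged pointwise on the
  shared angle grid. For identical flexors sharing one geometry the 2M
  and 7M sessions are exactly equivalent (summed forces and equal
  compartments), which the tests verify.
* **14M**: each muscle split into group A and group B sharing its
  geometry, with the fiber-weighted recruitment criterion. Group B's
  activation stays below 1% until its group-A partner is saturated,
  provided the fatigue-rate weights are well separated (the defaults,
  $F_A = 0.004$ vs $F_B = 0.1$, give a ~180-fold separation in the
  squared weights).

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline needs, deterministically
from a seed: toy elbow models (muscle strengths 200–800 N, optimal fiber
lengths 6–16 cm, flexor moment arms peaking mid-flexion, length tables
integrated analytically from the moment arms so the
$J = -\mathrm{d}l^{MT}/\mathrm{d}\varphi$ identity holds by
construction), raised-cosine hammer-curl kinematics with planar forearm
dynamics ($Q$ maximal near the horizontal forearm), MVC gauge traces
driven by the subject's true compartment parameters with i.i.d. Gaussian
noise, and a full benchmark session (baseline MVC triplet, 3 cycles of 3
sets of 10 curls with 90-s rests, MVC triplets between cycles, dumbbell
demand at 65% of rested capacity at the 50° MVC posture).

Deliberately not emulated: muscular potentiation (real second MVC peaks
can exceed the first; traces here are potentiation-free, which is also
why real calibration protocols discard the first maximal effort),
correlated or heteroscedastic gauge noise, motion-capture artifacts, and
any central-fatigue contribution. Passing the parameter-recovery tests
therefore shows the estimators are correct and noise-tolerant under the
stated noise model, not that they are robust to everything real gauges
and electrodes produce.

Subject-level "true" fatigue parameters for the generators are
$F = 0.01$, $R = 0.005$, $r_{rest} = 15$ — mid-range values for an
elbow-flexor pool sitting between the slow and fast group extremes, with
a rest multiplier in the range reported for the 3CCr family. The group-B
truth is $F_B = 0.1$ (full fatigue of type IIx well under a minute),
$R_B = 0.001$, $r_B = 10$.

## Numerical choices

* **Integrator**: fixed-step classical RK4, default `dt = 0.01` s, with a
  clip-at-zero and renormalize-to-100 guard each step. The controller is
  evaluated inside each RK4 stage; its switching surfaces technically
  reduce the local order at crossings, which is immaterial at these step
  sizes (the tests check step-halving self-consistency on smooth
  branches and pool conservation to $10^{-6}$ over $10^4$ steps).
* **Geometry**: cubic (natural spline) interpolation of the tabulated
  length and moment-arm curves; consistency between the two tables is
  checked to 2% relative error at interior grid points.
* **Degenerate inputs**: a musculotendon length at or below the tendon
  slack length raises an error naming the muscle and angle; zero
  contractile capacity with a non-passive force demand is an error; a
  zero-$F_0^M$ muscle (the group-B entry at `pct_decay = 0`) is carried
  with zero-width force bounds.
* **Ties**: the QP solution is unique (strict convexity), so no
  tie-breaking is needed; at the controller boundary $M_a = TL$ both
  printed branches give $C = 0$, which is what the implementation
  returns.
* **Problem sizes in the shipped tests**: session simulations use
  `dt = 0.02`–`0.05` s over tens of seconds and 6–8 work-rest cycles;
  failure-time checks run to a few hundred seconds; fatigue fits use
  60-s decay plus 6-s probe traces sampled at 20 Hz with a 0.05-s
  forward-model step. These sizes were chosen to exercise every coupling
  path at comfortably converged step sizes.

## Known limitations

* The Hill curve formulations are this package's choices; force traces
  will differ numerically from implementations built on other published
  curve sets even for identical parameters.
* The elbow is planar with a prescribed angle trajectory; no multibody
  inverse dynamics, marker processing, wrapping surfaces or via-points.
* No central fatigue, no long-term (slowly reversible) fatigue
  compartment, no potentiation: cyclic schedules that balance fatigue
  and recovery reach a stable equilibrium and would appear sustainable
  indefinitely, which real subjects do not report. The equilibrium flag
  exists precisely to make that model behavior visible.
* Moment-arm calibration rescales the arm's variation about full
  extension; it cannot fix errors that require moving muscle attachment
  points.
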