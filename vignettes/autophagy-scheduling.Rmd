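---
title: "Designing minimum-fuel drug schedules for autophagy control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing minimum-fuel drug schedules for autophagy control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(avctrl)
```

## The model

`avctrl` works with a deliberately minimalist ordinary-differential-equation
model of the kinase network that sets the rate of autophagic vesicle (AV)
synthesis in a single (average) cell. Four kinases are tracked through their
active fractions: MTORC1 (`x1`), ULK1 (`x2`), AMPK (`x3`) and VPS34 (`x4`);
the AV count per cell is `x5`. Two constant physiological inputs, the energy
supply `C_En` and the nutrient supply `C_Nu` (both in `[0, 1]`, low values =
severe starvation stress), drive the network: energy promotes AMPK
deactivation, nutrients promote MTORC1 activation. The regulatory wiring is

* AMPK activates ULK1 (`h23`), ULK1 deactivates AMPK (the `C_En x2 x3` term),
* MTORC1 represses ULK1 (`h21`), while ULK1 and AMPK repress MTORC1
  (`h12`, `h13`) — a double-negative toggle,
* ULK1 activates VPS34 (`h42`), and VPS34 drives AV synthesis:
  `T x5' = k3 x4 - k4 x5`.

Every regulatory influence is an activating Hill function
`h(x) = rb + (rm - rb) x^n / (x^n + theta^n)`. Each kinase fraction obeys a
conservation form `(1 - x) * activation - x * deactivation`, so the box
`0 <= x_i <= 1`, `0 <= x5 <= k3/k4` is forward invariant; `k3/k4` is the
reachable AV-count ceiling.

Six idealized drug types act through repressive Hill multipliers
`H(w) = rm - (rm - rb) w^n / (w^n + theta^n)` applied to individual rate
terms: (1) an MTORC1 kinase inhibitor, (2) a dual-specificity MTORC1+VPS34
inhibitor (its factor appears in both the MTORC1-activation and the
VPS34-activation terms), (3) an ULK1 inhibitor, (4) a drug suppressing AMPK
activation, (5) a drug suppressing AMPK *de*activation (raising AMPK
activity), (6) a VPS34 inhibitor. Because all drug curves have `rm = 1`,
drug-free dynamics are recovered exactly at zero concentration, and multiple
drugs combine multiplicatively (no binding interactions). Pharmacokinetics
are idealized: each concentration obeys `T w' = b u(t) - delta w`, i.e.
instantaneous injection at rate `u >= 0` and first-order clearance; the
Boolean `b` flags which drugs a therapy may use.

Note that the structure above fixes the *directions* of drug action: drug 4
lowers and drug 5 raises AMPK activity (and hence autophagy), because drug
4's multiplier sits on the activation term and drug 5's on the deactivation
term of the AMPK equation.

The right-hand side is implemented twice: a compiled C version (the deSolve
compiled-model interface) used by every integration, and a plain R version
used by the collocation transcription and as an independent cross-check in
the test suite.

## The packaged parameterization

The packaged defaults (`inst/extdata/default_parameters.yaml`) are a tuned
set, found by randomized search plus Nelder-Mead refinement of the
regulation-curve parameters against the reference drug-free phenotypes, and
gated by `verify_calibration()`:

* severe stress (`C_En = C_Nu = 0.1`): stationary AV count of approximately
  37 per cell (the verifier accepts 35-39; the shipped set gives 38.2);
* moderate stress (0.6): sustained oscillations with envelope approximately
  `[20, 27]` (shipped set: `[20.0, 27.0]`);
* replete conditions (1.0): a low stationary count (< 5; shipped set: 1.7);
* drug directions at 0.6: constant doses of drugs 1 and 5 raise, drugs 2, 3,
  4 and 6 lower the long-time AV count.

The AV turnover constants (`k3 = 3.92`, `k4 = k3/40`) put the ceiling at 40
AVs and the AV relaxation time near 10 min, so drug-free transients settle
well within 120 min. Drug clearance rates `delta` (0.012-0.028 per min,
half-lives of roughly 25-60 min) are chosen so concentration decay between
injections is visible on the 240-min design horizon. Drug curves use
`theta = 1` (concentration units), Hill coefficient 2, and residual
activities `rb` of 0.01-0.05, except the AMPK-activation blocker (drug 4)
which is steeper (`theta = 0.5`, `n = 4`) so that full blockade is reachable
below the absolute concentration cap of 2 used by the severe-stress
scenario.

What the calibrated model emulates: the qualitative stress phenotypes
(steady-low / oscillatory / steady-high autophagy), their quantitative
anchors above, and drug-direction pharmacology. What it does not emulate:
mechanistic detail below the four-kinase level (no AMP/ATP or Rag/RHEB
intermediates, no AV maturation stages), cell-to-cell variability, or drug
toxicity beyond the concentration caps. Passing tests therefore certify the
control machinery on this abstraction, not predictions for any particular
cell line.

## Long-time behavior analysis

`classify_long_time()` integrates past a burn-in (default 2000 min), then
observes a window (default 1000 min). The attractor is called oscillatory if
the peak-to-peak `x5` amplitude exceeds 0.5 AV — well below the 7-AV signal
of the moderate-stress limit cycle and well above integrator ripple at the
default tolerances (`rtol 1e-8`, `atol 1e-10`). The representative value is
the time average over an integer number of detected periods (peak-to-peak
timing) when oscillatory, else the terminal value; an envelope still
drifting between window halves is flagged rather than silently classified.
Attractor coexistence can be probed with five fixed initial states (four box
corners plus the drug-free fixed point); the probe set is deterministic.
`phase_diagram()` maps these calls over the `(C_En, C_Nu)` unit square, and
`dose_response()` holds one drug's concentration fixed (bypassing
pharmacokinetics) per dose.

The EC50 of a drug is the constant concentration at which its long-time
effect on the representative AV count, negative or positive, is half of its
saturating magnitude. It is located by a 25-point logarithmic scan spanning
`1e-3` to `1e3` times the drug's `theta`, then bisection to a relative width
of `1e-3`. Two operational choices matter. First, oscillatory conditions are
summarized by the time-averaged count, so EC50s are defined under moderate
stress as well. Second, the monotonicity guard is *relative*: deviations
from a monotone effect smaller than 25% of the saturating magnitude are
tolerated. This matters for drug 2, whose low-dose response is genuinely
biphasic (MTORC1 inhibition first disinhibits autophagy before VPS34
suppression dominates); an absolute guard would spuriously reject its EC50,
while truly non-monotone responses still raise an error naming the
offending doses.

## Therapy design as a minimum-fuel control problem

A therapy is a subset of the six drug types. Starting from a drug-free
stationary (or recurrent) baseline state — for oscillatory baselines, the
recorded point on the limit cycle at the end of burn-in — the design goal is
to bring the AV count into the band `x5f ± epsilon` and hold it there over
the maintenance window `[t0, tf]` (defaults 120 and 240 min), while
minimizing the unweighted total amount of drug injected,
`J = sum_i integral of u_i over [0, tf]`, subject to per-drug concentration
caps `w_i <= w_i^max` and nonnegative injection rates. Both cap conventions
used in practice are packaged: an absolute cap of 2 and `4 x EC50` at the
scenario's condition. The band is enforced on both sides by default; a
one-sided variant (admitting oscillatory solutions, relevant to drug 6,
which cannot quench the oscillation because VPS34 does not feed back into
the oscillator) is available as a flag.

`validate_solution()` is the arbiter of feasibility throughout: it
re-integrates the full model under the candidate schedule with a
high-accuracy adaptive solver, independent of any collocation grid, and
reports the band violation (only inside `[t0, tf]`), per-drug cap
violations, and `J`.

## The pseudo-spectral solver

`solve_ocp()` transcribes the problem on a single Legendre-Gauss-Lobatto
(LGL) grid over the full horizon `[0, tf]`. LGL nodes include both
endpoints, so the initial condition and the horizon end are collocation
points; the band constraint is applied at every node whose mapped time
reaches `t0`. States and controls at the nodes are the decision variables;
the dynamics become defect equalities through the differentiation matrix,
and the objective becomes the LGL quadrature of the running cost. A
property of this transcription is that *every* inequality reduces to a
variable bound (box on states, band on the AV-count nodes, caps on
concentrations, nonnegativity and a finite ceiling `u_max` on rates, pinned
initial state), leaving only the defect equalities nonlinear.

The nonlinear program is solved by the package's augmented-Lagrangian
backend: bound-constrained inner minimizations by projected Gauss-Newton
with an explicit dense defect Jacobian (direct Cholesky solves cope with
the severe conditioning of spectral differentiation, where limited-memory
quasi-Newton methods stall), Levenberg-Marquardt damping, and classical
outer multiplier/penalty updates (multipliers advance only on sufficient
feasibility progress). Defects are scaled per state and variables by their
natural magnitudes so residuals are relative rates of order one. The warm
start is a constant maintenance dose found by bisection on the simulated
window-average AV count, simulated forward — so the initial iterate is
nearly dynamically feasible.

Numerical choices, and why:

* **`N = 48` by default.** The minimum-fuel objective is linear in the
  controls, so optimal schedules are non-smooth (near-impulsive). On very
  dense grids (N of order 80) the NLP can exploit inter-node ripple in the
  concentration states — spectral ringing around non-smooth solutions — and
  the re-integrated trajectory then misses the band badly. `N = 48` resolves
  the 240-min horizon to ~5-minute mid-grid spacing while keeping the
  discretized and continuous dynamics in agreement. `N` remains a user
  parameter, and the solver automatically retries nearby grid orders and
  stiffer initial penalties when validation fails.
* **`u_max = 10` concentration-units/min.** An unbounded rate would make the
  minimum-fuel program unbounded in the impulsive limit; 10 units/min
  delivers a full cap-2 concentration jump in ~12 s, which is impulsive on
  the horizon scale yet integrable.
* **Band margin 0.25 AV.** The band enforced at the collocation nodes is
  tightened by this margin so that the continuous-time trajectory between
  nodes, and the re-integrated trajectory, retain slack against the true
  `±epsilon` band.
* **Schedule extraction.** The deliverable schedule is a staircase (one
  constant rate per interval of a 4-fold refined node grid). Because the
  pharmacokinetics are linear, interval rates are chosen so that *exact* PK
  integration reproduces the NLP's optimal concentration profile at the
  refined grid points, rather than sampling the node controls — removing
  the spectral-vs-staircase representation mismatch, which matters because
  the calibrated network's steady-state dose sensitivity is steep.
* **Entry alignment and polish.** The descent toward a downregulation
  target traverses a dynamically unstable stretch of the network (state
  deviations double every ~5 min), so small representation errors surface
  as a late band entry. The solver measures the re-integrated entry delay
  and advances the schedule by it, then runs a damped Gauss-Newton polish of
  the staircase rates against the true integrator (softplus-smoothed hinge
  residuals of the slightly tightened band, a mild pull toward the band
  center that regularizes weakly damped ringing modes, and cap overshoots).
  A solution is reported `"solved"` only if the NLP converged *and*
  independent re-integration shows a band violation of at most 0.05 AV with
  no cap violation; `"feasible"` marks validated schedules whose NLP stopped
  short of its tolerances.

First-order optimality diagnostics (`check_necessary_conditions()`) recover
costates from the defect multipliers via the quadrature weights (costate =
`-nu / ((tf/2) * wq)` in the package's sign convention) and evaluate each
drug's switching function `1 + costate_w / T` — the coefficient of its rate
in the Hamiltonian. For a minimum-fuel solution, drug is injected only where
the switching function is non-positive; the complementarity residual
`max u * max(0, sigma)` quantifies this. These diagnostics inform, but never
replace, validation by re-integration.

## Known limitations

* Solutions are locally optimal; multi-start perturbations and the retry
  ladder mitigate but cannot remove this.
* Under the packaged calibration, the steep dose sensitivity near a
  downregulation operating point (|dx5/dw| of order 150 AV per
  concentration unit for drug 4) leaves only ~±0.02 of concentration ripple
  inside the ±1 AV band, so maintenance requires near-continuous
  micro-dosing: replenishment must arrive every ~2 min. The textbook
  staircase signature — 80% of the dosage concentrated into pulses covering
  at most 30% of the horizon — therefore holds for the upregulation
  scenario (14% of the horizon) but genuinely fails for the downregulating
  drug-4 monotherapy (34%) and is marginal for the 2+6 dual therapy (31%).
  The corresponding acceptance test is left failing rather than weakened;
  the property is parameterization-dependent, not a property of the method.
* The dual-therapy sequencing observed here (both drugs starting together)
  is one local optimum; sequential protocols are not excluded.
* Costate recovery at the two boundary nodes inherits the usual LGL
  covector boundary artifacts; diagnostics near `t = 0` and `t = tf` should
  be read with that in mind.

## Problem sizes used by the tests and the acceptance script

Behavioral classification uses 2000 min burn-in + 1000 min observation;
the phase diagram is 21 x 21 cells; therapy solves use the default `N = 48`
(the solver may retry 54 and 42), with validation on 1201-point
re-integration at `rtol 1e-10`. These sizes were chosen so that the full
workflow — calibration checks, phase diagram, three therapy designs and the
property suite — completes in a few minutes on a single core.
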