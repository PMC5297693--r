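---
title: "A bistable model of the ER-stress life-and-death decision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bistable model of the ER-stress life-and-death decision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uprswitch)
```

## The biological question

Cells answering endoplasmic-reticulum (ER) stress choose between two
mutually exclusive programs: autophagy-dependent survival and apoptotic
death. Two ER-transmembrane sensors of the unfolded protein response drive
both programs — IRE-1 couples strongly to the autophagy machinery and weakly
to the death machinery, PERK the other way around — and the two downstream
inducers repress each other, forming a double-negative (toggle) feedback
loop. Experimentally, tolerable stress produces sustained autophagy with
only a transient flicker of the apoptosis markers; excessive stress produces
a transient autophagy window followed by switch-like, apparently
irreversible activation of apoptosis; silencing PERK delays death, while
inhibiting IRE-1 accelerates it. `uprswitch` implements a four-variable ODE
model of this decision circuit and the analysis machinery — bifurcation
curves, in-silico knockdowns, phenotype calling, synthetic
densitometry-style readouts — needed to interrogate it.

## The model

State variables are the active fractions of PERK (`perk`), IRE-1 (`ire1`),
the lumped autophagy inducer (`auto`) and the lumped apoptosis inducer
(`apop`), each confined to `[0, total]`. With stress signal $S$:

$$\dot P = (k_{sp} S + k_{ip} I)(P_T - P) - k_{dp} P$$
$$\dot I = (k_{si} S + k_{pi} P)(I_T - I) - k_{di} I$$
$$\dot A = (k_{pa} P + k_{ia} I)\frac{A_T - A}{J_{a,on} + A_T - A} -
           (k_{da} + k_{x,aa} D)\frac{A}{J_{a,off} + A}$$
$$\dot D = (k_{pap} P + k_{iap} I)\frac{D_T - D}{J_{ap,on} + D_T - D} -
           (k_{dap} + k_{x,apa} A)\frac{D}{J_{ap,off} + D}$$

The sensor layer is saturating mass action: stress and the partner sensor
activate the inactive pool, inactivation is first order. The inducer layer
uses Goldbeter–Koshland (zero-order ultrasensitive) activation/inactivation
fluxes — the Michaelis constants $J$ (0.05 activation, 0.01 inactivation)
are well below the totals (1.0), which is what lets the double-negative
couplings $k_{x,aa}, k_{x,apa}$ act as a sharp toggle. Setting a $J$ to
`Inf` selects the linear mass-action limit of that flux, which is how the
closed-form cross-checks in the test suite are built. Totals are conserved
(active + inactive); there is no synthesis or degradation and no basal
activation, so the origin is an equilibrium at zero stress.

### Why the sensor feedback gain exceeds one

The model must reproduce two facts simultaneously: the intact switch is
*irreversible* (a committed cell does not return to survival even if the
stressor is washed out, i.e. the death state persists at $S = 0$), and
knocking down either sensor makes it *reversible*. With no basal activation
this forces the sensor positive feedback to be self-sustaining for the
intact network: the zero-stress cross-activation gain

$$R_0 = \frac{k_{ip} I_T}{k_{dp}} \cdot \frac{k_{pi} P_T}{k_{di}}$$

is 1.44 for the default set, so at $S = 0$ the sensors hold themselves at a
low plateau (≈ 0.17) that keeps the committed death state alive; the origin
is then an unstable equilibrium. Because $R_0$ scales with $P_T I_T$, the
siPERK preset ($P_T \times 0.2$, $R_0 = 0.29$) and the IRE-1 preset
($I_T \times 0.1$, $R_0 = 0.14$) both extinguish the self-sustained sensor
state — at low stress their death branch loses its input and folds back at
positive stress, which is exactly the loss of irreversibility the knockdown
analysis demonstrates. An alternative design with a monostable sensor layer
was considered and rejected: without basal terms every branch then collapses
as $S \to 0$, so no parameter choice can make the intact switch
irreversible.

The flip side, a deliberate idealisation: at stress 0 the model's "resting
cell" sits at the self-sustained sensor plateau with autophagy high, and the
exact origin is unstable. Trajectories are therefore always started from
the origin *with* the stress step, as in the simulated experiments.

## Calibrated behaviour

Parameters are dimensionless; rate magnitudes were chosen so that, under
the cosmetic axis mapping of 2.5 minutes per time unit, the high-stress
apoptosis switch falls near the 90–120-minute analogue of the blot time
courses. The shipped default set was fixed by constraint-guided search
([`search_parameters()`]) against the behaviour catalogue C1–C8 of
[`check_constraints()`]:

```{r constraints, eval = FALSE}
report <- check_constraints(default_params())
report
```

* C1 — bistable window (two stable + one unstable state inside);
* C2 — intact switch irreversible: the death branch persists to the scan
  minimum at stress 0 (`sn_off_status = "below_scan_min"`);
* C3 — activation fold between the two scenario levels: SN\_on ≈ 32.0;
* C4 — at stress 25 the apoptosis inducer shows a transient peak (≈ 0.14 of
  total, at t ≈ 12) that decays back below threshold;
* C5 — siPERK preset: SN\_on beyond the scanned range (> 60) and
  SN\_off ≈ 2.7 > 0 (reversible);
* C6 — IRE-1-low preset: SN\_on ≈ 27.3, left of the intact fold, and
  SN\_off ≈ 1.6 > 0 (its survival branch is an isola: it also folds at
  stress ≈ 21.3, below which the death branch is the only attractor);
* C7 — no steady state anywhere in the scans has both inducers above half
  of their totals (mutual exclusion);
* C8 — at stress 40 the autophagy peak (t ≈ 14) precedes apoptosis
  half-activation (t ≈ 42).

Local robustness (`robustness_table()`): most single-rate ±10% changes
preserve all eight behaviours, but C4 (the size of the low-stress transient)
and C6 (the IRE-1-low left shift) sit closest to their boundaries and can
fail for individual perturbations — consistent with a qualitative, not
fine-tuned, calibration; the table reports rather than hides this.

## Numerical choices

* **Integration** — `deSolve::lsoda` with the analytic Jacobian, relative
  tolerance 1e-8, absolute 1e-10; stress schedules are integrated
  segment-wise with restarts at each discontinuity, never interpolating
  across an event.
* **Steady states** — damped Newton iteration with the analytic Jacobian
  from a multi-start grid; roots deduplicated at 1e-6 in the max norm;
  stability from the leading eigenvalue real part with a ±1e-9 margin
  (marginal roots are re-polished at tighter tolerance before classifying).
* **Signal-response curves** — a stress grid (default 600 points over
  [0, 60], bracketing both scenario levels) scanned with nearest-neighbour
  continuation in both sweep directions plus fixed canonical starts; branch
  labels by smallest state-space jump. Folds are located by following the
  survival branch upward and the death branch downward in stress (never by
  assuming they coincide with the edges of the two-stable window — they need
  not, as the IRE-1-low isola shows) and refined by bisection on branch
  existence to 0.01 stress units; bisection on existence needs no
  second-derivative test functions and is robust at zero-order
  ultrasensitivity, where fold curvature is extreme.
* **Reversibility** — `irreversible` when the death branch persists at the
  scan minimum of a scan starting at stress 0; `reversible` when its fold
  sits at positive stress; `no_switch` when the response is monostable.
* **Commitment (washout scenario)** — first time the apoptosis inducer
  exceeds 90% of its high-branch value at stress 40; the stressor is
  removed 15 time units later.
* **Degenerate inputs** — parameter sets violating the wiring (missing
  feedback legs, inverted strong/weak ordering) are rejected by the
  constructor unless `check = FALSE`, which is how the monostable control
  cases in the tests are built.

## Phenotype calling

Timing features are threshold-based: the "high" threshold is 0.5 of the
scale (a variable's total for model output, the series maximum for
normalized data), the transient-detection threshold 0.1, and a sustained
crossing must hold for 3 consecutive samples. One deliberate refinement:
commitment is terminal, so a sustained onset must belong to the *terminal
activated phase* — the stretch after the last run of ≥ 3 consecutive
below-threshold samples. A transient that crosses, lingers, and recedes for
good is never an onset, while isolated one-sample noise dips do not break
one. On max-normalized synthetic data this distinction is essential: the
low-stress transient normalizes to a peak of 1.0 and would otherwise be
mistaken for death. Calls are `death` (sustained onset), `delayed_death`
(onset more than one sampling step after the intact high-stress reference),
`survival` (no sustained onset), or `undetermined` (series shorter than the
sustain guard). The calls for the calibrated scenarios are unchanged for
onset thresholds anywhere in [0.4, 0.6] of scale.

## The synthetic-data generator

`generate_timecourse()` emulates densitometry panels from immunoblot
experiments: variables are mapped to their marker proxies (LC3-II,
ULK-555-P → autophagy inducer; cleaved PARP, CHOP, JNK-P → apoptosis
inducer; eiF2α-P → PERK; spliced XBP1 → IRE-1), sampled at fixed intervals
(default every 6 time units, the 15-minute analogue; horizon 120),
normalized to each marker's series maximum (band intensities are relative
quantities), and multiplied by lognormal noise with unit mean and a given
coefficient of variation. Defaults: three replicates (the usual number of
parallel blots) and cv = 0.15, a typical magnitude for blot densitometry;
no experimental noise magnitudes are available, so cv is an exposed choice,
not a fitted one. Replicates use distinct deterministic sub-seeds.

What the generator deliberately does **not** model: transfection-efficiency
dynamics, cell-population heterogeneity, saturation/background of the
detection chemistry, or correlated loading-control errors. Passing
recovery tests therefore show that the *pipeline* is consistent under
multiplicative noise of realistic size — not that the model fits any real
blot series quantitatively. `recovery_study()` quantifies pipeline
robustness: recovery is exactly 1 at cv = 0 by construction, stays ≥ 0.95
at cv = 0.1 (200 replicates), and degrades gracefully by cv = 0.2–0.3.

## Problem sizes used in the checks

Signal-response scans use 600 grid points over stress ∈ [0, 60] at
production resolution (unit tests use 60–150 points, which moves fold
estimates by less than 0.5 stress units); the brute-force steady-state
oracle integrates from a 6×6×6×6 grid of initial states; recovery studies
use 200 replicates per noise level; quasi-static hysteresis ramps step by
0.1 stress units near the folds with 600 time units of relaxation per step.

## Known limitations

* The calibration is qualitative. Fold positions, timings and the noise
  level are not fits to measured intensities; only orderings, signs and
  window memberships are claimed.
* From the *exact* origin, stress levels at or below ≈ 10 commit to death rather
  than survival: during the slow sensor ramp-up the strongly asymmetric
  double-negative coupling ($k_{x,aa} \gg k_{x,apa}$) lets the death side
  win the race before autophagy establishes. The reference scenario stress levels
  (25, 40) and the quasi-static analyses, which start on a branch, are
  unaffected.
* The model has no ATF6 branch, no CHOP/Gadd34 negative feedback on
  eiF2α-P, no translation-rate submodel, and no stochastic or spatial
  effects; `stress` is a single abstract signal onto which both chemical
  stressors are mapped.
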