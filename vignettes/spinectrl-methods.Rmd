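---
title: "Methods: a control-based beam-column model of trunk muscle recruitment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a control-based beam-column model of trunk muscle recruitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Trunk muscle forces cannot be measured directly, and the lumbar spine is
kinetically redundant: many more muscles cross each intervertebral joint than
there are equilibrium equations, so muscle forces are indeterminate from
statics alone.  Inverse (equilibrium-based) models resolve the redundancy
with an optimisation criterion; `spinectrl` implements the complementary
forward route: a feedback controller, one per muscle, learns online to hold
a prescribed posture, and the muscle forces are whatever the learned
controllers converge to.  The interesting empirical finding this enables is
that the learned recruitment turns the internal spinal force into a near
*follower load* — a compressive resultant that follows the local tangent of
the spinal curve, carrying load without shear and thereby maximising the
buckling resistance of the osteoligamentous column — without that condition
ever being imposed.

## Plant: a geometrically nonlinear beam-column

The lumbar spine (sacrum base plus L5..L1) is a 2D elastic beam-column in
the frontal plane: X vertical (gravity acts in $-X$), Z lateral.  The
reference posture is a slightly laterally bent curve (top vertebra 10 mm off
axis over a 190 mm column) with flexural rigidity $EI = 1.9$ N m² and a
constant 1225 mm² cross-section.  Since compressive loads of interest exceed
the fixed-free Euler load $\pi^2 EI / 4L^2 \approx 130$ N several times
over, geometric nonlinearity is essential; we use 2-node corotational
Euler–Bernoulli elements (small strain, large rotation) whose tangent
stiffness — material plus stress-stiffening terms — is the exact derivative
of the internal force (verified by finite differences to $10^{-6}$).
Shear deformation is neglected: at slenderness $\approx 190/35$ the
Timoshenko correction is far below every tolerance used here.  The element
is nodally exact for the cantilever oracle and reproduces the Euler buckling
load within 1% at 16 elements; on the 5-element spine mesh the critical load
is within 1.5%, and splitting every element in two changes converged section
loads by under 0.1%.

Only $EI$ is stated by the geometry; the axial rigidity is derived from a
35 mm square section via $E = EI/I$.  Axial strain at the loads of interest
is $\sim 10^{-2}$ mm scale and does not influence any reported quantity.

## Muscles

Five bilateral pairs of straight-line Hill-type actuators run from origins
on the fixed base at $(0, \pm D)$ to the five lumbar vertebral centres.
Each transmits

$$F = f_{max}\,\bigl(\alpha\, f_l(l)\, f_v(\dot l) + f_p(l)\bigr),$$

with the standard quartic force-length factor (clamped at zero where the
polynomial turns negative — a muscle cannot push), a sigmoid-in-$\sinh$
force-velocity factor (strictly increasing; lengthening raises force, which
is also the muscles' only intrinsic damping), and an exponential passive
term.  $f_{max} = 800$ N for every muscle and $\dot l_{max} = l_0/0.1$ s.

Two conventions had to be fixed that the force law leaves open:

* **Resting length.**  $l_0$ is set to each muscle's length in the *target*
  posture — the posture the controllers defend is also the muscles'
  reference state, so at convergence $f_l \approx 1.1$ and $f_v \approx 1$.
* **The passive term and the plant.**  With $l_0$ anchored at the target
  posture, $f_p(l_0) \approx 0.05$ means 40 N of resting tension per muscle;
  summed over ten near-vertical muscles this would add roughly 380 N of
  permanent compression at L5–S1.  The spinal loads this model is built to
  reproduce leave room for only ~100–260 N of *total* muscle action, so the
  plant cannot carry that preload.  The package therefore excludes the
  passive term from the force transmitted to the plant by default
  (`muscle_set(passive = FALSE)`); the full composition including $f_p$
  is implemented, tested, and available via the option.

## Controllers

One single-input single-output adaptive fuzzy unit drives each muscle.  The
input is the lateral position error $e$ (mm) of the muscle's insertion
vertebra; the output is the activation $\alpha \in [0,1]$.  Each unit
minimises
$$E = \tfrac12 k_e (h_1 e + h_2 \dot e + h_3 {\textstyle\int} e)^2
    + \tfrac12 k_\alpha \alpha^2$$
by steepest descent on its consequent weights,
$\Delta w_i = \eta\,(k_e h_1 r_e j - k_\alpha r_\alpha)\,\partial\alpha/\partial w_i$,
where $r_e = h_1 e + h_2\dot e + h_3\int e$ and $r_\alpha = |\alpha|$ are
the two critic signals and $j = \pm 1$ is the sign of
$\partial Z/\partial\alpha$, fixed per muscle from the lateral component of
its line of action (and verified against a static perturbation of the
plant).  Gains: $h_1 = h_2 = h_3 = 2$, $k_\alpha = 0.2$, and
$k_e = 15, 7, 2.5, 1, 0.1$ for L1..L5 — the error weighting prioritises the
upper levels, which also makes the upper controllers learn fastest.

The network itself is a zero-order Takagi–Sugeno grid: $7\times7$ Gaussian
memberships over $(e, \dot e)$ normalised by 2 mm and 20 mm/s and clipped to
$[-1,1]^2$ (so the family always covers the domain), one scalar weight per
rule, output the normalised weighted sum clipped to $[0,1]$.  This is the
simplest architecture consistent with the signal flow and with the
$\partial\alpha/\partial w_i = \mu_i/\sum\mu$ form the update needs; the
grid size and normalisation are configuration options.  Weights start at
zero (no pre-activation) and are never clamped — output clipping handles the
range, and the inactive antagonist's weights simply drift negative.

**Learning rate.**  $\eta$ is the one genuinely free constant.  It was
tuned once, against the two published behavioural bounds — tracking within
2 mm throughout learning and sub-0.2 mm steady-state error — and fixed at
$\eta = 10^{-4}$ per 1 ms control cycle.  The stability region is not
knife-edge (runs remain stable at $2\times\eta$ and at five times the
damping) but it is bounded on both sides: an order of magnitude faster and
the weight updates outrun the plant's lateral dynamics into bang-bang
divergence; an order slower and the controllers cannot catch the buckling
column during the load ramp.

**Control clock.**  The controller samples and updates every 1 ms
(`control_dt`), on its own clock.  Decoupling it from the integration step
keeps the learning trajectory invariant under time-step refinement, which is
what makes "halving `dt` changes steady outputs by <1%" a meaningful
convergence statement (measured: $<10^{-5}$ relative).

## Time integration and the transient surrogate

The steady state of interest is quasi-static, but reaching it requires a
transient, and a transient requires inertia and damping that the model
otherwise neglects.  These are numerical surrogates, not physiology: lumped
nodal masses (0.5 kg) and stiffness-proportional Rayleigh damping
($\beta = 10^{-3}$ s), integrated by Newmark average acceleration
(unconditionally stable, no numerical dissipation) with full Newton
iteration per step and step-halving on non-convergence.  Muscle forces enter
the Newton residual implicitly in both position and velocity — the
force-velocity slope is a stiff damping term that explicit coupling cannot
handle at 1 ms.  The surrogate's footprint is checked, not assumed: halving
the nodal mass changes converged section loads by $<10^{-5}$ relative.  The
0.5 kg default is deliberately above the smallest value that merely keeps
the integrator happy: with very light nodes the lateral divergence of the
heavily loaded column outruns any workable learning rate during the ramp,
and the concentrated-load case cannot be stabilised at all.

Loads ramp linearly over 0.2 s and are then held; the default horizon is
25 s at dt = 1 ms.  Steady state is declared at the earliest time after the
ramp from which all target deviations stay below 0.2 mm and lateral speeds
below 1 mm/s for a continuous 1 s window.  A lateral excursion beyond 50 mm
flags the run unstable — this is how the no-controller runs fail, as they
must, since all five load cases exceed the passive buckling load several
times over.

## The equilibrium baseline

The comparison model answers the same recruitment question by construction
instead of by learning: on the *fixed* reference geometry, one signed muscle
intensity per level is solved from the $5\times5$ linear system that zeroes
the local shear of the transmitted force at each intervertebral section
(sign selects the side; the side assignment is iterated to a fixed point,
which in practice is reached in one or two passes).  With purely nodal
loading, shear is piecewise constant along the column and the internal
moment is continuous and zero at the free end — so zeroing shear at the five
sections already makes the internal force a complete follower load; no
separate moment condition exists to impose.

The follower direction needs a tangent convention, and the choice matters
at the percent level because compressions are large: the default takes the
slope of a natural cubic spline through the vertebral centres at the
section's upper node (a continuous spinal curve); the piecewise chord is
available as an option.  The spline-at-node convention reproduces the
published baseline compressions to better than 1% in the two low-muscle-force
load cases.  In the higher-force cases (concentrated top load, or origins at
D = 25 mm) the published baseline values sit 8–18% above *any* solution
obtainable on the fixed reference geometry — inverting the published
compression and shear columns shows the implied tangent field differs per
load case, steepening with total compression, i.e. the original baseline was
evaluated on per-case load-deformed configurations that its published
description does not specify.  We report our exact-solve values and shear
residuals ($<10^{-9}$ N) rather than emulate an unspecified deformation.

## What the converged model shows

Under the default configuration all five load cases converge, unilaterally
(at most one muscle per level above $\alpha = 0.01$, at every load level of
the 150–750 N sweep), with recruited-muscle force scaling linearly in the
external load ($R^2 > 0.999$).  The follower-load angle —
$\arctan(|\text{shear}|/\text{compression})$ against the local deformed
tangent — stays below 1° at every level in every case: the learned
recruitment produces a follower load, which is the model's central
scientific claim.

Two convergence subtleties are worth stating plainly.  First, kinematic
convergence (sub-0.1 mm in a few seconds) is much faster than *internal*
convergence: the activation penalty keeps exchanging load among the
redundant muscles on a timescale of minutes of simulated time, so the exact
per-muscle stationarity condition $k_e h_1 r_e j = k_\alpha \alpha$ is only
met to $\sim 10^{-1}$ in the full assembly even at 120 s.  On a single-pair
(one-level) system, where the SISO analysis applies exactly, the residual
falls below $10^{-3}$ by 30 s.  Second, section loads are reported as means
over the final 1 s window of the 25 s run; the slow redistribution moves
them by only a few N over a further 100 s.

## Problem sizes

The shipped tests and the acceptance script run: five 25 s case simulations
(25 000 steps each, 6 nodes / 15 free DoF), a four-point load sweep, one
perturbation run with ±100 N pulses, one 30 s single-pair run, dt- and
mass-halving repeats of one case, and the closed-form beam oracles at up to
32 elements.  The full suite completes in a few minutes on one CPU.

## Limitations

Everything here is frontal-plane and idealised: no torsion, no facet
joints, no nonlinear disc behaviour, no muscle wrapping, pennation, tendon
compliance or activation dynamics, no spindle/reflex feedback, and no
formal stability proof — stability is demonstrated behaviourally (bounded
tracking, recovery from load pulses), not in the Lyapunov sense.  The
passing test suite shows the implementation is faithful to this idealised
model and that the follower-load result is robust within it; it says
nothing about predictive validity for real spines, which would require
richer geometry and validation against recorded muscle activity.
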