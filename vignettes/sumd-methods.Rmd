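---
title: "Supervised molecular dynamics on toy energy landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised molecular dynamics on toy energy landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumdtoy)
```

# The problem

Supervised molecular dynamics (SuMD) is an adaptive-sampling scheme for
ligand–receptor binding: instead of waiting for a binding event in one long
unbiased trajectory (typically hundreds of nanoseconds to microseconds for a
GPCR ligand), the simulation is cut into short unbiased windows, and the
trend of the ligand–binding-site center-of-mass distance over each window
decides whether the window is kept. Windows whose fitted distance slope is
negative are accepted and continued; all other windows are discarded, the
coordinates are restored and the atomic velocities are redrawn from the
Maxwell–Boltzmann distribution (a tabu-like move). Once the ligand first
comes within an arrival radius of the site, the supervision is switched off
for good and plain (classical) dynamics continues. Because every window is
itself unbiased dynamics, no forces are modified — the scheme reshapes only
which stretches of unbiased dynamics are retained.

`sumdtoy` re-implements this engine, together with the analyses usually run
on its output (recognition-energy landscapes, metastable-state detection,
occupancy gaps, residence-weighted path summaries), a well-tempered
metadynamics module for salt-bridge-like collective variables, and the
Eyring (transition-state) arithmetic that converts unbinding-rate changes
into barrier free-energy shifts — all at desk scale, on analytic toy energy
landscapes, so that every claim about the machinery can be tested against
closed-form or brute-force oracles in seconds.

# The toy landscape model

A `toy_system` is a single point ligand of mass $m$ (default 200 amu, a
fragment-sized ligand) moving in 1–3 dimensions in a potential

$$U(\mathbf r) = \sum_i -D_i\, e^{-(\rho_i - R_i)^2 / 2\sigma_i^2}
             + \sum_j H_j\, e^{-(\rho_j - R_j)^2 / 2\sigma_j^2}
             + U_{\rm wall}(\mathbf r),
\qquad \rho_k = |\mathbf r - \mathbf c_k|,$$

i.e. Gaussian wells (depths $D_i > 0$, attractive) and barriers
($H_j > 0$, repulsive), each either a point feature ($R = 0$) or a
spherical shell of radius $R$, plus harmonic walls
($k_{\rm wall} \sum_d \max(|x_d| - L, 0)^2$) outside a box of half-length
$L$ (default 25 Å, $k_{\rm wall} = 10$ kcal/mol/Å$^2$). Harmonic walls
rather than periodic boundaries: the supervision needs bounded diffusion,
and walls keep the site-distance coordinate single-valued.

Units are physical throughout — Å, ps, amu, kcal/mol, with
$k_B = 0.0019872$ kcal mol$^{-1}$ K$^{-1}$ and 1 kcal/mol = 418.4
amu Å$^2$ ps$^{-2}$ — so the production-scale parameter values (310 K, 2 fs
time step, 5 Å arrival radius, 600 ps windows) can be used verbatim.

## Why shell features

A receptor's extracellular vestibule is a funnel: every approach path
crosses it. An isotropic point Gaussian 15 Å from the site subtends well
under 1% of the solid angle seen by a ligand diffusing in from a 20 Å
shell, so random replicas would simply miss it. The presets therefore model
the metastable region and the repulsive ring as spherical shells about the
orthosteric center ($R = 15$ Å and $R = 10$ Å), which reproduces the
funnel's "must pass through" character while keeping the potential
analytic. `radius = 0` recovers the plain point Gaussian, and the
designated orthosteric well is always a point well at the monitored center.

## Presets

* **binder** — orthosteric well 6 kcal/mol deep ($\sigma$ = 3 Å), the global
  minimum of the landscape; a mild metastable shell (1.5 kcal/mol,
  $R$ = 15 Å) and barrier ring (1 kcal/mol, $R$ = 10 Å) on the way in. A
  competent orthosteric binder: supervised replicas reach the site.
* **pam** — orthosteric well only 3 kcal/mol; metastable shell 7 kcal/mol
  at 15 Å behind a 3 kcal/mol ring at 10 Å. The metastable shell is deeper
  than the site, and the inward climb is $\sim$9 kcal/mol, so replicas
  stall on the shell — the positive-allosteric-modulator phenotype of a
  fragment that never forms a stable orthosteric complex.
* **diffusive** — one shallow (1 kcal/mol) well; near-free diffusion.
  Overriding the depth to 0 gives a flat confined box.

The magnitudes were chosen once, from the geometry the scenarios emulate
(metastable region about 15 Å out, unfavourable ring about 10 Å out) and a
single-digit kcal/mol interaction scale appropriate to fragment-sized
ligands; they are deliberately qualitative and every one can be overridden
via `build_scenario(..., overrides = )` or a YAML/JSON scenario file. No
quantitative well depths are available for the metastable sites being
emulated — only the ordering "metastable deeper than orthosteric" for the
PAM case constrains the preset, and the binder preset enforces the
converse.

# Dynamics

The integrator is BAOAB Langevin splitting: half-kick, half-drift,
Ornstein–Uhlenbeck velocity refresh
($v \leftarrow e^{-\gamma\,\Delta t} v + \sqrt{1 - e^{-2\gamma\,\Delta t}}\,
\sqrt{k_BT/m}\,\xi$), half-drift, half-kick. BAOAB is chosen for its
accurate configurational sampling at finite step size; with $\gamma = 0$ it
reduces to velocity Verlet (energy-conserving), and with $T = 0,
\gamma = 0$ to ballistic motion — both limits are asserted in the test
suite (energy drift below $10^{-4}$ kcal/mol over $10^5$ steps; ballistic
positions to $10^{-8}$ Å). Defaults: $\Delta t$ = 0.002 ps (2 fs), 310 K,
friction 1 ps$^{-1}$.

All randomness flows through R's RNG (`set.seed`), including inside the
compiled core, so a seeded run is bit-reproducible. Frames (position,
velocity, potential and interaction energy, site distance) are recorded
every `sample_stride` steps (default 50, i.e. every 0.1 ps); those recorded
distances are exactly the points the supervision fits, since the original
scheme specifies only "regular time intervals" for the distance
collection.

# The supervision engine

Per window of duration $w$ (default 600 ps; the toy tests use 6 ps windows,
which are to these landscapes what 600 ps is to a membrane GPCR system,
and a 0.1 ps distance sampling interval):

1. run one unbiased segment from the current state;
2. if the minimum recorded distance fell below the arrival radius
   (default 5 Å), record **arrival**, keep the window, and run an
   unsupervised classical tail (default $10\times$ the window length;
   the production length of that tail is not prescribed);
3. else fit distance vs time and **accept** iff the slope $m$ is strictly
   below 0 — a slope of exactly zero is a rejection, reading "negative"
   strictly;
4. on **reject**, restore the window's starting coordinates exactly and
   redraw the velocities; trajectory time does not advance.

Arrival is tested against the window minimum, not the endpoint: "drops
below the threshold" is a first-passage condition, and testing only the
endpoint would discard windows that touched the site and bounced. Two slope
readings are implemented: the default `affine` ordinary-least-squares slope,
and a literal through-origin $f(x) = mx$ fit on times shifted to start at
zero. The affine fit is the default because a no-intercept line through a
distance series that starts near 20 Å has a slope dominated by the
intercept error, not the trend; the through-origin mode is kept for
fidelity to the published description and the choice is recorded in the
run configuration. No explicit tabu list is kept — the published procedure
is operationally reject-and-resample, and that is what is implemented. The
abort cap is `max_windows` (default 2000; the original scheme defines no abort condition).

`run_unbiased()` provides the control arm: one long classical segment with
the same integrator, reporting the first-passage arrival time. The paired
comparison (same seeds, same total simulated-time budget) is the package's
acceptance check that supervision accelerates binding: on the binder preset
with 6 ps windows and a 600 ps budget per replica (100 windows), 20
replicas give a SuMD median time-to-arrival well under half the (censored)
unbiased median, and a higher arrival fraction.

# Trajectory analyses

* `recognition_landscape()` — 2-D frame histogram over (site distance,
  interaction energy). The interaction energy is the toy potential *minus
  the wall term*: the walls are simulation plumbing, not receptor–ligand
  interaction. Stabilisation is negative by the package's sign convention;
  magnitudes of tens of kcal/mol correspond to what force-field interaction
  energies report for ionic fragment contacts.
* `find_metastable_states()` — maximal time-contiguous runs during which
  the distance stays within a tolerance of its running mean, kept if they
  dwell at least `min_dwell`. Reported per state: mean distance, span,
  dwell time, mean interaction energy.
* `occupancy_gaps()` — distance-histogram bins with occupancy below a
  threshold (default 0.5%, since "poorly populated" is not quantified
  anywhere) lying strictly between populated regions: the signature of
  unfavourable transition configurations between a metastable shell and
  the site.
* `path_summary()` — positions binned into cubic cells; one node per cell
  at the time-weighted mean position with the total residence time
  (trapezoidal frame weights, so node times sum exactly to the trajectory
  duration), ordered by first visit. Exportable as PDB pseudo-atoms with
  B-factor proportional to residence time, the standard way to render
  "sphere diameter = time spent" pathway pictures in a molecular viewer.

# Well-tempered metadynamics

On one or two collective variables (a coordinate, a distance, or a
periodic angle standing in for a dihedral), hills of initial height
$w_0 = 0.3$ kcal/mol are deposited every 0.5 ps with widths 0.04 Å
(length-like) / 0.3 rad (angle-like), damped by the well-tempered rule
$w = w_0\, e^{-V(s)/k_B(\gamma - 1)T}$ with bias factor $\gamma = 6$ at
298 K — the protocol of published salt-bridge stability analyses. The free
energy is recovered as $F(s) = -\frac{\gamma}{\gamma-1} V(s)$.

Two bias representations are used deliberately: the propagation loop
accumulates deposits on a fine CV grid ($\sigma/5$ spacing) and
interpolates the bias gradient, giving O(1) per-step cost; the R-level
`bias_potential()`/`estimate_fes()` evaluate the analytic hill sum, and the
tests check one against the other. `estimate_fes(tail_average = 0.5)`
additionally averages the estimator over checkpoints spanning the last
half of the deposition history — the standard remedy for the deposition
ripple of a converged well-tempered run, and what the barrier-recovery
checks use.

The `salt_bridge_system()` double well (closed state at 4.5 Å, open at
9 Å, wells 6 kcal/mol deep, $\sigma$ = 0.8 Å, giving a barrier of about
5.8 kcal/mol) emulates a salt-bridge distance coordinate whose closed
conformation gates ligand egress. Two quantitative recoveries are asserted:

* **barrier**: an 8 ns run recovers the barrier within 15% of the value
  obtained by direct Boltzmann quadrature of the analytic potential (a
  1-D coordinate CV makes $F(s) = U(s)$ up to a constant, so the oracle is
  exact);
* **stabilisation shift**: deepening the closed well by
  $\delta$ = 0.5 kcal/mol (emulating the presence of a bound modulator at
  the loop interface) moves the basin-integrated
  $\Delta F(\text{closed}-\text{open})$ by $\delta$ within
  0.2 kcal/mol, using 12 ns runs and replicate means (3 per condition in
  the test suite, 5 in the acceptance script). Basin integration
  ($F_{\rm basin} = -k_BT \ln \int_{\rm basin} e^{-F(s)/k_BT}\,ds$) is
  used rather than point minima because it is first-order insensitive to
  the residual FES ripple. The quadrature value of the true shift is
  0.474 kcal/mol, slightly under $\delta$, because deepening a Gaussian
  well also sharpens it.

The temperature-ramp equilibration used in production protocols is out of
scope here: toy runs start equilibrated at the target temperature.

# Unbinding kinetics

The Eyring/transition-state relation $k \propto e^{-\Delta G^\ddagger/RT}$
has a prefactor that cancels in rate ratios, so only barrier *changes* are
computed: $\Delta\Delta G^\ddagger = RT \ln(k_{\rm ref}/k_{\rm mod})$,
positive when the modulator slows unbinding — whether by destabilising the
transition state or stabilising the bound state, which the ratio cannot
distinguish. Default temperature 310 K (the simulation temperature; the
radioligand assay temperature is not stated with the rates, so it is a
parameter).

A note on the reference data the arithmetic is applied to: the assayed
koff pair 0.015 → 0.0095 min$^{-1}$ implies a 36.7% decrease, while the
assay's own annotation calls it 18% — the percentage is a reported
allosteric-modulation figure with its own definition, not derivable from
the printed pair. The package therefore exposes both entry points
(`ddg_from_rates()` for rate pairs, `ddg_from_percent()` for reported
percentages) and never converts one into the other. All of 18%, 8% and the
printed rate pair give $\Delta\Delta G^\ddagger$ between 0.05 and 0.29
kcal/mol — comfortably below 1 kcal/mol at any assay temperature between
273 and 373 K.

# What the toy validation does and does not show

The generator emulates: bounded diffusion of a point ligand, funnel-like
metastable shells and repulsive rings, site-distance supervision,
thermostat physics, and deposition-rule bookkeeping. It does not emulate:
protein flexibility, explicit solvent and membrane, rugged all-atom energy
surfaces, orientation-dependent binding, or multi-atom center-of-mass
geometry (the ligand is a point, so the COM machinery is exercised by
`com_distance()` and PDB selections rather than by the simulator). Passing
tests therefore certify the *algorithmic machinery* — decision rules,
restore semantics, estimator formulas, conservation properties and the
qualitative preset phenomenology — not force-field realism; absolute times
and energies on the toy landscapes are not predictions for any receptor.

# Numerical choices and degenerate inputs

* Slope fits require at least two points and strictly increasing times;
  constant-time windows are an error, not a zero.
* Arrival exactly at the threshold does not count (`<`, strict), matching
  the strict reading of "less than"; a slope of exactly zero rejects.
* A run started inside the arrival radius is productive with zero
  supervised windows and only a classical tail.
* Histogram edges span the data; a degenerate (constant) series widens its
  range by ±0.5 so conservation still holds. Out-of-range values clamp to
  the edge bins.
* The gridded metadynamics bias clamps CV excursions to its grid (the
  confinement box padded by 5 Å, or the periodic interval); hills are
  deposited at the true CV value.
* Shell-force evaluation at the exact shell center (ρ = 0) returns zero
  force (the potential is smooth but its radial direction is undefined
  there).
* Trajectory CSV/JSON output uses locale-independent fixed-precision
  formatting so seeded reruns are byte-identical.

# Problem sizes used by tests and the acceptance script

Simulation sizes were set from the physics of the toy landscapes (diffusion
times across a 25 Å box at 310 K, barrier-crossing rates at the preset
depths): 6 ps supervision windows with 100-window budgets and 20 paired
replicas for the acceleration comparison; 24 replicas with 50-window
budgets for the PAM phenotype; 8000 ps for metadynamics barrier recovery
and 12000 ps per replicate for the stabilisation shift; $10^6$ recorded
samples for the Boltzmann-statistics check; $10^5$ velocity draws for the
Maxwell–Boltzmann variance check.
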