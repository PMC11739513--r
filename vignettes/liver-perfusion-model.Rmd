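---
title: "Methods: synthetic liver vasculature and lumped-parameter CPA loading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic liver vasculature and lumped-parameter CPA loading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its model: what is being
computed, under which assumptions, which knobs matter, and where the
design was genuinely open and a choice had to be made.

## The model in one paragraph

The liver is reduced to (i) two rooted trees — portal vein in, hepatic
vein out — grown inside the organ volume by attractor-based space
colonization, and (ii) *k* lumped **super lobules** that absorb everything
the trees do not resolve: the microscopic lobules, arterioles, venules and
sinusoids. Each super lobule is a two-terminal resistor-and-volume element
bridging one inlet-tree terminal and one outlet-tree terminal, so the
union is a single connected hydraulic network. Flow is steady,
incompressible, Newtonian and laminar (Hagen-Poiseuille per vessel
segment), which turns the network into a linear circuit; the one unknown
material parameter, the shared super-lobule resistance $R_{SL}$, is
calibrated so the circuit reproduces prescribed bulk boundary conditions.
CPA loading is then an advection/displacement process on the solved flows.
The hepatic artery is deliberately not modeled: the portal vein carries
roughly three quarters of hepatic inflow, several preservation protocols
perfuse it alone, and omitting the artery halves the model complexity.

## Geometry and super lobules

The organ domain is any watertight triangulated surface (STL in, mm
units), or the built-in synthetic stand-in: a triaxial ellipsoid with
semi-axes in ratio 2 : 1.2 : 0.8 — elongated and flattened in roughly
hepatic proportions — scaled to 1.6 L, a representative healthy human
liver volume. Inside tests use the generalized winding number, which is
robust to near-degenerate triangles; interior sampling is rejection
sampling from the bounding box, so the cloud is uniform in volume by
construction.

Super lobules are the k-means clusters of that uniform cloud (k-means++
seeding, 10 restarts, empty clusters reseeded at the farthest point). On
a uniform cloud, minimizing within-cluster squared distance yields
clusters of roughly equal volume, which justifies giving every super
lobule the same volume and the same resistance. The volume each one
claims is

$$V_{SL,total} = V_{blood} - V_{vessels}, \qquad
  V_{SL,individual} = V_{SL,total}/n_{SL},$$

i.e. whatever part of the organ's blood volume the explicit vessels do
not occupy. The total blood volume is **not** a quantity this package can
derive; it is the config parameter `blood_volume_fraction` (default 0.25
of organ volume, a mid-range literature figure for hepatic blood
fraction). Treat it as an input, not a result.

## Space colonization with target attractors

Growth parameters (mm): step distance `D = 5`, kill radius `d_k = 10`,
sphere of influence `d_i = 15`, the values used for all reference models
here; well-behaved growth wants `D < d_k < d_i` (violations warn). Each
iteration: every active attractor is associated with its **single nearest
node** when within `d_i`; a node with associations adds a child at
distance `D` along the normalized mean of unit vectors toward its
attractors; ordinary attractors within `d_k` of any node are consumed.
Target attractors — the super-lobule centroids — are indestructible until
a node is placed *exactly* on them, which is what guarantees a terminal
per super lobule and hence a connectable model. Two-stage growth first
lays down primary branches (left/right portal; left/middle/right hepatic)
toward anatomical landmark positions, then grows the full tree; after all
targets are reached, every branch not on a terminal-to-root path is
pruned.

Choices made where the procedure sketch was open:

* **Association scope.** Attractors pull only their nearest node (not all
  nodes within `d_i`): letting several nodes chase one attractor produces
  duplicate growth toward the same point.
* **All-target nodes.** When everything pulling a node is a target, the
  node advances toward (or snaps onto, within `D`) the *nearest* target
  instead of the mean direction. Two targets flanking one node pull in
  opposite directions; their mean is ~zero and mean-direction growth
  provably deadlocks there.
* **Duplicate suppression and fallback.** The averaged direction can
  reproduce an existing node indefinitely without approaching any
  attractor (opposed pulls at distance > `d_k`). A child is never created
  on top of an existing node; when that happens the node instead steps
  toward its nearest associated attractor, which strictly decreases a
  distance and eventually triggers the kill radius.
* **Stalled-attractor culling.** An ordinary attractor that stays engaged
  (inside `d_i`) for 30 consecutive iterations without its nearest-node
  distance improving sits in a pocket the growth rule cannot colonize and
  is dropped. Targets are never dropped; if a target cannot be reached
  the run fails loudly with the unreached ids rather than silently
  relaxing a radius.
* **Primary stage reach.** Primary landmarks usually lie far beyond
  `d_i` of the root, so the primary stage runs with `d_i = ∞` (targets
  always engaged) and the main stage's `D` and `d_k`.
* **Stub consolidation.** Snapping onto a target can create segments far
  shorter than `D` (down to micrometres). Along an unbranched chain the
  Murray radius is constant, so contracting a sub-`min_segment_length`
  edge (default 0.5 mm) changes chain resistance and volume only through
  sub-millimetre geometry, while removing elements whose tiny volume
  would otherwise force the loading time step toward zero. Terminals and
  roots are never removed, so terminals stay exactly on the centroids.

Attractor-cloud density is the main robustness lever: the default is 200
points per super lobule with a floor of 5000, giving a mean inter-point
spacing comfortably below `d_i` for the 1.6 L domain. Sparser clouds can
stagnate (by design, this errors rather than degrades silently).

## Radii, resistances, and the circuit

Radii start from a 15 mm trunk diameter on both trees (`r_root = 7.5`
mm) and descend by the downstream-weighted Murray rule
$r_{child} = (\omega)^{1/\gamma} r_{parent}$, where $\omega$ is the
fraction of the parent's super lobules served (inlet) or drained (outlet)
by that child; $\sum\omega = 1$ at every branch so
$\sum r_{child}^\gamma = r_{parent}^\gamma$ exactly, and unbranched
chains keep their radius. $\gamma = 3$ is the laminar-flow Murray
exponent. Each colonization edge is one vessel segment with
$R = 8\mu L/(\pi r^4)$ and volume $\pi r^2 L$; viscosity defaults to 3.5
cP for blood *and* CPA, so loading introduces no interface rheology.

Unknowns are ordered as the $j+k$ element flows then the $l$ node
pressures; rows are $j+k$ Ohm relations, $l-2$ Kirchhoff current
relations, and two boundary rows (either both pressures, or the total
inlet flow plus the outlet pressure). The sparse asymmetric system is
LU-factorized (Matrix package). Internally everything is mm-dyn-s
(1 mmHg = 13.3322 dyn/mm², 1 mL/min = 16.667 mm³/s, 1 cP = 10⁻⁴
dyn·s/mm²); interfaces use mmHg, mL/min, cP.

Calibration: with pressures fixed, solved inflow decreases strictly in
$R_{SL}$, so bisection with automatic upper-bound doubling (initial upper
bound 1, doubled until the target is bracketed) converges
unconditionally when feasible. The stopping tolerance is |solved −
target| ≤ 10⁻⁸ **in mL/min**, stated in the reporting unit so results are
scale-stable. If even $R_{SL} = 0$ cannot pass the requested flow at the
requested pressure drop, the conditions are infeasible and the error
reports the maximum achievable flow; a singular solve at $R_{SL}=0$
(possible when a super lobule alone bridges the boundary nodes) is
treated as unbounded capacity, i.e. feasible.

## CPA loading

Starting from all blood ($C \equiv 0$), pure CPA ($C_{in} = 1$) enters at
the solved steady flows. Per step and per element,

$$C_{in} = \frac{\sum_i C_i Q_i}{\sum_i Q_i}, \qquad
  V_{in} = Q\,dt, \qquad
  C_{t+1} = \frac{V_{in} C_{in} + (V - V_{in}) C_t}{V}.$$

Elements are updated in topological (flow) order within each step and a
child mixes its parents' *already updated* concentrations, making the
scheme semi-implicit along paths. Two consequences are worth knowing:

* **Stability.** The update is a convex combination — hence bounded in
  [0, 1] and monotone under constant inflow — iff $V_{in} \le V$ for
  every element. This is enforced as an error (`max_stable_dt()` reports
  the limit) rather than clamped, because an over-displaced compartment
  silently corrupts downstream concentrations.
* **Conservation.** A parent's own update charges its efflux at the
  pre-update concentration while its child receives the post-update one,
  so the scheme is not exactly conservative link-by-link; the defect is
  O(dt) and is tracked by a running audit (cumulative inflow vs stored +
  cumulative outflow). At `dt = 0.01` s the audit closes to ≤ 0.5 % of
  cumulative inflow by the end of loading; during early front passage
  the defect can be a few percent of the (then small) cumulative inflow
  and halves with `dt`.

Times to 50/90/98 % are linearly interpolated between bracketing steps,
for the total volume-weighted concentration, for each element, and for
the slowest ("last") super lobule. `dt = 0.01` s is the default because
the dt ladder (`dt_convergence_study()`) shows all six reported times
changing by < 1 % between 0.01 and 0.005 s on a 100-super-lobule model.
The simulation kernel is compiled (Rcpp) because the in-step update is
inherently sequential along flow paths.

The boundary-condition sweep re-calibrates and optionally re-simulates
every (pressure, flow) cell, recording $R_{SL}$, maximum wall shear
stress $\tau = 4\mu Q/(\pi r^3)$ (vessels only — lumped elements have no
wall), and 90 %-loading times; infeasible cells are flagged rather than
fatal. The qualitative structure is: $R_{SL}$ falls with target flow and
rises with pressure (both directly from $\Delta P = QR$); higher flows
raise the maximum wall shear stress while higher pressures lower it,
because a larger calibrated $R_{SL}$ dominates branch resistances and
evens out the flow split — the same mechanism that tightens the
dispersion of per-super-lobule loading times at high pressure.

## What the synthetic generator does and does not emulate

The ellipsoid reproduces the volume, the aspect, and the
uniform-attractor statistics of a liver domain, so everything
topological, hydraulic and numerical exercised by the tests transfers.
It does **not** reproduce a real liver's surface concavities, lobar
boundaries, or the specific vessel-length distribution of an anatomical
mesh — so absolute per-model values (calibrated $R_{SL}$, per-super-
lobule pressure drops, which region fills slowest) are
geometry-specific, and passing tests certify internal consistency, unit
correctness and trend directions, not anatomical fidelity. One concrete
example: on the ellipsoid the vessel-only network is less resistive than
on a liver mesh of equal volume, so a (2 mmHg, 1000 mL/min) corner that
is infeasible on a liver model calibrates fine here.

## Problem sizes and determinism

Tests and the acceptance script use 10-25 super lobules with 2000-5000
attractor points for full pipelines and a 100-super-lobule model (20 000
points, ~1700 vessels) for the dt ladder; these sizes keep full suites in
the minutes range while exercising every code path at realistic depth.
All randomness (sampling, k-means, growth ordering) descends from one
master seed through private RNG streams, so identical configs and seeds
give bit-identical models; the command-style entry points are the
exported functions (`generate_model()`, `calibrate_flow()`,
`simulate_loading()`, `sweep_boundary_conditions()`) plus the bundle
writers, which together persist a manifest (seed, parameters, version),
geometry, trees (CSV + VTK polylines), network tables and solution
summaries.

## Known limitations

No hepatic artery; purely resistive elements (no compliance, so no
vasoconstriction/dilation transients); Newtonian, temperature- and
shear-independent viscosity; plug displacement without diffusion or
Taylor dispersion; a single shared $R_{SL}$, which is a calibration
convenience rather than physiology — it makes differently detailed
models meet the same bulk conditions, at the cost of letting the flow
distribution depend on the boundary conditions used to calibrate.
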