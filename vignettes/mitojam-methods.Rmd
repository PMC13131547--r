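---
title: "Modelling mitochondrial traffic jams and axonal swelling with mitojam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mitochondrial traffic jams and axonal swelling with mitojam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitojam)
```

# The model

mitojam is an agent-based simulator of bidirectional, motor-driven
mitochondrial transport in a short axonal segment.  It couples three
mechanical modules:

1. **Mitochondria** are overdamped, self-propelled bead-spring chains.  Each
   bead of radius $r_m$ obeys
   $$\dot{\vec r}_i = \frac{1}{\gamma_m}\vec F_i + v\,\hat n,$$
   where $\hat n = +\hat x$ for anterograde organelles (kinesin-driven, toward
   the presynaptic terminal) and $-\hat x$ for retrograde ones
   (dynein-driven, toward the soma).  Motor stepping is coarse-grained into
   the constant propulsion speed $v$; this corresponds to the limit in which
   motors and microtubules are plentiful.  $\vec F_i$ collects four
   contributions, each implemented as the exact negative gradient of an
   energy:
   * intra-chain Hookean bonds of rest length one bead diameter $2 r_m$
     (stiffness $k_{s,mito}$);
   * a quadratic bending energy $U_b = k_{b,mito}\,\theta^2 / (8 r_m)$ per
     interior bead triple, with $\theta$ the angle between consecutive bond
     tangents (zero for a straight chain);
   * a soft repulsive Hookean contact of range $2 r_m$ (stiffness $k_M$)
     between every non-bonded bead pair, the volume exclusion that makes
     opposing traffic collide;
   * a purely repulsive WCA (truncated, shifted Lennard-Jones) contact with
     $\varepsilon = \phi_0$, $\sigma = r_m$ and cutoff $2^{1/6} r_m$ between
     beads and membrane nodes.
2. **Lifecycle dynamics.**  Every timestep each chain of two or more beads
   fissions with probability $\min(k_{fission}\,\Delta t, 1)$ at a uniformly
   random internal bond; the severed fragment receives a fresh chain id and
   both fragments inherit the parent's direction.  Chain termini within
   $r_{fusion} = 1.1 \times 2 r_m$ of each other fuse with probability
   $\min(k_{fusion}\,\Delta t, 1)$ provided their orientations differ by at
   most $\theta_{cutoff} = 30^\circ$; a same-direction pair keeps its
   direction, a mixed pair picks one at random.  Lifecycle events edit ids
   and connectivity only -- geometry is untouched, and the new bond then
   relaxes under the bond spring.
3. **The axonal boundary** is a triangulated cylinder representing the
   membrane and the membrane periodic skeleton (MPS): circumferential actin
   rings every 180 nm connected by a spectrin lattice.  Node forces comprise
   hinge bending (rigidity $k_b$), a global area-elasticity constraint
   $U = \tfrac12 k_{AE} A_0 (A/A_0 - 1)^2$, Hookean spectrin and actin edge
   springs, and the reaction to the bead-node WCA contact.  Nodes follow
   $\dot{\vec r}_i = \vec F_i / \gamma_a$ in `deformable` mode and are frozen
   in `fixed` mode (the WCA force on mitochondria still applies).

## Parameters

All quantities are SI in the public interface.  The defaults of
`sim_config()` are the baseline axonal parameter set: axon radius
$r_{0,a} = 500$ nm, segment length $L = 3.8\ \mu$m, bead radius
$r_m = 125$ nm, propulsion $v_a = v_r = v_0 = 0.5\ \mu$m/s, drags
$\gamma_m = \gamma_a = 1$ kg/s, $k_{s,mito} = 100$ N/m, $k_M = 40$ N/m,
$\phi_0 = 5\times10^{-15}$ J, $k_{b,mito} \in [10^{-21}, 10^{-19}]$ N m$^2$
(default the rigid end $10^{-19}$), membrane $k_b = 5\times10^{-19}$ J,
$k_{AE} = 10^{-15}$ J, $k_S = 2.06\times10^{-4}$ N/m, $k_A = 0.26$ N/m,
spectrin lattice pitch $l_0 = 38$ nm, actin rest length $l_a = 65$ nm,
lifecycle rates $k_{fission}, k_{fusion} \in [0.01, 100]$ s$^{-1}$ (default
0: static chains).  The density is specified as a fraction of hexagonal
close packing, $\phi = x\,\phi_{max}$ with $\phi_{max} = \pi/(3\sqrt 2)
\approx 0.7405$; `density_to_bead_count()` converts it to a bead count
(81 / 162 / 243 beads at $x = 0.3 / 0.6 / 0.9$ for the default geometry).

## Nondimensionalization and integration

The engine integrates in dimensionless units: lengths in $r_{0,a}$, time in
$r_{0,a}/v_0$ (1 s for the defaults), forces in $\gamma_m v_0$.  The
stiffest dimensionless constant is $k^*_{s,mito} = k_{s,mito}
r_{0,a}/(\gamma_m v_0) = 100$, so forward-Euler linear stability requires
$\Delta t^* < 2/k^*_{max} = 0.02$; the default is $\Delta t^* = 10^{-3}$ and
the engine refuses anything above the bound.  `run_simulation(units =
"si")` integrates the identical dynamics in SI units; a test asserts both
paths agree to floating-point tolerance.  Empirically the WCA contact sets
the practical limit: $\Delta t^* = 5\times10^{-3}$ already triggers the
instability guard (any per-step displacement larger than $r_m$ aborts the
run with a diagnostic).

Numerical guards: the bending gradient uses the tangent dot product clamped
to $[-1, 1]$ and returns the analytic zero-force limit below
$\theta = 10^{-6}$ (the $\arccos$ gradient is singular at $\theta = 0$);
bead-node distances below $0.1\,r_m$ evaluate the WCA force at that floor
(counted and warned, to avoid overflow); the hinge geometric weight
$e_{ij}/A_{ij}$ ($A_{ij}$ = the sum of the two flanking triangle areas) is
frozen at the reference geometry so the hinge force is exactly
$-\nabla\,[k_b (e/A)(1 - \cos(\theta - \theta_0))]$ -- the discrete-shell
convention that keeps bending decoupled from in-plane stretching.
Reference dihedrals $\theta_0$ are those of the constructed cylinder, making
the fresh tube exactly stress-free (a flat reference would pre-stress it and
change its radius immediately).  Steric and WCA sums run over a cell list
with cell size equal to the interaction cutoff, with candidates sorted so
the result is bit-identical to the all-pairs double loop (both paths are
exposed and compared in the tests).

## Mesh construction

`build_axon_mesh()` places rings of $n_c = \mathrm{round}(2\pi r_{0,a}/l_a)
= 48$ nodes every $l_0$ along the axis, alternate rings rotated by half a
step, giving a triangular lattice.  Circumferential bonds of the rings
nearest to multiples of 180 nm are actin; every other bond (circumferential
or diagonal) is spectrin.  Because a triangular cylinder lattice cannot give
all spectrin bonds one identical length, per-edge rest lengths are recorded
from the constructed geometry -- which also makes the fresh mesh an exact
numerical equilibrium, an invariant the tests assert (maximum node speed
below $10^{-6} v_0$ in a membrane-only run).  The two terminal rings are
pinned: the segment stands for a portion of a longer axon and free ends
would curl under bending.  Face orientation is checked during deformable
runs; an inverted face aborts with a diagnostic.

## Simulation protocol

A run starts with two anterograde and two retrograde chains at the two ends.
Every $10 \times N_{chain}$ timesteps one further chain of each direction is
injected (anterograde rear bead at $x = 0$, beads spaced $2 r_m$ toward
$+x$; retrograde mirrored from $x = L$; shared $(y, z)$ uniform on the disc
of radius $r_{0,a} - r_m$) until the live bead count reaches the density
target; the injection cadence makes the filling rate $0.2$ beads per step
independent of chain length.  Because consecutive injections at the same end
overlap sterically before the previous chain has cleared, some freshly
injected beads are expelled through the open ends during filling -- the
"large steric forces while chains are generated" transient -- and are
replaced until the target population is actually reached.  The time at which
it is reached defines the start of the relief-time search window.

Escape removal is configurable.  The default, `removal = "exit"`, deletes a
bead only when it crosses the end it travels toward -- an anterograde bead
at $x > L$ has reached the rest of the axon and leaves the segment; a bead
shoved *backward* out of the segment by jam pressure has not gone anywhere
biologically, so it stays, confined radially by an analytic WCA cylinder
continuing the tube beyond the meshed ends, and re-enters under its own
propulsion.  Beads leave one at a time, shortening the chain they leave.
The alternatives are `"bead"` (any bead past either open end is deleted,
so dense plugs can also drain backward) and `"chain"` (an organelle is
deleted only once every one of its beads is outside; straddlers are
retained whole).  The choice matters at high density: with backward
removal an over-compressed plug partly drains through its own entry ends at
a morphology-independent rate, which shortens granular jams in particular;
with exit-only removal jams resolve by genuine passing and their lifetimes
separate much more strongly by morphology.

Each step executes: injection, force evaluation (recording the
instantaneous velocities $\vec F/\gamma_m + v \hat n$ used by the
observables), fission then fusion, the forward-Euler update, escape removal,
and recording.  All randomness (injection positions, lifecycle draws,
candidate shuffling) is drawn from R's RNG, so a seed makes whole
trajectories bit-identical.

## Observables

* **Ensemble axial speed** $\langle |v_x| \rangle$: bead-averaged absolute
  axial velocity, from the instantaneous equation-of-motion rates, not
  finite differences of frames (exact and stride-independent).
* **Relief time** $\tau_{relieve}$: the first time after the post-injection
  minimum of $\langle |v_x| \rangle$ at which it recovers to $0.95\,v_0$.
  Runs that never dip below the threshold return 0; runs that never recover
  return a flagged `NA` ("unrelieved") rather than a number.
* **Nematic order** $S_x = \langle (3\cos^2\theta - 1)/2 \rangle$ over
  intra-chain bond vectors relative to $\hat x$: 1 aligned, 0 isotropic,
  $-0.5$ perpendicular.  For single-bead populations the bond definition is
  undefined; `nematic_order_x()` signals this and can optionally substitute
  the polarity axis.
* **Shape factor** $SF$: per chain, the mean-square bead distance from the
  chain's centre of mass divided by $N^2$ and by the squared bead
  *diameter*; a straight $N$-chain at rest spacing gives $(N^2-1)/(12N)$,
  i.e. 0.4 at $N = 5$.  The diameter-squared normalization is fixed by that
  worked value; a bead-radius normalization would give 1.6 instead.
* **Maximum radial dilation**: per frame, $\max_i (\sqrt{y_i^2 + z_i^2} -
  r_{0,a})/r_{0,a}$ over membrane nodes -- the axonal swelling measure.
* `jam_summary()` reports the minimum smoothed $S_x$ (centred 5-frame moving
  average) and the shape factor at that time, restricted to the collision
  window: after injection completes and while the population is at least
  half its maximum.  The restriction keeps a near-empty tail of stragglers
  from masquerading as the jam minimum.
* `fit_sigmoid()` fits $y = f + (c - f)/(1 + e^{-s(x - m)})$ by
  Levenberg-Marquardt least squares, for relief times against log lifecycle
  rates; degenerate (flat) data and non-convergence are flagged, never
  silent.  `phase_diagram()` tabulates mean relief times over a
  $(k_{fission}, k_{fusion})$ grid with per-cell seeds.

# What the simulations emulate, and what they do not

Runs generate all data themselves; there is no external input.  The
generated traffic covers the regimes of interest: bidirectional populations
in a 3.8 um segment at 0.3-0.9 of close packing, chain lengths 1-5,
bending rigidities $10^{-21}$-$10^{-19}$ N m$^2$, lifecycle rates
$10^{-2}$-$10^2$ s$^{-1}$.  They do not emulate thermal noise (the
equations are deterministic apart from injection placement and lifecycle
draws), motor binding kinetics, microtubule geometry, hydrodynamics,
membrane fluidity or remeshing, or ATP feedback.  Passing tests therefore
demonstrate the collective mechanics of propulsion, crowding, morphology and
boundary deformation -- not agreement with any particular experimental
trajectory.

A consequence of determinism worth stating plainly: an athermal overdamped
packing can reach an essentially force-balanced state.  Dense bidirectional
plugs -- single-bead populations at $\phi = 0.9\,\phi_{max}$ especially --
can arrest for the entire run horizon with the ensemble speed at
$10^{-3} v_0$ or below, because nothing breaks the transverse symmetry
needed for the populations to lane past each other.  Real axons (and any
simulation with noise) creep out of such states.  Interpreting very long
relief times therefore requires care: they are lower-bounded, not measured,
once a run is flagged unrelieved.

# Design choices at genuinely open points

* **Chain orientation for fusion**: the end-to-end unit vector from first to
  last bead in chain order (the polarity axis for single beads).  End-to-end
  is the standard coarse orientation descriptor; at injection it coincides
  with the direction of motion.
* **Fusion conflict resolution**: candidate terminus pairs are enumerated,
  shuffled with the run RNG and processed greedily; a terminus fuses at most
  once per step, and orientations are evaluated against the live (possibly
  just-merged) chains.  Greedy randomized processing avoids order bias
  without inventing a simultaneous matching problem.
* **Fission split point**: a uniformly random internal bond; both fragments
  inherit the parent polarity (the only choice needing no new information).
  Fission probability is per organelle, not per bond, so long chains are not
  intrinsically more fissile.
* **Injection disc radius** $r_{0,a} - r_m$: prevents injected beads from
  starting inside the membrane's contact range.
* **Terminal rings pinned**, actin rings at the nearest lattice ring to each
  180 nm multiple, per-edge rest lengths: see *Mesh construction*.
* **Injection-stop rule**: the live bead count, not the cumulative injected
  count.  With the cumulative rule the ejection transient at the ends leaks
  a large fraction of single-bead injections and the axon never reaches its
  nominal density.
* **No maximum chain length** is imposed on fusion products.

# Problem sizes in the test suite

The unit tests run on small fixtures (3-12 beads, an 80-node tube).  The
acceptance suite simulates the full geometry at $\phi = 0.9\,\phi_{max}$
for the morphology comparison -- three seeds per chain length, with a 500 s
horizon on the granular arm because its jam lifetimes are heavy-tailed;
a run still jammed at the horizon enters the mean at the horizon, so the
reported relief-time ratio is a lower bound.  The density and lifecycle
trends use three seeds at 90-120 s; the rigidity trend uses six seeds at
120 s and averages the minimum nematic order over runs whose jam relieves
(a frozen plug preserves its orientational order by simply not moving, so
unrelieved runs carry no information about jam-induced scrambling).  The
swelling comparison runs a deformable half-length segment (L = 1.9 um,
about 2400 nodes) for 10 s, bracketing the dilation peak.  A fixed-axon run
of the full system costs roughly 0.4 ms per step on one core; deformable
runs about 2-3 ms per step.

# Membrane softness, wrinkling, and containment

The membrane-MPS parameters are literature values on the piconewton scale
(spectrin $2.06\times10^{-4}$ N/m, membrane bending $5\times10^{-19}$ J),
while the transport side of the model works on the force scale
$\gamma_m v_0 = 0.5\ \mu$N set by its drag coefficient.  The boundary is
therefore five to six orders of magnitude softer than the organelle contact
forces: in deformable mode nodes yield essentially freely where beads press
(the WCA reaction dominates their motion), dilation is limited by the jam's
own pressure release rather than by membrane elasticity, and the slow
elastic recovery after the jam is set by the actin springs
($\gamma_a / k^*_A \approx 4$ s).  Two consequences follow.  First, the
discrete shell *wrinkles* locally under contact -- hinges fold far from
their reference angles.  This is expected physics in this parameter regime,
so folded hinges are counted and reported
(`trajectory$max_folded_hinges`) rather than treated as a fatal mesh
failure; only genuinely degenerate geometry (a zero-area face) aborts.
Second, where the lattice is stretched far beyond its rest spacing the
node-based contact becomes porous and beads can eventually slip between
nodes; deformable runs are therefore most meaningful up to and around the
dilation peak (a few seconds after the collision), which is the window the
swelling observable targets.

# Known limitations

* Deterministic jamming attractors (above): relief-time statistics at high
  density are heavy-tailed across seeds, and a minority of runs never
  relieve within any practical horizon.  Relief-time *ratios* between
  conditions are correspondingly noisy for small seed counts, even where the
  ordering of the means is stable.
* The forward-Euler contact dynamics limit the usable timestep well below
  the spring-stability bound; stiffer contact parameters would require a
  smaller `dt_star`.
* Chains that lose interior beads to escape removal (possible, though rare,
  under `removal = "bead"`) keep a single chain id, so one nominal bond can
  briefly span a gap.
* The membrane has no volume constraint, osmotic pressure or remeshing; very
  large deformations (beyond the face-inversion guard) are outside the
  model's validity.
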