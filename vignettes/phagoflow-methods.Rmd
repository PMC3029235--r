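---
title: "phagoflow: model and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phagoflow: model and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

When a human neutrophil engulfs a zymosan particle it first *pushes the
target outward* by about a micrometre on a protruding pseudopod before
internalizing it; an antibody-coated bead of the same size is instead
embraced almost in place by a thin lamella, and engulfed roughly 2.5 times
faster. phagoflow is a continuum-mechanical simulation of this
single-cell/single-target experiment: a pipette-held cell, a rigid
spherical target of 3.2 µm diameter adhering irreversibly on contact, and a
small switchboard of target-specific mechanical effectors whose settings
distinguish the two phagocytic programs:

| effector                                   | antibody bead | zymosan |
|--------------------------------------------|---------------|---------|
| local stimulus of polymerization/protrusion| 100%          | 75%     |
| protrusive force at free membrane          | same          | same    |
| protrusive force at the contact region     | none          | 50% of free |
| membrane–cytoskeleton attraction at patch  | on            | off     |
| cortical tension (mN/m)                    | 0.025 → 0.15  | 0.025 → 0.3 |
| cytoplasmic viscosity                      | constant      | 5× rise with tension |

The package's deliverables are the simulated target trajectories and three
scalar readouts: push-out distance, engulfment time, and maximum inward
target speed.

## The two-phase flow model

The cytoplasm is modelled as a *reactive interpenetrating flow*: a mixture
of a cytoskeletal network phase (volume fraction $\theta$) and a cytosolic
solvent phase ($1-\theta$) that interconvert (polymerization /
depolymerization) and move with distinct velocities
$\mathbf v_n,\ \mathbf v_s$ coupled by interphase drag $H$. The network is
a viscous fluid whose shear viscosity is linear in its own density,
$\mu = \mu_0\,\theta$, optionally multiplied by a whole-cell stimulation
factor that ramps from 1 to 5 in lockstep with the cortical tension in the
zymosan program. Inertia is negligible (Stokes regime), so each instant
solves a quasi-static balance.

Because the solvent viscosity is negligible against the network
($\mu_{solv}\ll\mu_0\theta$), the solvent momentum equation reduces to a
Darcy drag balance, $(1-\theta)\nabla p = -H(\mathbf v_s-\mathbf v_n)$,
which we eliminate analytically. The remaining system in
$(\mathbf v_n, p)$ is

$$-\nabla\cdot\big(2\mu(\theta)\,\mathbf D(\mathbf v_n)\big) + \nabla p = \mathbf f,
\qquad
\nabla\cdot\mathbf v_n - \nabla\cdot\big(\kappa\,\nabla p\big) = 0,
\quad \kappa = (1-\theta)^2/H,$$

the second line being mixture incompressibility with the Darcy flux. The
solvent velocity is recovered after the solve. A generic signaling
messenger $m$ obeys $\partial_t m = D_m\nabla^2 m - k_{dec}\,m$ with a
Neumann influx on the membrane at the leading edge of fresh adhesion, and
drives polymerization
$\dot\theta = k_{pol}\,m\,(\theta_{max}-\theta) - k_{dep}(\theta-\theta_{base})$.

### Boundary conditions and interfacial mechanics

* **Cortical tension** enters variationally: the nodal force is the exact
  negative gradient of the discrete membrane area of revolution times
  $\gamma(t)$. This makes the static Laplace law ($p = 2\gamma/R$ on a
  sphere) hold to discretization accuracy without ever evaluating a
  discrete curvature. The tension timeline is piecewise linear (rest value
  until contact + 10 s, 60 s ramp, plateau), as measured.
* **Disjoining (protrusive) stress** $\sigma_p\,\theta$ acts outward on the
  membrane with the equal-and-opposite reaction on the membrane-adjacent
  network ring. The cell–target *contact region* is defined geometrically:
  the adhered patch plus membrane within `contact_zone_gap` of the sphere,
  with the zone weight blending linearly across the gap (a sharp zone edge
  couples the protrusion discontinuously to target motion and destabilizes
  the force balance). In the contact region the stress is scaled by the
  scenario's contact-protrusion factor (0, 0.5, or 1).
* **Membrane–cytoskeleton attraction** (antibody program) is a constant
  inward stress `sigma_attract` on the adhered patch, with the reaction on
  the adjacent network — the "flattening onto the bead".
* **Adhesion** is irreversible. Free boundary nodes within 2% of the
  target radius of its surface, contiguous with the patch, are captured,
  projected onto the sphere, and thereafter move rigidly with it. Adhered
  nodes are re-snapped onto the sphere every step: captures admit a gap
  tolerance, and leaving that jitter in place gives the patch polyline
  spurious concave wiggles that degenerate the adjacent quads.
* **Contact-line zipper.** At desk-scale resolution (elements of
  ~0.2–0.5 µm against a capture tolerance of 32 nm) contact formation
  cannot emerge from the resolved stress field alone: the membrane
  equilibrates just outside the capture tolerance and the cup freezes. We
  therefore model the advance of the adhesion front explicitly as a driven
  dashpot between the leading free node and the target: drive speed
  `zip_speed` scaled by the local polymerization state (so the 75% zymosan
  stimulus slows its cup), plus `zip_speed_attract` when the Fcγ
  attraction is present; the dashpot stiffness is a stress scale times the
  local membrane area and the instantaneous tension ratio. The reaction
  acts on the target. This is the package's principal sub-grid closure; it
  is what carries the engulfment-time differences between the programs.
* **Rigid target.** The sphere's axial velocity $W$ is one additional
  unknown; all patch-node momentum rows are condensed onto it, so the
  quasi-static force balance on the target (adhesion tractions, tension,
  contact-zone push, zipper reaction) is solved monolithically.
* **Micropipette.** The holding pipette is an axisymmetric stand-in: the
  rear cap of the cell (arclength `rear_hold_len`, default 1.2 µm — a
  realistic pipette mouth) is a flat, fixed disk with no-slip velocity;
  the pipette lip is a genuine convex corner of the cross-section.

## Discretization

The cross-section is a single structured block of bilinear quadrilaterals:
logical row $j=0$ on the symmetry axis, the membrane meridian along the
other three sides, 30 × 26 elements at resolution 1 (780 elements, chosen
so the radial (right) logical column holds more boundary nodes than the
fully wrapped patch consumes — a block corner cannot survive on the
concave adhered arc). Velocities and pressure are equal-order Q1–Q1; the
physical Darcy term plus a small Brezzi–Pitkäranta term stabilizes the
pair, and the nodal pressure matches the model's field layout. Momentum
and the backward-Euler messenger step assemble sparse matrices solved by
direct LU (Matrix package).

Each cycle advances: adhesion capture → momentum solve (with $W$) →
timestep control → Lagrangian advection of the mesh with the network flow
(element network mass $\theta V$ is exactly conserved) → node
repositioning → conservative remap → implicit messenger step → phase
interconversion → bookkeeping.

Numerical choices that matter:

* **Timestep.** The Courant bound rarely binds; the binding constraint is
  the *capillary* limit of explicit boundary motion under surface tension,
  $\Delta t \le 0.3\,\mu_{min} h_{min}/\gamma$. Violating it produces a
  slowly growing, then explosive, oscillation of the free surface that
  masquerades as a physical expulsion of the target.
* **Repositioning.** Free-membrane nodes slide along the polyline toward
  weighted equal-arclength positions (bounded moves, the zipper's lead
  node anchored); interior nodes relax by red-black SOR on the Winslow
  (inverse-harmonic) stencil, which does not fold at concave boundary
  sections (plain Laplacian smoothing does, exactly where the engulfment
  cup forms). A backtracking blend guarantees the global minimum
  scaled-Jacobian quality never degrades materially, with a local
  untangler as a rescue path.
* **Remap.** After repositioning, element fields are remapped by upwind
  swept-face volume exchange (exactly conservative and monotone for the
  small moves involved); nodal fields by a gradient-based update clipped
  to old extrema with a bounded conservative mass fix for the messenger.
* **Volume.** Mixture incompressibility keeps the enclosed volume constant
  up to time-integration error; a uniform normal displacement of the free
  membrane (sub-nanometre per step) corrects the residual drift, so
  cumulative volume drift over a full run stays far below the 2% contract.
* **Membrane regularization.** An optional high-passed spring toward the
  neighbour midpoint (`bending_stab`, pN/µm) stands in for the bending
  rigidity of the membrane–cortex composite at the element scale. With
  the capillary timestep in place the calibrated runs do not need it and
  it defaults to off (any midpoint spring, even high-passed, slightly
  biases the Laplace balance on non-uniformly spaced polylines).

## Parameters and calibration

Units are µm, s, pN throughout (stresses pN/µm² = Pa; tensions pN/µm;
1 mN/m = 1000 pN/µm, converted once when configs are read). Measured
inputs are the target radius (1.6 µm), the cell radius (4.25 µm), and the
tension timelines. All constitutive magnitudes are unprinted in the
source experiments and are calibration choices of this package
(`default_params()`), fixed once with `scripts/calibrate.R`:

* `mu_network_0 = 30000` pN s/µm² per unit θ (resting bulk viscosity
  `mu_network_0 * theta_base` = 1.5 kPa s). Lower, more literature-typical
  viscosities make the sub-equator cup configuration expel the target
  faster than the adhesion front can advance at this resolution, so the
  calibration sits deliberately on the viscous side; the cost is that
  simulated speeds and times are slower than the measured ones (see
  Limitations).
* `sigma_protrude = 2000` pN/µm² per unit θ: sets the zymosan push-out
  scale through the 50%-scaled contact-zone stress.
* `sigma_attract = 120` pN/µm², `attract_range = 0.3` µm.
* messenger: `D_m = 0.8` µm²/s, `k_decay = 3` /s (signal localized to
  ~0.5 µm of the leading edge), `tau_transient = 10` s, source annulus two
  boundary nodes wide.
* polymerization: `k_poly = 1.2` /(a.u. s), `k_depoly = 0.12` /s,
  `theta_base = 0.05`, `theta_max = 0.5`.
* zipper: `zip_speed = 0.25` µm/s (polymerization-saturated),
  `zip_speed_attract = 0.1` µm/s, stiffness scale 80000 pN s/µm³.

## What the synthetic benchmarks emulate

`gen_trace()` builds experiment-like noisy target-position traces from the
published population statistics (push-out 1.03 ± 0.3 µm and completion
167 ± 73 s for zymosan; 0.12 ± 0.14 µm and 66 ± 19 s for antibody; inward
speed ~33 nm/s), with a smooth rise–plateau–linear-inward skeleton and
i.i.d. Gaussian tracking noise (SD 0.05 µm, sub-pixel scale) at 1 Hz. The
skeleton shape itself is an emulation — the experiments constrain the
three scalar metrics, not the detailed wave form — so recovery tests prove
the observables pipeline, not the biology. Cohort summaries are computed
from the noise-free skeletons so that they estimate the generating
parameters free of tracking-noise bias.

## Problem sizes used by the shipped tests

The test-suite and acceptance runs use the coarse default mesh (780
elements); scenario runs are truncated where a metric does not require the
full span (the resolution-doubling comparison, for instance, compares
push-out over the first 90 s of the zymosan program at 1× and 2×
resolution). The full zymosan and antibody runs span 300 s and 150 s of
simulated time.

## Known limitations

* **Engulfment does not close at desk scale.** With the calibrated
  parameters both programs form a deep cup (the adhered arc reaches
  roughly 75–100° of the 175° completion criterion within the simulated
  span) but the adhesion front slows in the strongly wrapped regime: the
  lamella that must fold around the equator is the most viscous, most
  stressed part of the domain, and on the stable side of the calibration
  its advance is slower than measured. Engulfment-time readouts are
  therefore reported as incomplete by `engulfment_time()` rather than as
  numbers, and the corresponding acceptance checks fail honestly. At the
  same time the early-phase mechanics — the push-out contrast between the
  two programs and its ordering in the contact-protrusion scale — is
  reproduced quantitatively.
* Simulated inward target speeds (~8 nm/s for the zymosan program) are a
  factor of a few below the measured ~33 nm/s, for the same
  viscosity-calibration reason; the antibody run ends before its
  internalization phase, so its speed readout is degenerate.
* Because the contact-line zipper is a node-spacing-dependent closure
  (its capture cadence and force capacity scale with the local element),
  observables inherit a stronger resolution dependence than the resolved
  flow solution: the push-out shifts by a few tenths of a micrometre
  between 1× and 2× resolution.
* The early phase (push-out) is numerically robust; the post-ramp phase
  is dynamically sensitive, so late-trajectory readouts such as the
  inward speed can shift noticeably under small perturbations.
* The messenger advects with the network rather than the solvent; the
  difference is second order at the drag coefficients used.
* No membrane area reservoir, no receptor kinetics, no myosin
  contractility (the latter deliberately: the modelled force inventory
  follows the effector table).
* The initial shape (sphere with a flat held cap) is not a tension
  equilibrium; the first ~10 s contain a small shape-relaxation transient.
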