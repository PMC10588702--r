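---
title: "Soft-body physics for a partial-nephrectomy trainer: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft-body physics for a partial-nephrectomy trainer: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kidneysim)
```

## The problem

Laparoscopic partial nephrectomy (LPN) removes a kidney tumour while
preserving the organ. The critical skill is marking and cutting precisely
along the tumour margin. `kidneysim` reproduces the physics of that training
task headlessly: a deformable triangle-mesh organ with a labelled
"cancerous" lobe, scripted interaction (ray picking, cut marking), tearing
of over-stretched connections, and resection of the labelled region. Every
run is deterministic given its configuration and seed, so task outcomes
(label purity, healthy-tissue damage, component counts) are reproducible
measurements rather than screenshots.

## The two-layer deformation model

The soft body is a closed triangle surface whose vertices carry mass
(default 1 kg per vertex), velocity and an accumulated force. Two layers
act on it each frame.

**Force layer.** The per-vertex composite force is
$F_j = F_{s,j} + F_{d,j} + F_{p,j} + F_{o,j}$:

* *Spring* (`k_spring`, N/m): Hooke's law along every mesh edge,
  $k\,(\lVert x_i - x_j\rVert - d_{12})$ with rest length $d_{12}$,
  applied equal-and-opposite. The linear form along the edge direction is
  the standard choice for an edge-spring network.
* *Pressure* (`pressure`, N/m²): per face, $P \cdot \Delta A \cdot \hat n$
  with the *current* area and outward normal, distributed in equal thirds
  to the face vertices. On a closed mesh a uniform pressure produces a net
  force that vanishes (divergence theorem), which the tests verify; it
  inflates the body and gives the surface its volumetric feel. Equal
  thirds (rather than angle weighting) is the simplest rule consistent
  with a per-face force statement.
* *Damping* (`damping` = $d$, 1/s): written directly as the velocity
  rescale $v \leftarrow v\,(1 - d\,\Delta t)$, applied after force
  integration. It occupies the damping slot of the composite force but is
  implemented exactly as the printed rescaling formula; $d\,\Delta t > 1$
  would flip velocity signs and is rejected at validation.
* *Offset* (`offset_magnitude`, N): the interaction component. When a tool
  contacts the surface, contacted vertices are additionally driven along
  their inward normals (or a fixed direction), so poked vertices follow
  the surface rather than sliding off it.

Interaction forces attenuate with distance from the contact point as
$F / (1 + d^2)$ — full strength at zero distance, smooth falloff with no
extra parameters.

Integration is semi-implicit Euler in a fixed documented order: accumulate
forces, $\Delta v = (F/m)\,\Delta t$, damping rescale, $\Delta p = v\,\Delta t$.
The order matters for reproducibility; the equations alone do not pin it
down, so it is frozen here and covered by the free-fall test (position
error against $\tfrac12 a t^2$ bounded by the first-order term
$a\,\Delta t\,t/2$).

**Constraint layer (position-based dynamics).** After velocities are
updated, predicted positions $p = x + v\,\Delta t$ are projected onto the
constraint manifold by Gauss–Seidel sweeps (`iterations` per step, fixed
order stretch → bend → collision), then $v = (p - x)/\Delta t$ and
$x = p$. Constraints are:

* *Stretch*: $C_{str} = \lVert x_1 - x_2\rVert - d_{12}$ per edge.
  Projection moves endpoints along the edge direction weighted by inverse
  mass; pinned vertices have $w = 0$ and never move.
* *Bend*: $C_{bend} = \arccos(n_1 \cdot n_2) - \varphi_{12}$ per interior
  edge, with $n_1, n_2$ the unit normals of the triangles
  $(x_1, x_3, x_2)$ and $(x_1, x_2, x_4)$ built on the shared edge
  $(x_1, x_2)$. With consistent outward winding both normals point
  outward, so a coplanar pair evaluates to zero and $\varphi_{12}$ is the
  rest dihedral deviation in $[0, \pi]$. Normals are evaluated at
  *current* positions against the *rest* angle: evaluating both at rest
  (as a literal reading of "normal vectors in the rest position" would
  suggest) would make the constraint a constant. The projection follows
  the canonical analytic dihedral gradient; the dot product is clamped to
  $[-1, 1]$ before `acos`, and degenerate triangles or near-zero gradients
  skip the constraint for that sweep rather than producing NaN.
* *Collision*: inequality constraints $C \ge 0$ against static colliders
  (half-space planes and static triangle meshes), generated per step for
  vertices whose motion segment ends on the wrong side. Colliders are
  static by convention — the organ bed does not react. Self-collision is
  not handled.

Stiffness values $k \in [0,1]$ are converted to the per-iteration form
$k' = 1 - (1-k)^{1/n_s}$ so the effective stiffness is independent of the
iteration count. The solver monitors the total constraint energy
$E_{tot} = \sum (k_{str} C_{str}^2 + k_{bend} C_{bend}^2)$, which is zero
exactly at a satisfied configuration and non-increasing across sweeps at
stiffness 1 (a property test).

**Hybrid ordering.** The combination of the two layers is deliberately:
force layer produces tentative velocities only; the PBD layer predicts,
projects and derives the final velocities. Letting the force layer also
move positions would integrate the same displacement twice. This ordering
is the package's choice (the combination itself admits several), and the
long-run stability test — 5,000 steps on a pressurized sphere at default
parameters with bounded positions and inflated volume — is the contract
that pins it.

## Tearing, cutting, resection

Every stretch constraint can be flagged *breakable* with a threshold.
After each solve, `tear_step()` permanently removes breakable constraints
whose extension exceeds the threshold — by default the **relative**
extension $\lVert p_i - p_j\rVert / d_{12} - 1 > 0.4$ (an absolute-length
mode is available). The relative form is chosen because breakability
should depend on the rest length: a long edge should not tear sooner than
a short one at the same strain. Bend constraints hinged on a torn edge
are removed with it. Tearing is monotone: the constraint set only shrinks.

Cutting never re-meshes. A cut path is an ordered sequence of surface
samples (typically from `cast_ray()`); `mark_cut_path()` connects
consecutive samples across the face-adjacency graph and records every
shared edge the walk crosses. `apply_cut()` either severs the constraints
on those edges immediately or marks them breakable so they fail under
load. `resect()` removes face-to-face adjacency across the crossed edges,
splits the faces into components, and extracts the component matching the
requested label; vertices on the separating cycle are duplicated so both
pieces become independent meshes. Note the two graphs involved: severing
constraints on the cut line leaves the *vertex* graph connected (the cut
line's vertices are shared until resection); it is the *face* graph that
separates, and the vertex sets separate when resection duplicates the
cut-line vertices.

`plan_boundary_cut()` scripts the ideal trainee: it orders the label
boundary edges into a cycle and emits a closed sample loop whose marked
cut severs every boundary edge. Connector hops between crossings are
routed by a cheapest-safe-path search in which re-crossing an already-cut
edge is free and severing the last intact edge of any triangle is
forbidden — without that rule a zigzag along a convoluted boundary can
strand single triangles as extra components. The planner verifies that
its severed set yields exactly two components before returning.

## The synthetic phantom

Trainer assets of this kind are usually hand-modelled in a 3D editor; the
phantom is generated procedurally instead, so every test builds its own
geometry:

* base surface: icosphere at `subdivision` 3 (642 vertices, 1,280 faces) —
  chosen as the trade-off point between solver cost and a smooth enough
  dihedral field; configurable.
* bean profile: a seeded, smooth radial indentation (Gaussian in angular
  distance, depth ≈ 0.18–0.22 of the radius) on the hilum side, kept
  orthogonal to the tumour direction.
* tumour: an exophytic lobe along `tumor_direction` with angular radius
  $\theta = \arcsin(f)$ for `tumor_fraction` $f$ (default 0.35, emulating
  a 3–5 cm peripheral mass on a ~11 cm organ), raised-cosine bulge of
  height $0.5 f$; faces whose unit-sphere centroid lies in the cap are
  labelled `"cancerous"`. Labels are assigned on the unit sphere *before*
  displacement and scaling, so the labelled area fraction can be checked
  against the analytic cap area $(1 - \cos\theta)/2$.
* anisotropic scale `kidney_scale` (default semi-axes 5.5 × 3.5 × 3.0 cm).

The generator is a pure function of its spec: identical specs give
bit-identical meshes (the jitter stream is a self-contained
Lehmer generator seeded from the spec, so the global RNG state is never
touched). What the phantom does **not** emulate: patient-specific anatomy,
vessels and ureter, multi-layer fascia, or contact with neighbouring
organs — so passing tests demonstrate the physics and the task logic, not
anatomical fidelity.

## Parameters that matter

| parameter | unit | default | notes |
|---|---|---|---|
| `dt` | s | 0.01 | explicit step; stability guard warns if `k_spring*dt^2/m > 1` |
| `k_spring` | N/m | 50 | edge-spring stiffness |
| `damping` | 1/s | 0.5 | must satisfy `damping*dt <= 1` |
| `pressure` | N/m² | 0–20 | negative deflates |
| `offset_magnitude` | N | 0 | interaction offset along inward normals |
| `iterations` | – | 4 | PBD Gauss–Seidel sweeps per step |
| `k_str`, `k_bend` | – | 0.9, 0.5 | in [0,1], per-iteration corrected |
| `break_threshold` | – | 0.4 | relative extension before tearing |
| `subdivision` | – | 3 | phantom resolution (20·4^k faces) |
| `tumor_fraction` | – | 0.35 | tumour radius / organ radius |

## Numerical choices and degenerate inputs

* Degenerate (zero-area) faces contribute zero pressure force and zero
  normal; coincident edge endpoints produce zero spring force and skip
  stretch projection (direction undefined) instead of erroring mid-run.
* `acos` arguments are clamped; isolated vertices get a flagged zero
  normal, never NaN.
* Non-manifold meshes (an edge with more than two faces, or inconsistent
  winding) are rejected up front: both physics layers assume at most two
  faces per edge.
* Ray casting breaks exact ties by the smaller face index; the dual-graph
  walks used in cut marking add a small constant to edge weights so
  equal-length walks resolve to fewer hops, deterministically.
* STL has no shared vertices; import welds on exact coordinate equality,
  which is correct for generated fixtures (scanned data would need a
  tolerance weld).

## Problem sizes used by the test-suite

The suite exercises icospheres at subdivisions 0–3 (12–642 vertices), the
default 1,280-face phantom, and a 5,000-step hybrid stability run at
default parameters followed by a 500-step relaxation; the full suite runs
in well under a minute on one core. Kinetic energy during relaxation is
checked as a windowed envelope (maxima over 100-step windows
non-increasing) because Gauss–Seidel projection exchanges tiny amounts of
energy between constraints step to step; the envelope, not the raw
per-step sequence, is the physically meaningful decay.

## Known limitations

* Single-layer surface: no volumetric (tetrahedral) elasticity, no fascia
  layers, so a resected margin has no thickness.
* No self-collision; colliders are static.
* Cutting follows existing mesh edges (no progressive re-meshing), so cut
  fidelity is bounded by mesh resolution.
* The simulator is headless: haptic feedback is represented as a logged
  contact-force/tear event stream, not device vibration.
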