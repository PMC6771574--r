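---
title: "Methods: automated LITT trajectory planning in littplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated LITT trajectory planning in littplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(littplan)
```

## The planning problem

Laser interstitial thermal therapy (LITT) for mesial temporal lobe
epilepsy ablates the amygdalohippocampal complex through a single laser
fibre placed along a stereotactic trajectory from an occipito-temporal
entry point. The quality of a trajectory is judged by a handful of
heuristics that surgeons normally weigh by eye: it should follow an
avascular corridor, avoid the ventricles and sulci, keep its distance
from the brainstem, stay short, and meet the skull close to
perpendicular so the drill does not skive. `littplan` turns these
heuristics into a deterministic constrained search: for a fixed
anatomically parameterised target, every candidate entry point on a
labelled entry region is scored and filtered, and the survivors are
ranked.

The package consumes a whole-brain parcellation (a labelled voxel
volume) plus a vasculature mask; producing these is upstream
segmentation work and out of scope. A role map connects parcellation
label IDs to planning roles, because label numbering differs between
parcellation pipelines.

Coordinates are RAS millimetres throughout; voxel indices are 0-based;
a voxel occupies the closed unit cube centred on the world image of its
index. "Medial" is toward the mid-sagittal plane, estimated as the x
midpoint of the skull-shell bounding box, so its sign depends on the
hemisphere being planned.

## Target parameterisations

Three automated targets are defined relative to the amygdala centroid:

* `centroid_T2` — the centroid itself (the benchmark parameterisation);
* `expert_T3` — 3 mm anterior, 3 mm medial and 3 mm inferior to the
  centroid (expert-consensus parameters);
* `ml_T4` — 3 mm anterior and 3 mm medial, with no inferior shift
  (machine-learning-derived parameters).

`centroid_T2` and `expert_T3` search entries on the inferior occipital
gyrus; `ml_T4` uses a temporo-occipital-junction entry region. The
target is fixed per parameterisation; the search is over entry points
only, enumerated as the entry region's scalp-facing surface voxels in a
deterministic lexicographic order.

## Hard constraints

Defaults follow standard LITT planning practice and are all
configurable via `planning_constraints()`:

| constraint | default | unit |
|---|---|---|
| maximum length | 120 | mm |
| maximum drilling angle to the skull normal | 30 | degrees |
| minimum clearance from vessels and sulci | 3 | mm |
| minimum clearance from the brainstem | 7 | mm |
| no-entry structures | lateral ventricle | — |

Comparisons are inclusive at the printed bound (a 120.0 mm trajectory
passes; the angle limit is implemented as `<= 30`), which avoids
floating-point knife edges. Sulci share the 3 mm critical-structure
margin with vessels by default but both margins are independently
configurable.

Clearances are evaluated by sampling a Euclidean distance field of each
critical structure at 128 equally spaced trajectory nodes. Distance
fields are exact (voxel-centre) Euclidean distance transforms honouring
anisotropic spacing, computed by the separable lower-envelope algorithm
in compiled code; off-grid queries are trilinearly interpolated and
clamp to the border voxel, because entry points sit on the scalp near
the grid edge.

No-entry structures are tested by exact voxel traversal
(`segment_intersects_exact()`, a 3-D digital differential analyser that
walks every voxel the segment passes through). Sampled intersection
testing was the original design — it is simpler and sub-voxel accurate
at the stated margins — and the sampled `segment_intersects()` (0.5 mm
default step) remains the general-purpose utility. But a sampled test
at any fixed step can miss a corner graze whose chord through a voxel
is shorter than the step, and corridor-recovery audits on adversarial
phantoms showed exactly such grazes of the ventricle at ranked entries.
A no-entry zone is a strict prohibition, so the planner's transgression
test must be exact rather than "accurate with high probability"; the
traversal costs no more than the sampled test.

The drilling angle is measured between the trajectory and the
skull-surface normal line (orientation-insensitive). The normal is the
gradient of a Gaussian-smoothed (sigma = 1 voxel) signed distance of
the filled skull shell, evaluated by central differences at the entry.
Filling the shell first makes the sign of the gradient unambiguous on
and inside the shell itself, where entry voxels live; on the outer
surface this equals the signed distance of the shell. A smoothed
gradient is robust on voxelised shells, where raw finite differences
alias badly.

## The risk score

The avascular-corridor risk score samples the vessel distance field at
`n_nodes = 128` nodes (entry and target inclusive) and maps each node
distance $d$ to a per-node risk

$$ r(d) = \frac{d_{max} - \min(d, d_{max})}{d_{max} - d_{safe}}, $$

with $d_{safe} = 3$ mm (the safety margin) and $d_{max} = 10$ mm (the
radius beyond which a vessel contributes nothing). So $r(d_{max}) = 0$,
$r(d_{safe}) = 1$, and $r$ rises linearly above 1 inside the margin up
to $r(0) = d_{max}/(d_{max}-d_{safe}) = 10/7$. The score is the mean
over nodes.

Three choices here were genuinely open:

* **Linearity.** The only hard anchor for the per-node form is that the
  normalised value exceeds 1 exactly when the vessel distance falls
  below the user-defined safety margin. The linear ramp is the simplest
  continuous form satisfying that anchor.
* **$d_{max} = 10$ mm.** The outer radius of the risk zone is not a
  published constant; 10 mm keeps the risk local to the corridor while
  making $r(d_{safe}) = 1$ exact. It is a `risk_params()` field, not a
  hard-coded number.
* **Mean aggregation.** The node count is fixed regardless of
  trajectory length precisely so longer trajectories do not accrue more
  risk; a sum would reintroduce that length dependence, so the default
  aggregate is the mean. Under mean aggregation "score > 1" means the
  corridor is *on average* inside the margin; under max aggregation it
  means *some* node is inside the margin. Both readings are defensible,
  so `risk_params(aggregate = "max")` exposes the second; the default
  is the mean.

## The ablation model

The thermal cavity is modelled as a uniform-diameter capsule (cylinder
with hemispherical caps) along the distal trajectory. The diameter is
one constant in [5, 15] mm, default 15 — the estimated maximal uniform
cavity; the range expresses device and titration variability, not
along-fibre tapering. The capsule's distal endpoint is the target; its
proximal endpoint is the most proximal trajectory point whose distance
to the union of the mesial ROIs (amygdala, hippocampus, entorhinal
cortex, parahippocampal gyrus) is at most the capsule radius — i.e. the
cavity is extended exactly as far back as it still touches the ROI
complex. An optional clipping plane (e.g. at the level of the tectum)
can truncate it, which matters for reproducing manual plans; the
default applies no plane because the phantom defines no tectum
landmark.

The capsule is voxelised by the point-to-segment distance predicate at
voxel centres, and overlap volumes are voxel counts times voxel volume.
Percent ablation normalises each structure's overlap by its
preoperative volume. The capsule (rather than a flat-ended cylinder)
was chosen because thermal cavities are rounded at the fibre tip and
the capsule has clean closed forms ($\pi r^2 h + \tfrac43 \pi r^3$)
against which the voxeliser is tested to 2% on a 0.5 mm grid.

## Ranking

Feasible candidates are ranked by (1) ascending risk score,
(2) descending combined amygdala + hippocampus ablation percentage,
(3) ascending length, with final ties broken by entry enumeration
order. Safety outranks ablation because vascular conflict is the
dominant complication mechanism; ablation percentage is the efficacy
surrogate; length is a tie-breaker only. Ablation metrics are computed
lazily for the candidates whose risk ties could affect the returned
top-k, which keeps the exhaustive entry scan cheap.

## The phantom generator

`generate_phantom()` builds a synthetic head on a 128^3, 1 mm grid: an
ellipsoidal amygdala (closed-form volume about 1.5 mL), a curved-tube
hippocampus with an anterior head bulge lying along the natural
occipital approach axis, a flattened parahippocampal sheet inferomedial
to it, an entorhinal blob at its anterior end, a temporal-horn
ventricle superolateral to the hippocampus, a midline brainstem
cylinder, and a spherical skull shell carrying two labelled entry
patches. Structure geometry is deterministic; the seed drives only the
tortuous vessels and the sulcal sheets. Vessels are concentrated inside
the two entry approach cones so that, without intervention, almost
every candidate trajectory violates the 3 mm vessel margin; the
`corridor = "open"` mode then carves an avascular tube of radius 6 mm
from each entry-patch centre to its target, guaranteeing (and
verifying, via the planner's own feasibility checker at generation
time) at least one feasible trajectory per parameterisation.
`corridor = "blocked"` instead seals both approaches with a vessel
sheet just inside the skull, so a correct planner must return an empty
result. Ground truth records hold independent 0.5 mm quadrature
measurements of the generating shapes, the carved corridor mouths, and
the pre-verified trajectories.

What the phantom does *not* emulate: MRI intensities, bias fields,
hippocampal sclerosis, realistic vascular trees, gyral folding, or
patient-to-patient anatomical variability. Passing the phantom suite
therefore demonstrates the planner's geometric and algorithmic
correctness — constraint enforcement, corridor recovery, metric
computation — not clinical validity on patient parcellations. Cohort
statistics from patient studies (mean risk scores, mean ablation
percentages) are not reproducible from phantoms and are not targets of
the test suite. One known stylisation: with a 15 mm capsule on a
phantom whose mesial structures are only a few capsule radii across,
centroid targeting already covers most of the amygdala, so the
between-parameterisation spread of amygdala ablation is compressed
relative to patient cohorts; the phantom is built so the three
parameterisations remain measurably different (in particular `ml_T4`
spares the parahippocampal gyrus and posterior hippocampus, and
`expert_T3` ablates the most parahippocampal gyrus).

## Numerical choices and problem sizes

* Distance transforms are exact to voxel centres; interpolation error
  off-grid is bounded by one voxel diagonal and all oracle tests use
  that tolerance.
* The risk score's steepest sensitivity to distance error is
  $1/(d_{max}-d_{safe}) = 1/7$ per mm, which converts the interpolation
  bound into the score tolerance used in tests.
* Quadrature ground truth for phantom structures uses 0.5 mm midpoint
  evaluation of the analytic predicates — independent of the 1 mm
  rasterisation it is compared against (3% volume, half-voxel centroid
  tolerances).
* Degenerate inputs error early and explicitly: empty masks for
  centroids or distance fields, zero-length trajectories, targets
  outside the grid, structures of zero volume.
* The test suite audits 20 seeded open-corridor phantoms and 20 blocked
  phantoms at the default 128^3 grid with an entry stride of 2
  (roughly 120 candidates per method), which keeps the full sweep
  around four minutes on one CPU while still exercising every
  constraint on every seed.

## Limitations

* Single-trajectory planning only; staged multi-fibre ablations are not
  modelled.
* The thermal model is a uniform capsule: no bioheat simulation, no
  heat-sink effects from CSF or vessels, no per-patient cavity
  nonlinearity.
* Vessel calibre is ignored by the risk score; a large vein and a small
  vessel at equal distance contribute equally.
* Image registration, parcellation and vessel segmentation are
  upstream of the package.
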