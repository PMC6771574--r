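# littplan

Automated stereotactic trajectory planning for laser interstitial
thermal therapy (LITT) of the mesial temporal lobe, for neurosurgical
planning researchers and imaging scientists who work with whole-brain
parcellations.

LITT for mesial temporal lobe epilepsy places a laser fibre along a
single trajectory from an occipito-temporal entry to the amygdala, then
ablates the amygdalohippocampal complex. Surgeons plan such trajectories
by heuristics — find an avascular corridor, avoid ventricles and sulci,
stay clear of the brainstem, keep the path short and near-orthogonal to
the skull. `littplan` implements those heuristics as a deterministic
constrained search over candidate entry points, with:

* **hard constraints**: length ≤ 120 mm, drilling angle to the skull
  normal ≤ 30°, ≥ 3 mm from vessels and sulci, ≥ 7 mm from the
  brainstem, no ventricle transgression;
* **a risk score** summarising the avascular corridor: the vessel
  distance *d* is sampled at 128 equally spaced nodes (length-invariant
  by construction) and each node contributes
  *r(d) = (d_max − min(d, d_max)) / (d_max − d_safe)*, normalised so
  that *r* = 1 at the 3 mm safety margin and *r* > 1 inside it; the
  score is the node mean;
* **three target parameterisations** relative to the amygdala centroid:
  the centroid itself (`centroid_T2`), a 3 mm
  anterior + medial + inferior shift (`expert_T3`), and a 3 mm
  anterior + medial shift (`ml_T4`);
* **an ablation estimate**: a uniform 5–15 mm diameter capsule
  (default 15) along the distal trajectory, voxelised and intersected
  with the amygdala, hippocampus, entorhinal cortex and parahippocampal
  gyrus, reported as volumes and percentages of each structure's
  preoperative volume;
* **a seeded phantom generator** producing complete synthetic head
  scenes (with a guaranteed avascular corridor, or deliberately
  blocked), so the whole pipeline runs and is tested without any
  patient data.

## Worked example

```r
library(littplan)

ph <- generate_phantom(phantom_spec(seed = 42))
ph
#> <litt_phantom> seed 42, left hemisphere, corridor open
#> <litt_scene> left hemisphere, grid 128 x 128 x 128, midline x = 63.5 mm
#>   amygdala                   1539 mm^3
#>   hippocampus                3278 mm^3
#>   entorhinal_cortex           648 mm^3
#>   parahippocampal_gyrus      1201 mm^3

pl <- plan_trajectories(ph$scene, spec = target_spec("expert_T3"), stride = 2)
pl
#> <litt_plan> method expert_T3: 1 feasible plan(s) of 119 entry candidates
#>   rank 1: length 63.4 mm, angle 21.7 deg, risk 0.407, amygdala 65.4%, hippocampus 89.9%

estimate_ablation(pl$plans[[1]]$trajectory, ph$scene)
#> <ablation_estimate> total 12337 mm^3, length 59.9 mm
#>   amygdala                  1007 mm^3  ( 65.4%)
#>   hippocampus               2947 mm^3  ( 89.9%)
#>   entorhinal_cortex            1 mm^3  (  0.2%)
#>   parahippocampal_gyrus      456 mm^3  ( 38.0%)
```

The rank-1 plan threads the carved avascular corridor (risk 0.407 means
the corridor averages comfortably outside the 3 mm margin), meets every
hard constraint, and its 15 mm cavity covers 65% of the amygdala and
90% of the hippocampus while barely touching the entorhinal cortex.
`evaluate_trajectory()` computes the same record for a user-supplied
entry/target pair (e.g. a reconstructed manual plan), and
`compare_methods()` summarises per-method cohorts with a one-way ANOVA
and Bonferroni-corrected pairwise comparisons.

A thin CLI wraps the same functions:

```sh
exec/litt phantom --seed 1 --out-dir scene/
exec/litt plan --labels scene/phantom_labels.nii.gz \
               --rolemap scene/phantom_rolemap.yaml --method expert
exec/litt evaluate --labels ... --rolemap ... --entry 39,21,35 --target 45,79,57
exec/litt compare --metrics litt_output/expert_T3_metrics.csv --metric risk_score
```

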