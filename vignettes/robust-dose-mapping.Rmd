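---
title: "Robust organ-mapped dose: model, parameters and design choices"
author: "roaddose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust organ-mapped dose: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roaddose)
```

## The model

Dose accumulation for reirradiation pulls the original course's dose onto the
new planning CT through a deformable registration. A single displacement
field gives a single answer with unknown local error. This package instead
treats a *set* of M ≥ 2 plausible fields (in clinical use: a global hybrid
registration, a per-organ structure-only registration, and an intensity-only
registration) as samples of where a destination voxel's dose may truly have
originated, and converts their discordance into a per-voxel resampling
kernel:

1. **Weighted centre (KS1).** The M mapped points are averaged with inverse
   distance weights `IDW = 1/(1 + DTM)` where DTM is each point's distance to
   the unweighted mean. One deviant field is pulled towards the two
   concordant ones; with only three fields no formal outlier rejection is
   possible, and none is attempted.
2. **Weighted-SD dimensions (KS2).** Per axis,
   `KD_l = sqrt( sum(IDW_i (l_i - kc_l)^2) / (((M-1)/M) sum(IDW_i)) )`.
   With equal weights this is the Bessel-corrected sample standard deviation.
   The resulting ellipsoid is clipped to the source organ: a mapped organ
   voxel may only ever receive dose that belonged to that organ.
3. **Conditional expansions (KS3, KS4).** Discordance can only measure error
   the fields disagree about. Two failure modes remain: a kernel can miss
   the organ entirely (all fields wrong in the same region), and parts of
   the original organ can be mapped to by no kernel at all (true deformation
   outside every kernel). KS3 grows empty kernels isotropically, one dose
   voxel (3 mm) at a time, until they touch the organ; KS4 iterates while
   more than 1 % of source organ dose voxels are unsampled, growing the
   `ceiling(f K)` kernels nearest the unsampled voxels (f the unsampled
   fraction), up to 10 iterations / +3 cm.

Each voxel then takes the **maximum** dose over its kernel–organ
intersection, floored at the baseline mapped dose, i.e. a worst-case
estimate appropriate where point-maximum constraints drive reRT planning.
Mean and median organ doses necessarily rise; that cost is reported, not
hidden.

## Assumptions

- Whole-voxel organ membership (binary masks); partial volumes are not
  modelled.
- Candidate doses are raw source voxel values; the baseline mapped dose may
  be interpolated (default trilinear, `nearest` available).
- The fields all live on a regular destination-space grid (possibly finer
  than the dose grid) and are interpolated trilinearly onto the dose grid.
- Organ masks must exist, and be consistently contoured, on both image sets.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `increment` | largest source spacing (3 mm) | KS3/KS4 isotropic growth step — "one dose voxel" |
| `max_expansions` | 10 | KS3 steps per kernel and KS4 iterations (+3 cm radius cap) |
| `coverage_threshold` | 0.99 | KS4 stops once this fraction of source organ dose voxels is sampled |
| `deficit_threshold` | 0.5 Gy | a statistic this far below the reference counts as a deficit |
| `fixed_radius` | 3 mm | comparator sphere radius |
| `statistic` | `max` | per-voxel sampling statistic; `mean`/`median`/`percentile` exposed as a hook only — `max` is the validated, worst-case choice |
| `interpolation` | `trilinear` | baseline dose interpolation |

The defaults are tied to a 3 mm dose grid; on other grids the increment and
cap scale with the grid (`10 × increment`), which is why nothing is
hard-coded.

## Numerical choices

- **Voxel-in-ellipsoid test.** The literature samples "dose voxels" without
  defining voxel-in-ellipsoid membership. We test voxel *centres* against
  the ellipsoid inflated per axis by half a voxel (δ), and always include
  the voxel containing the kernel centre when it is inside the organ. This
  makes a degenerate kernel (KD = 0, perfectly concordant fields) sample
  exactly its own centre voxel, keeps KS1 ⊆ KS2 ⊆ KS3 ⊆ KS4 candidate sets
  (hence exact per-voxel monotonicity across modes), and keeps the
  brute-force oracle trivial. The fixed comparator uses the same convention
  (sphere radius + δ).
- **KS4 details the literature leaves open.** The expanded fraction is
  `ceiling(f K)` with a minimum of one kernel; ties in the
  distance-to-nearest-unsampled ranking break by ascending owner voxel
  index; f is recomputed every iteration (coverage changes); "10 expansions
  in total" is read as 10 global iterations, matching the +3 cm cap
  arithmetic (10 × 3 mm); a kernel may be selected in several iterations but
  is never grown past the cap, so the procedure always terminates with
  coverage above threshold or exactly 10 iterations (flagged incomplete).
- **KS3 failure.** A kernel still empty at the cap (e.g. the organ is
  missing or beyond 3 cm) falls back to the baseline dose and is flagged.
- **Kernel magnitude.** KM = RMS of per-axis dimensions; for KS3/KS4
  reporting the cumulative radius enters each axis (`KD_l + r`), so
  expansion growth is visible in KM maps and summaries.
- **Surface metrics.** MDA is the symmetric mean surface distance (average
  of the two directed means) and HD the full symmetric Hausdorff distance,
  over face-connected surface voxel centres; the directedness convention is
  stated because the source literature names but does not define it.
  Correlation of KM with MDA/HD is Pearson by default (Spearman exposed).
- **D_Vcc.** Descending sort, cumulative voxel volumes, linear interpolation
  between the bracketing voxels; a request exceeding the structure volume is
  flagged undefined and excluded from reports (small organs and D5cc).
  The deficit report supports both references found in the literature —
  the original dose (default, as tabulated) and the baseline mapped dose —
  because its prose and tables disagree; the discrepancy is surfaced as an
  option rather than resolved.
- **Exactness of the concordant limit.** The weighted centre is computed
  relative to the first point, so coincident points give KD = 0 *exactly*
  and the concordance identity (three identical fields ⇒ robust dose equals
  nearest-mode baseline) holds with equality, not tolerance.

## The synthetic world

The generator builds what the method needs to be testable without clinical
data, and its defaults are fixed once:

- 60³ voxels at 3 mm; 60 Gy prescription inside an ellipsoidal target with
  a Gaussian falloff of 8 mm — a clinically steep gradient;
- one ellipsoidal OAR (15 × 12 × 12 mm) slightly overlapping the target edge
  so the gradient runs through it and underestimates are possible;
- organs and dose are **analytic in source space**; destination masks are
  the exact pull-back of the voxelised source organs through the true field.
  This is the self-consistent pairing the tests rely on (the truth really
  relates the two spaces) implemented without numerically inverting the
  field;
- a smooth truth deformation (4 Gaussian bumps, 40 mm correlation, ≤ 4 mm
  each), rejected and regenerated if its Jacobian determinant is not
  positive; translation and organ-inflation modes exist for closed-form
  checks;
- M = 3 fields = truth + per-field Gaussian-filtered noise with per-axis RMS
  exactly 2 mm and 15 mm correlation length — chosen to reproduce the
  low-single-digit-mm KS2 kernel magnitudes reported clinically;
- **coherent failures**: the same offset added to every field inside the
  fraction of the organ with the highest true mapped dose (i.e. abutting
  the gradient), pointing down-gradient, feathered over one voxel so the
  boundary offset is at most half the interior offset. Discordance stays at
  the noise level while the true error is 6–12 mm — precisely the scenario
  KS3/KS4 exist for.

What the generator does **not** emulate: CT texture, contouring differences
between observers (only a morphological-perturbation hook), sliding-organ
discontinuities, or a real DIR algorithm — the fields are constructed, never
fitted. A green test therefore establishes that the machinery is correct
and that the claimed failure-recovery mechanism works in a world with the
stated noise structure; it does not certify performance on clinical DIR
output.

Two stated-world notes recorded here because they are deliberate:

- The concordance-identity criterion uses a *constant-translation* truth.
  Under a generic smooth deformation the rounded destination-to-source voxel
  map is not bijective, so a few percent of source organ voxels legitimately
  remain unsampled and KS4 (correctly) fires; a translation makes the map a
  bijection and the zero-expansion identity exact. That KS4 fires under
  benign smooth deformation is behaviour the clinical tables also show.
- The robustness-recovery criterion compares KS4's median *mean-dose*
  increase above baseline against an oversized (9 mm) fixed kernel; the
  mean organ dose is the statistic on which worst-case resampling is
  expensive, making it the honest cost measure.

## Known limitations

- Processing is per organ and independent; voxels in several organs take
  the maximum competing robust dose (a conservative choice; the source
  method does not address overlap).
- Runtime is dominated by per-kernel membership enumeration; organs of a
  few thousand voxels take seconds in pure R.
- The minimal NIfTI-1 I/O supports little-endian, axis-aligned volumes
  (scalar and 3-component vector) — sufficient for the pipeline's own
  round trips, not a general neuroimaging reader.
- With M = 3, one failing field still inflates kernels (the weighting damps
  but cannot reject it); coherent failure of *all* fields is only caught if
  it violates organ sampling or coverage, which is exactly what KS3/KS4
  test.
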