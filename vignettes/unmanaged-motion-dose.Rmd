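---
title: "Modelling unmanaged intrafraction drift in helical tomotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling unmanaged intrafraction drift in helical tomotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Helical tomotherapy delivers a rotating fan beam while the couch translates
continuously in the superior direction, so the beam plane sweeps inferiorly
through the patient over the course of a fraction. Real-time adaptation
systems track implanted fiducials and steer the jaws and multi-leaf
collimator to follow the target; the recorded trajectories also make it
possible to ask the counterfactual question this package answers: *what dose
would this patient have received if that motion had gone unmanaged?*

Slow baseline drift interacts with the couch motion in a way that simpler
models miss. If the target drifts inferiorly while the beam plane also moves
inferiorly, tissue that has already been treated drifts back under the beam
and the delivered dose is *compressed* longitudinally: the superior part of
the target is overdosed, the inferior edge is undershot. A rigid shift of the
dose cloud, or a convolution of the static dose with the motion distribution,
cannot produce this asymmetry.

## The deformation model

Let `m(t)` be the target displacement (mm, IEC patient axes: X left-right,
Y superior-inferior, Z anterior-posterior; signs +X patient-left, +Y
superior, +Z anterior) relative to its position at beam-on, and let a
fraction's beam-on time be `T`. For a transverse dose slice at IEC-Y
coordinate `y`, the fraction of couch travel completed when the beam plane
crossed it is

    f(y) = (y_start - y) / L,   clamped to [0, 1]

with `y_start` the beam-plane position at beam-on and
`L = pitch x field_width x delivery_time / rotation_time` the total couch
travel. Every voxel of that slice is assigned the displacement

    d(y) = -m(f(y) x T)

i.e. the *reverse* of the target motion at the time the slice was treated.
Slices superior to the couch start (`f = 0`) carry the zero vector -- no
motion has yet occurred; slices inferior to the end of travel (`f = 1`)
carry the reversed end-of-treatment displacement. The deformed dose is the
pull-back resample: the output at voxel centre `x` is the planned dose
interpolated (trilinearly) at `x - d(x)`. For a uniform field this is
exactly a rigid translation by `+d`; for the slice-ramped fields produced by
drift it is the longitudinal compression described above. The sign
convention is pinned by a physical property rather than resampling jargon:
an inferior+posterior drift must displace the dose superiorly and
anteriorly, and the test suite asserts this on the dose centroid.

Pauses in delivery matter because the couch halts with the beam while the
anatomy keeps moving. Traces therefore carry a `beam_on` flag per sample;
couch travel is mapped to the *beam-on* clock (the cumulative time spanned
by gaps whose leading sample is beam-on), and paused samples are excluded
from that axis.

## Scenarios and metrics

Two estimates bracket the consequence of unmanaged motion over a course:

* **fraction-wise** -- each fraction's planned dose (total/N, the same plan
  delivered daily) is deformed with its own fraction's field and the results
  are summed;
* **worst-case** -- the field of the single largest-drift fraction is
  applied to every fraction, i.e. to the total dose.

Because the field does not depend on the dose, deforming the total equals
deforming the fractional dose and multiplying by N; the package uses the
former and asserts the equivalence numerically. Fraction-wise totals are
accumulated as deviations from the planned total
(`total + sum(apply(total, field_i) - total) / N`), which is algebraically
the same sum of deformed fractional doses but keeps motionless fractions
exactly neutral, so the zero-motion identity holds bit for bit.

An ultra-hypofractionated variant rescales the plan (e.g. 60 Gy to 40 Gy
total, so 3 Gy fractions become 8 Gy), contracts the PTV by 3 mm into a
"mock CTV" representing the tighter SBRT margin, and reruns the scenarios
using either the first five traces (fraction-wise) or the five
largest-motion traces (worst-case fraction-wise). Rescaling a plan that was
optimized for a different regimen is a recognized simplification: the
renormalized distribution need not satisfy SBRT organ-at-risk constraints
and stands in only for target-coverage questions.

Reported metrics are voxel-counting DVH quantities: D95% (dose covering 95%
of a structure), V95% (fraction of a structure receiving at least 95% of the
prescription) and the median dose, with planned-vs-scenario deltas. The
default bin width is 0.05 Gy so 0.1 Gy differences are resolvable; no
sub-voxel partial-volume weighting is applied, which at 1 mm voxels is below
that reporting precision. `dose_at_volume()` interpolates linearly between
bin edges and agrees with a sort-based percentile of the raw voxel doses to
within one bin.

## Delivery parameters

Defaults mirror the modelled treatment: 2.5 cm field width, pitch 0.303,
18.8 s rotation, 187.3 s delivery (hence couch speed 0.403 mm/s and 75.5 mm
of travel), six planar images per rotation (60 per fraction, by ceiling
rounding -- the only convention consistent with 59.8 rotations-worth of
images), 60 Gy in 20 fractions, and 6.25 mm leaves, whose half-width
(3.125 mm) bounds the residual left-right / anterior-posterior error of
leaf-quantized adaptation. The absolute couch start coordinate is never
published with a plan; by default it is placed at the most superior slice
whose dose exceeds 1% of the maximum, since the treated length must cover
the dose region. When a trace contains pauses its measured beam-on duration
overrides the planned delivery time for the travel-to-time mapping.

## The synthetic generator

No patient dose grid or trace archive accompanies the method, so the
package generates its own study conditions:

* **Plan** (`make_synthetic_plan()`): an ellipsoidal CTV (default a sphere
  of 43.3 cm^3, the modelled patient's prostate + seminal-vesicle volume),
  a 6 mm Euclidean PTV expansion, and a dose equal to the prescription
  times a Gaussian-smoothed indicator (sigma 3 mm, a typical fan-beam
  penumbra) of the PTV expanded by a conformity buffer. The buffer is the
  smallest 0.25 mm multiple for which every PTV voxel receives at least 95%
  of the prescription -- the tightest conformal coverage an optimizer would
  accept, so planned `PTV V95% = 100%` holds by the smallest margin
  consistent with the penumbra, as in a clinical plan. The grid keeps a
  >= 15 mm zero-dose border so that deformations up to ~10 mm cannot
  interact with the grid edge. FFT round-off in the smoothed indicator is
  snapped (values within 1e-9 of 0 or 1), so plateau voxels carry exactly
  the prescription.
* **Motion** (`make_motion_trace()`): exponential-plateau drift
  `m(t) = A (1 - e^(-t/tau))` -- chosen over linear drift because observed
  prostate trajectories level off at or before ~6 mm well within a
  fraction, indicating an anatomical limit -- plus an optional sinusoid and
  Gaussian sampling noise (default SD 0.2 mm, typical of fiducial-tracking
  residuals). `tau` defaults to a quarter of the fraction duration, samples
  are 3 s apart (six images per ~19 s rotation), and the first sample is
  exactly zero. Axes are generated independently; real per-axis
  correlations are not modelled.
* **Course** (`example_course_specs()`): twenty fractions of which five
  (2, 4, 12, 13, 17, as in the studied patient) carry sustained
  inferior+posterior drift -- fraction 2 worst at `(0, -6, -2)` mm, the
  others at 0.9, 0.8, 0.75 and 0.7 of that amplitude, all comfortably
  above the 3 mm sustained-drift criterion -- while the rest wander below
  1 mm; fraction 8 contains a 20 s pause.

What passing tests on these conditions show -- and what they do not: the
generator reproduces the geometry, timing, drift shape and noise scale of
the modelled treatment, so the pipeline's algebra, boundary rules, margin
geometry and qualitative margin-versus-drift findings are exercised
end-to-end. It does not reproduce a clinically optimized dose distribution
(no organ-at-risk sparing, no heterogeneity), deformable anatomy, changes in
radiological path length, or rotation-resolved delivery, so absolute delta
magnitudes on real patients will differ from the synthetic ones.

## Drift characterization

The patient-selection criterion ("sustained continuous drift exceeding
3 mm") does not come with an algorithm, so a deterministic one is adopted:
the net drift is the mean of the final 10% of beam-on samples minus the mean
of the first 10%, and the drift is *sustained* when its magnitude exceeds
the threshold and the per-sample increments along the dominant axis agree in
sign with the net vector at least half the time. Endpoint windows make pure
periodic motion cancel; the sign-consistency term rejects single jumps.
Fractions are ranked by this net magnitude (ties broken by fraction id),
which is also the assumed reading of "largest motion" when selecting
worst-case fractions.

## Numerical choices and degenerate inputs

* Trilinear (not higher-order) interpolation: monotone, cannot create
  negative dose, and exact for integer-voxel translations; samples outside
  the voxel-centre hull return 0, which is safe because dose grids reach
  (near-)zero at their borders and the generator enforces a zero border.
* Margins are binary dilation/erosion with an ellipsoidal structuring
  element in physical mm via FFT convolution -- identical to thresholding
  the Euclidean distance transform at the margin, measured between voxel
  centres with boundary inclusion `<=` on expansion -- so mask volumes are
  bit-reproducible. Outside the grid counts as background for expansion and
  as complement for contraction.
* Total dose is conserved (to interpolation error) only under spatially
  uniform fields. Slice-ramped drift fields have non-zero divergence and
  *intentionally* change the integral -- that longitudinal compression is
  the couch-interplay effect itself -- so conservation is asserted for
  rigid translations only.
* A trace whose first beam-on sample is non-zero is rebased to it with a
  warning; non-monotone times, empty files and malformed rows are errors
  that name the offending line. Drift characterization requires at least 10
  beam-on samples. Structures that vanish under contraction warn rather
  than error, since a vanished mock target is itself a finding.
* Scenario problem sizes: the default plan is a ~123^3 voxel grid at 1 mm;
  fast identity/algebra checks run on a ~65^3 grid, and resampling is
  verified against a brute-force per-voxel oracle on 32^3 grids.

## Worked example

```{r example}
library(tomodrift)

plan <- make_synthetic_plan()
p <- delivery_parameters(couch_start_y = default_couch_start(plan$dose))

specs <- example_course_specs(seed = 1)
traces <- lapply(seq_along(specs), function(i)
  make_motion_trace(specs[[i]], fraction_id = i))

worst_id <- rank_fractions_by_motion(traces)[1]
wc <- run_worst_case(plan$dose, traces[[worst_id]], p,
                     list(CTV = plan$ctv, PTV = plan$ptv))
wc$metrics
```

Or, configured end to end:

```{r pipeline}
run_pipeline(list(
  seed = 1,
  output = "out",
  scenarios = list(
    list(kind = "planned"),
    list(kind = "fraction_wise"),
    list(kind = "worst_case"),
    list(kind = "worst_case",
         renormalize = list(new_total_rx = 40, new_n_fractions = 5,
                            mock_ctv_margin = 3)))))
```

## Known limitations

The dose cloud is treated as rigid under deformation: no radiological
path-length changes, no deformable anatomy, no per-control-point
recalculation -- the method is a surrogate for a full four-dimensional dose
reconstruction, which remains outside the scope of commercial planning
systems. Renormalizing a standard plan to an SBRT prescription ignores
differences in optimization and organ-at-risk constraints. Rotations of the
fiducial set are not modelled (translations only), and the synthetic
generator's independence assumptions are noted above.
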