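---
title: "Measuring pedicle screw placement accuracy from paired CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pedicle screw placement accuracy from paired CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

After instrumented spine surgery, the clinically meaningful question about
each pedicle screw is geometric: where does the implanted screw sit relative
to the trajectory that was planned on the preoperative CT? Answering it
automatically requires three estimates, each with its own error budget:

1. the pose of each implanted screw in the **postoperative** scan
   (screw detection);
2. a rigid transform per vertebra carrying **preoperative** world
   coordinates into **postoperative** world coordinates (registration) --
   vertebrae move relative to one another between scans, so one global
   alignment is not enough;
3. an anatomically meaningful frame in which to resolve the residual
   difference between the mapped plan and the detected screw
   (the screw-aligned ML/AP/SI frame).

`screwpose` implements all three plus the statistics that summarize them,
and a digital phantom generator that produces paired scans with exact
ground truth so every stage can be validated quantitatively.

## Coordinate conventions

World coordinates follow the radiographic RAS convention: +x toward the
patient's right, +y anterior, +z superior, all in millimetres. Voxel
indices are 0-based and mapped to world space by the NIfTI affine, which
is honoured as-is (no axis-order assumption). Per-screw errors are
reported in a frame anchored to the *planned* trajectory:

* **AP** along the planned shaft (tail to tip), anterior positive;
* **SI** the component of the inferior endplate normal orthogonal to AP,
  superior positive;
* **ML** completing the orthonormal triad, with its sign chosen so that
  positive always points *medially* for the screw's side. This mirrors
  right-sided screws across the sagittal plane, so left and right screws
  pool directly and a positive ML error always means "toward the canal".

## The digital phantom

`phantom_spec()` / `simulate_case()` emulate the acquisition the pipeline
targets: helical-CT-like anisotropic voxels (default 0.5 x 0.5 mm in-plane,
0.625 mm slice spacing), five intensity plateaus (air -1000, soft tissue
40, trabecular 300, cortical 1200, metal 3000 HU-like units), Gaussian
partial-volume blur (sigma 0.3 mm, on the order of half a CT point-spread
FWHM) and additive Gaussian noise (default SD 20 HU). Each vertebra is an
elliptic-cylinder body with flat endplates, two pedicle tubes flanking the
canal (the tubes overlap into body and lamina so the junctions are solid
bone), and a posterior lamina slab, all wrapped in a 1.5 mm cortical
shell. Screws are 4.5 mm diameter, 40 mm long, rasterized as metal
capsules whose hemispheric cap forms the rounded tip -- the metal apex
coincides exactly with the tip landmark -- plus a wider short tulip-head
capsule posterior of the tail. Optional 1 mm beads embed in the body.

Rasterization is deliberately *hard* (nearest material per voxel), so a
blur-free, noise-free, texture-free scene contains exactly the five
declared plateaus; partial volume then comes from the blur alone. Two
realism exceptions are configurable: beads are rasterized with
partial-volume occupancy (at 0.625 mm slices a hard 1 mm sphere aliases
by up to ~0.3 mm in z, which would defeat any sub-voxel bead oracle),
and the trabecular compartment carries a smooth seeded texture field
(sum of random 3-D cosines, SD 40 HU, 2-6 mm wavelengths) that moves
rigidly with its vertebra. The texture matters: real trabecular bone is
spatially heterogeneous and that internal structure is much of what an
intensity metric uses to pin *rotation*; with a perfectly homogeneous
interior the mutual-information surface is nearly flat in rotation and
restarted optimizations scatter far more than they do on real scans.
Set `texture_sd = 0` (and `n_beads = 0`) for the idealized five-plateau
configuration.

Study conditions (the defaults of `run_validation_study()`): per-level
inter-scan motions drawn uniformly up to 10 degrees / 10 mm -- large
enough to defeat identity initialization, small enough to keep the
vertebra in the field; planted screw deviations generated as a small rigid
perturbation of the plan (translation up to 1.5 mm plus rotation up to
2 degrees about the tail), matching the error scale reported for robotic
placement (sub-millimetre to low-millimetre translations, ~1.5 degree
angles). Generating the deviation as a rigid perturbation keeps the true
shaft length equal to the plan -- the detector fixes length to the plan
(screws are of predetermined length), so length-inconsistent tip/tail
offsets would make exact recovery ill-posed. Everything is deterministic
given the seed.

What the phantom does *not* emulate: cortical microarchitecture, scoliotic
deformity, streak/beam-hardening artifact, and metal-artifact-reduction
reconstruction. Passing tests therefore demonstrate correctness of the
geometry/optimization machinery under realistic contrast, blur and noise,
not robustness to pathological artifact.

## Screw detection

Metal voxels are thresholded (phantom default: midway between the cortical
and metal plateaus; ~2500 HU is typical for real scans) and grouped into
26-connected components; components smaller than half a screw-shaft volume
(beads, fragments) are discarded. Each component is oriented by the
principal eigenvector of its voxel covariance, the tip anchored at the
extreme projection farther from the volume's posterior face, and the tail
placed one nominal length behind.

The refinement maximizes a matched-filter contrast: the total *metal
occupancy* captured inside the shaft model minus the occupancy leaking
into a one-radius-thick surrounding shell, over five degrees of freedom
(tip position and two axis components; length fixed to plan). Occupancy
is a logistic squash of intensity centred on the metal/background
interface midpoint (estimated from the data as the midpoint between the
median supra- and sub-threshold intensities, width 5% of that contrast):
this clips streak-artifact brightness above the threshold *and* flattens
bone-vs-soft-tissue contrast below it, so the shell term responds to
metal only and surrounding anatomy cannot bias the fit. Membership
boundaries are logistic with softness max(0.25 mm, half a voxel) so the
objective is smooth; shell voxels behind the tail (closer than 2r + 1 mm)
are excluded so the angulated poly-axial tulip head cannot bias the shaft
axis. A Nelder-Mead stage gives capture range, BFGS finishes.

Because the shaft continues posteriorly into the tulip, the capsule
contrast constrains the axial position only at the tip. A final 1-D apex
localization therefore slides the model along its fitted axis so the apex
sits where the on-axis occupancy profile crosses one half (sub-voxel by
linear interpolation). Off-axis rays would cross the curved apex surface
early and bias the estimate tail-ward, so a single on-axis ray is used.

Detections are matched to plans by exact minimum-cost assignment on
tip-to-tip distances (permutation enumeration for small scenes, globally
greedy beyond seven screws where exhaustive enumeration is pointless);
unmatched plans or detections are reported, never dropped.

## Per-level registration

Each vertebra is registered independently. The initialization is the
least-squares rigid alignment (Kabsch/Umeyama with determinant
correction) of the planned tip/tail landmarks onto the detected ones.
A single-screw level leaves rotation about the screw axis unconstrained;
the vertebra mask centroid paired with the nearest metal-component
centroid is then added as a third pseudo-landmark, keeping initialization
automatic, and the result carries a degeneracy flag.

Refinement maximizes mutual information between the scans, computed over
preoperative voxels inside the vertebra's label (the inclusive mask) that
map to postoperative voxels below the metal threshold; samples whose
8-voxel interpolation support touches metal, an exclusion region (e.g.
dilated fiducial beads) or the field edge are dropped entirely. The joint
histogram uses 32 x 32 bins over the masked intensity ranges with
partial-volume (linear) weighting, in natural-log units.

Numerical design choices that proved load-bearing:

* **Jittered sampling.** Partial-volume interpolation imprints
  grid-periodic local optima on the MI surface (restarts would land in
  dimples exactly one voxel apart). Each fixed sample is therefore
  displaced by a deterministic quasi-random (R3 low-discrepancy)
  sub-voxel offset, with the fixed intensity interpolated there. The
  public `mutual_information()` keeps exact voxel-centre sampling, so MI
  of a volume with itself at identity equals its masked histogram entropy
  exactly.
* **Trust region about the initialization.** MI is spuriously high for
  small-overlap configurations; a quadratic fence (soft beyond ~5 degrees /
  5 mm from the landmark initialization, which is itself accurate to a
  few millimetres) keeps quasi-Newton excursions honest.
* **Schedule.** Two smoothing levels (sigma = 2 and 0 voxels, sample
  strides 8 and 4), BFGS at each with rotation parameterized about the
  mask centroid (decorrelating rotation from translation); then, on the
  full jittered sample set, a safeguarded quadratic-stencil polish, a
  NEWUOA trust-region finish (restarted with a fresh trust region while
  it keeps improving) and a deterministic rotational basin hop (probe
  rotations of half and one degree about each axis and re-finish from
  any that genuinely raises the objective). NEWUOA's quadratic model
  tracks the nearly flat rotational ridges of the MI surface, which is
  what makes restarts from perturbed initializations settle onto the
  same optimum. The whole schedule runs up to twice (a restart escapes
  the occasional subsidiary basin); a stage whose quasi-Newton step
  diverges falls back to a simplex search, and if the final objective is
  below the initialization's the routine retries from the initialization
  and, as a last resort, returns it flagged unconverged. The reported
  `mi_final` is always evaluated at full resolution without jitter and
  never falls below `mi_init`.

Validation mirrors the two standard procedures: *fiducial* -- 1 mm beads
(detected automatically here; manually identified coordinates can be
supplied) are masked out of the metric by 2-voxel-dilated spheres and
their post-alignment discrepancy reported as MAE and SD; *perturbation* --
the initialization is composed with random rigid transforms of exactly
2 degrees and 2 mm, refinement re-run, and the discrepancy to the
unperturbed baseline measured at the vertebra centroid (translation) and
as the rotation angle of the difference transform.

## Frames, mid-pedicle locus and error resolution

The inferior endplate plane is fitted by total least squares to exterior
surface voxels whose outward direction is within 45 degrees of inferior,
that lie in the inferior 30% of the label's SI extent and in its anterior
half (keeping posterior-element under-surfaces out); candidates are
shifted to the half-voxel surface crossing so the plane is not biased half
a voxel into the bone. The mid-pedicle point is the sample (0.1 mm arc
steps along the *planned* trajectory, ties toward the tail) with the
most-negative/least-positive signed distance to the medial pedicle wall,
the wall being canal-facing boundary crossings of the label within 8 mm
of the trajectory; negative distance means the trajectory lies outside
the label toward the canal (breach). Anchoring the analysis planes to the
plan keeps the target-plot origin well-defined regardless of where the
actual screw went.

Per-screw errors map the planned tip, tail and locus through the level's
transform, carry the frame axes through its rotation (so errors stay
expressed in the anatomically anchored planned frame regardless of
inter-scan motion), and resolve: tip and tail component errors, the
in-plane (ML, SI) offset where the detected axis pierces the plane
through the mapped locus normal to AP, and the angle between mapped
planned axis and detected axis.

## Statistics

Summaries report, per metric: SME (signed mean error -- systematic bias),
MAE (mean absolute error -- accuracy) and precision as 2 sample standard
deviations (n - 1) of the signed errors. Euclidean composites (tail 3D,
tip 3D, mid-pedicle 2D) report MAE only; a signed mean is undefined for
them. Regional comparisons (upper thoracic T2-T6, lower thoracic T7-T12,
lumbar L1-L4) use one-way ANOVA on absolute errors with all-pairs t-tests
and Bonferroni correction, generalizing the published mid-pedicle ML
comparison to any metric column.

Target plots scatter per-screw (ML, SI) errors at a chosen plane around
the planned position, with 2 and 4 mm reference rings, a star at
(SME_ML, SME_SI) and an axis-aligned ellipse of per-axis 2 SD half-widths
(a covariance ellipse is available behind a flag). The plotted statistics
are taken verbatim from `summarize_accuracy()` -- the plot never
recomputes them.

## Validation problem sizes

`run_validation_study()` defaults to ten single-level phantom cases
(~124 x 160 x 84 voxels each) with four beads; perturbation analysis
(10 replicates of 2 degrees / 2 mm) runs on the first five levels. These
sizes give 20 screws, 40 bead pairs and 50 perturbation replicates --
enough for stable means while a full study completes in minutes on one
CPU. Unit tests use a coarsened 0.8 mm phantom for speed.

## Known limitations

* The screw-fit objective is a declared engineering choice; vendors'
  (unpublished) fitting procedures will differ in detail. Thread geometry
  is not modelled.
* The phantom's vertebra is schematic; endplate and pedicle-wall
  heuristics (45-degree cone, 30% SI band, anterior half, 8 mm wall
  capture) are declared, not anatomically derived, and may need tuning
  for severely deformed anatomy.
* Registration assumes each vertebra is rigid across scans and visible in
  both fields of view; deformable changes (fracture, hardware loosening
  between scans) violate the model.
* Bead usability in real data ("extra-osseous placement") is an
  anatomical judgment; the package exposes a usable flag rather than
  deciding.
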