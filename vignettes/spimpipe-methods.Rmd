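---
title: "Methods: image computation for live SPIM imaging of tumor spheroids"
author: "spimpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image computation for live SPIM imaging of tumor spheroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`spimpipe` implements the computation chain needed to monitor cell division
in large multicellular tumor spheroids imaged live by single-plane
illumination microscopy (SPIM): removal of the stationary stripe artifacts
characteristic of light-sheet illumination, registration and fusion of
opposing (0/180 degree) views, compensation of slow sample drift during
time-lapse acquisition, 3D detection of chromatin-labelled nuclei with
classification of mitotic figures, localisation of every detection relative
to the fitted spheroid surface, and tracking of divisions over time with
mitotic-duration and drug-arrest scoring.

All stages operate on a single container, the `image_volume`: a numeric 3D
array indexed `[y, x, z]` with physical voxel size in micrometres.  `x`
(dimension 2) is the illumination axis -- stripes run along it and the light
sheet attenuates along it; `z` (dimension 3) is the detection axis along
which optical sections are stacked.  The default voxel size, 0.645 x 0.645
x 1 um, is the acquisition raster of a 10x/0.3 NA detection lens with 1 um
slice spacing.  The physical coordinate of a voxel center is
`(index - 1) * voxel_size`.

Because live SPIM data of spheroids come with no usable ground truth, the
package ships a synthetic generator that emulates the acquisition,
including its artifacts, and records exact truth for every quantity the
pipeline estimates.  Every accuracy claim made by the test suite is a claim
about this generator; the section on limitations states what that does and
does not imply about real data.

# The synthetic spheroid generator

## Geometry and labelling

`place_nuclei()` draws nucleus centers uniformly inside a sphere by
dart-throwing with a hard minimum separation, a standard hard-core model of
confluent tissue.  Defaults (desk scale): radius 50 um, 220 nuclei, nucleus
radius 5 um, minimum separation 9 um -- values typical of HCT116 colon
carcinoma spheroids, whose nuclei are about 10 um across and tightly
packed.  A 400-um-diameter acquisition corresponds to the documented
`scene_preset("large")`; all tests run at desk scale (192 x 192 x 128
voxels) so the whole suite stays within desktop budgets.

Only a fraction of nuclei (default 0.7) carry the fluorescent label,
mirroring a reporter clone in which a subpopulation expresses the
histone-fusion protein; unlabelled nuclei contribute no signal but still
occupy space.  Mitoses are restricted to the proliferative outer rim
(default thickness 15 um): a nucleus whose depth from the surface is within
the rim is mitotic with probability 0.25, deeper nuclei never are.  This
encodes the proliferation gradient of spheroids -- cycling cells in the
outer layers, quiescence in the core.

## Photometry and optics

Nuclei are rendered as Gaussian blobs (sigma = r/2) rather than hard
spheres: differentiable, cheap, and realistic at 10x/0.3 NA where the blur
is comparable to chromatin texture.  Condensed mitotic chromatin is a
prolate Gaussian (axis ratio 2.2, smaller volume) with peak intensity
multiplied by `mitotic_gain` (default 2) -- condensed chromosomes
concentrate the histone label.  The metaphase plate is an oblate (disc)
Gaussian whose normal is the spindle axis; anaphase renders two small
masses separating along the spindle axis at constant speed.

Three optical effects corrupt the ideal signal, in physical order:

* **Illumination attenuation.** Each voxel's signal is multiplied by
  `exp(-d/l)` where `d` is the chord length travelled inside the ideal
  truth sphere along the illumination axis to that voxel (closed-form chord
  geometry, not ray marching -- testable against the analytic decay).  The
  default attenuation length `l = 200 um` is a deliberate choice -- no
  measured value exists for this quantity -- tuned so that nuclei stay
  identifiable throughout a desk-scale spheroid while the deep-side signal
  loss familiar from real stacks remains clearly visible.
* **Depth-dependent detection blur.** Each z-slice is blurred with sigma
  `sigma0 + k * dz` (defaults 0.8 um + 0.01 per um of tissue depth along
  z), a light proxy for aberration growth with imaging depth.
* **Sensor noise.** Shot noise (Poisson at `photon_scale = 200` photons per
  unit intensity) plus additive Gaussian read noise (sd 0.01).  Intensities
  live in [0, 1] before noise and are never clipped, preserving the
  linearity that several tests rely on.

## Stripes

Stripe artifacts are generated exactly as the removal stage models them:
a sparse Bernoulli-Gaussian white-noise coefficient field `lambda`
(density 0.05, sd 0.5) convolved with an elementary stripe pattern `psi`,
an anisotropic Gaussian elongated along the illumination axis (sigma 15 x
0.8 um, unit L2 norm), drawn independently per z-slice because stripes
live in the light-sheet plane.  The corruption is exactly additive,
`corrupted = clean + b`, so the destriper's decomposition identity can be
checked against truth.  With these amplitudes the stripe field has an RMS
of roughly 0.11 on unit-scaled images -- strongly visible streaks.

## Time-lapse and the division state machine

Frame `t` is globally shifted by `t * drift_per_frame_um` before rendering
(rigid drift, the component the compensation stage removes).  Every frame
draws a fresh stripe field and fresh sensor noise from seeds derived from
the time-lapse seed, so movies are bit-reproducible.

A division event enters at its `entry_frame` and walks condensed (30% of
frames) -> metaphase (40%) -> anaphase (30%) over
`ceiling(duration/interval)` frames; two daughter interphase nuclei appear
on the following frame, 5.5 um either side of the parent along the spindle
axis.  The default unperturbed duration is 21 min, in the usual range for
HCT116 division, at the live-acquisition cadence of one stack every 3 minutes.  The spindle
axis is chosen among seeded random candidates to maximise the daughters'
clearance from neighbouring nuclei -- cells divide into available space;
without this, daughters of adjacent divisions can overlap, which real
tissue geometry forbids.

In `paclitaxel_mode` the machine never leaves the condensed state: the
chromosome mass jitters every frame (0.8 um sd), never forms a metaphase
plate and never enters anaphase, through movie end.  Events default to
entry at frame 0 because the drug is applied hours before acquisition, so
blocked cells are already blocked when imaging starts.

# Stripe removal as MAP estimation

The observed slice is modelled as `u0 = u + b` with `b = lambda (*) psi`:
stationary noise, i.e. white noise convolved with a fixed elementary
pattern.  Under a total-variation prior on the image and a sparsity prior
on the coefficients, the MAP estimate solves

```
lambda_hat = argmin_lambda  TV(u0 - lambda (*) psi) + alpha * Phi(lambda)
```

with `u_hat = u0 - lambda_hat (*) psi`, so the decomposition
`u_hat + b_hat = u0` holds to floating-point round-off by construction.  Choices the
model statement leaves open, and how this implementation fixes them:

* **TV discretisation**: isotropic, forward differences, Neumann
  (reflective) boundaries -- no periodic wrap-around at the spheroid edge.
* **Coefficient prior `Phi`**: l1 by default (stripe coefficients are
  sparse streaks); a Gaussian (l2) prior is available.  Each slice is
  normalized internally by its maximum absolute intensity before solving,
  so `alpha = 1` always refers to unit-scaled data; with the l1 prior the
  objective is 1-homogeneous and `destripe(c * u0)` equals
  `c * destripe(u0)` at the same `alpha` (tested; for the l2 prior the
  covariant scaling is `alpha -> alpha / c`).
* **Convolution boundary**: zero-padded linear convolution.  The operator
  and its adjoint are applied as direct separable convolutions in C++
  (numerically identical to zero-padded FFT convolution; a naive
  direct-space oracle checks the generator's convolution at small size).
  Non-separable user-supplied kernels take a dense 2D path.
* **Optimiser**: Chambolle-Pock primal-dual with deterministic zero
  initialisation.  Step sizes satisfy `sigma tau L^2 < 1` with `L`
  estimated by power iteration on `D o A` (computed once per volume and
  shared across slices).  A dual-heavy step ratio (`tau/sigma = 0.01`)
  converges severalfold faster on stripe problems than symmetric steps and
  is the default.
* **Stopping and the reported trace**: the primal objective of
  Chambolle-Pock is not monotone, so the solver tracks the best iterate
  and reports the best-so-far objective -- a non-increasing trace -- and
  returns that iterate.  Iteration stops when the per-iteration relative
  decrease of the best objective, averaged over a 10-iteration window,
  falls below `tol = 3e-4` (or at `max_iter = 500`).  A tighter 1e-5
  threshold spends hundreds of extra iterations on an objective tail that
  changes PSNR and stripe-field correlation by under 0.1 dB / 0.001; the
  default stops once the estimate has stabilised, and the threshold is a
  user-visible parameter.
* **Per-slice versus volumetric**: stripes live in the light-sheet plane,
  so slices are processed independently by default.  `per_slice = FALSE`
  runs a single volumetric solve with 3D TV coupling the slices (psi still
  acts in-plane; separable psi only).  The volumetric form only helps when
  the stripe and noise structure is coherent along z: on slice-independent
  noise the z-component of the 3D TV dominates the prior's dual and
  suppresses the stripe estimate, which is the quantitative reason
  per-slice processing is the default.

`psi` is user-suppliable but never estimated from the data (no blind
deconvolution).  With `psi` a Dirac delta and the l2 prior the problem
reduces exactly to ROF TV denoising, which the test suite exploits: an
independently implemented Chambolle-projection oracle must agree with the
solver to 0.1% on small images.

# Opposing-view registration, fusion, drift

The two-view (0/180 degree) geometry is fixed: rotating the sample half a turn
about the vertical axis flips the stack along x and z, leaving only a
residual translation.  That translation is estimated by 3D phase
correlation -- Hann windowing against edge ringing, spectral whitening with
epsilon 1e-6, parabolic refinement of the correlation peak per axis for
subvoxel accuracy.  The normalized peak height serves as a reliability
score; registrations scoring below 0.05 are rejected (pure-noise pairs
score far below this floor).  General multi-angle registration is out of
scope.

Fusion resamples every view into the reference frame by trilinear
interpolation and combines them by a weighted average whose weights sum to
one at every voxel.  The default `ramp` rule weights each view linearly
decreasing along its own illumination direction -- each view is trusted on
the side its light sheet enters, which is exactly where attenuation has not
yet degraded it; `local_contrast` (Gaussian-windowed gradient energy) is
available behind a flag.  Voxels mapped from outside a view's support get
zero weight for that view; voxels outside every view fall back to equal
weights.  The true fusion rule used by the original external plugin is not
described anywhere; this weighted average is the package's own stand-in.

Drift compensation estimates a per-frame translation by the same phase
correlation against the first frame (default; no error accumulation) or
the previous frame (chained shifts, for large drifts), applies subvoxel
correction by trilinear interpolation, and reports shifts in micrometres.
Unreliable frames fall back to zero incremental shift with a warning.

# Nucleus detection, classification, geometry

**Detection** is multiscale scale-normalized Laplacian-of-Gaussian blob
detection: the volume is first scaled by its 0.999 quantile (making the
response threshold invariant to global intensity scaling), lightly
pre-smoothed, then filtered at scales bracketing the expected nucleus
radius (r = sigma sqrt 3; defaults bracket 3-7 um).  Local maxima of the
across-scale maximum response above 0.2 are kept, then greedily
deduplicated at a 6-um minimum separation (strongest response wins).  The
0.2 threshold was calibrated on generator scenes: nucleus responses sit
above 0.33 even at full attenuation depth while residual stripe artifacts
stay below 0.15.  All distances honour the anisotropic voxel size in
micrometres.

**Measurement** grows a marker-based watershed (priority flood,
6-connectivity, C++) on the smoothed volume from the detected seeds; each
region floods down to 30% of its own seed intensity, which keeps
segmentation stable across the attenuation gradient.  Per region:
volume, mean intensity, local background (median in a concentric shell 2-4
detection radii out, excluding labelled voxels -- a local shell because the
attenuation gradient makes any global background meaningless), and the
second-moment tensor of the smoothed, floor-subtracted signal restricted
to 2.5 radii around the seed (the restriction immunises the moments
against occasional label bleed into a missed neighbour).  Elongation is
`sqrt(e1/e3)` of the tensor's eigenvalues; `sphericity_proxy` is its
reciprocal.

**Classification** operationalises the visual criteria for mitotic figures
-- high fluorescence intensity plus the condensed-chromosome shape -- as an
explicit rule: mitotic iff `background_ratio >= 1.6` and (`elongation >=
1.8` or volume below 0.6 of the interphase median volume).  The interphase
median is taken over sub-threshold-intensity detections.  All three
thresholds are exposed; the applied rule is recorded verbatim in the
output's metadata.  On generator scenes the intensity criterion is
non-discriminative (there is no cytoplasmic background, so every nucleus
sits far above its local background) and the shape and volume criteria do
the separating; on real data with diffuse background the intensity ratio
is expected to carry more weight.

**Surface geometry.** The spheroid surface is fitted as a sphere to the
outer-hull detections -- the directional support points of the centroid
cloud (argmax of projections on ~300 quasi-uniform directions, a subset of
the convex hull vertices) -- by an algebraic least-squares fit refined with
a geometric Gauss-Newton pass.  Because nuclei sample the volume at finite
density, the raw support fit underestimates the radius by roughly one
inter-nuclear spacing (about 5% at desk-scale density); a Monte-Carlo
correction removes this bias by resampling synthetic clouds from the
empirical radial distribution with fresh uniform directions (fixed
internal seed, deterministic) and adding the observed fit deficit back.
For points that genuinely lie on a sphere the correction vanishes.  The
residual RMS is reported so non-spherical samples can be flagged.  Depth
from surface is `radius - ||centroid - center||`, positive inside; small
negative values are legitimate for surface-straddling nuclei.

# Tracking, mitotic events, arrest scoring

Linking is greedy nearest-neighbour under a 10-um gate with ties broken by
distance then id, gaps up to one frame bridged -- adequate at spheroid
nuclear densities where typical inter-frame motion is far below the
inter-nuclear spacing; no global assignment is attempted.  Because greedy
linking continues a dividing cell into its nearest daughter, a division
appears as a mitotic-to-interphase transition inside one track plus one
new track starting alongside; the tracker splits the parent at that
transition and links both as daughters (geometric division detection, no
intensity heuristics).

A mitotic event is a maximal run of mitotic classification within a track.
Runs shorter than 2 frames are discarded as flicker, and single-frame
interphase interruptions inside a run are bridged for the same reason.
Exit is the first frame with daughters, or the reversion to interphase
(outcome `completed`, duration `(exit - entry) * interval`).  A run that
reaches movie end is `censored`, unless its observed duration reaches the
60-min arrest horizon -- the standard criterion for calling a
paclitaxel-type mitotic block -- in which case it is `arrested`.  Censored and arrested durations use the
inclusive occupancy `(last - entry + 1) * interval`: the cell is mitotic
throughout each observed frame, and with the exclusive convention a
20-frame, 3-min movie could never exhibit a 60-min arrest at all.

Metaphase-plate alignment uses the planarity of the chromosome mass: the
smallest-to-middle eigenvalue ratio of its second-moment tensor.  A flat
plate collapses one axis (ratio << 1); both spheres and prolate condensed
masses keep it near 1, so the drug phenotype -- condensed chromosomes that
never align -- is cleanly separable.  An event is `aligned` when the ratio
drops below 0.35 for at least two consecutive frames.

`compare_conditions()` reports per-arm counts, median completed duration
(censored medians flagged as lower bounds), arrested and aligned
fractions, and a rank-based (Wilcoxon) two-sample comparison of observed
durations -- reporting plumbing, not a scientific claim of the method.

# Problem sizes and numerical choices in the test suite

The suite exercises the pipeline at sizes chosen to keep a full run on one
desktop core within minutes while leaving every contract meaningful:
destriping accuracy on three seeded desk-scale volumes (192 x 192 x 128)
and a timed 192 x 192 x 64 volume; detection and classification on the
same three desk scenes; registration and fusion on 72 x 72 x 48 view
pairs; drift on three seeds x three magnitudes; dynamics on 20-frame,
88 x 88 x 56 movies (three control, two drug) with three divisions each,
destriped with a 35-iteration cap -- enough to push stripe residues well
below the detection threshold; full convergence changes no downstream
call.
Division candidates are chosen well separated (>= 25 um) via
`suggest_division_ids()` -- adjacent simultaneous divisions would place
daughters inside each other, which the hard-core tissue model itself
forbids.

Degenerate inputs are handled explicitly: empty volumes yield empty
detection tables; coplanar centroids make the sphere fit fail loudly;
infeasible placement densities abort with the attempt budget; unknown
pipeline-config keys fail before any computation.

# Known limitations

* The generator has no cytoplasmic or out-of-focus background, no
  photobleaching, no chromatin texture, and its drift is purely rigid;
  passing accuracy tests therefore demonstrates correctness of the
  algorithms under the stated forward model, not performance on real
  stacks.  The classification thresholds in particular have no
  paper-derived values to match and will need recalibration on real data.
* Stripe removal assumes the elementary pattern is known (or close);
  there is no blind kernel estimation.
* Only the two-view opposing geometry is supported; multi-angle bead-based
  registration is out of scope.
* Lineages are tracked through a single division; no grand-daughter
  generations, no cell-death phenotypes.
* The volumetric destriping solve requires a separable stripe pattern.
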