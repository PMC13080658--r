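---
title: "Correlative microscopy-MRI analysis: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlative microscopy-MRI analysis: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromri)
```

# The problem

Intravital two-photon (2P) microscopy resolves single capillaries and
individual tumor cells; MRI surveys the whole brain at voxel sizes of
40-100 um. Relating the two voxel-by-voxel -- so that the microscopic
content of each MRI voxel (vessel volume fraction, glioma cell density,
blood flow) can be read off directly -- requires (i) geometrically exact
co-registration, (ii) careful resampling of the microscopy onto the MRI
grid so values keep a volume-fraction meaning, (iii) intensity
normalization that makes MR sequences comparable across sessions, and
(iv) evaluation metrics that tolerate the residual registration error
instead of hiding it. `micromri` implements that pipeline, the
quality-control statistics around it, and a synthetic phantom generator
that provides exact ground truth for every stage.

# Conventions

All volumes are `ImageVolume` objects: a (z, y, x)-ordered array with
per-axis spacing in micrometers and the world coordinate of the center
of voxel (0, 0, 0). Indices are 0-based and the voxel-center convention
is `world = origin + index * spacing`; file formats that store
millimeters (NIfTI, Slicer FCSV) are converted at the I/O boundary.
Landmark-fitted transforms map **fixed to moving** world coordinates,
which is the pull-back direction resampling needs: the target grid is
scanned, each center is mapped into the moving volume, and the moving
volume is interpolated there. This avoids inverting a thin-plate spline
numerically; when an explicit inverse is wanted, `invertTransform()`
refits with the landmark roles swapped, which is exact at the landmarks.

# Registration model

Four landmark-fit modes are provided. Rigid and similarity use the
closed-form orthogonal least-squares (Procrustes/Umeyama) solution;
affine is linear least squares; the elastic mode is a thin-plate spline
with kernel `U(r) = r` in 3D and `U(r) = r^2 log r` in 2D -- the standard
kernels of thin-plate theory per dimension. With the default
regularization `lambda = 0` the spline interpolates its landmarks
exactly (residual below 1e-6 um); positive `lambda` is exposed for noisy
landmarks. Whether a practitioner's elastic registration includes
regularization is usually unstated, so exact interpolation is the
documented default assumption here.

Degenerate configurations (collinear points for a rotation fit, coplanar
points for affine/TPS in 3D) are rejected with the degeneracy named, not
silently regularized.

Longitudinal sessions are aligned with a rotation+translation model
only: closed form when landmarks are given, otherwise a multi-start
Nelder-Mead search maximizing intensity correlation, with at least 50%
volume overlap required and a lowest-parameter-norm tie-break so the
result is deterministic. Failures are reported with diagnostics, never
returned as a silent identity.

Registration quality is quantified as landmark RMSE, and inter-rater
reproducibility by pushing a regular per-slice coordinate grid (50 x 50
by default) through two raters' transform chains and taking the RMSE of
the mapped positions over a seeded random subsample.

# From microscopy stacks to MRI voxel values

`groupZByAverage()` averages consecutive 2P slices so one output slice
spans one MRI voxel depth; for a binary input the result is the
foreground volume fraction in [0, 1]. The MRI depth must be an integer
multiple of the slice spacing (within 1%); anything else is an error
suggesting resampling, because silent interpolation would break the
fraction interpretation. A trailing partial group is dropped with a
warning, so total foreground volume is conserved up to that partial
group.

`downsampleXYDensity()` brings the z-grouped map to the MRI in-plane
grid. Although the in-plane step is nominally bilinear, plain bilinear
*sampling* at scale factors of 4-10 aliases badly and destroys the
volume-fraction meaning; the implementation therefore uses area-weighted
block averaging whenever the factor is an integer of at least 2 and falls
back to bilinear sampling otherwise. Constant fields and linear ramps
pass through exactly (to 1e-9), which is the test oracle.

MRI sequences are z-normalized to normal-appearing gray matter (NAGM):
`out = (in - mean_NAGM) / sd_NAGM`, computed per volume (a per-slice
variant would interact with the reslicing step and is not offered). The
NAGM mask is an explicit input -- in practice it is drawn from the 2P
signal excluding tumor, vessels and artifacts -- and the package refuses
masks smaller than 30 voxels or with zero variance. T2* maps are fitted
per voxel by weighted log-linear regression of the mono-exponential decay
`S(TE) = S0 exp(-TE/T2*)` (weights `S^2`, at least 3 echoes);
non-physical fits are masked invalid rather than clamped.

`extractVoxelTable()` then emits one row per labeled voxel with every
registered layer's value, and `binByDensity()` groups rows into the
density classes used throughout: a `w/o glioma` class for normal-tissue
voxels and half-open bins `[0,5) [5,25) [25,50) [50,75)` percent with a
closed top bin `[75,100]`. Printed bin labels in the field overlap
("0-5", "5-25") without stating the boundary rule; half-open with a
closed top is this package's documented convention, and a density of
exactly 5% falls in `5-25%`.

Growth rates use the first and last timepoints,
`100 * (d_last - d_first) / (t_last - t_first)` in percent per day,
restricted to the intersection of all session masks; per-interval rates
are available behind a flag. Group comparisons (ANOVA + Tukey HSD,
Kruskal-Wallis + Dunn's z-tests with Bonferroni adjustment,
Mann-Whitney U, Welch) wrap base R tests; Dunn's post-hoc is implemented
directly from the rank formula with tie correction because no installed
package provides it.

# Vessel geometry, stability QC and velocimetry

The local vessel diameter is the **maximal inscribed sphere** diameter:
every foreground voxel receives the diameter of the largest sphere that
fits inside the mask and contains it, computed from the anisotropic
Euclidean distance transform followed by ridge propagation (painting
spheres in decreasing radius order). A naive `2 x EDT` would
underestimate off-axis voxels of a tube and wrongly delete them at a
diameter threshold; maximal-inscribed-sphere assigns the full tube
diameter to the whole cross-section, which is what the 30 um visibility
filter requires. All distances are world-metric, so anisotropic grids
(e.g. 25/25/100 um) are handled correctly. The original neighborhood
macro this mirrors is unspecified; the implementation is validated
against cylinder and sphere phantoms (one-voxel tolerance), not against
the macro.

Stability of the vessel-diameter distribution across sessions uses an a
priori equivalence margin of +/-5%: a diameter category is stable if the
maximum absolute deviation of its proportion from the reference
timepoint stays within the margin. Contrast-agent uptake QC uses percent
signal enhancement, `PSE = (SI_post - SI_pre)/SI_pre * 100`, summarized
as cohort mean, sample (n-1) SD and coefficient of variation.

Kymograph velocimetry converts streak slopes to speed:
`v = |dpx| * pixel_size / (|dlines| * line_interval)`, with mm/s and
um/ms numerically identical. The manual mode takes drawn line segments;
the automatic mode sweeps candidate slopes, integrates the image along
each direction (with wraparound) and maximizes the variance of the
integrated profile, refining the best slope on a finer grid. A flat
angular response (best response under 5x the median, a threshold far
below the >100x contrast of real streaks) is reported as indeterminate
rather than as a number. Speed only is reported; the slope sign is
discarded.

# Segmentation evaluation

Predictions are compared to the registered microscopy ground truth, so
plain Dice would penalize the registration error itself. The Dilated
Dice credits matches within a spatial tolerance:

`DD = (|A ∩ D(B)| + |D(A) ∩ B|) / (|A| + |B|)`

where `D(X)` dilates by a world-metric ball (default radius 50 um --
"50 um added on both sides" is read as a radius, not a diameter; with
100 um slices the ball adds no out-of-plane neighbors, and the tolerance
is configurable). `DD(A,A) = 1`, tolerance 0 reduces to plain Dice, and
`DD` is monotone in the tolerance. The exact symmetric form used here is
inferred from the symbol set (A, B, D(A), D(B)) and the identity
`DD(A,A)=1`, and is verified against those properties and a brute-force
all-pairs oracle rather than against any external implementation.

The mean absolute surface distance is computed over **all** foreground
voxels, exactly as its symbol definitions state ("a is a voxel in the
ground truth"), not only boundary voxels; a `surfaceOnly` flag provides
the conventional ASSD for comparison. Both metrics share the same exact
(Felzenszwalb-Huttenlocher) distance transform, so they agree with
brute-force all-pairs computation to machine precision.

Training-pair preparation resamples to the 25/25/100 um grid, applies
the 30 um diameter filter to labels, binarizes, and applies seeded
in-plane flips and 90-degree rotations identically to image and label;
pairs are exported in an `imagesTr`/`labelsTr` layout with `CASE_xxxx`
naming for an external 2D U-Net trainer. Cross-validation folds are
grouped by subject so no animal appears on both sides of a split.
Network training itself is out of scope; the package prepares its inputs
and evaluates its outputs.

# Lesion quantification

`quantifyClusters()` reproduces particle analysis per ROI: threshold,
connected components (default 26-connectivity in 3D; the classic 2D tool
convention of 8-connectivity is the in-plane degeneration of 26, and
6/18 are exposed), minimum-size filter, then counts and world-unit
volumes. Lesion classes are compared with Mann-Whitney U.
Marker co-positivity is the fraction `|A+ ∩ B+| / |A+|` over segmented
nuclei. Classifying lesions by perilesional signal (e.g. a hypointense
T2* shell) has no published threshold -- the assessment is visual in
practice -- so the rule here (mean normalized signal in a configurable
shell vs a configurable z-cutoff, logged with the result) is explicitly
a parameterized assumption, not a reproduction.

# The phantom generator

Every stage is tested against `PhantomScene` objects with known ground
truth:

- **Vessel trees** grow by recursive binary branching with a Murray-type
  radius decay (`r^3 = r1^3 + r2^3`, exponent configurable) and a
  bounded random walk inside the scene box; bifurcation points are
  recorded and serve as registration landmarks, matching how anatomical
  landmarks are chosen in practice. Flow velocity is assigned
  monotonically in radius (defaults 0.5-8 mm/s over 10-60 um radii,
  spanning reported cortical capillary-to-arteriole speeds).
- **Tumor fields** are clamped sums of Gaussian blobs with a small
  cutoff subtracted so tissue outside the infiltration margin has
  exactly zero density -- giving a genuine `w/o glioma` stratum.
- **MRI contrast** is a linear model:
  `t2w = baseline - k_vessel * vesselFraction + k_tumor * tumorDensity`,
  `tof = baseline + k_flow * flowFraction`, plus optional Gaussian
  noise. No MR physics is claimed (no Bloch simulation, no quantitative
  T2*-vs-pathology transfer function exists to copy); the model fixes
  the *signs* of the dependencies so downstream statistics have known
  directions. Ground-truth per-voxel fractions are computed by
  oversampled rasterization and block averaging and are emitted
  alongside.
- **Deformations** are identity/rigid/affine or smooth random warps
  built as thin-plate interpolants of random displacements on a coarse
  control grid; because the warp is linear in the control
  displacements, it is rescaled exactly so the maximum displacement
  equals the requested amplitude, and amplitudes below half the control
  spacing keep it invertible. Landmark pairs are exact by construction
  (preimages solved by fixed-point iteration to 1e-9).
- **Kymographs** draw dark Gaussian streaks advancing
  `v * line_interval / pixel_size` pixels per line (defaults 1.1838 um
  pixels, 0.15 ms line interval -- the line-scan geometry of the
  acquisition this emulates) with wraparound and optional noise.
- **Longitudinal series** evolve the tumor field as
  `density(t) = clamp(density(0) + rate/100 * t)`, interpreting growth
  rate as absolute density percentage points per day.

All generators are pure functions of their parameters and a seed; no
global RNG state is touched (the caller's stream is saved and restored).

What the phantoms do *not* emulate: optical scattering and
depth-dependent attenuation, vessel pulsation and motion artifacts,
Rician MR noise, susceptibility geometry, or real infiltration
morphology. Passing tests therefore demonstrate algorithmic correctness
(geometry, formulas, conservation, metric exactness, direction of
contrast effects) -- not that the pipeline's accuracy on real acquisitions
equals the phantom numbers.

# Numerical choices and degenerate inputs

- Trilinear interpolation outside the voxel-center hull returns the
  configurable fill value; masks always resample nearest-neighbor.
- In-plane upscaling replicates edge voxels beyond the first/last
  centers so a half-voxel border is not filled with zeros.
- The EDT uses a finite sentinel (1e30) instead of infinities inside the
  parabola recurrence; empty feature sets return infinite distances.
- Sphere painting in the local-thickness pass includes a voxel if its
  center lies within the inscribed radius plus 1e-9 um.
- Density/probability volumes are clamped to [0, 1] at construction;
  densities outside the range in a voxel table are an error, not a
  clamp, because they indicate an upstream bug.
- Bonferroni adjustment is `min(1, m * p)` over the actual number of
  pairwise comparisons.

# Problem sizes

The test suite and the acceptance script run desk-scale problems chosen
to exercise every code path at full fidelity: microscopy grids up to
128^3 voxels (1280 um at 10 um spacing), MRI grids of 16^3 at 80 um,
vessel trees with tens of segments, 100-trial metric-oracle sweeps on
10 x 10 x 3 masks, and 400-line kymographs. These sizes keep each stage
well-determined (thousands of voxels per density bin) while the whole
suite completes in minutes; all routines accept larger inputs unchanged.

# Known limitations

- The TPS inverse is exact only at landmarks; far from them the
  role-swap refit is an approximation.
- Intensity-based longitudinal registration is local: it assumes the
  initial misalignment lies within the configured search bounds.
- The automatic streak detector assumes a single dominant flow
  direction; bidirectional flow in one line scan is reported as the
  stronger orientation.
- `LabelMask` ROIs are taken as drawn; the package does not segment
  lesions or infer NAGM masks.
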