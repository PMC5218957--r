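---
title: "Quantitative Lu-177 SPECT with luquant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative Lu-177 SPECT with luquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`luquant` is a simulation-fed pipeline for absolute activity quantification
in Lu-177 SPECT, following the MIRD pamphlet 23/26 workflow: acquire three
energy windows around the 208 keV photopeak, reconstruct with OSEM
including CT-based attenuation correction (AC), resolution recovery (RR)
and triple-energy-window (TEW) scatter handling, convert reconstructed
counts to becquerels with a camera normalization factor (CNF), segment each
object, and report the percent error of the recovered activity against the
known truth. Because every input is generated by the package's own digital
phantoms, the truth is exact and the pipeline can be validated by parameter
recovery.

This vignette documents the models, the tunable parameters with their
defaults and units, the numerical conventions, and the places where the
design was genuinely open.

## The forward model

### Phantoms

A phantom is a set of co-registered voxel maps: activity (MBq per voxel),
material (air, water, lung, bone, bed) and linear attenuation at 208 keV
(cm^-1). Inserts are spheres or axis-aligned cylinders rasterized with
fractional boundary fill: interior voxels are 1, boundary voxels receive
the fraction of their volume inside the solid, estimated by 4^3 midpoint
supersampling (cylinders use an exact axial-overlap factor times a 2D
supersampled cross-section, because their flat caps align with the grid and
would otherwise bias a pure midpoint rule). Rasterized volumes agree with
the nominal insert volumes to well under 1% at the default 2.4 mm phantom
pitch, so rasterization error is negligible against the segmentation
effects under study. The per-insert "true activity" used in all error
calculations is the activity actually placed on the grid (concentration
times rasterized volume), so quantification errors measure the pipeline,
not the rasterizer.

The eight study configurations (spheres of 0.5-113 ml and bottles of
8.5-34 ml in a 22.2 cm Jaszczak cylinder in air, cold water, or warm
background at signal-to-background ratios 6.5 and 49.1; four 34 ml bottles
in an elliptical thorax body with lung, spine and bone inserts; and
160-200 ml bottles on the camera bed with and without 2 L water bags) ship
as YAML presets. The thorax body is an approximation — an elliptical water
cylinder with two lung-density ellipsoids, a posterior bone rod for the
spine and a second, shorter bone rod standing in for a real bone — because
the exact vendor geometry is not public. Insert positions inside the
Jaszczak cylinder are likewise a declared convention: the 113 ml sphere at
the centre with the others on a ring of radius 88 mm (bottles at 80 mm),
as wide as the cylinder allows, so that each object's spill and background
shell stay clear of its neighbours.

Attenuation coefficients at 208 keV are frozen constants taken once from
standard mass-attenuation tables: water 0.136 cm^-1, cortical bone 0.25,
inflated lung 0.041, bed 0.06, air 0 (vacuum approximation; the true
1.6e-4 cm^-1 is irrelevant at these path lengths).

### Projector

The system operator is a rotation-based projector. For each view the
activity volume is *splatted* (bilinear distribution of each voxel to its
rotated position) into the view frame; each emission plane is weighted by
the cumulative attenuation towards the detector with a half-voxel offset
(a photon sees half of its own plane's mu plus everything nearer the
detector), blurred with a distance-dependent Gaussian
`sigma(d) = sigma0 + slope * d`, summed along the ray, and block-summed to
detector bins. Splatting rather than interpolation (gathering) was chosen
for the forward direction because it conserves each voxel's counts exactly:
a point source projects to exactly its emitted counts in every view, and
total projected counts equal total activity times sensitivity times
projection time when attenuation is off. The backprojector uses the
matching bilinear gather, which makes the pair an exact matrix transpose —
the adjoint dot-product test holds to floating rounding, which OSEM's
convergence theory assumes.

PSF defaults are `sigma0 = 3 mm` and `slope = 0.02` (sigma per mm of
distance), representative of a medium-energy low-penetration collimator at
208 keV (FWHM about 19 mm at 25 cm). These are shared by the simulator and
the reconstructor; the validation targets recovery with a matched response,
not any particular absolute resolution. `psf_from_fwhm()` converts two
measured FWHM calibration points into these parameters.

The orbit is circular at 250 mm by default; a per-view radius vector is
accepted for non-circular orbits. The detector samples 90 views over 360
degrees.

### Energy windows and scatter

The three acquisition windows are: lower scatter window 153.0-187.0 keV,
photopeak 187.2-228.8 keV, upper scatter window 229.5-280.2 keV (widths
34.0 / 41.6 / 50.7 keV), treated as half-open intervals.

Scatter is modelled in projection space, not by photon transport. The
photopeak self-scatter component S is a scaled, spatially broadened copy of
the primary sinogram (`self_scatter_fraction` times a Gaussian of FWHM
`kernel_fwhm = 60 mm`); the high-energy downscatter component H is scaled
by `he_fraction = 0.03` — three percent of the primary photopeak counts,
the magnitude reported for Lu-177's high-energy emissions — and broadened
twice as much, since those photons mostly scatter inside the crystal.
Self-scatter defaults to 0.25 of primaries in water-filled media and 0.05
in air; no published value exists for this fraction at 208 keV, so these
are declared assumptions at the plausible end for the two regimes.

The flanking-window counts come from a spectral-density model built so that
TEW bias is controlled by a single knob. The density across the photopeak
is a quadratic in energy,
`rho(E) = rho0 * (1 + s (E - 208) + q (E - 208)^2)`, normalised so its
photopeak integral equals S + H per bin, with *flat shelves* over the two
flanking windows pinned at the photopeak-edge values `rho(187.2)` and
`rho(228.8)`. Because the photopeak window is symmetric about 208 keV, the
TEW trapezoid — heights `C_ls/w_ls` and `C_us/w_us`, width `w_pw` —
integrates the linear part exactly: with `q = 0` TEW is unbiased in
expectation for any slope `s`, and the bias grows monotonically with `q`.
(A model that integrated one global linear density over the three windows
cannot have this property, because the flanking-window centres at 170 and
255 keV are not symmetric about 208 keV.) Defaults `s = -0.002 /keV` and
`q = 5e-5 /keV^2` give TEW a relative scatter-estimation bias of about
1.4%, so the correction is exercised against a ground truth it never
trivially equals. Counting noise is independent Poisson per bin and window.

## Reconstruction

OSEM uses 10 subsets and 6 iterations (the clinical compromise between
small- and large-object accuracy), views assigned angle-interleaved
(view i to subset i mod 10; 90/10 = 9 views per subset exactly). The
scatter estimate enters the denominator of the multiplicative update —
added to the forward projection of the current image — never subtracted
from the data, which preserves the Poisson structure and nonnegativity.
Three scatter modes exist: `tew` (the estimate from the measured flanking
windows, clamped at zero, no smoothing), `ideal` (the simulator's exact
expected S + H — the stand-in for a perfect model-based correction), and
`none`.

Numerical conventions: the denominator is floored at `1e-10` times the
maximum forward-projected value; the initial image is uniform ones on the
full reconstruction grid (initialising only inside the attenuation-map
support would inject object-location knowledge in the in-air
configurations, where only the inserts attenuate); voxels with zero subset
sensitivity are excluded from the update and remain zero; exact zeros are
fixed points of the multiplicative update.

The reconstructed image is *count-preserving*: the system matrix is the
per-view geometric projector scaled by 1/n_views, so total image counts
approximate the total counts acquired over the whole scan. This is the
convention under which the tomographic normalization factor
`CNF = C_rec / (A * t_p * n_p)` recovers the planar sensitivity, and voxel
counts convert to activity as `MBq = counts / (CNF * n_p * t_p)`.

The reconstruction grid is the detector grid (4.8 mm voxels); the phantom
is simulated at 2.4 mm and the attenuation map is block-averaged to the
reconstruction grid, so simulated data never live on the reconstruction
grid (no pure inverse crime) while scatter is generated by the window
model rather than the TEW estimator itself.

## Camera normalization

Three CNF estimators are implemented. Planar method 1 divides all
photopeak counts of a point-source scan by activity times duration; it is
biased high by whatever scatter sits in the photopeak. Planar method 2
first removes the TEW estimate from the window totals. The tomographic
method reconstructs an extended phantom with AC + RR + TEW and divides
total image counts by activity times total scan time. The simulated planar
source sits 30 cm from the collimator (sensitivity is distance-independent;
the distance only widens the blob). In simulation, method 2 recovers the
configured sensitivity to 0.1% when the scatter spectrum is curvature-free,
and the spread between planar method 2 and three tomographic scans at
different activity levels stays well inside the bounds reported for the
physical camera.

## Segmentation

All methods threshold relative to a reference value: the mean of the 9
hottest voxels in the object's volume of interest. The fixed-threshold
method uses 0.1% in air, 1% in cold water (low cuts that deliberately
capture counts spilled outside the object by partial-volume effects) and
40% in warm background (the common clinical choice). CT-based segmentation
sums the image over the voxels whose centres fall inside the physical
insert geometry (the fractional-fill mask rasterized at the reconstruction
resolution, binarized at half occupancy), so the segmented volume matches
the physical volume to within the boundary-voxel discretization; spill
beyond the boundary is lost, so it underestimates blurred objects — more
than an adaptive threshold, less than the 40% cut, reproducing the
reported method ordering.

The iterative adaptive dual-threshold (IADT) method uses two calibration
curves — threshold fraction versus SBR, one reproducing true volume and
one reproducing true activity — built from separate simulated scans of six
bottles (17-199.5 ml, 0.62 MBq/ml) at SBRs 14.0, 8.0, 5.3 and 4.1. For
each calibration insert the fractions reproducing truth are found by
bisection on the monotone threshold profiles; per SBR level the median
fraction across inserts forms a knot. Knots are indexed by the SBR
*measured in the calibration image with the same estimator the segmenter
uses at query time* (9-hottest reference over the mean of VOI voxels one
voxel clear of the current mask and inside the body contour), which keeps
calibration and query abscissae consistent; the true SBR is kept as
provenance. The body-contour restriction — background sampled only where
the attenuation map exceeds half the water value, i.e. inside the
CT-visible body — is essential: without it the background reading depends
on how much of an object's VOI falls outside the phantom, so the measured
SBR of a centrally placed object and a wall-adjacent one would sit on
different scales and the calibration would not transfer. Clinically the
body contour is always available from the CT. Interpolation is
piecewise linear in log(SBR) with clamped extrapolation — a query at SBR
49 uses the highest calibrated knot, exactly as a physical calibration
limited to SBR 14 would. Segmentation starts from the 40% mask and
iterates measure-SBR / look-up / re-threshold until both fractions move by
less than 1e-3 (cap 20 iterations, non-convergence flagged).

Two behaviours deserve emphasis. First, the optimal threshold fraction
*rises* as SBR falls: the background pedestal sits at roughly `ref/SBR`,
so lower SBR forces a higher cut. The calibration curves inherit this
ordering and the tests assert it. Second, a single fraction-versus-SBR
curve is a compromise across object sizes: the optimal fraction is
volume-dependent through partial-volume effects, so IADT applied even to
its own calibration inserts recovers large objects (>= 50 ml) to a few
percent but degrades below ~30 ml — consistent with the method's known
failure for small or non-uniform objects, and the reason quantification
below 17 ml is reported but not trusted.

Volumes of interest stand in for manually drawn regions: a bounding box
around each insert centre padded to three equivalent radii *plus one
reconstructed-PSF diameter* (24 mm), intersected with the insert's
surface-distance Voronoi cell so neighbouring objects never share a VOI.
The fixed padding matters for millilitre-scale objects, whose spilled
counts extend several object radii; the Voronoi restriction matters for
the 113 ml sphere, whose 3-radius box would otherwise swallow its
neighbours.

## Analysis

Quantification error is the signed percent difference from truth. Group
summaries (median, IQR, min, max of per-insert mean errors) reproduce the
content of the study's box plots. The Mann-Whitney rank-sum test (exact p
when sample sizes and ties permit, via `stats::wilcox.test`) compares
scatter corrections within a configuration; Mood's median test (own
contingency construction, `stats::chisq.test` without continuity
correction) compares the three segmentation methods at once. p < 0.05 is
flagged as a significant difference; no multiple-testing correction is
applied. The study driver averages each insert's error over five seeded
Poisson realizations and excludes the 0.5 ml sphere everywhere, the 1 ml
sphere in warm background (invisible there) and the first bed bottle
(whose physical assay was unusable), mirroring the experimental analysis.

## Problem sizes and determinism

The default study geometry is a 100 x 100 x 90 phantom grid at 2.4 mm,
a 50 x 45 detector at 4.8 mm, 90 views, and a 50 x 50 x 45 reconstruction
grid — small enough that the full eight-configuration study with five
noise realizations, the four-scan IADT calibration and the CNF study run
on one CPU in roughly ten minutes, while keeping at least 10^6 detected
events per acquisition. Every random stage (Poisson draws, calibration
scans, planar scan) derives its seed from one master integer, and
`add_poisson()` restores the caller's RNG state, so identical seeds give
bit-identical reports.

## What passing tests do and do not show

The generator emulates the geometry, windows, counting statistics, scatter
magnitudes and background conditions of the physical study, but not photon
transport: scatter has no object-dependent spatial asymmetry, septal
penetration and collimator scatter are absent, detector energy resolution
is folded into the window-fraction model, and dead time is ignored
(negligible at these activities). Parameter recovery within the reported
bounds therefore validates the reconstruction-and-quantification chain —
attenuation correction, resolution recovery, TEW behaviour under a
controlled spectral bias, normalization and segmentation — under
controlled conditions; it does not certify accuracy on a physical camera,
where the scatter model itself is part of the error budget. The
out-of-scope analytical scatter estimator the study compared against is
represented here only by the `ideal` mode, which bounds what a perfect
spatial scatter model could achieve.

## Known limitations

- The IADT calibration-curve aggregation (median across insert volumes)
  limits small-object accuracy by construction; per-volume curves would
  remove this but are not what the method prescribes.
- Attenuation maps come from the phantom itself (block-averaged), so CT
  artefacts, registration error and HU-to-mu conversion error are outside
  the error budget.
- The projector models in-plane rotation only (parallel-beam MELP
  geometry); slant-hole or fan-beam collimation is out of scope.
- Bremsstrahlung contamination (shown elsewhere to be below 0.02% for
  Lu-177) is ignored.
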