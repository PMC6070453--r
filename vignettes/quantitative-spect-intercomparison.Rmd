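---
title: "A synthetic multi-site quantitative Lu-177 SPECT/CT inter-comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A synthetic multi-site quantitative Lu-177 SPECT/CT inter-comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(luquant)
```

## The problem

Absolute activity quantification with SPECT/CT underpins dosimetry for
molecular radiotherapy with ¹⁷⁷Lu. Different clinics quantify with different
cameras, energy windows, reconstructions, segmentation rules, calibration
geometries and uncertainty recipes, and multi-site phantom exercises have
shown that identical sources can yield activity estimates tens of percent
apart. `luquant` rebuilds such an exercise entirely *in silico*: a digital
dual-compartment "shell sphere" (hot 26-ml inner sphere inside a warm
~80-ml concentric shell, concentration ratio ≈ 15:1) sits in a water-filled
elliptical body phantom with low-density lung and bone-equivalent spine
inserts; a gamma-camera simulator produces multi-window projections; and
seven named protocol presets (H1…H7) replay the sites' full chains —
calibration, OSEM reconstruction, VOI segmentation, counts-to-activity
conversion and uncertainty budget — so that each source of inter-site spread
can be switched on and off at desk scale.

Because every stage is simulated, the "true" volumes and activities are
known voxel-exactly, which turns the exercise's qualitative observations
(CT-based segmentation beats SPECT thresholding; totals beat single
compartments; matched-geometry calibration brackets truth; partial-volume
losses of ≲15 % with resolution recovery and ≲30 % without) into testable
propositions.

## The phantom

`shell_source_spec()` derives the compartment radii from the *measured*
volumes of the six shipped sources (inner 26.0–27.2 ml, shell
79.3–81.6 ml, selectable by site id) rather than from the nominal 36-mm
diameter, since the measured volumes exceed the nominal-diameter volume.
The nominal values (36 mm sphere, 11 mm shell) are retained for the VOI-rule
arithmetic of protocol H1, whose "+10 mm in each spatial direction" margin
is interpreted as a *radial* margin: 18 + 10 = 28 mm against a 29-mm
physical shell radius leaves exactly the outermost millimetre of the shell
outside the inner VOI — the only reading consistent with the rule's stated
consequence.

Voxelization uses voxel-centre sampling on a grid aligned with the phantom
axes, origin at the phantom centre. Compartment walls are zero-thickness
(their influence on the physical exercise was judged negligible). The lungs
are cylinders of the catalogued volumes (900/1100 ml) at 0.3 g/ml — the
printed unit "g/cm²" is read as the obvious typo for g/cm³ — and the spine
insert is a 38 mm × 152 mm cylinder of dipotassium-phosphate solution at
1.33 g/ml (≈100 g salt in 67 g water). Attenuation maps are linear in
density with the water mass-attenuation coefficient at the photopeak energy
(0.165 and 0.136 cm²/g at 113 and 208 keV). Body contour rings and the
couch are not voxelized. The axial position of the source is not printed
anywhere; it defaults to the phantom centre and is configurable.

## The simulator

`acquire()` produces parallel-beam projections: line integrals of the
activity weighted by `exp(-∫μ dl)`, blurred per depth slab with a Gaussian
collimator-detector response `FWHM(d) = sqrt(intrinsic² + (slope·d)²)`
(defaults 4 mm and 0.05, ≈9 mm at 10 cm — representative of medium-energy
collimators; the 113-keV peak gets a slightly wider PSF and 0.6× the
sensitivity, the emission-probability ratio). Orbits are circular or
contoured (body support + 30 mm clearance). Scatter is a kernel/fraction
model, not Monte Carlo: each window receives a fixed fraction of the
unattenuated broad-beam projection convolved with a wide (60 mm FWHM)
Gaussian. The defaults (0.08 in the photopeak, 0.037 in each ±5 % scatter
window) give a scatter-to-detected-primary ratio of roughly 0.3 through the
water body and make the triple-energy-window estimate approximately
unbiased. The true scatter component is stored per window, so "ideal"
scatter correction is available downstream; counts are Poisson with a
configured seed. Absolute sensitivities (default 10 cps/MBq at 208 keV) are
free parameters — no real cps/MBq values are printed anywhere, and all
quantification is relative to a simulated calibration.

Two deliberate simplifications are documented rather than modelled: the
upper scatter window (214 ± 5 %) overlaps the 208 ± 10 % photopeak as
printed, but no spectral overlap is simulated; and septal penetration,
energy resolution, dead time and ¹⁷⁷ᵐLu impurities are out of scope.

## Reconstruction

`osem_reconstruct()` is ordered-subset EM from a uniform-disk initial
image, with CT attenuation correction always on, the scatter estimate as an
additive forward-model term (protocol H5 instead pre-subtracts, as that
site did), optional PSF modelling ("resolution recovery"), per-photopeak
reconstruction with post-summation, and an optional Gaussian post-filter
(8 mm for H6). The C++ projector/backprojector pair is an exact matrix
transpose — the emitter rotation is applied in scatter (mass-conserving)
form in the forward model and gather form in the adjoint, attenuation is a
shared diagonal, and the blur kernels are symmetric — so with one subset
the Poisson log-likelihood is provably non-decreasing, which the test suite
asserts on noisy data. Reconstruction is matched to the simulator (the
"inverse crime"): that is the design point, because the acceptance
questions are about protocol differences, not model error. TEW estimates
are smoothed (2 px Gaussian) before use, standard practice the source
protocols leave unstated. Update denominators are floored at 1e-12.

Site-specific Monte-Carlo scatter corrections (H3, H6) and ESSE (H7) cannot
be replicated at desk scale; both are emulated by the "ideal" mode (the
simulator's true scatter term), their best-case surrogate. This mapping is
per-protocol and explicit in `site_protocol()`.

## Segmentation, calibration, quantification

The four VOI families are: CT-geometry spheres with a radial margin
(`sphere_voi`), relative iso-contours (`iso_contour_voi`, largest
6-connected component), Otsu auto-thresholding on a 256-bin in-region
histogram (`otsu_voi`), and fixed-diameter spheres (H6's arbitrary 8-cm
VOI). "Manual" freehand outlining (H4, H7's outer shell) cannot be
replicated; it is emulated by the truth mask perturbed by ±1 voxel of
6-neighbourhood dilation/erosion drawn from the run's seed, which brackets
operator variability. H2's threshold-selection procedure is a calibration-
time search (`calibrate_iso_threshold`) for the fraction whose volume best
matches the known compartment volumes; the found thresholds are then frozen
for the comparison run. Because the paper's two threshold-selection images
(outer-only, then both compartments at *equal* concentration) leave the
inner boundary without contrast once both are filled, the search runs on
the depth-matched calibration shell filled at the comparison-like 15:1
ratio. H7's Otsu search region is not described; the default is a sphere of
twice the source extent.

Calibration factors are cps/MBq by each site's geometry: a large
homogeneous source with a +10 mm VOI plus three NEMA spheres for the
partial-volume check (H1, the 130-ml "bottle" modelled as a 130-ml
sphere); a shell source of the comparison design at two depths with the
depth-matched factor selected by distance-to-surface (H2); a 16-ml sphere
centred (H3), at three positions averaged (H4), or with six VOIs — one
slightly smaller and one slightly larger per position — averaged (H5; the
displaced position is 12 cm, the largest displacement that keeps sphere and
enlarged VOI inside the body); a 6.9-l homogeneous cylinder with a central
VOI (H6); and planar petri-dish imaging with a 10-cm ROI, background
subtraction and the mean over five sources (H7). H7 additionally fits a
recovery curve RC(V) = 1 − exp(−(V/v₀)^p) — a monotone, bounded,
two-parameter form chosen here, since only "a curve was fitted" is stated —
to Otsu-segmented sphere acquisitions of known activity, and divides its
inner-sphere estimate by RC(V). The H1-style "volume above which
partial-volume correction is unnecessary" is the smallest volume with
RC ≥ 0.95, available in closed form (`pvc_threshold_volume`).

Activity is `cps / factor` (`activity_estimate`), and relative
uncertainties combine Poisson counting terms, calibration-factor spread and
extra terms in quadrature, encoded per protocol exactly as each site
described (H6 reports none; segmentation uncertainty is faithfully absent
everywhere but available as an extra term). H5's unstated rule for
combining its two VOIs per image is implemented as the mean of the six
factors. No decay correction is applied: all activities are referenced to
one time point (¹⁷⁷Lu decay over a session is <1 %).

## Desk scale, tolerances, and what a green test establishes

The clinical acquisitions were 120 × 30 s projections on 128² matrices;
the default simulations run 60 projections on 64³ grids at 4.8 mm (the
clinical pixel size), and the unit-test fixtures are smaller still (32³ at
9.6 mm, 24 projections). Subsets are adapted to the largest divisor of the
projection count not exceeding the site's setting. Count levels are then
high enough that Poisson terms are small; the spread between protocols is
dominated — as in the physical exercise — by segmentation, calibration
geometry and partial-volume effects.

Three numerical behaviours are worth knowing. First, the thin (11 mm ≈ 2.3
voxel) shell makes the inner:outer concentration-ratio recovery converge
slowly: the shell contrast sits near the PSF's null space, so the ratio
approaches the true 15 from below and needs thousands of EM updates to get
within 10 %; the acceptance run therefore uses 200 iterations × 60 subsets
(≈12 000 effective updates, a few minutes of compute). Second, the
partial-volume arms behave oppositely — without PSF modelling the recovery
coefficient of a 26-ml sphere settles near 0.75 regardless of iterations (a
genuine model-mismatch loss), while with PSF modelling it converges upward
towards 1 (≈0.94 at the acceptance settings). Third, the Gaussian
kernels are truncated at 3.5σ and renormalised, so blur conserves counts to
≪0.5 % provided content stays away from the grid edge, which the phantom
geometry guarantees.

A green suite therefore establishes that the *pipeline arithmetic and
physics model* behave as specified under a matched system model with
synthetic scatter — not that any physical camera is reproduced. The
per-site numbers of the physical exercise (produced on real cameras with
vendor software) are out of scope by design; what is reproduced is their
*structure*: the report conventions (signed percent differences, spread =
max − min, within-threshold tables), the segmentation-family ordering, the
volume-to-activity monotonicity, and the cited partial-volume bounds.

## Known limitations

Parallel-beam geometry with a Gaussian response; fraction/kernel scatter
(no energy spectrum, no septal penetration); matched reconstruction by
default (a deliberate inverse crime — a mismatch knob would be the natural
next step); binary voxel-centre voxelization (no partial-volume weighting
at the phantom-building stage, so voxelized volumes carry O(spacing²)
error); "manual" segmentation reduced to seeded morphological perturbation
of truth; volumes persisted in a simple text format rather than NIfTI, as
no NIfTI-capable package is available in the target environment.
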