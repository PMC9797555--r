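---
title: "Depth-resolved wide-field reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved wide-field reconstruction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(astivol)
```

This vignette is the package's own account of the science it implements:
the optical model, the two reconstruction modes, every tunable parameter
that matters, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## The astigmatic imaging model

A weak cylindrical lens in the detection path splits the focus so the two
lateral axes of the PSF reach best focus at different depths. We model
each axis with the Gaussian-beam hyperbola

$$ w_\mathrm{x}(z) = w_{0x}\sqrt{1 + \left(\frac{z - z_{fx}}{z_{Rx}}\right)^2}, $$

and analogously for $w_y$. The image of a point emitter is the elliptical
Gaussian $f(x,y) = a\,\exp(-2(x-x_0)^2/w_x^2 - 2(y-y_0)^2/w_y^2) + c$,
and depth is read out from the ellipticity
$e = (w_x - w_y)/(w_x + w_y)$, which is strictly monotone in $z$ between
the two focal planes for every valid parameter set (a property the test
suite checks over a parameter sweep).

The defocus law itself is a modelling choice: any smooth, monotone pair of
width curves supports the method, and the hyperbolic form is the standard
one for astigmatic localization. $z_R$ is exposed as a free calibration
parameter rather than derived from optics.

**Default optics** (`default_psf_params()`): in-focus width
$w_0 = 12.6/\sqrt{2\ln 2} \approx 10.70\,\mu m$ so that the in-focus FWHM
is the system's 12.6 µm lateral resolution; focal planes at
$z_f = \mp 300\,\mu m$ giving the ~600 µm usable depth range; and
$z_R = 300\,\mu m$, which keeps the ellipticity range at ±0.38 across the
600 µm — comparable to published astigmatic calibration curves and
comfortably within the monotone regime. The depth convention puts $z = 0$
midway between the focal planes (round PSF for symmetric optics), with $z$
increasing away from the objective. All lengths are micrometres; speeds
are mm/s; times are seconds.

## Depth calibration

`build_calibration()` localizes the spots of a fluorescent-slide z-stack
(50 µm steps, 13 planes spanning ±300 µm in all shipped examples),
averages the PSF-shape metric per plane within each subregion of the FOV
(mean aggregation; the alternative of fitting through all spot-level
points was rejected as needlessly sensitive to stragglers), and fits a
monotone piecewise-cubic interpolant (Hyman-filtered spline) over the
largest strictly monotone run of each subregion's curve. Monotone
interpolation guarantees invertibility without assuming a parametric law.
The run's depth extent is the subregion's valid range; lookups outside it
clamp to the nearest endpoint and carry an `out_of_range` flag that
downstream stages treat as "no depth claim".

Subregions partition the FOV by integer division (5 × 5 by default,
matching the discrete per-region calibration files of the instrument);
there is no blending across boundaries. Subregions without usable spots
are flagged and fall back to the nearest populated subregion with a
warning.

Field-dependent aberration is emulated as a smooth deterministic
perturbation of $(z_{fx}, z_{fy}, w_0)$ across the FOV
(`aberration = list(zf_amp_um =, w0_rel =)`); with an 80 µm focal-plane
perturbation the 5 × 5 calibration strictly reduces the mean absolute
depth error relative to a single global curve, which is the quantitative
content of the sub-region design.

### PSF-shape metrics under scattering blur

`compare_depth_metrics()` rebuilds the unblurred global curve per metric
(ellipticity, axis difference $w_x - w_y$, single axis $w_x$), re-measures
the blurred stack, and reports the largest depth error from re-using the
unblurred curve. Out-of-range lookups are counted at their clamped error —
otherwise the worst metric would have its largest errors silently
excluded.

Under the isotropic Gaussian convolution model used here (blur SD $s$
adds in quadrature: $w' = \sqrt{w^2 + 4s^2}$), one can show
$e' = e\,(w_x + w_y)^2/(w_x' + w_y')^2$ while the axis difference only
compresses by the first power of that ratio. The ellipticity is therefore
robust against the *single-axis* readout (the comparison the instrument's
designers report) at every blur level — the suite asserts this — while the
axis difference, rarely used because its units are not scale-free, can
compress less under this particular blur model. Real tissue scattering is
better described as a common multiplicative broadening, under which the
ellipticity is exactly invariant; the convolution model is the
conservative choice for simulation.

## Localization

Candidate detection thresholds each background-subtracted frame at
`median + k · MAD` (robust SD; default `k = 4` — the adaptive-threshold
constant is a declared choice, as the instrument software does not define
its rule). When the MAD is degenerate relative to the frame's dynamic
range — which happens on noiseless synthetic frames whose background
spread vanishes — the background statistics are re-estimated from the
sub-threshold pixels of a plain-SD first pass. Components are 8-connected;
those touching the border are flagged `edge`.

Fitting uses Levenberg–Marquardt least squares with the analytic Jacobian
of the six-parameter model, initialised from image moments (amplitude
= max − median, offset = median, centre = intensity-weighted centroid,
widths = twice the second central moments), iteration cap 100. The fit
window is a square of half-width ~3× the largest expected PSF width
(10 px at the 5.56 µm pixel). Candidates closer than the window width are
both flagged and excluded from depth mapping — overlapping PSFs carry no
reliable shape. Noiseless round trips recover all six parameters to
better than 1e−6 relative error.

## Sparse-localization (SL) reconstruction

Frame-to-frame linking solves an optimal bipartite assignment (Hungarian
algorithm with potentials, implemented in the package and tested against
brute-force enumeration) between active track heads and the next frame's
detections, with lateral Euclidean cost gated at `max_disp_um` per link;
unmatched heads survive `max_gap` missing frames (default 1). The default
gate `10 mm/s ÷ frame rate` corresponds to the fastest flows of interest
and must be set explicitly for real data.

Velocity per link is `|displacement| × frame rate / gap`. Both 3D and
lateral-only displacements are supported. The 3D default follows the
principle that depth is available, but note the bias it carries: with a
per-detection axial scatter $\sigma_z$ of tens of micrometres at the
simulated in vivo brightness, a 10 µm per-frame displacement acquires a
positive bias of order $\sigma_z\sqrt2 /\Delta$. The quantitative speed
tests therefore use lateral displacements, where the scatter is ~1 µm;
with brighter emitters or faster flows the 3D speeds converge to the same
values.

Maps are rendered by rasterizing every link as a 2D segment with linear
interpolation of depth and uniform speed along it; each touched pixel
accumulates count, depth and speed sums, and the maps are per-pixel means
with untouched pixels NA (empty, never zero). Tracks shorter than 3
detections are not rendered (spur suppression; configurable). Rendering
is order-independent and the suite checks it.

## Multifocal-illumination (MI) reconstruction

One volume consumes exactly one frame per scan position
(`effective_volume_rate(2250, 225) = 10` Hz). The three steps per frame:

1. **Spot localization against the reference.** The scan recorded on a
   uniformly fluorescent slide gives each spot's expected position; in the
   acquisition frame the local maximum within `search_radius_px`
   (default 4) is accepted if above the adaptive threshold. Spots dark in
   the scene are recorded absent — this is signal, not an error.
2. **Depth from shape.** The same elliptical-Gaussian fit as in SL,
   ellipticity mapped through the LUT subregion containing the spot.
3. **Digital pinhole and superposition.** Pixels outside a disc of
   `pinhole_radius_px` (default 4 px ≈ 1.5× the in-focus half-width; the
   radius is not specified by the instrument and is exposed as a flag)
   about the localized centre are zeroed, and the filtered subimages are
   summed into the compounded intensity. Depth compositing where pinholed
   spots overlap uses the amplitude-weighted per-pixel mean — the exact
   rule is unstated upstream, and weighting by retained intensity matches
   the superposition language.

Compounding is permutation-invariant over scan positions, and volume
segmentation reports (never drops) trailing frames that do not fill a
cycle.

**Time-to-peak.** Per pixel, TTP is the time of the maximum of the
moving-average-smoothed intensity curve (window 3 volumes), ties broken to
the earliest frame; pixels whose prominence (smoothed max − min) is below
`prominence_min` are masked. The series origin is the first volume —
the injection event is an acquisition-level timestamp outside the data.
ROI statistics (5 × 5 px regions by convention) are means and SDs over
valid pixels, with fully masked ROIs reported as undefined rather than
zero.

## Vessel quantification

ROIs undergo a fixed pipeline: 2× bilinear upsampling, self-guided
edge-preserving filtering (radius 4 px, regularisation 1e−3), multiscale
Frangi vesselness (scales {1, 2, 4, 8} px on the upsampled grid,
β = 0.5, structureness constant = half the per-scale maximum Hessian
norm), min–max normalisation, then global Otsu binarization. None of the
filter constants are published for the upstream tool; these defaults are
declared, not inferred.

Skeletonization is Zhang–Suen thinning followed by a sequential
simple-point cleanup (Yokoi 8-connectivity number 1): Zhang–Suen alone
leaves 2-px diagonal staircases on masks with rough boundaries, which
would inflate the branch-point count. A branch point is a skeleton pixel
with more than two nonzero 8-neighbours; removing branch points partitions
the skeleton into branches, and branches shorter than 3 px are pruned
before counting (thinning-artifact suppression; configurable). On rendered
vessel-tree phantoms the recovered branch count equals the generator's
ground truth exactly for trees of up to 3 bifurcations.

Paired statistics use the exact small-sample formulae:
$t = \bar d/(s_d/\sqrt n)$, two-sided $p$ from Student's $t$ with $n-1$
degrees of freedom, paired Cohen's $d = \bar d/s_d \equiv t/\sqrt n$.
Zero-variance differences leave $t$ and $d$ undefined (reported as such,
never as zero).

## The synthetic-data generator

The simulator emulates: astigmatic PSFs with depth-dependent axis widths
and energy-conserving amplitudes ($a = 2I/(\pi w_x w_y)$, so defocused
emitters are dimmer, as in reality); tilted-slide, crossing-channel and
branching-tree phantoms with chord-weighted emission across vessel
lumina; constant-brightness beads advected at constant per-bead speeds
whose arrivals form a stationary Poisson process; gamma-variate perfusion
boluses $((t-d)/t_p)^2 e^{2(1-(t-d)/t_p)}$ per branch (standard perfusion
kinetics; the curve family is a modelling choice); scanned illumination
lattices with per-position reference stacks; and a camera model of
optional isotropic scattering pre-blur, Poisson shot noise on signal +
background, and Gaussian read noise. All generators are pure functions of
(parameters, seed) and export ground truth sufficient to score every
pipeline.

The reference conditions (`reference_noise()`) are a 20-count background,
shot noise, 3 counts RMS read noise, with 2 × 10⁴ integrated counts per
in vivo emitter/illumination spot; this yields a per-detection axial
scatter of roughly 40 µm at mid-range depths, so medians over many
detections (the quantities the pipelines report) are accurate to a few
micrometres while single detections are not. The calibration slide is a
different regime: a bright uniform target (default 10⁵ counts per spot)
recorded with several laterally jittered exposures per plane
(`n_exposures`), so that each FOV subregion accumulates enough spots for
its curve to be strictly monotone over the full depth range — without
this the spatially variant calibration rests on single noisy fits, which
is not how the physical procedure works. The 5.5 µm depth-repeatability
figure of the physical instrument corresponds to those bright calibration
spots; the monitored per-pixel depth SD of the simulated phantoms under
in vivo brightness is reported by the test suite but does not gate it.

**Not emulated:** skull-bone optics, hemoglobin absorption, motion
artifacts, fixed-pattern camera noise, bead size dispersity, and
dye-binding kinetics. Passing tests therefore demonstrate the
reconstruction's correctness against its own forward model, not
performance on tissue.

The effective pixel size is internally ambiguous upstream (5.6 mm/1008 px
= 5.56 µm vs an 11 µm camera pixel at 1.5× = 7.33 µm); 5.56 µm is the
default and the value is configurable everywhere.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes on one CPU: 162–240 px sub-FOVs
(0.9–1.3 mm), 2 × 2 or 3 × 3 illumination lattices scanned over up to
45 × 45 positions (2025 frames), 120-frame SL recordings, 13-plane
calibration stacks with 36–100 spots per exposure and up to 4 exposures
per plane. The phantom
reconstruction measures the median inter-channel depth difference over
~2 000 depth-map pixels. All geometry, optics and noise parameters match
the full-scale conditions; only the lateral extent and lattice density
are reduced.

## Known limitations

- Depth assignment is single-valued per spot: two emitters sharing
  lateral coordinates at different depths produce one (amplitude-weighted)
  depth, mitigated but not solved by spatial/temporal sparsity.
- The linker has no motion model; dense, fast, crossing flows will swap
  identities at the gate boundary.
- Frangi + Otsu segmentation assumes bright curvilinear structure on a
  darker background; diffuse perfusion signal lowers the threshold and
  can merge adjacent vessels.
- The 32-bit map TIFFs use an affine range encoding with a JSON sidecar
  (the R `tiff` writer cannot emit IEEE-float samples); readers outside
  this package need the sidecar to recover physical units.
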