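---
title: "Quantitative K-edge imaging with kedge: models, parameters, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative K-edge imaging with kedge: models, parameters, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kedge)
```

## The measurement model

Hyperspectral X-ray CT reconstructs a linear attenuation coefficient
µ(z, y, x, E) on a grid of energy channels. `kedge` models each voxel's
spectrum as

µ(E) = µ_medium(E) + Σ_elements c · A · E⁻³ · j(E),   j(E) = r for E ≥ E_K, else 1,

where `c` is the element's local concentration in mg/ml, `A` (cm²/g·keV³)
sets the magnitude of its mass attenuation, `r > 1` is the K-edge jump
ratio, and the factor 10⁻⁴ (folded into `elemental_mu()`) converts
(cm²/g)·(mg/ml) to mm⁻¹. Two properties of this model carry the whole
method:

1. **Linearity in concentration.** The solute term is exactly
   proportional to `c`, and attenuation of mixtures is additive
   (Beer–Lambert). Hence the edge step Δµ₀ is an affine function of `c`
   and a two-point phantom calibration suffices in principle.
2. **A discontinuity at a known energy.** The jump at E_K identifies the
   element; everything else in the spectrum is smooth.

The packaged element table (`element_table()`) anchors `A` and `r` so the
pre-edge mass attenuation at E_K matches tabulated magnitudes (I 6.55,
Ba 4.98, W 1.96, Ca 28.9 cm²/g; jump ratios 5.47, 5.49, 4.94, 8.90). The
two-branch E⁻³ law is a deliberate simplification of the full tabulated
curves: it keeps the ground-truth edge step in closed form,
Δµ₀(c) = c·A·E_K⁻³·(r−1)·10⁻⁴, which every stage of the chain can be
tested against. Users with other contrast elements can supply a CSV with
the same schema.

The default background medium is an agarose/water-like power law with
µ = 0.027 mm⁻¹ at 35 keV. Phantom builds for projection work place the
tube in air (`medium_model(0, type = "flat")` as the global background)
so that projections are not truncated at the detector edges — a square
grid filled with medium would project wider than the detector at diagonal
angles and produce cupping.

## Windows: the two parameters that matter

Both K-edge subtraction and edge-height estimation use the same window
convention. With k the first channel whose centre energy reaches E_K,
width w and separation s (all in channels):

* pre-edge window: channels k−s−w … k−s−1 (inclusive)
* post-edge window: channels k+s … k+s+w−1 (inclusive)

`width` (default 5) controls noise averaging versus locality; at 0.25 keV
channels the default window spans ≈1.25 keV per side. `separation`
(default 2) excludes the guard channels over which a measured edge
actually rises — detector energy blur (~1.27 keV FWHM for the emulated
system) spreads the theoretical discontinuity over a few channels.
Tungsten edges measure broader still, so `default_kes_params("W")` raises
the separation to 10 channels. KES windows are averaged, not summed, so
Δµ stays in attenuation units and is directly comparable to Δµ₀.

**KES versus edge height.** KES (window-mean difference) picks up the
local spectral slope: a steeply falling co-stain inflates or deflates Δµ
at a foreign edge. The edge-height estimator fits a line per side and
extrapolates both to E_K, cancelling the slope exactly; for ideal steps
with flat flanks the two agree identically. For segmentation masks and
all quantification the package therefore prefers `edge_height_map()`.

**Curvature bias.** On a curved (power-law) spectrum, a straight-line fit
extrapolated to E_K carries a second-order bias: Δµ₀ measured on the
simulator's own spectra is ~0.5% below the analytic step at the default
windows. The bias is exactly proportional to `c`, so it drops out of the
phantom calibration — which is the reason calibration against phantoms of
the same contrast agent, rather than conversion through tabulated
attenuation values, is the right procedure on real data too. Tests assert
exact (1e-9) agreement on piecewise-linear spectra and 1% agreement on
power-law spectra.

## Edge detection

`detect_edges()` smooths the spectrum (moving average, width 3 channels),
takes forward differences, and for each candidate element selects the
largest positive difference within ±1 keV (configurable) of its K-edge.
Because smoothing spreads a sharp step over three equal differences and
the falling background tie-breaks toward the wrong side, the candidate is
refined to the largest *raw* difference within the smoothing half-width;
the detected energy is the channel-centre energy of the first post-step
channel, consistent with the edge-channel convention. A step is reported
only if it exceeds 5× the MAD (median-centred) of the differences outside
all edge search windows; median centring matters because the background
slope would otherwise masquerade as noise. On 0.25 keV channels this
localises the I, Ba and W edges to within one channel of 33.17, 37.44 and
69.53 keV.

## Detector calibration

Photopeaks are fitted as Gaussian + constant by Levenberg–Marquardt
(`minpack.lm`), with moment-based starts; FWHM = 2√(2 ln 2)·σ. The
channel→energy relation is an OLS line through (centroid, known energy)
pairs; with ≥4 peaks, residuals beyond 3× their MAD flag a peak (e.g. a
misidentified foil line) and the line is refitted once without it.
Energy resolution is summarised as the per-pixel fitted FWHM at the
59.5 keV photopeak, in keV via the axis gain; failed pixels (dead or
flat) are excluded and counted rather than imputed.

Inter-pixel gain correction fits each pixel's own response from ≥2
reference peaks and rebins its counts onto the global axis
*conservatively* — by linear interpolation of the cumulative spectrum —
so total counts are preserved by construction. Pixels whose fitted
response already matches the global axis to within the centroid-fit
precision (0.05 channels across the axis) are left untouched; this guard
is what makes the correction idempotent, since refitting rebinned peaks
reproduces the global axis only to ~0.01–0.05 channels.

## Ring suppression and centre of rotation

Ring artifacts originate as detector-column stripes in the sinogram. The
filter decomposes each projection row with a periodised orthogonal DWT
(db5 default, 3 levels) along the detector axis; within each level's
detail band, components that are nearly constant along the angle axis are
damped by 1 − exp(−f²/2σ²) (σ = 2 frequency indices by default) in the
FFT domain along angle, and the sinogram is reassembled. The
perfect-reconstruction property of the wavelet bank is unit-tested, so
the filter is exactly transparent when nothing is damped.

An intrinsic limitation: the filter cannot distinguish a stripe from
genuine structure that is constant along the angle axis. A rotationally
symmetric object centred on the rotation axis *is* such structure — its
sinogram does not vary with angle — and sharp-edged objects put genuine
energy into the detail bands' angle-DC, which the damping removes. On
smooth, non-symmetric objects (the filter's intended regime) the filter
passes clean sinograms through with <1% RMS change, suppresses the
ring metric of a single bad column by >90%, and moves phase means by
<0.5%; the package's tests use 128-column smooth fixtures for exactly
this reason, and binary-edged fixtures document the worst case.

The centre-of-rotation estimator cross-correlates the 0° projection with
the mirrored 180° projection over integer lags and refines the peak with
a parabola; the axis offset is half the best lag. It requires an opposed
pair within half an angular step (else it errors, suggesting
interpolation) and is accurate to <0.25 px for offsets in ±5 px.
Correction resamples all projections by linear interpolation.

## Reconstruction

The package reconstructs with per-channel parallel-beam filtered
back-projection. The ramp filter is built from the spatial-domain Ram-Lak
kernel (¼ at zero, −1/(πn)² at odd lags) rather than by sampling |f|,
which would bias the DC term — with the kernel form, a uniform disk's
interior mean is recovered to 0.04%. A Shepp–Logan window is available.
FBP deliberately stands in for iterative TV-regularised reconstruction,
which is out of scope; the volume container accepts externally
reconstructed data so the spectral analysis applies unchanged. Forward
projection shares one bilinear sampling stencil per angle across all
energy channels.

## Quantification conventions

* Phase measurements average Δµ₀ per slice within the phase ROI, then
  across six slices (or all available); the error bar is the sample
  (n−1) SD, appropriate at n = 6.
* The calibration line keeps its intercept by default (`force_origin =
  FALSE`): real reconstructions carry small energy-independent offsets
  (scatter, medium curvature) that an intercept absorbs; the
  zero-intercept variant is one flag away.
* Concentration maps clamp negatives to zero but keep the pre-clamp
  values in a diagnostics array, so noise/ring speckle remains
  inspectable; invalid fits are masked, never silently zeroed.
* "Standardised intensity" for conventional single-energy scans is a
  two-point affine rescale anchoring the air ROI mean to 0 and the
  agarose ROI mean to 1 (scale configurable). This anchoring convention
  is the package's own reconstruction of common practice with
  agarose-embedded specimens and is flagged as such.
* Histograms count unmasked voxels only and always sum to the unmasked
  voxel count; overlap reports label each voxel with the set of elements
  above threshold, so multi-stained voxels are first-class.

## The synthetic generator: what it does and does not emulate

The simulator reproduces the features the analysis chain is sensitive
to: K-edge jumps proportional to concentration, smooth power-law
backgrounds, Beer–Lambert projection, Poisson counting statistics,
Gaussian detector energy blur, per-column gain errors (rings) and
centre-of-rotation misalignment, and the built-in three-phantom layouts
(I₂KI 25.3/50.6/76.0/101.2 mg/ml; BaSO₄ 100/200/400 mg/ml; PTA
50/100/200 mg/ml) as cylinders in an agarose-filled tube.

It does **not** emulate cone-beam geometry, a polychromatic source
spectrum (beam hardening), detector charge sharing or pile-up, scatter,
or sub-voxel vessel structure. Passing tests therefore demonstrate the
correctness of the algorithms under the stated physics, not performance
on real detector data; in particular, partial-volume effects make edge
heights underestimate concentrations in structures smaller than a voxel,
and the simulator only reproduces that regime through its optional
supersampled rasterisation.

Rasterisation is centre-in-circle by default (exact, reproducible label
maps); `supersample` enables fractional boundary coverage when
partial-volume behaviour is wanted.

## Numerical conventions and degenerate inputs

* Axis order is (z, y, x, energy); all user-facing indices are 1-based
  inclusive, idiomatic for R. Energies are channel centres in keV;
  attenuation is mm⁻¹ (chosen to suit ~100–200 µm voxels; nothing
  downstream depends on the unit since calibration is affine).
* The edge channel is the *first* channel with centre energy ≥ E_K; ties
  are impossible for positive gain.
* Empty ROIs, out-of-range windows, counts-mode sinograms fed to the
  reconstructor, mismatched elements between map and curve, and
  sub-180° sinograms for COR estimation all raise errors naming the
  offending object rather than proceeding.
* Seeded stages (Poisson sampling) restore the caller's RNG state; the
  same seed is bit-reproducible and different seeds differ.

## Problem sizes

The test suite and acceptance script run at desk scale by choice:
phantoms of 64×64×(1–12) voxels with 40–200 energy channels, 90–180
projection angles, and 128-column sinograms for the ring studies. These
sizes keep the full suite in tens of seconds while leaving every
algorithmic property measurable; all operators are vectorised (the
edge-height map, for instance, is two matrix products over fixed window
weights), so larger volumes scale linearly in voxels × channels.

## Known limitations

* Overlapping absorption edges are not unmixed; elements closer than the
  window span interfere (W separation 10 already borders this).
* The ring filter attenuates genuine angle-constant detail (see above);
  severe, wide stripes need more levels or polar-domain methods.
* FBP needs ~πN/2 angles for alias-free reconstruction; with a typical
  180-projection acquisition at N = 64–128 detector columns, mild streaks
  remain and are absorbed by phase averaging.
* The E⁻³/jump-ratio attenuation model is for testing and simulation;
  real quantitative work must calibrate against phantoms of the actual
  contrast agent — which is precisely the workflow the package
  implements.
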