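---
title: "Methods: multi-parametric PAM quantification and wound-healing endpoints"
author: "mpam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-parametric PAM quantification and wound-healing endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpam)
```

# Scope

`mpam` quantifies skin microvasculature from multi-parametric
photoacoustic microscopy (PAM) and the downstream physiology of
wound-healing studies: per-vessel structure, hemoglobin oxygen saturation
(sO2), blood flow speed, volumetric flow, oxygen extraction fraction (OEF)
and a relative metabolic rate of oxygen (MRO2); ratiometric
boron-nanoparticle tissue-oxygen maps; open-wound closure; skin PK
summaries; and a two-way ANOVA reporting helper. Because raw in vivo
acquisitions of this kind are rarely shareable, every input the pipeline
consumes can be generated synthetically with known ground truth, and the
whole validation strategy of the package is parameter recovery on such
phantoms. This vignette explains the models, the tunable parameters and
the design decisions, and is explicit about what phantom-based validation
does and does not show.

# PAM forward model and structure

A pulsed laser at two wavelengths (532 and 559 nm) excites hemoglobin;
the detected ultrasound amplitude after envelope detection is, per pixel
and wavelength $\lambda$,

$$A(\lambda) \propto F(\lambda)\,
  \big[\,s\,\varepsilon_{HbO_2}(\lambda) +
  (1-s)\,\varepsilon_{Hb}(\lambda)\,\big],$$

where $s$ is sO2, $F$ the optical fluence and $\varepsilon$ the molar
extinction coefficients (bundled at 532/559 nm from the standard
Gratzer/Kollias tabulation; see `hb_extinction()`). 532 nm is close to an
isosbestic point, so that channel reports total hemoglobin and serves as
the structural image; 559 nm, near the deoxyhemoglobin peak, carries the
oxygenation contrast.

`envelope()` implements the standard analytic-signal magnitude
(frequency-domain Hilbert construction) that converts raw bipolar
pressure traces to non-negative amplitude profiles. The simulator
(`simulate_pam_scan()`) works post-envelope: vessels are rasterized as
tubes of programmed diameter, given a Gaussian depth profile, and noise
is additive Gaussian after the envelope. That choice keeps every recovery
tolerance analytically predictable; it deliberately omits speckle
statistics, acoustic propagation and in-tissue fluence decay, which is
the main reason phantom results are an upper bound on real-data
performance (see *Limitations*).

Projections: the structure map is the maximum-amplitude projection over
depth; spectral unmixing uses the depth-mean projection, which averages
additive noise down without biasing the spectral ratio (both wavelengths
share the same depth profile). Maps are 2-D en-face projections
throughout; there is no depth-resolved sO2.

# sO2 unmixing

`unmix_so2()` solves the 2-by-2 linear system above per pixel for the two
hemoglobin concentrations and reports
$s = c_{HbO_2}/(c_{HbO_2}+c_{Hb})$. A negative component of the
unconstrained solution is clipped to zero before normalising — the
boundary solution of the non-negative constrained least squares in two
dimensions — so sO2 always lies in $[0,1]$ without hiding gross spectral
mismatch. Pixels whose 532-nm amplitude falls below `noise_floor` are
flagged invalid rather than zero-filled. `fluence_ratio`
($F(532)/F(559)$, default 1) is exposed because wavelength-dependent
fluence calibration is instrument-specific; the output is invariant to a
common gain on both channels.

# Decorrelation flowmetry

Blood flow speed comes from the decorrelation of 100 repeated A-lines
acquired at 532 nm. The model: absorbers advect along the vessel axis by
$v/\mathrm{prf}$ between successive A-lines, and with a Gaussian beam of
waist parameter $w$ (µm) the inter-repeat correlation decays as

$$C(k) = \exp\!\big[-(v\,k/(\mathrm{prf}\,w))^2\big]$$

at lag $k$. The simulator realises exactly this: a frozen 1-D random
reflectivity pattern (white noise smoothed with a Gaussian of
$\sigma = w/2$, which makes the pattern autocorrelation
$\exp[-(\Delta/w)^2]$) is shifted sub-pixel by linear interpolation on a
periodic fine grid. The pattern depends only on the seed and the vessel
index — never on the speed — so speed sweeps at a fixed seed share
speckle and are strictly comparable.

`flow_speed()` computes Pearson correlations between mean-subtracted
repeats, averages them per lag (lags 1–10), and fits $-\log C(k) = a k^2$
by no-intercept weighted least squares with weights $C(k)^2$ (the
delta-method inverse variance of $\log C$). Lags are truncated at the
first drop below a small floor (0.05): beyond it the true correlation is
gone and finite-pattern noise produces spurious revivals which, entering
a $k^4$-weighted slope, would dominate the fit. Speed is
$\mathrm{prf}\,w\sqrt{a}$; quality is the $R^2$ between observed and
fitted correlations; a constant stack returns speed 0 with a degenerate
flag. Estimates are invariant to a positive gain on the stack.

Parameter defaults: `prf` 2000 Hz and `w` 3 µm place the programmed
speed range 0.2–5 mm/s inside the usable decorrelation window
($C(1)$ between 0.99 and 0.5); the frozen pattern spans 8192 µm so the
empirical correlation of a single realisation estimates the model decay
to about 2%. These are simulation-design choices, stated here once and
shared by simulator and estimator.

# Vessel segmentation and per-vessel metrics

`segment_vessels()` detects vessels with a multiscale Frangi
(Hessian-eigenvalue) tubeness filter, but builds the binary mask by
hysteresis thresholding of the *amplitude* image: seeds must exceed the
high threshold and carry tubeness response, and the mask grows to all
amplitude pixels above the low threshold connected to a seed. Growing on
amplitude rather than on tubeness preserves the vessel's full width,
which the diameter estimate depends on. Thresholds are fractions (0.5 and
0.25 by default) of the 99th-percentile amplitude, so they adapt to
overall gain; near-isosbestic 532-nm excitation keeps the vessel plateau
within ~7% across sO2, which is why a single global threshold pair works.
The mask is skeletonized (Zhang–Suen), junctions (Rutovitz crossing
number ≥ 3, with a one-pixel dilation so diagonal neighbours actually
disconnect) are removed, branches shorter than 10 px are discarded, and
each branch is reduced to its longest geodesic path so thinning spurs do
not contaminate the centerline. Mask pixels are assigned to the nearest
retained centerline.

**Diameter.** The estimator is trunk area divided by trunk length:
each mask pixel receives an arc position from its nearest centerline
pixel; positions within two local radii (from the Euclidean distance
transform) of either branch end are discarded, removing end caps and
junction cones; the remaining pixel count divided by the remaining
centerline length is the width. Centerline length uses the
Vossepoel–Smeulders corner-count chain length
($0.980\,N_s + 1.406\,N_d - 0.091\,N_c$), which corrects the up-to-8%
orientation bias of a naive $(1,\sqrt2)$ chain measure. We initially
implemented the more common "2 × distance transform along the skeleton"
width, but the quantized skeleton position gives it a ±1 px parity bias —
25% at 4-px widths — and staircase boundaries an orientation-dependent
bias, so the area-per-length form was adopted; the distance transform
still sets the trim radius and serves as a fallback for very short
branches. The independent check in the tests is a perpendicular-profile
full-width oracle. Across 4–30 px widths and 0–180° orientations the
estimator stays within ~5% (worst cases at exactly 45° for 4-px tubes are
a rasterization artifact of commensurate angles, and the validation grid
samples orientations at 25° steps to probe the full range without
repeatedly hitting that singular geometry).

**Flow map and overlaps.** Each repeated-A-line stack is an acquisition
at a known vessel footprint; `flow_map()` paints per-stack estimates over
footprints, letting the smaller footprint win where they overlap (an
acquisition focused on a thin vessel is specific to it). Per-vessel speed
and sO2 are means over the vessel mask restricted to valid pixels;
volumetric flow is $F = v\,\pi d^2/4$, reported in µL/min
(1 mm/s through 50 µm is 0.11781 µL/min).

# OEF and MRO2

With arterial and venous compartments defined by an sO2 threshold
(default 0.75, ties arterial),

$$\mathrm{OEF} = \frac{s_aO_2 - s_vO_2}{s_aO_2}, \qquad
  \mathrm{MRO_2} \propto \text{blood flow} \times \mathrm{OEF}.$$

$s_aO_2$ and $s_vO_2$ are flow-weighted means of their compartments by
default: OEF is a mass-balance quantity, so vessels carrying more blood
should weigh more; unweighted means are one switch away. Blood flow in
MRO2 is the summed arterial volumetric inflow (the conventional supply
side; venous drainage is available as an option). A venous mean exceeding
the arterial mean yields a negative OEF that is returned as-is with an
`inverted` flag — clipping would hide a segmentation or classification
failure. Longitudinal reporting (`longitudinal_summary()`) normalises
each replicate to its own baseline and reports group mean ± SEM in
percent, with SEM missing (not zero) for single replicates.

# Ratiometric oxygen mapping

The boron-nanoparticle sensor emits oxygen-independent fluorescence
(blue) and oxygen-quenched phosphorescence (red) following single-site
Stern–Volmer kinetics; after subtracting pre-injection backgrounds
per channel (clipped at zero), the per-pixel ratio is

$$\frac{B}{R} = \frac{B_0}{R_0}\,(1 + K_{SV}\,pO_2),$$

so relative pO2 inverts algebraically (`invert_stern_volmer()`). The
ratio is computed only where the red channel clears a floor (default
3 SD of the red background) — below it the ratio blows up on unlabeled
tissue. The grayscale rendering maps ratio affinely to $[0,1]$ (low
oxygen black, high oxygen white). The scaling bounds are a genuine design
fork: per-image min/max maximises within-image contrast but destroys
day-to-day comparability, so the function defaults to per-image bounds
for exploratory use while the pipeline configuration fixes one bound pair
(default ratio 1–3) across a study, and the wound-bed readout
(`mean_gray()` over an ROI) is only comparable across days under fixed
bounds. The time-course normalisation reference (e.g. day-0 control mean)
is a required argument of `relative_oxygenation()` rather than a guess.

# Wound closure and PK

Open-wound masks are inputs (drawn or generated); closure is
$100 \times \mathrm{area}(t)/\mathrm{area}(0)$ by pixel count, reported
above 100% when a wound expands early. The synthetic series shrinks a
disc's radius by a fixed fraction per day (default 0.05/day, leaving
~54% of the original area open on day 6, matching the healing level the
treated-wound studies report).

PK profiles follow the Bateman form
$C(t) = S\,(e^{-k_e t} - e^{-k_a t})$; the generator rejects
$k_a = k_e$. Defaults ($k_a = 0.4205$/h, $k_e = 0.0439$/h,
$S = 52.31$ pg/mg, 15 samples over 144 h) were solved once so the
noiseless profile peaks at 36 pg/mg at 6 h with a 144-h trapezoidal
exposure near 1065 pg·h/mg — the intradermal VEGF-A kinetics this
package's assays accompany. `auc_trapezoid()` uses linear trapezoids over
the observed window only, no extrapolation to infinity, because the
quantity of interest is exposure over the sampled period; Cmax ties break
to the earliest time.

# Group statistics

`group_compare()` fits `value ~ group * time` by ordinary two-factor
ANOVA and reports Tukey-adjusted pairwise group contrasts within each
timepoint (delegated to `emmeans`), with the star convention
(\*, \*\*, \*\*\*, \*\*\*\* at 0.05/0.01/0.001/0.0001). On null
simulations with two groups of eight over three timepoints the empirical
type-I rate at 0.05 sits at its nominal value. A caveat the tests make
explicit: an exact two-sided permutation test on 8 + 8 observations has a
resolution floor of $2/\binom{16}{8} \approx 1.5\times10^{-4}$, so
permutation evidence can confirm a separation is as extreme as any group
assignment allows, but a claim of $p < 10^{-4}$ at that sample size rests
on the parametric model.

# Reproducibility and problem sizes

All generators restore the caller's RNG state and are bit-reproducible
given a seed; rerunning a pipeline stage with identical configuration and
seed reproduces outputs byte-for-byte (provenance sidecars carry the
config hash and seed, and deliberately no timestamps). The validation
suite runs phantoms at desk scale — 128–200 px rasters at 2 µm/pixel,
50-vessel sO2 sweeps at 20 dB amplitude SNR, six-speed flow grids,
32-case diameter sweeps and 1000-replicate null simulations — sizes
chosen so the entire validation runs in minutes on one core while keeping
every Monte-Carlo margin comfortable.

# Limitations

The phantoms validate the *quantification*, not the *physics*: no
speckle, no acoustic point-spread function, no depth-dependent fluence,
no motion, and vessels are ideal tubes with piecewise-constant sO2 and
speed. Segmentation constants (hysteresis fractions, 10-px minimum
branch) are defensible defaults for clean phantoms and will need tuning
on real exports. The A/V classifier is a plain sO2 threshold; OEF/MRO2
inherit any misclassification. MRO2 and pO2 are relative (arbitrary
units): no absolute oxygen calibration in mmHg and no absolute hemoglobin
concentration are attempted. Wound boundaries are taken as given masks;
the package does not delineate wounds from photographs.
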