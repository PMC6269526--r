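# mpam

Quantification stack for **multi-parametric photoacoustic microscopy
(PAM)** of the skin microvasculature and for longitudinal wound-healing
studies — the image-analysis side of experiments that track how a
pro-angiogenic treatment changes vessel structure, oxygenation, flow and
healing over weeks.

The package is aimed at imaging scientists who have (or simulate)
dual-wavelength PAM acquisitions and wound photographs and need the
derived physiology, per vessel and per day:

* **PAM core** — analytic-signal (Hilbert) envelope of raw A-lines;
  dual-wavelength (532/559 nm) spectral unmixing of hemoglobin oxygen
  saturation, solving per pixel
  `A(λ) = F(λ)[s·εHbO2(λ) + (1−s)·εHb(λ)]` for `s = sO2`;
  blood-flow speed from the decorrelation of 100 repeated A-lines,
  fitting `C(k) = exp[−(v·k/(prf·w))²]`.
* **Vessel quantification** — Frangi tubeness + hysteresis segmentation,
  skeleton-based centerlines, per-vessel diameter, mean sO2, speed and
  volumetric flow `F = v·π·d²/4`; arterial/venous classification; oxygen
  extraction fraction `OEF = (saO2 − svO2)/saO2` and relative oxygen
  metabolism `MRO2 ∝ blood flow × OEF`.
* **Ratiometric oxygen mapping** — background-subtracted blue/red
  (fluorescence/phosphorescence) ratio images of boron-nanoparticle
  sensors, Stern–Volmer inversion `B/R ∝ 1 + Ksv·pO2`, grayscale
  rendering (low oxygen black, high oxygen white) and wound-bed mean
  gray readouts.
* **Endpoints** — open-wound closure as % of day-0 area; noncompartmental
  PK (Cmax, Tmax, trapezoidal AUC over the sampled window); two-way
  ANOVA with Tukey-adjusted per-timepoint group contrasts and star-tier
  reporting.
* **Synthetic phantoms** — generators for every input above with known
  ground truth (vessel geometry/sO2/speed, advected speckle stacks,
  quenched channel pairs, shrinking wound discs, Bateman concentration
  profiles), so the full pipeline is testable end to end without
  instrument data.

## Worked example

Simulate an arterial/venous phantom study and quantify it end to end:

```r
library(mpam)
out <- tempfile()
run_pipeline("all", out_dir = out, seed = 3)

read.csv(file.path(out, "vessels.csv"))
#>   vessel_id diameter_um       so2 speed_mm_s flow_ul_min    class n_pixels
#> 1         1    24.65181 0.9480959  2.0174645 0.057775641 arterial      634
#> 2         2    30.29287 0.6501943  1.1856919 0.051273598   venous      802
#> 3         3    13.20388 0.8080053  0.5616974 0.004614734 arterial      160
#> ...

jsonlite::read_json(file.path(out, "oxygen_summary.json"))
#> sao2 0.928, svo2 0.650, oef 0.300, mro2 0.0392
```

The demo phantom programs an artery (24 µm, sO2 0.95, 2 mm/s), a vein
(30 µm, sO2 0.65, 1.2 mm/s) and a crossing capillary; the recovered
table shows the artery and vein split at the crossing (hence two rows
each), with diameters within ~3%, sO2 within 0.005 and speeds within a
few percent of the programmed truth. The oxygen summary then follows by
substitution: OEF = (0.928 − 0.650)/0.928 ≈ 0.30, and MRO2 is the summed
arterial inflow times OEF.

The PK module reproduces its targeted exposure profile exactly from the
closed form:

```r
pk_summary(simulate_pk_profile())
#>   cmax tmax_h      auc
#> 1   36      6 1081.164
```

i.e. a 36 pg/mg peak at 6 h and ~1081 pg·h/mg trapezoidal exposure over
the 144-h sampling window.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/mpam.R all --out demo_run --seed 1
```

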