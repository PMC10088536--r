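# ebusdepot

Quantitative analysis of intratumoral drug injections in B-mode
endobronchial ultrasound (EBUS) video.

When a drug such as cisplatin is injected into a peribronchial lung tumor
under EBUS guidance, the forming depot appears as a growing hyperechoic
region next to the needle tip. `ebusdepot` turns such recordings into
numbers: how fast the depot appears, how big it is, what fraction of the
injected volume is retained in the imaged tissue, and which physical
mechanism — porous (Darcy) flow through the interstitium or propagation of
tissue fractures — can plausibly account for how the fluid was
accommodated. It is aimed at interventional-pulmonology and
drug-delivery researchers working with ultrasound video of injection
procedures, and at anyone who needs a fully synthetic, ground-truthed
test bed for speckle-robust segmentation and uptake-kinetics pipelines.

## What it computes

* **Screening.** The percent intensity variation in a 1 cm × 1 cm region
  of interest centered on the needle tip,
  ΔI(t) = 100·(Ī(t) − Ī(0)) / Ī(0), smoothed with a 1-s moving average;
  a video is analyzed further only if the smoothed signal rises above
  20 %.
* **Uptake kinetics.** The background-subtracted mean cone intensity
  µ(t) is fit with the exponential-plateau law
  µ(t) = c + a·(1 − e^(−bt)).
  The injection duration is Δt = ln(20)/b — the time to reach 95 % of the
  plateau — and the mean volumetric flow rate is Q = V/Δt for injected
  volume V.
* **Depot segmentation.** Per-frame masks from background subtraction,
  edge-preserving anisotropic diffusion (Perona–Malik), two-cluster (Otsu)
  intensity thresholding over the imaging cone, and morphological closing
  with hole filling.
* **Shape and retention.** Centroid paths and min/max Feret diameters in
  a needle-centered coordinate frame, and the retained volume as the solid
  of revolution of the final segmented area about the needle axis
  (two-sided Pappus construction, V = 2π·Σ|ȳ|·A); retention % = 100·V/V_injected.
* **Mechanisms.** The hydraulic conductivity implied by radial Darcy flow,
  K = Q/(4πR·P_i), compared against literature values; the
  Hutchinson–Suo crack-tunneling stress threshold
  σ_th = √(πEΓ/2h) for macro-crack and micro-crack-percolation regimes;
  and linear pressure-from-flow scaling of published needle-tip pressure
  measurements.
* **Synthetic EBUS videos.** A simulator producing fan-shaped B-mode
  phantoms with multiplicative gamma speckle, heartbeat intensity
  modulation, a needle-line artifact and a depot that grows so the
  noiseless cone-mean trace follows the plateau law exactly — with
  per-frame ground-truth masks, the true Δt and the true retention
  fraction, so every stage of the pipeline is testable without clinical
  data.

## Worked example

```r
library(ebusdepot)

cfg <- simulation_config(duration = 12, t0 = 2, frame_rate = 10,
                         image_size = c(160, 160), px_per_cm = 32, b = 0.3)
sim <- simulate_video(cfg)                      # video + ground truth
res <- run_full(sim$video, sim$annotation,
                segmentation = list(frame_stride = 6L))
res
#> <injection_result> synthetic: included
#>   delta_t 9.96 s, Q 0.803 mL/s, R^2 0.635, retention 14.7%

glance(res$uptake)
#> # A tibble: 1 × 4
#>   r_squared delta_t_s     n b_at_boundary
#> 1     0.635      9.96   100 FALSE

glance(res$retention)
#> # A tibble: 1 × 4
#>   rotation_volume_ml injected_volume_ml retention_pct escaped_volume_ml
#> 1               1.18                  8          14.7              6.82
```

The simulated injection used b = 0.3 s⁻¹, so the true duration is
ln(20)/0.3 ≈ 9.99 s; the fit recovers 9.96 s from a video with realistic
speckle and heartbeat noise (the modest R² is typical of such noise).
The true retention fraction was 15 %; segmentation plus the
rotation-volume estimate recover 14.7 %.

The mechanism layer, at its defaults (Q = 0.4 mL/s, P_i = 10 mmHg,
depot radius 0.1–1 cm, injection stress 240–300 kPa):

```r
mechanism_report()
#> <mechanism_report>
#>   Implied hydraulic conductivity 0.00318-0.0318 cm^2/mmHg/s exceeds
#>   literature values by 4.0-5.0 orders of magnitude (cutoff 3): porous Darcy
#>   flow is implausible. Estimated injection stress 240-300 kPa vs tunneling
#>   thresholds 114 kPa (macro-crack) and 127 kPa (micro-crack percolation):
#>   tissue fracture is plausible.
```

A thin command-line front end with `simulate`, `screen`, `analyze`,
`cohort` and `mechanisms` subcommands is installed at
`inst/cli/ebusdepot.R`.

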