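# impulsedr

Two-compartment microstructural diffusion MRI in R: forward modelling,
Monte-Carlo verification, voxelwise fitting and cohort-level statistics for
combined pulsed (PGSE) and oscillating (OGSE) gradient spin-echo protocols,
together with a synthetic breast-tumour cohort generator that exercises the
whole pipeline.

## Who this is for

Researchers working on microstructural diffusion MRI of tumours (IMPULSED-style
cell-size imaging) who need a tested, scriptable implementation of the forward
signal model, its inversion, and the downstream group statistics — without
access to patient data. Everything runs on synthetic cohorts whose enrollment
structure, immunohistochemistry (IHC) label frequencies and tissue-parameter
distributions emulate a published breast-tumour study population.

## The model

Tissue water is split into two non-exchanging pools. For an effective gradient
waveform `g(t)` with first moment `q(t) = γ ∫ g dt`:

```
S/S0 = f_in · S_in(d_mean, D_in) + (1 − f_in) · exp(−b · D_ex)
```

* `S_in` — Gaussian-phase-distribution (GPD) attenuation of water restricted in
  impermeable spheres of diameter `d_mean` (μm), evaluated in the frequency
  domain: `ln S_in = −(1/π) ∫ |q̃(ω)|² D(ω) dω`, where `D(ω)` is the sphere
  restriction spectrum `Σ_k B_k a_k ω²/(a_k² + ω²)` with `a_k = μ_k² D_in/R²`,
  `B_k = 2R²/(μ_k²(μ_k²−2))` and `μ_k` the roots of
  `(μ²−2)·sin μ + 2μ·cos μ = 0`.
* `f_in` — intracellular signal fraction; `D_ex` (μm²/ms) — hindered
  extracellular diffusivity; `D_in` fixed at 1.58 μm²/ms for stability.
* Cellularity index = `f_in/d_mean` (μm⁻¹), computed voxelwise then averaged.
* Per-sequence apparent diffusion coefficients from `S/S0 = exp(−b·ADC)`.

One frequency-domain code path covers rectangular PGSE and cosine OGSE (and
any future waveform); an independent Monte-Carlo random-walk simulator in C++
(elastic specular reflection inside the sphere) serves as ground truth for the
GPD approximation.

Fitting is bounded multi-start nonlinear least squares over
`4 < d_mean < 30 μm`, `0 < f_in < 1`, `0 < D_ex < 3.5 μm²/ms`, with a
profile-likelihood identifiability flag for the diameter when the
intracellular fraction is small.

## Worked example

```r
library(impulsedr)

prot <- default_protocol()          # DWI + PGSE + OGSE 17/33 Hz, Table-style b lists
p    <- tissue_params(d_mean = 15.74, f_in = 0.346, D_ex = 2.119)
sig  <- two_compartment_signal(p, prot)
head(sig, 3)
#>   sequence family    b S_over_S0
#> 1      DWI   pgse    0   1.00000
#> 2      DWI   pgse 1000   0.36747
#> 3     PGSE   pgse    0   1.00000

fit <- fit_impulsed(data.frame(sequence = sig$sequence, b = sig$b, S = sig$S_over_S0), prot)
fit
#> <impulsed_fit> d_mean=15.740 um f_in=0.346 D_ex=2.119 um^2/ms cellularity=0.02198 /um
#>   rms=1.86e-10 converged=TRUE restarts=6 boundary=FALSE d_spread=0
```

The fitted diameter, intracellular fraction and extracellular diffusivity
reproduce the inputs; `cellularity` is their ratio `f_in/d_mean`. The ADCs of
the three microstructural sequences, fitted from the same forward signals,
show the diffusion-time ordering expected under restriction
(`ADC_33Hz = 1.67 > ADC_17Hz = 1.23 > ADC_PGSE = 0.61 μm²/ms` for this
parameter set).

A full synthetic study — 236 collected patients, 23 excluded, 83 benign /
130 malignant lesions with exact IHC marginals, noisy voxelwise signals,
fits, and the comparison/ROC report tables:

```r
out <- run_pipeline(run_config(seed = 1, snr = 50, out_dir = "run1"))
# run1/roster.csv, cohort.csv, composition.csv, table4_report.csv,
# table5_report.csv, icc_report.csv, roi_summary.csv, maps/, manifest.json
```

A command-line front-end mirrors the stages
(`inst/cli/impulsed simulate|forward|oracle|fit|stats|run`).

## Limitations

Synthetic cohorts only — no DICOM/BIDS import, no motion or eddy correction,
no transcytolemmal water exchange, no perfusion compartment. See the methods
vignette (`vignettes/impulsed-methods.Rmd`) for modelling assumptions, numeric
choices and what the synthetic tests do and do not establish.
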