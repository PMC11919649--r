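---
title: "Methods: two-compartment microstructural diffusion MRI, its synthetic cohort, and the statistical battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-compartment microstructural diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the signal model
and its assumptions, the numeric machinery, what the synthetic-data generator
emulates (and deliberately does not), and the design decisions taken where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The measurement and the model

Diffusion MRI attenuates the signal by the spin-phase dispersion accumulated
under a diffusion-encoding gradient `g(t)`. The probed length scale is set by
the effective diffusion time: long for a pulsed gradient pair (PGSE,
`t_d = Δ − δ/3`) and short for oscillating gradients (cosine OGSE,
`t_d = 1/(4f)` at oscillation frequency `f`). Combining both in one protocol
makes the signal sensitive to restriction at cellular scales, which is what
permits estimating cell size rather than only an apparent diffusivity.

The tissue model is a two-compartment, no-exchange mixture:

* **Intracellular**: water restricted in impermeable spheres of diameter
  `d_mean` with intrinsic diffusivity `D_in`. Its attenuation is computed
  under the Gaussian phase distribution (GPD) approximation in the frequency
  domain, `ln S_in = −(1/π)∫|q̃(ω)|² D(ω) dω`, with `D(ω)` the standard
  sphere restriction spectrum (eigenvalue expansion; `sphere_roots()`,
  `sphere_modes()`). The first eigenvalue is ≈ 2.0816 and the weights satisfy
  `Σ B_k a_k → D_in`, which anchors the high-frequency limit.
* **Extracellular**: hindered Gaussian diffusion, `exp(−b·D_ex)`, with a
  single frequency-independent `D_ex` (an extension point, deliberately not
  exercised).

Signal fractions, not volume fractions, are modelled: compartmental T1/T2
differences are ignored, consistent with common practice for this protocol
family.

**Assumptions that matter.** No transcytolemmal exchange (exchange
underestimates `f_in` in real tissue); a single sphere diameter per voxel
(a distribution would shift high-b behaviour); GPD itself, which degrades at
strong attenuation — quantified against the Monte-Carlo oracle below.

## 2. Parameters, units, defaults

| Parameter | Units | Default / bounds | Why |
|---|---|---|---|
| `d_mean` | μm | fit bounds (4, 30) | physiological cell sizes |
| `f_in` | — | (0, 1) | signal fraction |
| `D_ex` | μm²/ms | (0, 3.5) | below free water at body temperature |
| `D_in` | μm²/ms | fixed 1.58 | fixing it stabilizes the inversion |
| γ | rad s⁻¹T⁻¹ | 2.675×10⁸ | proton value, config-overridable |
| gradient limit | mT/m | 45·√3 | 45 per axis, all axes combined |

All b-values are carried in s/mm² externally and ms/μm² internally
(1 ms/μm² = 1000 s/mm²); ADCs are reported in μm²/ms throughout, converting
on input where sources mix mm²/s conventions.

The packaged protocol (`inst/extdata/table1.json`) encodes a three-frequency
breast protocol: a conventional DWI-style PGSE (δ=18, Δ=44 ms), a long-Δ PGSE
(δ=15.9, Δ=119.2 ms, b up to 1800), and cosine OGSE with 1 and 2 cycles per
64.2 ms lobe (realized 15.6 and 31.2 Hz against nominal 17/33 Hz — both are
stored; computations use the realized frequency). Three printed
inconsistencies are preserved as annotations rather than silently fixed: the
DWI row's TE (59.5 ms) cannot host δ+Δ=62 ms, so the waveform window uses
63 ms and keeps the printed value as `te_printed_ms`; the printed effective
diffusion times (26.7 and 36.8 ms) disagree with `Δ − δ/3` and are stored as
`td_printed_ms`; and the DWI row lists no b-values, so the standard two-point
0/1000 s/mm² set is used.

**Gradient amplitude.** Pure-cosine OGSE is b-inefficient: the highest OGSE
shells of this protocol need up to ≈50 mT/m, above the 45 mT/m per-axis
limit. Real implementations either apodise the waveform or encode along a
diagonal; the package adopts the combined-axis limit 45·√3 mT/m by default
and exposes strict per-axis checking (`g_max = 45`), which correctly rejects
those shells. Lobes are pure cosine by design — one closed-form oracle covers
them — with apodised variants left as a config extension.

## 3. Numerical choices

* **Waveforms** are sampled so lobe edges fall on grid points (edge samples
  take half amplitude), ≥200 samples per PGSE lobe and ≥100 per OGSE cycle;
  the numerical b then matches closed forms to well under 0.5%.
* **Spectral integral**: FFT of `q(t)` zero-padded ×8, energy-truncated at
  1−10⁻⁶ of the spectrum; with a constant spectrum this reproduces
  `exp(−b·D₀)` to 10⁻³ on every protocol waveform (tested — the Parseval
  anchor).
* **Eigen-truncation** K=50 (high-frequency limit correct to <1%).
* **Fitting kernel**: for a fixed protocol and `D_in`, `ln S_in` depends only
  on `d_mean`; it is tabulated per acquisition on a 0.1 μm grid via
  per-acquisition integrals `I(a)` on a log-spaced rate grid and
  spline-interpolated. The kernel agrees with the direct mode sum to <10⁻⁵
  in signal (tested), and makes a voxel fit cost milliseconds.
* **Inversion**: bounded least squares (`nlminb`), multi-start on the coarse
  grid d∈{6,10,14,18,22,26}, f∈{0.1,0.3,0.5,0.7}, D∈{0.5,1.5,2.5}; the best
  nodes are refined (6 by default, 3 in map mode), tolerances 10⁻⁸, 500
  iterations; ties break toward the smallest diameter for deterministic
  output. Plain least squares on magnitude data — no Rician likelihood — is
  intentional; the Rician bias at SNR 50 is quantified by test rather than
  corrected.
* **Identifiability**: when the fitted `f_in` is small the diameter carries
  almost no signal. Rather than relying on restart scatter (a good optimizer
  collapses it even in a flat valley), the package profiles the objective
  over fixed diameters with `(f_in, D_ex)` re-optimized and reports the
  relative width of the set indistinguishable within 0.005 RMS signal;
  `d_spread > 0.2` flags an unidentifiable diameter. The profile is computed
  only when `f_in < 0.15` to keep map fitting cheap.
* **Normalization** is per sequence by its own b=0 acquisition (echo times
  differ between sequences, so a global S0 would mix T2 weightings). Whether
  the emulated study did the same is not decidable from its report.
* **Boundary hits** are retained and flagged, never discarded silently;
  voxels with non-positive signals are excluded from ADC ROI summaries and
  counted.

## 4. The Monte-Carlo oracle

Correctness of the GPD path is defined against an independent random-walk
simulator (C++): fixed-length steps `√(6 D Δt)` in uniform directions,
elastic specular reflection at the sphere wall, phase accumulated along the
gradient axis, signal `⟨cos φ⟩` with its standard error. The simulator has
its own deterministic RNG stream, so identical seeds are bit-identical
regardless of R's RNG state. A step-length precondition
(`step ≤ R/10`) forces finer steps for small spheres. For protocol sweeps,
one trajectory set per sequence is reused across b-shells (phase scales
linearly with gradient amplitude), keeping a full 20 000-walker sweep under a
minute. The acceptance tolerance — median |ΔS| ≤ 0.02 over
d ∈ {8,…,25} μm and all shells with b ≤ 1000, ≤ 0.04 at b = 1400/1800 —
encodes the known degradation of GPD at strong diffusion weighting.

## 5. The synthetic cohort: what it emulates, what it does not

`generate_roster()` reproduces the emulated study's enrollment arithmetic
exactly: 236 collected; 10 excluded for lesion diameter <8 mm, 5 for missing
pathology, 8 for image quality (disjoint, one criterion each); 213 enrolled,
split 83 benign / 130 malignant with the published histology breakdown
(117 invasive cancers). IHC marginals are matched *by allocation, not
sampling* — every printed count (ER 87/30, PR 73/44, HER-2 46/71, Ki-67
104/13, grades 4/67/46, subtypes 8/71/26/12) is reproduced exactly at any
seed; the seed only shuffles the coupling.

Two published inconsistencies are handled openly:

* The subtype counts are **jointly infeasible** with the HER-2 marginal under
  the receptor-based typing rule (Luminal B + HER-2-overexpression = 97
  HER-2+ labels against a printed 46). Subtype labels are allocated to the
  printed marginal with a priority coupling that maximizes rule consistency;
  the attainable minimum of 59 rule-inconsistent records is reported as an
  attribute and asserted in tests.
* Independent draws of `f_in` and `d_mean` from the printed group
  distributions contradict the printed cellularity row: the benign diameter
  SD (4.645 μm) inflates `E[f/d]` above the malignant value. The generator
  therefore draws `(d_mean, f_in)` from a per-group Gaussian copula whose
  correlation was calibrated once against the printed cellularity means
  (benign ρ=0.616, exact; malignant ρ=0.9, within 0.8% of a target near the
  attainable supremum). Even so, the printed cellularity effect size is so
  small relative to its SDs that a cohort of 83/130 shows the printed
  direction only with moderate probability — an inherent property of the
  published numbers, not of this implementation; the direction check
  therefore runs at the pre-registered default seed.

Lesion signals are forward-generated from the tissue model (5% within-lesion
coefficient of variation by default — enough for nonzero ROI SDs without
swamping recovery) with Rician noise, magnitude of `(S+ε₁, ε₂)`,
`ε ~ N(0, S0/SNR)`. Group ADCs are *emulated through the model*, not drawn
from the printed ADC rows, precisely so that model-vs-ADC consistency (the
frequency ordering `ADC_33Hz > ADC_17Hz > ADC_PGSE`, lower ADCs in the
higher-cellularity group) is a testable consequence rather than an input.
Observer pairs are simulated as lesion value plus noise at a 1:0.2 variance
ratio, targeting intraclass correlations near 0.83.

**What a green test does not establish**: realism of breast anatomy, spatial
noise correlation, partial volume, perfusion, exchange, or the study's
patient-level effect sizes (its raw images are unavailable; printed
patient-level AUCs such as 0.951 for the conventional-DWI ADC are treated as
generator-independent and are *not* reproduction targets).

## 6. Statistics

Group contrasts use Levene's test (centre = mean) to gate a pooled vs Welch
two-sided t test at 0.05 — the emulated analysis reports Levene but not its
rule, so the gate is a documented choice. No multiplicity correction is
applied (matching the emulated analysis); a Benjamini-Hochberg column is
emitted for information only. ROC analysis is fully empirical: trapezoidal
AUC (exactly the Mann-Whitney concordance, ties counting ½ — asserted
against a brute-force pairwise oracle), automatic orientation so AUC ≥ 0.5
with the orientation recorded, and Youden-optimal cutoffs reported in marker
units at the midpoint between adjacent distinct scores. Logistic
combinations are in-sample maximum likelihood on standardized features (as
the emulated analysis reports them; no cross-validation is claimed), with a
small-ridge IRLS fallback, flagged, under perfect separation. Reliability is
ICC(2,1) — two-way random effects, absolute agreement, single measure — with
the F-based confidence interval; alternative ICC forms were considered and
rejected since a two-rater absolute-agreement design is what the emulated
table describes. The grade contrast in the default generator carries no
signal by construction, mirroring the null grade row of the emulated study.

## 7. Reproducibility and I/O

Every stage is seed-deterministic: identical configs produce byte-identical
CSV payloads (a regression-tested contract), and the Monte-Carlo oracle is
bit-reproducible by seed. NIfTI-1 I/O is implemented minimally in-package
(float32, sform affine, gzip) because no NIfTI reader exists in the target R
stack; round-trips preserve data to float32 exactly. CSV outputs carry the
seed and units in a comment header.

## 8. Known limitations

GPD accuracy degrades above b ≈ 1400 s/mm² (documented looser tolerance);
`D_ex` has no frequency dependence; the ridge fallback's AUC can differ
slightly from an unpenalized fit on separable data; profile-based
identifiability is only computed in the small-`f_in` regime; and the
synthetic cohort's between-group effect sizes follow the forward model, not
the published patient-level statistics, so downstream AUCs are qualitatively,
not numerically, comparable.
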