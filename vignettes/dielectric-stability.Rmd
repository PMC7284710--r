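---
title: "Methods: dielectric stability analysis of amorphous dispersions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dielectric stability analysis of amorphous dispersions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielstab)
```

# The analysis chain

`dielstab` analyses broadband dielectric spectroscopy (BDS) measurements of
amorphous drug–polymer dispersions.  The chain has four stages, each usable
alone and each returning a classed object with `print`, `coef` and
`predict` methods:

1. `fit_hn()` — Havriliak–Negami fit of one loss spectrum, with a
   dc-conductivity term;
2. `fit_vft()` — Vogel–Fulcher–Tammann fit of the α-relaxation map
   τ~α~(T), then `tg_from_vft()` / `isochronal_temperature()`;
3. `fit_gt_k()` — Gordon–Taylor fit of T~g~ versus composition, and
   `gt_invert()` for the reverse read-out;
4. `detect_onset()`, `kinetics_summary()`, `residual_composition()` —
   crystallization onset, isothermal kinetics, and the solubility-limit
   pipeline.

`run_characterize()` and `run_stability_compare()` wire the stages into the
two standard workflows (non-isothermal characterization; isothermal versus
isochronal storage comparison).

# Models and conventions

**Permittivity sign convention.**  Everywhere ε\*(ω) = ε′ − iε″ with
ω = 2πf, so the loss ε″ is non-negative for admissible parameters.
Temperatures are kelvin, frequencies Hz, times seconds; conversions happen
only at I/O boundaries.  The vacuum permittivity is fixed at
ε~0~ = 8.8541878128×10^−12^ F/m.

**Havriliak–Negami with conductivity.**

$$\varepsilon^*(\omega) = \varepsilon_\infty +
  \frac{\Delta\varepsilon}{[1 + (i\omega\tau_{HN})^a]^b} +
  \frac{\sigma_{dc}}{\varepsilon_0 i\omega}$$

One relaxation process is modelled; secondary (β) relaxations are out of
scope.  The conductivity exponent is fixed at 1 (pure dc conduction), with
no fractional-power term.  Box bounds enforce physical admissibility:
0 < a ≤ 1, 0 < b ≤ 1, Δε > 0, τ~HN~ > 0, ε~∞~ ≥ 1, σ~dc~ ≥ 0.

**Peak-time conversion.**  The α-relaxation time reported on relaxation
maps is the reciprocal of the loss-peak angular frequency,

$$\tau_\alpha = \tau_{HN}
  \left[\sin\frac{\pi a}{2+2b}\right]^{-1/a}
  \left[\sin\frac{\pi a b}{2+2b}\right]^{1/a}.$$

Two opposite exponent-sign conventions for this formula circulate in the
literature.  The one implemented here is validated in the test suite
against dense numeric maximization of the HN loss over the full (a, b)
admissible grid (agreement to 0.1%), and against the two closed-form
limits: the Debye identity τ~α~ = τ~HN~ at a = b = 1 and the
Cole–Davidson relation ω~max~τ = tan(π/(2b+2)) at a = 1.  The reciprocal
convention fails both checks (it yields τ~α~ ≥ τ~HN~ always), so it is not
offered as an option.

**VFT and derived temperatures.**
τ~α~(T) = τ~∞~ exp(B/(T − T~0~)).  The glass transition uses the
dielectric convention T~g~ = T(τ~α~ = τ~ref~) with τ~ref~ = 100 s;
isochronal reference temperatures use the same closed-form inverse
T = T~0~ + B/ln(τ/τ~∞~) with τ = 1.5 ms by default.  Both reference times
are exposed as arguments.  T~g~ lies below the fitted range by
construction; the returned value carries the extrapolation distance (in
kelvin below the coldest fitted point) and a first-order standard error
propagated from the parameter covariance.

**Gordon–Taylor.**
T~g~(w₂) = (w₁T~g1~ + Kw₂T~g2~)/(w₁ + Kw₂), with component 1 the drug and
component 2 the polymer; w₂ always denotes the *polymer* weight fraction
and all I/O labels fractions explicitly, because drug/polymer swaps are
the classic blunder with this equation.  K may be computed from
heat-capacity steps (K ≈ ΔC~p2~/ΔC~p1~, `gt_k_from_dcp()`) or fitted to
measured mixture T~g~s (`fit_gt_k()`).  The fit holds the pure-component
T~g~s fixed at their measured values — they are data, not parameters — and
minimizes unweighted kelvin residuals.  The inversion
w₂ = (T~g~ − T~g1~)/[(T~g~ − T~g1~) + K(T~g2~ − T~g~)] is exact; because
the relation flattens when the component T~g~s are close, `gt_invert()`
reports the sensitivity dw₂/dT~g~ and a first-order standard error, which
is how the inherent uncertainty of solubility read-outs from shallow
T~g~–composition curves is surfaced rather than hidden.

# Fit objectives and numerical choices

* **HN objective.**  Loss spectra span several decades, so the default
  objective is least squares on log ε″ (`mode = "loss_only"`).  ε~∞~ does
  not enter ε″ and is therefore not fitted in this mode; it is taken from
  the minimum of ε′ when available.  `mode = "complex"` jointly fits log
  residuals on ε″ and relative residuals on ε′ and does estimate ε~∞~.
* **HN initialization.**  τ~HN~ from the observed interior loss-peak
  position (Debye assumption), Δε as twice the peak height, a = b = 0.8.
  When conduction buries the peak, σ~dc~ is pre-estimated from the
  lowest-frequency limb, subtracted, and the peak search repeated on
  frequencies where conduction contributes less than half the observed
  loss.
* **Degenerate inputs.**  A loss that is a clean ω^−1^ power law
  (conduction with no resolvable relaxation) returns a result flagged
  non-identifiable — not an exception — because a series may genuinely
  contain such spectra.  A spectrum with no interior peak and no
  conduction signature raises an initialization error unless explicit
  starting values are supplied.
* **Optimizer.**  All nonlinear fits use bounded Levenberg–Marquardt
  (`minpack.lm::nls.lm`) on transformed parameters (log₁₀ for Δε, τ, σ)
  with tight tolerances (`ftol = ptol = 1e-15`), which is what lets
  noiseless round trips recover parameters to 10^−6^–10^−10^ relative.
* **VFT fitting.**  Residuals are on log₁₀τ with unit weights (τ spans
  many decades; linear-time residuals would see only the slowest points).
  T~0~ is first located by profiling — for fixed T~0~ the model is linear
  in 1/(T − T~0~) — then all three parameters are polished by LM.  The
  covariance comes from the final Jacobian.  Arrhenius-like data push
  T~0~ to its lower bound and set the `t0_bounded` flag instead of
  failing.
* **Relaxation-map hygiene.**  `extract_relaxation_map()` skips, with a
  recorded reason, spectra that fail to fit, are non-identifiable, or
  whose fitted loss peak falls outside the measured frequency window (a
  fit extrapolated beyond the window says nothing trustworthy about
  τ~α~).  It never interpolates over failures.  With
  `drop_crystallized = TRUE` it additionally screens the fitted Δε(T)
  with the onset detector and truncates the map at a detected collapse,
  so crystallized spectra cannot contaminate the VFT fit.

# Crystallization detection

The dielectric strength is proportional to the number of reorienting
dipoles (Δε ∼ Nμ²), so crystallization — which immobilizes dipoles —
appears as a shortfall of Δε (or of ε′ at fixed frequency) below the
non-crystallizing trend.

* **"Noticeable drop"** is quantified as a ≥ 10% relative shortfall from
  the extrapolated baseline (`threshold = 0.1`, configurable).  The test
  suite includes a threshold sweep showing the detected onset moves by at
  most one grid step for thresholds of 5–15% on a sharp collapse, so the
  choice is not load-bearing.
* **Baselines.**  For wide-band series the baseline is a least-squares
  A/T fit to the pre-onset dielectric strengths — the Langevin 1/T decay
  expected from thermal agitation.  For single-frequency ε′(T) scans a
  local linear trend over the last five pre-onset points is used instead,
  because a fixed-frequency ε′ trace also contains the step at the glass
  transition and has no single closed-form shape.
* **No onset is a result, not an error.**  Stable formulations simply
  never cross the threshold; `detect_onset()` returns
  `detected = FALSE`, and stability reports carry `tc = NA` with no
  stability factor.
* **Kinetics.**  Normalized traces
  ε′~N~(t) = (ε′(0) − ε′(t))/(ε′(0) − ε′(∞)) use ε′(0) from the mean of
  the first three points (the initial plateau) and a user-supplied ε′(∞)
  — there is no safe way to guess the high-frequency limit from an
  incompletely crystallized trace.  Induction is the first crossing of
  ε′~N~ = 0.05; cessation is the start of the terminal window whose local
  slope stays below 10^−3^ per hour; the plateau mean below 0.95 flags
  incomplete crystallization.

# The solubility-limit pipeline

After crystallization of the excess drug ceases, the surviving relaxation
(α′) belongs to the saturated drug-in-polymer solution.
`residual_composition()` chains the stages: α′ relaxation map → VFT fit →
T~g~ extrapolation → Gordon–Taylor inversion, and propagates the VFT
covariance through dw₂/dT~g~ into a standard error on the drug fraction.
A T~g~ outside the endpoint range is reported (with a warning), never
clamped; a composition indistinguishable from the neat polymer (< 2 wt.%
drug) warns that the drug may have crystallized completely or be
immiscible — the two cases a T~g~ read-out cannot separate.

# The synthetic-data generator

The generators exist so that every stage can be validated against known
ground truth; they share the analysis forward models and attach a manifest
(`ground_truth()`) sufficient to regenerate any dataset bit-exactly.

* τ(T) follows VFT; Δε(T) = A/T below the programmed onset and
  A/T·(1 − X) above it, with X a stretched-exponential (Avrami-like)
  crystallized-fraction kernel X = x~max~[1 − exp(−k·Δ^n^)].  The kernel
  is a *generator* choice — sigmoidal crystallinity curves admit several
  kinetic laws — and the detectors deliberately assume nothing about it.
  A cap x~max~ < 1 models incomplete crystallization.
* Noise is multiplicative Gaussian (relative), applied last, 1% by
  default in validation studies: dielectric loss spans decades, so
  additive noise would swamp the low-loss wings.  The noiseless branch
  equals the analytic model to machine precision.
* One global integer seed; per-spectrum substreams are derived
  deterministically from (seed, index), so series are reproducible
  element-wise.
* Not emulated: secondary (β) relaxations, electrode polarization,
  fractional-power conductivity, temperature-dependent shape exponents,
  and DSC heat flow.  Passing recovery tests therefore demonstrates
  correctness of the estimators under the stated forward models — not
  robustness to every artefact of real spectra; spectra contaminated by
  strong electrode polarization, in particular, would need masking before
  fitting.

# Validation study sizes

The test suite validates each stage at sizes chosen to make Monte-Carlo
statements meaningful while keeping the whole suite fast: spectra use the
0.1 Hz–1 MHz window at 30 points/decade (211 points); HN recovery runs 100
seeded spectra at 1% noise (success = τ~HN~ within 5%, a and b within 0.05,
required in ≥ 95 runs); T~g~ stability runs 100 seeded 15-point maps at 5%
τ noise (sd < 0.5 K); the solubility pipeline is exercised end-to-end at
saturated drug fractions of 0.17, 0.10 and 0.06 with recovery within
±0.02.  The full suite runs in a few seconds.

# Known limitations

* Single-process HN fits: overlapping α and β processes bias the shape
  exponents.
* The onset detector assumes the pre-onset baseline window contains at
  least four (wide-band) or five (single-frequency) clean points.
* T~g~ and isochronal temperatures are extrapolations; the reported
  standard errors capture parameter uncertainty under the VFT model, not
  model error from non-VFT curvature outside the fitted range.
* Gordon–Taylor inversion inherits the flatness of the T~g~–composition
  curve: near-equal component T~g~s make any composition read-out
  qualitative, which is exactly what the reported dw₂/dT~g~ quantifies.
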