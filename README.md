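# dielstab

Broadband dielectric spectroscopy (BDS) is the workhorse technique for
assessing the *physical stability* of amorphous solid dispersions (ASDs) —
formulations in which a poorly soluble drug is dispersed, molecularly, in a
polymer matrix.  The amorphous drug is thermodynamically unstable and tends
to recrystallize; dielectric spectroscopy tracks both the molecular
mobility that drives this process and the crystallization itself.
`dielstab` implements the complete analysis chain for such studies, for
formulation scientists and glass-physics researchers working with
drug–polymer dispersions:

1. **Havriliak–Negami (HN) fitting.**  Each loss spectrum is fitted with

   ε\*(ω) = ε<sub>∞</sub> + Δε / [1 + (iωτ<sub>HN</sub>)<sup>a</sup>]<sup>b</sup> + σ<sub>dc</sub>/(ε<sub>0</sub>iω),  ω = 2πf,

   where Δε is the dielectric strength, a and b the symmetric and
   asymmetric broadening exponents, and σ<sub>dc</sub> the dc conductivity.
   The fitted τ<sub>HN</sub> is converted to the α-relaxation peak time

   τ<sub>α</sub> = τ<sub>HN</sub> [sin(πa/(2+2b))]<sup>−1/a</sup> [sin(πab/(2+2b))]<sup>1/a</sup>.

2. **Vogel–Fulcher–Tammann (VFT) analysis.**  The relaxation map
   τ<sub>α</sub>(T) = τ<sub>∞</sub> exp(B/(T − T<sub>0</sub>)) is fitted in
   log τ and extrapolated to the dielectric glass-transition convention
   T<sub>g</sub> = T(τ<sub>α</sub> = 100 s), and to isochronal reference
   temperatures such as T(τ<sub>α</sub> = 1.5 ms) for comparing samples at
   matched molecular mobility.

3. **Gordon–Taylor composition modelling.**  Mixture glass transitions
   follow T<sub>g</sub>(w₂) = (w₁T<sub>g1</sub> + Kw₂T<sub>g2</sub>)/(w₁ + Kw₂)
   with K ≈ ΔC<sub>p2</sub>/ΔC<sub>p1</sub>; the package fits K to measured
   tables, predicts mixture T<sub>g</sub>s, and *inverts* the relation —
   which converts the T<sub>g</sub> of the residual amorphous phase left
   after crystallization into the drug's solubility limit in the polymer.

4. **Crystallization detection and kinetics.**  Crystallization
   immobilizes reorienting dipoles (Δε ∼ Nμ²), so its onset is detected as
   the collapse of Δε below the extrapolated 1/T baseline (wide-band
   scans) or of ε′ below its local trend (single-frequency scans).
   Isothermal kinetics are summarized through the normalized permittivity
   ε′<sub>N</sub>(t) = (ε′(0) − ε′(t))/(ε′(0) − ε′(∞)): induction time,
   cessation time and final crystallinity plateau.

A seeded synthetic-data generator produces ground-truth-labelled spectra,
temperature scans, crystallization traces and composition tables from the
same forward models, so every stage of the chain is testable end to end.

## Worked example

Fit the Gordon–Taylor parameter to the dielectric glass-transition table of
a drug–copolymer series (pure components 328 K and 377 K), holding out the
midpoint composition:

```r
library(dielstab)
tab <- read_composition_table(system.file("extdata", "sil_kva_tg_bds.csv",
                                          package = "dielstab"))
fit <- fit_gt_k(tab[tab$w2 %in% c(0.25, 0.75), ], tg1 = 328, tg2 = 377)
fit
#> <gt_model> Tg1 (drug) = 328.00 K, Tg2 (polymer) = 377.00 K, K = 0.9491
#>   fitted on 2 interior point(s); residuals (K): -0.78, 0.74
gt_predict(fit, 0.5)
#> [1] 351.8598
```

The held-out 50 wt.% mixture is predicted at 351.9 K, within 0.2 K of its
measured value (352 K) — the mixing behaviour is captured by a single K.

Characterize a complete (here synthetic) non-isothermal measurement — HN
fits, relaxation map, VFT extrapolation, onset detection:

```r
f <- 10^seq(-1, 6, by = 1/30)             # 0.1 Hz .. 1 MHz, 30 pts/decade
r <- hn_peak_time(list(tau_hn = 1, a = 0.8, b = 0.6))   # tau_alpha / tau_HN
vft_true <- list(tau_inf = 1e-14, B = 2000,
                 T0 = 328 - 2000 / log(100 / (r * 1e-14)))  # Tg_true = 328 K
temps <- sort(vft_true$T0 + vft_true$B /
                log(10^seq(-1, -5, length.out = 12) / vft_true$tau_inf))
series <- generate_temperature_series(
  vft_true, A = 1500, eps_inf = 3, tc_true = max(temps) + 4,
  temp_grid = c(temps, max(temps) + c(2, 4, 6, 8, 10)),
  freq_grid = f, noise_sd = 0.01, seed = 42)
run_characterize(list(`SIL-like sample` = series))
#> <stability_report> SIL-like sample
#>   Tg(tau = 100 s) = 327.97 K (se 0.018 K)
#>   T(tau = 0.0015 s) = 350.60 K (isochronal reference)
#>   Tc = 377.03 K, stability factor Tc - Tg = 49.05 K
#>   14/17 spectra fitted (3 skipped)
```

The generating glass transition (328 K) is recovered to 0.03 K from 1%-noisy
spectra; the programmed crystallization onset is found within one 2 K
temperature step; the skipped spectra are those whose loss peak fell outside
the measured frequency window or whose dielectric strength had collapsed.
The thermal stability factor T<sub>C</sub> − T<sub>g</sub> measures the
width of the supercooled-liquid window over which the sample resists
crystallization.

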