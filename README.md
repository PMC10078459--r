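# ringdisc

Benchmarking leaf gas-exchange theory against tree rings. `ringdisc`
predicts leaf-level carbon isotope discrimination (Δ¹³C, ‰) from summer
climate with the least-cost optimality stomatal model — including
photorespiratory and mesophyll effects — converts measured tree-ring δ¹³C
chronologies to the same Δ¹³C scale, and runs the standard model–data
comparison statistics over a multi-site network. It is written for
ecophysiologists and land-surface modellers who want to evaluate simulated
χ = c_i/c_a against dendro-isotopic archives.

## The model

Discrimination is

Δ¹³C = a·(c_a−c_i)/c_a + b·c_c/c_a − f·Γ\*/c_a + a_m·(c_i−c_c)/c_a

with a = 4.4‰, a_m = 1.8‰, b = 28‰, f = 12‰, and the CO₂ partial pressures
from the least-cost optimality solution

c_i = Γ\* + (c_a − Γ\*)·ξ/(ξ + √D),  ξ = √(β(K + Γ\*)/(1.6 η\*)),

where D is the July–August vapour pressure deficit (Pa), Γ\* the
photorespiratory compensation point and K the effective Michaelis–Menten
constant (both Arrhenius functions of temperature, linear in pressure).
The chloroplastic pressure c_c uses ξ_c = ξ/√(1 + g_sc/g_m). Tree-ring
δ¹³C is de-corrected for any applied Suess correction and converted with

Δ¹³C_TR = (δ¹³CO₂ − (δ¹³C_TR − d)) / (1 + (δ¹³C_TR − d)/1000),  d = 2.1‰.

Comparison statistics: absolute year-matched offsets with Max/Min/Mean/SD
summaries; Spearman rank correlation; inter-annual variability as the
population standard deviation; a Wilcoxon matched-pairs signed-rank test on
the variability pairs; OLS trends; an unweighted composite chronology; and
multiple linear attribution regressions of Δ¹³C on [CO₂] (ppm), T_air (°C),
VPD (kPa) and — pooled across sites — elevation (km).

A seeded synthetic-network generator (`network_scenario()`,
`simulate_network()`) emulates a 12-site, 1979–2016 oak network with known
ground truth, so the entire pipeline is testable offline. The package also
ships the reference offset and variability tables of a published 12-site UK
oak evaluation as plain-text fixtures (`read_offset_matrix()`,
`read_sd_table()`).

## Worked example

Predict five years of Δ¹³C for a Scottish highland site and compare against
a short tree-ring series:

```r
library(ringdisc)
p <- disc_params()
fc <- build_forcing(site_meta("Aviemore", 57.15, -3.84, 300),
                    data.frame(year = 2000:2004,
                               tair_c = c(13.2, 14.1, 13.8, 15.0, 13.5),
                               vpd_pa = c(520, 610, 580, 700, 540)),
                    data.frame(year = 2000:2004,
                               co2_ppm = c(369.7, 371.3, 373.4, 375.9, 377.6),
                               d13co2 = c(-8.05, -8.09, -8.13, -8.17, -8.21)))
pred <- predict_site(fc, p)
pred
#> <chronology> kind = Delta13C, source = predicted, 1 site(s), 5 year-values
#>    site_id year    value
#> 1 Aviemore 2000 18.81166
#> 2 Aviemore 2001 18.58113
#> 3 Aviemore 2002 18.65203
#> 4 Aviemore 2003 18.40953
#> 5 Aviemore 2004 18.77908
```

The model discriminates least in 2003, the warmest, driest year: high VPD
closes stomata, lowers c_i/c_a and enriches the wood. Converting a measured
δ¹³C series (~−26‰) and comparing:

```r
obs <- delta_from_d13c(
  chronology("Aviemore", 2000:2004, c(-25.6, -26.1, -25.2, -26.4, -25.8),
             kind = "delta13c_raw", source = "tree_ring"),
  data.frame(year = 2000:2004, co2_ppm = 1,
             d13co2 = c(-8.05, -8.09, -8.13, -8.17, -8.21)), p)
compare_site(pred, obs)
#> <site_comparison> Aviemore: n = 5
#>   offsets (permil): mean 1.71, sd 0.59, range [1.06, 2.52]
#>   Spearman rho = -0.70 (p = 0.188)
#>   inter-annual SD (permil): model 0.15, observed 0.42
#>   trends (permil/yr): model -0.0237 (p = 0.709), observed 0.0323 (p = 0.862)
```

Here the model sits ~1.7‰ above the trees on average (a typical
site-level bias), and — as expected from a five-year toy series — the rank
correlation is not significant. The predicted inter-annual variability is
smaller than the observed, the usual signature of smooth gridded forcing
versus real trees. An end-to-end synthetic run is one call:
`run_pipeline(read_run_config("config.yml"))` simulates a network, predicts
it, and writes offset, variability and attribution report tables.

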