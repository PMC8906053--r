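# cardioquant

Quantification of cardiomyocyte function and architecture from microscopy
assays, with matched synthetic-data generators for verification.

Cultured cardiomyocytes on engineered substrates are phenotyped through a
standard battery of imaging assays: calcium-transient recordings report
excitation–contraction coupling, traction force microscopy reports
contractile force on soft hydrogels, gap-FRAP reports intercellular
coupling through gap junctions, α-actinin striation images report
sarcomere organization and content, and immunofluorescence reports where
junctional and turnover-related proteins sit. cardioquant implements the
full quantification stack for these assays as composable, pipe-friendly R
functions, and — because such microscope recordings are rarely shareable —
pairs every assay with a synthetic-data generator that emits exact ground
truth, so each estimator is validated by parameter recovery.

## What is inside

| Assay | Core method | Key functions |
|---|---|---|
| Calcium transients | Prominence + upstroke (dF/dt) event detection; rhythm-grid classification of spontaneous release events; contaminated-beat exclusion; monoexponential decay fit | `detect_transients()`, `classify_spontaneous()`, `transient_kinetics()`, `summarize_cell()` |
| Traction force | PIV bead tracking (sub-pixel NCC) and regularized Fourier-transform traction cytometry (FTTC) on a 10 kPa elastic half-space | `piv_displacement()`, `fttc_inversion()`, `total_force()`, `contraction_metrics()` |
| Gap-FRAP | Double normalization (reference cell, pre-bleach) and multi-exponential recovery with the amplitude-weighted rate constant k_FRAP = Σ A·k / Σ A | `normalize_frap()`, `fit_recovery()`, `mobile_fraction()` |
| Sarcomere architecture | Scanning-window band-limited 2D-FFT orientation mapping; axial (period-180°) circular statistics; Otsu-based sarcomere content | `orientation_map()`, `organization_index()`, `sarcomere_content()`, `zdisc_mask()` |
| Localization | Puncta per myocyte nucleus, channel area ratios, junctions per mm on groove-parallel lines, vinculin metrics, distance-transform compartment partition (Ub_sarc:Ub_non-sarc) | `cx43_content()`, `area_ratio()`, `count_junctions()`, `vinculin_metrics()`, `ubiquitin_partition()` |
| Statistics | Two-tailed t, one-way ANOVA, Fisher exact on 2×2 counts, Mann–Whitney, paired Wilcoxon; mean ± SEM summaries | `compare_groups()`, `summarize_groups()` |
| Synthetic data | Paced transient trains with Poisson spontaneous events, Boussinesq forward fields and bead-image pairs, FRAP curve sets, striated images with von Mises orientations, partition images, junction profiles — all with ground truth | `gen_calcium_trace()`, `boussinesq_forward()`, `gen_bead_images()`, `gen_frap_curves()`, `gen_striated_image()`, `gen_partition_image()`, `gen_junction_profile()` |

Fitted objects follow broom conventions (`tidy()`, `glance()`), result
types have `autoplot()` methods (traces with marked events, FRAP fits,
rose plots, quiver fields), and all tabular results are tibbles.

## Worked example

Simulate two minutes of a paced (0.5 Hz) Fluo-4 recording with spontaneous
release events, then run the full calcium pipeline:

```r
library(cardioquant)

p <- calcium_sim_params(stim_freq_hz = 0.5, amplitude = 2, decay_tau_s = 0.5,
                        spont_rate_hz = 0.05, seed = 42)
sim   <- gen_calcium_trace(p, duration_s = 120)
trace <- normalize_df_f0(sim$trace)
beats <- trace |> detect_transients() |>
  classify_spontaneous(stim_freq_hz = 0.5, trace = trace)
summarize_cell(trace, beats) |> dplyr::glimpse()
#> $ beat_rate_hz     <dbl> 0.4916667
#> $ n_transients     <int> 59
#> $ n_spontaneous    <int> 9
#> $ spont_freq_hz    <dbl> 0.075
#> $ has_spontaneous  <lgl> TRUE
#> $ n_included_beats <int> 51
#> $ mean_tau_s       <dbl> 0.5055277
#> ...
```

The cell beats at the pacing rate (0.49 Hz measured over the recording),
all 9 injected spontaneous events are found (`n_spontaneous = 9`,
0.075 /s), the beats they contaminate are excluded from kinetics
(51 of 59 beats included), and the mean decay constant recovers the
generator's 0.5 s within ~1%.

FRAP and sarcomere organization follow the same pattern:

```r
fr  <- gen_frap_curves(frap_sim_params(k_true_per_s = 0.02,
                                       immobile_frac = 0.2,
                                       noise_sd = 0.01, seed = 1))
fit <- fr$traces |> normalize_frap(n_prebleach = 5) |> fit_recovery()
fit
#> <frap_fit> 1 component(s); k_FRAP = 0.02046 /s; mobile fraction = 0.800; R2 = 0.9939

g   <- gen_striated_image(striation_sim_params(mean_angle_deg = 90,
                                               angle_kappa = 8, seed = 1))
org <- orientation_map(g$image) |> organization_index(groove_axis_deg = 90)
org
#> <organization_result> index = 0.905; mean angle = 1.6 deg; n = 49
```

k_FRAP recovers the simulated 0.02 /s, the mobile fraction recovers
1 − 0.2 = 0.8, and a concentration-8 orientation distribution scores an
organization index of 0.905 centred on the groove axis (`autoplot(org)`
draws the rose plot).

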