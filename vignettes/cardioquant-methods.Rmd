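---
title: "Methods: models, estimators and design choices in cardioquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in cardioquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioquant)
options(cardioquant.quiet = TRUE)
```

cardioquant quantifies five imaging assays used to phenotype cultured
cardiomyocytes on engineered substrates — calcium handling, traction force,
gap-junction coupling, sarcomere architecture and protein localization —
together with synthetic-data generators that emit exact ground truth. This
vignette explains the models behind each estimator, the parameters that
matter, the numerical choices, and what the synthetic data do and do not
establish about real recordings.

## Conventions

Images are numeric matrices with the origin at the top-left; `x` is the
column index, `y` the row index, and orientation angles are degrees
counterclockwise from the +x axis on [0, 180). All function boundaries use
physical units — micrometres, seconds, pascals, nanonewtons — and pixel
conversions happen only inside the I/O layer. Acquisition metadata (pixel
size, frame interval, substrate modulus) is never read from image headers:
it comes from an `assay_config()`, validated once, because microscope TIFFs
rarely carry trustworthy physical calibration.

## Calcium transients

**Waveform model.** The synthetic transient is the product pulse
$s(t) = (1 - e^{-t/\tau_r})\, e^{-t/\tau_d}$, rescaled to a peak
$\Delta F/F_0$ amplitude. This is the standard single-peaked surrogate with
independently tunable upstroke ($\tau_r$, default 0.05 s — a realistic
Fluo-4 time-to-peak of ~120 ms) and decay ($\tau_d$). Stimulated beats sit
on a fixed grid at the pacing frequency (default 0.5 Hz field stimulation);
spontaneous release events are the same pulse scaled by
`spont_amp_frac` < 1 at homogeneous-Poisson times, reproducing their two
defining features: lower amplitude and random occurrence.

**Detection.** Peaks are topographic-prominence maxima at
$\geq 4\times$ the robust noise SD, where the noise SD comes from the
median absolute successive difference of the raw trace. Peak geometry is
measured on a ~50 ms moving-average copy: over a long trace the prominence
of raw high-rate noise exceeds any fixed multiple of the per-sample SD, so
some smoothing is required for the threshold to mean what it says; 50 ms is
far below the transient time scale, so beat geometry is unaffected.

**Spontaneous-event classification.** The rule is slot assignment on the
rhythm grid (the stimulation frequency when known, else the mode of the
inter-peak interval distribution): each grid slot is claimed by the
largest-amplitude transient within a quarter period; unclaimed transients
whose amplitude is below `alpha` (default 0.5) times the median
rhythm-locked amplitude are spontaneous. A naive "more than 25% of the
period off the grid" timing test would misclassify roughly half of all
random events — under pacing every slot is already occupied by a
full-amplitude beat, and a uniformly-timed event lands within a quarter
period of some slot with probability one half — while slot assignment keeps
both of the defining criteria intact.

Events that superpose with a beat produce no separate fluorescence peak.
Two further stages recover them when the trace is supplied:

1. *Upstroke analysis.* Calcium release is fast relative to decay, so each
   event contributes a maximum of dF/dt. Extra upstroke maxima (above 6
   robust SDs of the smoothed derivative, 30 ms resolution) inside a beat
   window are appended as fused events when their intensity rise stays
   below the median beat amplitude.
2. *Amplitude excess.* An event released within about one rise time of the
   stimulus merges even its upstroke with the beat's, but release
   superposes: the host beat's amplitude exceeds the rhythm median by the
   event amplitude. Locked beats whose excess clears both the beat-to-beat
   spread (6 MADs) and a 10% floor are flagged as hosting a coincident
   event.

Any rhythm-locked beat whose transient window (median locked duration,
widened 25% so exclusion errs conservative at the decay tail) contains a
spontaneous event's onset is `host_excluded` and dropped from kinetics —
contaminated beats must not shape the cell's kinetic means.

**Kinetics.** Threshold crossings (time to 50%/90% of peak on the rise,
50%/90% return to baseline on the decay) are linearly interpolated between
samples. Tau comes from a least-squares monoexponential fit to the decay.
The fit window runs from 70% down to 10% of the amplitude: near the peak
the finite upstroke still contributes several percent of signal, and
starting at 90% biases tau upward by ~11% for fast decays
($\tau_d$ = 0.2 s) — at 70% the bias falls below 4% and is negligible for
$\tau_d \geq$ 0.5 s. The window is configurable and logged. The window is
taken as a contiguous run between the first crossings, never by value
filtering, which would let noisy diastolic samples flatten the fit. Exact
exponential input defeats the nonlinear solver (zero residuals); the
log-linear estimate, exact in that case, is the fallback.

**What recovery tests show.** With pacing slow enough that the transient
returns to baseline (the recovery tests pace at
$\max(2, 6\tau_d)$-second periods, since a cell whose decay outlasts its
diastole has no measurable tau), the median recovered tau is within ~1% of
truth at amplitude SNR 20 and within 15% at SNR 5. The generator does not
model baseline drift, photobleaching, motion artifacts or calcium-dye
buffering kinetics; passing these tests demonstrates estimator correctness,
not robustness to those real-world effects.

## Traction force microscopy

**Forward model (oracle).** The substrate is an elastic half-space (Young's
modulus $E$, default 10 kPa; Poisson ratio $\nu$, default 0.5 for
polyacrylamide). Focal adhesions are tangential disc loads whose vector sum
is zero. The forward displacement is evaluated by direct spatial summation
of the Boussinesq/Cerruti surface Green's function over disc sample points
(Plummer-softened at half the sampling pitch so on-disc values stay
finite). This path is deliberately slow and simple, and shares nothing with
the Fourier inversion it validates.

**Bead images and PIV.** Beads are Gaussian spots (default 0.15 per µm²,
σ = 0.4 µm) displaced by the elastic field. Displacement is recovered by
windowed cross-correlation: an FFT correlogram locates the integer-pixel
peak, then the sub-pixel offset comes from a 3-point Gaussian fit to
*exact* overlap-normalized correlation values around that peak — the
zero-padded correlogram's triangular overlap weighting otherwise biases the
sub-pixel fit toward zero shift. The default 12 µm window (~30 beads)
keeps every vector of a pure-translation pair within 0.05 µm; at 8 µm,
windows with a bright bead at the edge occasionally err by 0.06 µm.
Low-quality vectors (correlation < 0.3) are replaced by the local median
and flagged.

**Inversion.** Regularized Fourier-transform traction cytometry: the
half-space Green's operator is inverted per wavevector with Tikhonov
damping, and the zero-frequency component is set to zero (rigid drift and
any uniform offset cannot carry traction). The default regularization is
*resolution-matched*: $\lambda = 3(1+\nu)/(E k_{Ny})$, i.e. 1.5× the
operator gain at the grid Nyquist wavenumber, which suppresses
sub-resolution modes by ≥ 70% while leaving resolved modes nearly
untouched. An L-curve corner selector is available (`lambda = "lcurve"`)
but is not the default: on a band-limited PIV grid the noise-amplification
branch of the L-curve is bounded (the inverse gain is capped at Nyquist),
the corner degenerates, and the curvature maximum lands on the
oversmoothing bend — in round-trip benchmarks it cost 30–50% of the total
force. An optional inverse filter for the PIV window MTF exists but is off
by default; at these settings its bias reduction is outweighed by noise
amplification.

**Total force and contraction metrics.** Total force is
$\sum |T|\,\mathrm{d}A$ over the grid (1 Pa µm² = $10^{-3}$ nN),
restricted to a cell mask when given — the mask matters, because the
magnitude integral accumulates reconstruction ringing over empty
substrate. Contraction and relaxation velocities are the extrema of the
central-difference derivative of the mean bead-displacement magnitude;
displacement-based velocity is robust to the regularization choice, unlike
force-based velocity.

The round-trip benchmark (forward oracle → bead rendering → PIV → FTTC →
masked total force) recovers the generator's $\sum_i |F_i|$ with a median
error under 5% across balanced 2–6-adhesion sets. The random sets enforce a
25 µm minimum separation: a ± force pair much closer than the measurement
resolution is a physically unresolvable dipole (a 10 µm pair lost 73% of
its magnitude to cancellation), and the force-transmitting sites of real
contracting cardiomyocytes — cell ends and costameres — are tens of
micrometres apart. The simulation does not model bead detachment, focal
drift, finite substrate thickness or out-of-plane traction.

## Gap-FRAP

The bleached-ROI, reference-cell and background series are combined by
double normalization, $F(t) = \frac{(B-bg)/(R-bg)}{\langle \text{same
ratio} \rangle_{\text{pre-bleach}}}$, so the pre-bleach level is exactly 1
and any multiplicative acquisition photobleach shared by both cells cancels
identically (the generator's drift test verifies this to machine
precision). The bleach frame, when not given, is the largest single-frame
drop. Recovery is fit as $F(t) = F_\infty - \sum_i A_i e^{-k_i t}$ with one
or two components; the order is chosen by corrected AIC unless forced, a
negative fitted amplitude falls back to one component, and the
amplitude-weighted rate constant is $k_{FRAP} = \sum A_i k_i / \sum A_i$ —
on noise-free biexponential input this identity is exact. The mobile
fraction is $(F_\infty - F_{0^+})/(1 - F_{0^+})$. Curves with no measurable
recovery (an isolated cell without neighbours: total amplitude below 2% of
the bleach depth) report `k_frap = NA` rather than an arbitrary rate.
Recovery across $k \in \{0.005, 0.02, 0.08\}\,s^{-1}$ on 5-minute, 2-second
curves at 2% noise holds the median error under 1%.

## Sarcomere architecture

**Orientation mapping.** The α-actinin image is scanned with
50%-overlapping windows (default 12.8 µm, which must be at least three
times the largest spacing in the band). Per window, the 2D FFT power is
restricted to the annulus of spatial frequencies for Z-disc spacings of
1.4–2.6 µm; a window is striated when the band holds ≥ 10% of the non-DC
power. The band-limited peak, refined by a 3×3 centroid (needed to beat
the ~8° angular quantization of a single FFT bin), gives the spacing
(1/|f|) and the striation normal; the reported angle is the Z-disc *line*
direction, perpendicular to the normal, so a myocyte aligned with vertical
grooves reads 90° — the convention used for rose plots where 90° means
perfect longitudinal alignment. A Hann window suppresses spectral leakage
from patch edges.

**Organization score.** Angles are taken relative to the groove axis and
doubled (orientations have period 180°); the organization index is the
strength-weighted resultant length of the doubled angles — 1 when every
striated window agrees, ~$1/\sqrt{n}$ for uniform angles, exactly 0 for
equal orthogonal populations. The index is monotone in the generator's von
Mises concentration over $\kappa \in \{0, 2, 8, \infty\}$. Only ordering
and relative differences are meaningful; the absolute scale of any
particular plotted organization metric elsewhere cannot be reproduced
without its exact window and weighting choices.

**Sarcomere content.** Otsu's threshold, computed on the within-mask
histogram (256 bins), classifies Z-disc vs non-sarcomeric pixels;
$I_{sarc}/Area$ is the summed above-threshold intensity divided by the
cell area in µm². The in-package Otsu operates on arbitrary masked pixel
vectors, which whole-image implementations do not support. Degenerate
(constant) images are flagged rather than forced through.

## Localization statistics

* **Puncta per myocyte nucleus** — puncta are Otsu objects within 0.1–10
  µm²; nuclei are Otsu + hole-fill + ≥ 20 µm²; a nucleus is a *myocyte*
  nucleus when its 2 µm perinuclear ring exceeds the α-actinin Otsu
  threshold (primary cultures contain fibroblasts, which lack perinuclear
  sarcomeric actinin). The rule is deterministic and configurable.
* **Area ratio** — per-channel Otsu areas, numerator/denominator.
* **Junctions per millimetre** — intensity profiles along lines parallel
  to the groove axis, spaced 10 µm (the groove+ridge pitch, so each
  myocyte lane is sampled once). The baseline is a 20 µm rolling median;
  peaks are excursions above β = 3 robust SDs of the *raw* residual with
  2 µm minimum separation, detected on a 1 µm-smoothed profile so
  single-sample noise spikes can neither fake nor split a junction.
  Detection meets 0.95 sensitivity and precision at peak SNR 5.
* **Vinculin** — mean intensity within the cell mask plus focal-adhesion
  area (Otsu-within-mask, ≥ 0.2 µm² objects) normalized to cell area.
* **Compartment partition** — the sarcomeric compartment is every cell
  pixel within 0.65 µm (Euclidean distance transform, ceiling pixel
  radius, so the stated distance errs inclusive — at 0.25 µm/px the
  radius is 3 px) of a Z-disc pixel; the statistic is the in/out ratio of
  per-pixel means. The distance-transform construction matches a
  brute-force per-pixel oracle bit-exactly and is invariant to intensity
  rescaling.

## Group statistics

`compare_groups()` wraps the menu used for these assays — two-tailed
pooled-variance Student's t, ordinary one-way ANOVA, Fisher's exact test on
2×2 event counts (e.g. cells with/without spontaneous events per group),
Mann–Whitney rank-sum, and the paired Wilcoxon signed-rank — with
mean ± SEM per group. Fisher's two-sided p agrees with exhaustive
hypergeometric enumeration for every table with margins ≤ 12, and two-group
ANOVA reproduces $F = t^2$ to 1e-10. No multiple-testing correction is
applied by default, matching per-panel testing practice; Holm adjustment of
ANOVA pairwise comparisons is available behind a flag.

## Problem sizes and reproducibility

Every generator is bit-reproducible under a fixed seed and attaches its
ground truth; no synthetic output is accepted without one. The recovery
studies in the test suite and in `scripts/acceptance.R` use 128 µm bead
fields at 0.5 µm/px, 51–102 µm striation images at 0.1 µm/px, 200 s calcium
traces at 100 Hz, and 10–20 seeds per condition — sizes chosen so the full
battery runs in minutes on one core while keeping Monte-Carlo error well
below every tolerance being checked.

## Known limitations

* The calcium generator's events are copies of the beat pulse; real
  spontaneous release (waves, sparks) has distinct morphology that may be
  easier or harder to classify.
* FTTC assumes an infinite half-space; gels thinner than a few tens of
  micrometres need a finite-thickness correction that is out of scope.
* The orientation mapper reports one angle per window; crossing myofibril
  bundles within a window are summarized by the stronger band component.
* Cell segmentation is an input everywhere, never a responsibility of this
  package.
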