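---
title: "Quantifying synchronized islet calcium dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synchronized islet calcium dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletsync)
```

## The scientific problem

Pancreatic islets secrete insulin in pulses because the β cells of a healthy
islet depolarize and admit Ca²⁺ in near-synchrony: gap-junction coupling
between neighboring β cells turns a hundred noisy oscillators into one
coherent electrical syncytium, often traversed by slow traveling calcium
waves. When islet architecture is disturbed — fewer homotypic β–β contacts,
more intermixing with α and δ cells — this synchrony degrades: the islet
fragments into independently oscillating regions, pairwise functional
connectivity drops, and highly connected "hub" β cells become rare.

`isletsync` implements the quantitative toolchain for studying this
phenomenon from intravital time-lapse fluorescence recordings of a
genetically encoded calcium sensor:

1. **Movie conditioning** — 5 × 5 pixel spatial averaging, exclusion of
   saturated and non-fluorescent pixels, per-pixel linear detrending
   (photobleaching correction), and a rigid-motion gate.
2. **Activity and coordinated area** — classification of pixels as active
   (peak amplitude above 1.5× background), tiling into 5 × 5-pixel block
   traces, and transitive merging of blocks whose time courses correlate
   above 0.7 into coordinated regions; the headline statistics are the
   active fraction and the fraction of active area in the largest
   coordinated region.
3. **Wave dynamics** — peak frequency from the periodogram of the islet
   average, per-block Fourier phases at that frequency, phase lag between
   the extreme regions converted to a time lag, and wave speed as centroid
   distance over time lag, gated on >80% coordinated area and a clear
   spatial phase gradient.
4. **Functional networks** — pairwise Pearson correlation between cell
   traces, links at R ≥ 0.95, hub cells linked to ≥25% of the islet,
   normalized-degree clustering coefficient, characteristic path length and
   global efficiency with the fixed n(n−1) denominator.
5. **Architecture** — nearest-neighbor contact probabilities by category
   (β–β homotypic, β heterotypic, α/δ homotypic, α–δ heterotypic).
6. **Perfusion** — timing of glucose-analog arrival near and far from
   vessels: image-average arrival detection (>5-unit jump), F/F_max
   normalization over a −5..+10 s window, AUC, and across-ROI dispersion
   at +3 s.
7. **Statistics** — Shapiro–Wilk and F-test gated routing to Student,
   Welch or Mann–Whitney tests, plus ROUT outlier removal at Q = 0.1%.

Because no machine-readable imaging data accompany the recordings this
analysis was designed for, the package ships a first-class synthetic islet
generator with exact ground truth, and every stage is validated against it.

## The synthetic islet generator

`generate_architecture()` places cells on a jittered triangular lattice
clipped to an ellipse (aspect 1.4, spacing 12 µm ≈ a β-cell diameter) and
assigns types by radial sorting — β cells in the core, α/δ in the mantle —
blended with a random permutation whose weight is the `intermix` parameter.
`intermix = 0` gives a sorted, control-like islet; `intermix = 1` a fully
intermixed one, spanning the contact statistics of normal and disrupted
architecture. Contacts are all pairs within 1.2× the median
nearest-neighbor spacing.

`generate_calcium_movie()` builds per-cell clean traces and rasterizes them
into a (T, Z, Y, X) movie:

* The slow component is a smoothed square wave (plateau fraction 0.5,
  logistic edge softness 0.15 of a radian) — a relaxation-type waveform on
  which "fast oscillations riding the plateau" are well defined. In the
  `mixed` pattern a fast sinusoid is gated by the slow plateau
  (`0.7·slow + 0.3·slow·fast`); `slow` and `fast` use each component
  alone. Default periods are 120 s (valid range 60–620 s, matching periods
  observed in vivo from ~1 to ~10 min) and 15 s (range 4–31 s).
* K synchronization domains are equal-count angular sectors. Domain phases
  are a common Uniform(0, 2π) rotation plus evenly spaced offsets 2πk/K
  (`phase_mode = "spaced"`): each domain's phase is marginally uniform, but
  domains are maximally phase-separated, which is what "K independent
  domains" must mean for them to be resolvable at all;
  `phase_mode = "independent"` draws fully independent phases, under which
  two domains occasionally coincide by chance.
* Cells within 1.8× the lattice spacing of another domain are **silent**
  (sensor-positive but non-oscillating, held at baseline), and active-cell
  counts are equalized across domains by moving excess border cells into
  the silent band. This models the weakly active cells that separate
  independently oscillating regions in functionally disrupted islets. It is
  also a mathematical necessity of the analysis being validated: optical
  smoothing mixes the signals of interface cells, and a spatial continuum
  of mixed traces transitively bridges any two domains whose clean traces
  are not exactly anti-correlated under a transitive correlation-threshold
  merge. With the silent band, recovered region structure reflects the
  ground-truth domains rather than interface artifacts.
* An optional planar wave (major-axis direction) delays each cell's trace
  by projected distance ÷ `wave_speed_um_s`.
* Acquisition realism: a sensor mosaic silences `1 − sensor_fraction` of
  cells; intensities are baseline 20 + amplitude 100 over background 10;
  z-planes attenuate signal as exp(−depth/100 µm); linear bleaching
  multiplies the mean; additive Gaussian noise (`noise_sd`, so SNR =
  100/noise_sd); clipping at `saturation_value` (default 4095, a 12-bit
  detector).

Defaults describe one islet of 100 cells (75% β, 15% α, 10% δ) imaged at
0.2 Hz for 10 minutes at 1 µm/pixel in a single plane — one of the
acquisition configurations the analysis targets (0.03–1 Hz, 1–12 planes,
512 × 512 frames at ~1 µm sampling). These sizes keep a full
simulate-analyze round trip to a few seconds, so ensemble validation (tens
of movies) runs at desk scale.

`generate_perfusion_movie()` emits a 1 Hz single-plane movie in which a
sinuous vessel rises first with a logistic bolus and tissue pixels follow
with delay proportional to distance from the vessel (default 0.15 s/µm),
Gaussian-smoothed to mimic diffusion; the per-pixel arrival-delay map is
stored as ground truth.

What the generator does **not** emulate: biophysical electrophysiology (no
conductance-based oscillator models), vascular network topology,
photon-accurate (Poisson) noise, non-rigid tissue motion, or z-dependent
optical blur. Passing tests therefore demonstrate that the analysis
recovers the statistical structure it assumes — synchrony, phase
gradients, domain partitions, contact statistics — not that it is robust
to every artifact of real microscopy.

## Numerical and design choices

**"Significant fluorescence".** The exclusion threshold is undefined in
the original description; the default is the Otsu threshold of the
temporal-mean image (parameter-free and reproducible), overridable via
`min_mean_intensity`.

**Border handling.** The 5 × 5 filter uses reflect padding so border
pixels are not dimmed. Detrending is per pixel (the alternative — detrend
only the islet average — is not what a per-pixel analysis needs).

**Activity background.** A noise-only trace of length T has an expected
peak amplitude (max minus 10th percentile) of roughly
σ·(qnorm(T/(T+1)) + qnorm(0.9)) ≈ 3.7σ at T = 120 — always above 1.5σ, so
the 1.5× rule applied to the raw noise scale would classify pure noise as
active. The package therefore takes that expected noise-extreme amplitude
as the "background" of the 1.5× rule, and thresholds peak prominence at
twice the same quantity. `classify_active()` keeps the explicit
`background` argument so the rule itself is transparent.

**Merging without contiguity.** Coordinated regions are the connected
components of the >0.7 correlation graph over active blocks; spatial
contiguity is *not* required (synchronized but non-adjacent areas are
colored alike), though `require_contiguity = TRUE` is available.
Correlation is zero-lag Pearson on detrended block means; lags are the
phase analysis's job. Peak-coincidence co-seeding (≥50% of peaks aligned
within ±1 frame) is reported as a diagnostic
(`peak_coincidence_pairs()`), not as an extra merge criterion — the
partition is defined by the correlation graph alone.

**The time-lag formula.** The wave analysis this package reproduces prints
`dt = (1/f)·tan⁻¹(φ₁ − φ₂)` with f the *sampling* frequency — a
dimensionally unusual form (arctangent of a phase difference, scaled by
the frame rate). Both it (`mode = "as_printed"`, the default, for
fidelity) and the conventional `dt = Δφ/(2π·f_peak)`
(`mode = "standard"`) are implemented; parameter-recovery tests use the
standard mode, which converges to the true speed as noise vanishes.

**"Clear phase transition".** Quantified as R² ≥ 0.5 of the linear fit of
included-block phase against position (phases first rotated so their
circular mean is zero, avoiding ±π wrap-around). The >80% coordinated-area
gate is strict, as stated.

**Network conventions.** Links use R ≥ R_th (the results convention);
hubs use ≥25% (the figure convention over the text's "more than 25%");
both boundaries are configurable. The printed clustering coefficient
equals normalized degree — it is implemented as printed, with conventional
transitivity available as `method = "transitivity"` for comparison.
Characteristic path length and global efficiency divide by n(n−1)
regardless of reachability, so disconnected pairs contribute zero.
Threshold calibration fits a least-squares line to log₁₀(count) vs
log₁₀(degree) over occupied nonzero-degree bins and accepts R² ≥ 0.9 with
≥5 bins; link significance uses a circular time-shift permutation null,
which preserves autocorrelation.

**Perfusion boundaries.** The 10 µm near/far boundary is assigned *near*
(the original wording leaves exactly 10 µm unassigned); ROI distance is
measured center-to-vessel; arrival-frame indices are 0-based so that
index × frame interval is the arrival time; the arrival "unit" is a raw
intensity unit of the recording.

**Statistics.** The normality gate is Shapiro–Wilk alone (the "visual"
check is not computable). ROUT is implemented from its published
description for the constant-only model: median location, robust scale
from the 68.27th percentile of absolute residuals with the n/(n−1)
small-sample correction, and Benjamini–Hochberg FDR at Q on the residual
t-scores, largest first. Removing flagged points cannot raise any
percentile of the absolute residuals about the original robust location
(the invariant the tests assert); the re-estimated scale itself can move
slightly because the median shifts. Replicate policy is explicit: islets
are technical replicates averaged per mouse for architecture comparisons,
and biological replicates for intravital oscillation metrics.

**Degenerate inputs.** Constant traces are excluded from networks with a
warning and yield errors from spectral and normalization operations;
zero kept or active pixels raise undefined-result errors rather than NaN;
a zero time lag flags infinite wave speed and is excluded.

## What the validation shows

The test suite and `scripts/acceptance.R` recompute, from fresh synthetic
data: exact closed-form graph metrics; equivalence of the region partition,
shortest paths and correlation means with brute-force oracles; recovery of
a 30 µm/s planar wave within a few percent (standard mode, 10 seeds);
recovery of K ∈ {1, 2, 4} domains with the largest coordinated fraction at
1, 0.5 and 0.25 (±0.03) and the correct region count; zero links among
independent traces at R_th = 0.95 across 100 seeds; strictly decreasing
β–β homotypic contact probability with intermixing; decision-tree type-I
error at the nominal 5% (2000 replicates) and ROUT specificity ≥99% on
clean samples; and byte-identical pipeline outputs for identical seed and
configuration.

The printed group differences of the in vivo study (coordinated fractions,
R_avg, hub fractions, contact probabilities of control vs architecture-
disrupted islets) derive from recordings that are not available in
machine-readable form; they are not reproduced numerically, though the
generator's control-like and intermixed regimes produce the same
qualitative contrasts.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1, n_domains = 2, noise_sd = 20)
arch <- generate_architecture(cfg)
gen <- generate_calcium_movie(arch, cfg)

sm <- smooth_movie(gen$movie)
mask <- mask_islet(sm)
dtm <- detrend_linear(sm)
blocks <- block_traces(dtm, mask)
map <- merge_coordinated(blocks, r_min = 0.7)

largest_coordinated_fraction(map)  # ~0.5: two equal domains
n_major_regions(map)               # 2

net <- build_adjacency(extract_cell_traces(dtm, gen$truth), R_th = 0.95)
network_metrics(net)$R_avg         # low: anti-phase halves cancel
```

## Known limitations

* The synthetic generator validates the analysis against its own
  statistical assumptions; real recordings add motion, optical blur,
  heterogeneous expression and non-stationary frequencies that are only
  partially modeled (rigid shifts, mosaicism, bleaching).
* The transitive correlation merge cannot, in principle, separate
  adjacent domains whose interface cells remain active with smoothly mixed
  signals; the generator's silent interface band reflects that boundary
  condition rather than removing it.
* Phase estimation uses a single periodogram bin (no interpolation), so
  frequency resolution is 1/(T·Δt); short recordings quantize the peak
  frequency accordingly.
* ROUT is implemented for the constant-only (single-sample) model, which
  is how it is used here; regression-model ROUT is out of scope.
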