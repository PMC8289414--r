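# isletsync

Quantitative analysis of synchronized intra-islet Ca²⁺ oscillations from
time-lapse fluorescence imaging — with a ground-truthed synthetic islet
generator so the whole pipeline is testable without external data.

## The problem

β cells in a healthy pancreatic islet are electrically coupled through
gap junctions at their homotypic β–β contacts, so their intracellular
Ca²⁺ oscillations — the proximal trigger of pulsatile insulin secretion —
are synchronized across the islet, often as slow traveling waves. When
islet architecture is disrupted and β cells lose homotypic neighbors, the
islet can fragment into independently oscillating regions, overall
functional connectivity drops, and highly connected "hub" β cells
disappear. `isletsync` implements the measurements used to quantify this
in vivo:

* **Movie conditioning** — 5 × 5 pixel smoothing, Otsu-based
  fluorescence masking with saturation exclusion, per-pixel linear
  detrending, rigid-motion gating (trim at 0.5 cell-width displacement).
* **Activity & coordinated area** — pixels are *active* when their peak
  amplitude exceeds 1.5× background; 5 × 5-pixel block traces that
  correlate above R = 0.7 are merged transitively into coordinated
  regions. Headline statistics: active fraction and the largest
  coordinated fraction of active area.
* **Wave dynamics** — peak frequency f from the periodogram of the islet
  average; per-block Fourier phases φ at f; the extreme-phase lag
  converted to a time lag (both the literal `dt = (1/f)·tan⁻¹(φ₁−φ₂)`
  form and the standard `Δφ/(2πf)` form); speed = centroid distance / dt,
  gated on >80% coordinated area and a clear spatial phase gradient.
* **Functional networks** — pairwise Pearson R between cell traces,
  links at R ≥ 0.95 (power-law calibration scan included), hubs = cells
  linked to ≥25% of the islet, clustering coefficient C_i = degree/(n−1)
  as used in this analysis, characteristic path length
  L = Σ L_jk / (n(n−1)) and global efficiency
  E_glob = Σ 1/L_jk / (n(n−1)).
* **Islet architecture** — nearest-neighbor contact probabilities over
  the four categories ββ, β–(α/δ), (αα|δδ), αδ, with per-mouse averaging
  for group comparisons.
* **Perfusion kinetics** — glucose-analog arrival frame (first >5-unit
  image-average jump), near/far ROI classes about a 10 µm vessel
  distance, F/F_max normalization over −5..+10 s, AUC, and across-ROI SD
  at +3 s.
* **Statistics** — the Shapiro–Wilk → F-test → Student/Welch/Mann–Whitney
  decision tree, and ROUT outlier removal at Q = 0.1%.

The synthetic generator (`generate_architecture`,
`generate_calcium_movie`, `generate_perfusion_movie`) produces islet
architectures with tunable β/α/δ intermixing, movies with slow/fast/mixed
oscillation patterns, K phase-independent synchronization domains, planar
waves of set speed, sensor mosaicism, noise, bleaching and saturation —
all with exact per-cell ground truth.

## Worked example

A two-domain islet — the signature of disrupted synchrony — simulated and
analyzed end to end:

```r
library(isletsync)

cfg   <- simulation_config(seed = 1, n_domains = 2, noise_sd = 20)
arch  <- generate_architecture(cfg)
gen   <- generate_calcium_movie(arch, cfg)

sm     <- smooth_movie(gen$movie)
mask   <- mask_islet(sm)
dtm    <- detrend_linear(sm)
blocks <- block_traces(dtm, mask)
map    <- merge_coordinated(blocks, r_min = 0.7)

arch
#> architecture_map: 100 cells (alpha 15, beta 75, delta 10), 189 contacts
map
#> coordination_map: 287 blocks (287 active), 2 regions, r_min 0.70
largest_coordinated_fraction(map)
#> [1] 0.5089829
n_major_regions(map)
#> [1] 2

net <- build_adjacency(extract_cell_traces(dtm, gen$truth), R_th = 0.95)
round(network_metrics(net)$R_avg, 3)
#> [1] -0.003
contact_probabilities(arch)
#> contact_probabilities over 189 contacts:
#>          beta_homotypic        beta_heterotypic   alpha_delta_homotypic
#>                   0.709                   0.217                   0.032
#> alpha_delta_heterotypic
#>                   0.042
```

The two anti-phase domains are recovered exactly (2 regions, largest
coordinated fraction ≈ 0.5), the islet-wide mean pairwise correlation
collapses to ≈ 0 because the halves cancel, and the sorted architecture
(intermix 0.1) shows the high β–β homotypic contact share typical of a
control islet.

`run_pipeline(run_config(seed = 1, out_dir = "out"))` drives the whole
chain (simulate → condition → coordination → wave → network →
architecture) and writes `results.json`, block/phase tables, and a
reproducibility manifest; identical seed and configuration give
byte-identical outputs.

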