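# pelletmetrics

Quantitative morphology and viability analysis of filamentous biopellets.

Filamentous microorganisms such as the rebeccamycin producer *Lentzea
aerocolonigenes* grow in submerged culture as dense spherical hyphal
pellets. Pellet size, shape and internal viability structure are strongly
linked to secondary-metabolite productivity, and process interventions
(e.g. glass-bead addition) are judged by how they shift these descriptors.
pelletmetrics implements the full quantification stack such studies need,
for R users in bioprocess and biological image analysis:

* **Brightfield macro-morphology** — adaptive local-mean binarization,
  watershed splitting of fused pellets, per-object measurement of
  projected area, perimeter, area-equivalent circle diameter
  $d_a = \sqrt{4A/\pi}$, circularity $4\pi A/P^2$, min/max Feret diameters
  (rotating calipers), the 200 µm²/edge exclusion filters, and normalized
  number- (q0) and volume-weighted (q3) size density distributions.
* **Stained-slice viability (CLSM)** — per-channel Otsu binarization,
  closing with bounded hole filling, and the three-region decomposition of
  green/red masks into live, dead and overlap area shares; live ratio =
  living area / total (union) area.
* **Pulse-shape flow cytometry** — per-particle analysis of spatially
  resolved FSC/SSC/FLG/FLR profiles: signal length, pellet classification
  (FSC core saturation + length > 80 µm), compactness (SSC FWHM / signal
  length; √3/2 for a homogeneous projected sphere), FDA- and PI-based
  viable layers, viability factor 2·vl/L, and the autofluorescence factor
  (FLG/FSC area ratio on unstained runs).
* **Kinetics & statistics** — biomass-specific productivity
  $q_P = (1/X)\,dP/dt$ and per-day one-way ANOVA comparisons between
  conditions (α = 0.05), with explicit handling of skipped and degenerate
  days.
* **Synthetic data with ground truth** — seeded generators for brightfield
  fields (log-normal pellet sizes, fuzzy hyphal coronas), concentric
  live/dead slice pairs, projected-sphere pulse profiles with FSC
  saturation, and logistic growth / delayed production cultivation series.
  Every analysis stage is validated against these generators' analytic
  truth.

## Worked example

```r
library(pelletmetrics)

# --- brightfield morphology on a synthetic field with known truth
g   <- generate_pellet_image(image_gen_params(
         image_width_px = 1024L, image_height_px = 768L,
         n_pellets = 30L, seed = 7L))
res <- analyze_pellet_image(g$image)
m   <- res$measurements
sprintf("n = %d pellets | mean d_a = %.1f um (truth %.1f)",
        nrow(m), mean(m$equivalent_diameter_um),
        mean(g$truth$true_equivalent_diameter_um))
#> "n = 30 pellets | mean d_a = 200.5 um (truth 200.2)"

# --- stained-slice viability
pair <- generate_clsm_pair(260, 223, 12, noise_sd = 0.04, seed = 7L)
analyze_slice(pair$green, pair$red)
#> <viability_shares> live 0.097 | dead 0.735 | overlap 0.168 | live ratio 0.097 | total 5.309e+04 um^2

# --- pulse-shape flow cytometry on a seeded population
pop <- generate_pulse_population(n = 60L, seed = 7L)
s   <- summarize_population(pop$profiles, min_pellets = 50L)
s$summary[, c("n_pellets", "signal_length_mean_um", "compactness_mean")]
#>   n_pellets signal_length_mean_um compactness_mean
#> 1        53              191.3962         0.874086

# --- productivity kinetics and the per-day statistics
ser <- generate_cultivation_series(cultivation_gen_params(
         P_max = 95, production_rate = 1.2, seed = 7L))
qp  <- specific_productivity(ser)
anova_oneway(list(c(1, 2, 3), c(2, 3, 4)))
#> One-way ANOVA: F(1, 4) = 1.5, p = 0.2879 (not significant at alpha = 0.05)
```

The measured mean diameter tracks the generator's truth to a fraction of a
pixel; the slice decomposition reports a production-phase pellet with a
thin viable rim (live ratio 0.10); the pulse population's compactness sits
just above the homogeneous-sphere value √3/2 ≈ 0.866 because the dense
core saturates FSC; and the two-group ANOVA on the classic hand-computed
fixture returns exactly F = 1.5 on (1, 4) degrees of freedom.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic data
and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates both conditions' raw data (TIFF fields + truth CSVs, slice pairs, pulse-profile CSV/JSON files, cultivation series) |
| `02_morphology.R` | segments every field, pools per-pellet measurements, builds q0/q3 distributions |
| `03_viability_clsm.R` | quantifies the stained slices, writes shares and QC overlays |
| `04_flow_cytometry.R` | reads the pulse dialect, computes per-particle metrics and population summaries |
| `05_kinetics_anova.R` | q_P per condition and per-day diameter ANOVA |
| `06_full_demo.R` | the end-to-end two-condition, ten-day demonstration via `run_demo()` |

Run them in order with `Rscript analysis/01_simulate.R` etc.

## Documentation

The methods vignette (`vignettes/pelletmetrics-methods.Rmd`) documents the
underlying models, every tunable parameter with units and defaults, the
conventions adopted where the field's practice is ambiguous (live-ratio
denominator, bounded hole filling, the dimensional repair of the PI
viable-layer estimator), and the known limitations of validating against
synthetic data.
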