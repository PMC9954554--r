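# izgradient

Quantifying the CD8+ cytotoxic T-cell density gradient across the tumor
epithelium–stroma interface in papillary urothelial carcinoma, and relating
it to recurrence-free survival (RFS) after BCG immunotherapy.

Papillary bladder tumors rarely present a broad invasive margin: tumor–host
interaction happens along a thin, elongated epithelium–stroma interface.
Absolute CD8+ densities per compartment wash this signal out; what carries
prognostic information is *where* the cells sit relative to the interface.
`izgradient` implements, for pathologists and computational-pathology
researchers:

- **Interface-zone band sampling.** From a labeled tissue raster
  (epithelium / stroma / artifact / background) the epithelium–stroma
  boundary is traced, boundaries shorter than 1000 µm are removed, and each
  tissue pixel within 150 µm of a retained boundary gets a signed band rank
  r: magnitude ⌈d/w⌉ for Euclidean distance d and band width w = 10 µm,
  positive on the epithelial side, negative on the stromal side.
- **Gradient indicators.** Per-band CD8+ densities ρᵣ (cells/mm²) give the
  *immunodrop* ID(r) = ρ₋ᵣ/ρᵣ (ratio of paired stromal to epithelial band
  densities; >1 means density drops entering the epithelium) and the
  *center of mass* CM = Σᵢ rᵢρᵢ / Σᵢ ρᵢ (density-weighted mean band rank;
  <0 means CD8+ mass skewed toward stroma), each over a grid of
  interface-zone widths (20–300 µm).
- **Survival-model selection.** Censoring at 60 months, an event-stratified
  117/40 train/test split, univariable Cox screening (p < 0.05, lowest-p
  indicator variant), enumeration of all covariate subsets of size ≥ 2, an
  all-covariates-significant filter, ranking by mean Harrell's C over
  5-fold cross-validation, hold-out evaluation, Kaplan–Meier/log-rank
  stratification, and a 3-point recurrence risk score (G3 grade + positive
  repeat resection or recurrent tumor + medium/high immunodrop tertile;
  0–1 low, 2 intermediate, 3 high).
- **Synthetic data.** Generators for papillary masks (elongated epithelial
  fronds in stroma), band-structured Poisson cell patterns with a
  controllable stroma→epithelium decay, and proportional-hazards cohorts
  whose hazard depends on history, grade and immunodrop — so the entire
  pipeline is testable without patient data.

## Worked example

```r
library(izgradient)

spec <- mask_spec(canvas_um = c(1200, 1200), pixel_size_um = 2,
                  n_papillae = 5, seed = 42)
mask <- generate_papillary_mask(spec)
interfaces <- filter_short_boundaries(extract_interface(mask), 1000)
interfaces
#> interface_set: 2 boundary polyline(s), total 7746.9 um
bands <- compute_band_map(mask, interfaces)
bands
#> band_map: 600 x 600 px, 10 um bands, ranks -15..15, IZ area 1.189 mm2

cells <- generate_cells(bands, gradient_spec(rho_s = 300, rho_e = 100,
                                             lambda = 0.5, seed = 43))
profile <- band_density_profile(assign_cells_to_bands(cells, bands),
                                bands$areas_mm2)
variant_grid(profile, widths_um = 20)[, c("variant_label", "value")]
#>   variant_label      value
#> 1    ID 0-10 um  4.0529334
#> 2   ID 10-20 um  4.4412045
#> 3    CM 0-10 um -0.6041903
#> 4    CM 0-20 um -0.9608141
```

The slide was generated with a stromal plateau of 300 cells/mm² decaying
into the epithelium from 100 cells/mm² (λ = 0.5 per band), and the
indicators read it back: immunodrop well above 1 (density drops ~4.4-fold
from the 10–20 µm stromal band to its epithelial counterpart) and a
negative center of mass (CD8+ mass on the stromal side).

```r
cohort <- simulate_cohort(cohort_spec(n = 157, seed = 7))
res <- run_survival(cohort,
  features = c("id_value", "cm_value", "g3", "pt1", "retur_or_recurrent",
               "positive_retur", "density_epithelial"),
  indicator_groups = list(id = "id_value", cm = "cm_value"),
  config = list(seed = 11))
res$ranking
#>                           model n_covariates mean_validation_cindex   aic train_cindex
#> 2 cm_value + retur_or_recurrent            2                 0.7104 260.5       0.7172
#> 1 id_value + retur_or_recurrent            2                 0.6851 262.9       0.7025
res$best
#> Cox model: cm_value + retur_or_recurrent (n = 117, events = 30)
#>                    term   coef     hr     se         p
#>                cm_value -1.268 0.2814 0.4295 0.0031547
#>  retur_or_recurrentTRUE  1.809 6.1023 0.5450 0.0009042
#> logLik = -128.241, AIC = 260.483, train C = 0.7172
table(res$cohort$risk_category)
#>          low intermediate         high
#>           62           62           33
```

With 117 training patients and 30 events, screening is honest and noisy: on
this seed G3 misses the 0.05 cutoff and the center of mass (hazard ratio
0.28 per rank unit: higher CM, i.e. CD8+ mass toward the epithelium, is
protective) pairs with the history flag (HR 6.1) as the best
cross-validated model. The risk score still stratifies the full cohort
into low/intermediate/high groups.

A thin command-line wrapper with `generate` / `spatial` / `survival` /
`all` subcommands over a YAML config lives at `inst/cli/izgradient`.

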