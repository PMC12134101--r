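# avlipidomics

Quantitative lipidomics of human aortic-valve tissue across the stages of
fibro-calcific aortic valve disease (FCAVD): mildly diseased, fibrotic and
calcific leaflet sections.

Aortic-valve disease progresses through lipid infiltration and local lipid
remodeling — lipoprotein-derived cholesteryl esters (CE) and sphingomyelin
(SM) accumulate in the leaflet, and enzymatic conversion of PC to LPC
(lipoprotein-associated phospholipase A2) and SM to ceramide
(sphingomyelinase) primes lipoprotein aggregation, fibrosis and
calcification. `avlipidomics` is a tidyverse-style R package for the full
quantitative analysis of such a tissue lipidome, from raw
internal-standard-spiked peak areas to disease-stage statistics:

* **Nomenclature** — a shorthand parser for ~480 species over a 28-subclass
  registry (`CE 18:2`, `SM 32:0;O3`, `Cer 18:1;O2/24:0`, `PE P-38:4`),
  with sum-composition collapse, category mapping (NL / GPL / lysoGPL /
  SP / ST) and elemental-formula composition. Ceramide subclasses (Cer,
  dhCer, deoxyCer, phytoCer, sphdCer) are resolved from the sphingoid
  base.
* **Quantification** — single-point class-matched calibration
  `conc = (A_analyte / A_ISTD) · (M0_ISTD / M0_analyte) · n_spike / m_tissue`
  with adduct/in-source-fragment channel summation, type I isotopic
  correction (monoisotopic-fraction ratio), type II correction (M+2
  subtraction from the ΔDB = 1 neighbour, cascaded within homologous
  series), deuterium-purity handling, calibration-linearity screening and
  recovery rates.
* **Statistics** — class totals, lipoprotein-proxy ratios (LPC/PC, Cer/SM,
  SM/PC, LPE/PE, CE/TG), stage fold changes, Welch t and one-way ANOVA,
  volcano tables with the joint FC > 1.5 & p < 0.05 gate, heatmap and
  distribution-plot preparation.
* **Trends** — one-fifth-minimum imputation, stage averaging, z-scoring and
  Gaussian-mixture clustering (k = 5, full covariance) of stage
  trajectories into deterministic, size-ordered clusters.
* **Topology** — structure-aware UMAP of the lipidome: exact
  maximum-common-edge-subgraph (MCES) distances between class backbones
  (compiled branch-and-bound with myopic thresholding), PCA reduction,
  and a weighted feature matrix of z-scored abundances plus chain and
  backbone features.
* **Sphingolipid flows** — decomposition of each ceramide into sphingoid
  base, subclass and N-acyl, aggregated into mass-conserving Sankey link
  tables, with a very-long-chain fatty acid (C22–C26) flag.
* **Synthetic studies** — a ground-truthed generator that emulates the
  cohort design (21 patients × 3 sections, ~20 mg tissue), the reference
  class totals, the published stage/sex effect structure, 0.16%
  missingness, and a forward measurement model (response factors,
  isotopologue interference, ISTD spikes) that `quantify_areas()`
  inverts exactly at zero noise.

## Worked example

```r
library(avlipidomics)

sim      <- simulate_av_study(seed = 7)                # ground-truthed study
peaks    <- simulate_peak_areas(sim$concentrations, seed = 8)
metadata <- unique(sim$concentrations[, c("sample_id", "patient", "sex",
                                          "morphology", "stage", "tissue_mass_mg")])
conc     <- quantify_areas(peaks, metadata)            # pmol/mg wet tissue

ratio_metric(conc, "LPC_PC")
#> Class ratio LPC_PC over 63 samples
#> # A tibble: 3 × 5
#>   stage             mean     sd     n fold_change
#>   <chr>            <dbl>  <dbl> <int>       <dbl>
#> 1 calcific        0.229  0.165     21        3.94
#> 2 fibrotic        0.134  0.0577    21        2.31
#> 3 mildly_diseased 0.0581 0.0221    21        1
```

The LPC/PC ratio — the LpPLA2 activity proxy — rises ~2.3-fold in fibrotic
and ~3.9-fold in calcific sections of this simulated cohort (the generator
plants 2.8/4.0; n = 21 gives sampling spread). Class totals show the CE
surge that dominates leaflet lipid accumulation:

```r
dplyr::filter(class_totals(conc, summarise_by = "stage"), subclass == "CE")
#> # A tibble: 3 × 5
#>   subclass stage           mean_total_pmol_mg sd_total_pmol_mg     n
#> 1 CE       calcific                    27922.           10058.    21
#> 2 CE       fibrotic                    34038.           14802.    21
#> 3 CE       mildly_diseased             11723.            3348.    21
```

Downstream steps chain the same way:

```r
imputed <- impute_min_fifth(conc)
sig     <- dplyr::filter(anova_by_lipid(imputed), p_value < 0.05)$lipid
trends  <- gmm_trend_cluster(stage_average(dplyr::filter(imputed, lipid %in% sig)))
autoplot(trends)

emb <- embed_lipidome(topology_features(imputed), seed = 42)
plot_embedding(emb)

plot_sphingo_flow(sphingo_flow(conc))
```

`run_pipeline(config)` executes the whole chain from a YAML/list
configuration and writes every table as TSV plus a JSON run manifest.

## Scope

The package starts from integrated peak areas (transition-report exports);
peak picking, retention-time alignment, MS/MS identification and raw-file
handling are out of scope, as is figure styling beyond the provided
`ggplot2` helpers.
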