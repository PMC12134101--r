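---
title: "Models and methods behind avlipidomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind avlipidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the measurement
model inverted by the quantification step, the statistical procedures and
their assumptions, the clustering and embedding methods, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The quantification model

A tissue lipidomics run reports, per sample, integrated signal areas for
each analyte on one or more channels (adducts and in-source fragments).
With a class-matched internal standard (ISTD) spiked at a known amount
before extraction, the concentration of analyte $a$ in a sample of wet
tissue mass $m$ (mg) is obtained by single-point calibration:

$$
c_a \;=\; \frac{A_a}{A_{\mathrm{ISTD}}}\cdot
\frac{f_0(\mathrm{ISTD})}{f_0(a)}\cdot
\frac{n_{\mathrm{spike}}}{m}
\quad\left[\tfrac{\mathrm{pmol}}{\mathrm{mg}}\right],
$$

where $f_0(x)$ is the monoisotopic fraction of species $x$ — the share of
its full isotopologue envelope carried by the M0 peak,
$f_0 = \prod_e p_e^{n_e}$ over elements $e$ with lightest-isotope
abundance $p_e$ and atom count $n_e$. The ratio
$f_0(\mathrm{ISTD})/f_0(a)$ is the **type I isotopic correction**: it puts
both signals on the scale of their whole envelopes and reduces to the
familiar carbon-count-only factor when the formulas differ only in
carbons. Deuterated standards contribute $\pi^{n_D}$ to their $f_0$,
where $\pi$ is the isotopic purity per label position (default 0.98,
configurable per standard; certificate values should be supplied when
known). The purity impurity (D→H) shifts mass *down*, so it never
contaminates the M+1/M+2 region — this is why a scalar attenuation
suffices.

**Type II correction** removes the M+2 isotopologue of the species with
one more double bond that co-elutes on a species' monoisotopic peak.
Within each *homologous series* — same subclass, same ether linkage, same
carbon and oxygen count (and, for chain-resolved species, the same chain
skeleton, since chromatography separates isobars of different chain
makeup) — areas are processed from the most unsaturated member downwards:

$$
A'_{(C,d)} = \max\!\left(0,\; A_{(C,d)} - A'_{(C,d+1)}\cdot r_2(C,d+1)\right),
$$

with $r_2 = \mathrm{M{+}2}/\mathrm{M0}$ computed from the isotopologue
distribution of the $(C,d{+}1)$ member (polynomial convolution of
per-element isotope vectors; abundances from a fixed, configurable table:
$^{12}$C 0.9893, $^{1}$H 0.999885, $^{14}$N 0.99636, $^{16}$O 0.99757,
$^{31}$P 1.0). The cascade uses corrected upstream areas, so on noise-free
data with exactly this interference structure the correction is an exact
inverse. Clipping at zero is the documented behaviour for over-subtraction.

Two diagnostics mirror common laboratory practice. `fit_calibration()`
fits area on amount by OLS and reports the **linear range** as the widest
contiguous window of calibration levels within which a refitted line
leaves every level within a relative tolerance (default 20%).
`linearity_screen()` regresses calculated concentration on summed area
per lipid across samples and flags lipids with $R^2 < 0.8$ and samples
with externally studentized residuals beyond $|3|$; residuals are
computed in both regression directions because an inflated-area sample is
a leverage point in one direction but a clean outlier in the other, and
a leave-one-out fallback handles the degenerate case where deleting the
point leaves an exact fit. Thresholds are defaults, not study-derived
values. Recovery rates are $100\cdot\bar A_{\text{before}}/\bar
A_{\text{after}}$ for pre- versus post-extraction spiking.

## Differential statistics

All statistics operate on the long concentration table (one row per
lipid × sample, NA = not detected).

* **Fold changes** are ratios of group arithmetic means of concentrations
  (not means of per-patient ratios); the per-sample-ratio alternative is
  available for the class ratios through their sample tables.
* **Class ratios** (LPC/PC, Cer/SM, SM/PC, LPE/PE, CE/TG) are per-sample
  ratios of class totals, summarized per stage; dhCer, deoxyCer,
  phytoCer and sphdCer count toward the Cer pool. Samples with a zero
  denominator are excluded with a warning.
* **Tests**: Welch's unequal-variance t (two-sided) and classical
  unpaired one-way ANOVA across the three stages. The unpaired ANOVA is
  used although sections share patients — the paired structure is part of
  the generator and available to users, but the default mirrors the
  unpaired convention for this analysis. No multiple-testing adjustment
  is applied by default (raw p < 0.05 reporting); Benjamini–Hochberg is a
  `p_adjust = "BH"` switch in `volcano_prep()`.
* **Volcano tables** require both |fold change| beyond 1.5 (either
  direction) and p < 0.05; lipids missing in more than half of either
  group are excluded.
* **Heatmap preparation**: one-fifth-minimum imputation, then
  $\log(x + g)$ with guard $g = 10^{-3}\cdot\min(x > 0)$ so zeros stay
  finite, then per-row centering and unit scaling; constant rows are
  dropped with a warning. The additive guard breaks exact scale
  invariance at the $10^{-4}$ level, which is documented rather than
  hidden.

Because concentrations are log-normal-ish and group sizes are ~21, the
raw-scale Welch test is slightly conservative; the calibration checks in
the test suite verify the type-I error stays within 0.05 ± 0.01 under the
generator's dispersion.

## Trend clustering

The trend analysis averages each lipid (after one-fifth-minimum
imputation of missing cells) to the three stage means, z-scores the
triplet, and fits a k = 5 Gaussian mixture with unconstrained covariance,
assigning each lipid to its maximum-posterior component. Two numerical
points matter:

1. A z-scored 3-vector has mean 0 and sd 1 — two constraints — so the
   data live on a circle (one degree of freedom). A full-covariance
   mixture in 3-D is therefore singular; the model is fitted in a 2-D
   orthonormal basis of the zero-sum plane, an orthogonal change of
   coordinates that leaves hard assignments invariant. A near-singular
   fit is retried with a conjugate prior as covariance regularization and
   the result flags `regularized = TRUE`.
2. A **flat trajectory is unidentifiable** after z-scoring: with no
   direction of its own, it maps to noise uniformly spread on the
   z-circle, and no clustering method consuming z-scored data can
   recover it as a coherent group. The archetype-recovery tests therefore
   plant five *identifiable* shapes, placed at even 72° spacing on the
   z-circle (monotone up, monotone down, fibrotic peak, fibrotic dip,
   calcific loss) — the identifiability optimum for five shapes in this
   space.

Cluster labels are re-ordered by descending size, making results stable
to component permutation; the EM initialization (model-based hierarchical
agglomeration) is deterministic, and the seed argument covers any
stochastic fallback. The default input set is the ANOVA-significant
lipids (p < 0.05), matching the trend-analysis convention; it is a plain
argument.

## Structure-aware topology

Each subclass is represented by a class backbone: acyl chains truncated
to acetyl stubs (so chain identity never contributes, while slot counts
and head groups do), the sphingoid base truncated, and sugar units kept
schematic. Ceramide variants share the Cer backbone, giving 24 distinct
backbones for the 28 subclasses. The backbone table is an editable TSV.

Pairwise backbone distances are **maximum-common-edge-subgraph (MCES)**
distances, $d = |E_1| + |E_2| - 2\,|\mathrm{MCES}|$, with element labels
and bond orders required to match and connectivity *not* required. The
search is an exact branch-and-bound over injective vertex mappings
(compiled code) with three devices: a connectivity-guided branching
order, candidate ordering by Morgan-refined neighbourhood labels (a
near-isomorphism is walked on the first descent), and a per-edge-type
capacity bound. Distances are **myopic** with a default cap of 15: exact
below the cap, reported as the cap beyond it. The cap is a computational
budget in the same spirit as thresholded MCES distances in the
cheminformatics literature — far pairs are all simply "far", and the
near-field structure that the downstream PCA uses is preserved exactly.
Without the cap, boundary pairs such as cardiolipin (whose two identical
phosphoglycerol arms double every search path) against glycosphingolipids
plateau for hours. The bundled 24 × 24 matrix was computed by this same
code; users can substitute their own square TSV.

The distance matrix rows are reduced by centered PCA (10 components
computed, top 5 retained), and the feature matrix concatenates three
blocks: z-scored abundances (log10 of group means by default — the
lipidome spans ~6 orders of magnitude, so z-scoring raw concentrations
would be dominated by the giants), min-max-scaled chain features (total
carbons and double bonds), and the min-max-scaled backbone PCA scores
mapped through each species' subclass. Per-block weights default to 1
and are exposed as study-tunable parameters. UMAP (Euclidean, 15
neighbours, `min_dist` 0.1 — the field's library defaults, documented as
such) embeds the matrix; with a fixed seed and single-threaded SGD the
coordinates are bit-reproducible. Coordinates carry no contract beyond
determinism and neighbourhood preservation: stochastic-gradient UMAP
schedules updates over rows, so row order changes coordinates (though
not the recovered cluster structure), and distances between far clusters
are not metrically meaningful.

## Sphingolipid flows

Chain-resolved sphingolipids split into sphingoid base (first chain),
subclass, and N-acyl (second chain). Ceramide subclasses key on the base
oxygenation/unsaturation pattern — 18:1;O2 sphingosine → Cer, 18:0;O2 →
dhCer, 18:1;O deoxysphingosine → deoxyCer, ;O3 → phytoCer, 18:2;O2 →
sphdCer — at any base chain length; glycosylated classes keep their
head-group subclass with the base annotated. Flow tables sum mean
concentrations over a sample group (default: mildly diseased sections)
per (base → subclass) and (subclass → acyl) link; both sides sum to the
pool total by construction, and percentages are relative to the pool.
Species-level sphingolipids cannot be decomposed and are excluded with a
count, never silently. The VLCFA flag marks N-acyls of 22–26 carbons
inclusive.

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested:

* **Design**: 21 patients (11 male, 10 female), three sections each
  (mildly diseased, fibrotic, calcific), tissue masses ~N(20, 2²) mg.
* **Panel**: 480 species over the 28-subclass registry. Baseline class
  totals reproduce the reference mildly diseased tissue (CE 10.8, TG
  1.65, PC 0.8, SM 0.76, etherPE 0.27 nmol/mg, with plausible values for
  the remaining classes); within-class species follow a power-law rank
  profile spanning ~6 orders of magnitude, with CE 18:2 the most and SM
  32:0;O3 the least abundant species. Ceramide-family species are
  chain-resolved with base and acyl weights set so that the pool shares
  approximate the reported sphingoid-base (≈74/10/7%) and acyl
  (≈31/21/18%) composition.
* **Effects**: multiplicative per-subclass stage effects planted to
  mirror the headline trends — CE 2.7/2.3, free sterol 2.6/3.0, SM
  1.9/1.8, and class multipliers chosen so the proxy ratios come out at
  LPC/PC 2.8/4.0, Cer/SM 1.5/1.8, SM/PC ≈1.6/1.8, LPE/PE 1.7/1.8 —
  plus sex terms (higher male baseline CE/TG, a female CE surge at the
  fibrotic stage, male-specific elevation of polyunsaturated TG in
  calcific tissue).
* **Noise**: a log-normal patient factor shared across a patient's three
  sections (CV 0.25), species-level log-normal residual (CV 0.4), and
  missing-at-random cells at rate 0.0016. The dispersions are declared
  assumptions — per-species dispersion of real tissue is unknown.
* **Measurement model**: per-subclass response factors (log-normal,
  spread 0.3), multiplicative noise (CV 0.2 by default), ISTD spikes at
  20 × the class baseline total (pmol per ~20 mg sample, i.e. mid-range
  of the endogenous signal), deuterium labels d7 at purity 0.98, and M+2
  isotopologue leakage between ΔDB = 1 neighbours — on by default so the
  default forward model and the default quantification (type II on) are
  exact inverses.

What passing tests show — and what they do not: the generator emulates
the *effect structure* and *measurement arithmetic* of a real study, so
round-trip and recovery tests validate the estimators and corrections.
It does not emulate chromatographic artefacts, batch effects,
identification errors, censoring at the detection limit (missingness is
MAR, not intensity-dependent), or inter-class correlation beyond the
shared patient factor; conclusions about robustness to those phenomena
cannot be drawn from these tests.

For statistical calibration, `null_study()` forces all stage and sex
multipliers to one **and draws sections independently** (the patient CV
is folded into the residual): the calibration targets the marginal null
behaviour of the unpaired tests, which a shared patient factor would
deflate. The paired generator remains the default for effect studies.

## Problem sizes and runtimes

The test suite exercises full-size studies (480 lipids × 63 samples) for
round-trip and acceptance checks, 10,000 null lipids for type-I-error
calibration, 200 planted trajectories for archetype recovery, and
reduced designs (2–4 patients per sex) for structural unit tests; the
whole suite runs in a few minutes on one core, and
`scripts/acceptance.R` in about two.

## Known limitations

* Species-level quantification only; no sn-position or double-bond
  position resolution, and no MS/MS identity scoring.
* The type II correction models the canonical ΔDB = 1 M+2 interference
  within homologous series; exotic isobaric overlaps (e.g. across ether
  classes) are not corrected.
* The 28-subclass registry is study-specific and shipped as an editable
  table; the backbone set and MCES cap are likewise editable defaults
  rather than universal constants.
* GM3 and the larger glycan head groups use schematic backbone
  structures; their absolute MCES distances are coarser than those of
  the glycerophospholipids.
* The mixed patient/section design is analysed with unpaired tests by
  default for fidelity to the reporting convention; a mixed-effects
  treatment of patient nesting is out of scope.
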