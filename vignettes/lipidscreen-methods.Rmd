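---
title: "Methods: quantitative lipidomic screening with OPLS-DA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative lipidomic screening with OPLS-DA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidscreen)
```

`lipidscreen` implements a serum-lipidomics screening analysis for
pancreatic cancer end to end: quantitation of centroided mass spectra
against class internal standards, cohort preprocessing, gender-stratified
OPLS-DA classification, univariate dysregulation statistics, CA 19-9
comparison, and survival analysis on median-dichotomized lipid
concentrations. This vignette records the models, the parameter defaults
and why they are what they are, the numerical conventions, and the known
limitations.

## Quantitation model

A sample is measured as one centroided peak list per lipid-class scan
window (pairs of m/z in Th and intensity in counts). Quantitation is a
four-stage chain:

1. **Thresholding.** Only centroids with intensity strictly above
   `min_intensity` (default 3000 counts) are extracted. The boundary is
   strict: a 3000-count peak is discarded.
2. **Matching.** A peak is assigned to a database species of the same
   class window when |measured − theoretical m/z| ≤ `tolerance`
   (default 5 mDa, inclusive). Each peak goes to its nearest qualifying
   species (exact ties to the lower theoretical m/z — an arbitrary but
   frozen convention), and each species takes its most intense qualifying
   peak. Database entries closer than twice the tolerance trigger a
   warning because nearest-wins is then doing real work.
3. **Isotope correction.** Species are identified by their monoisotopic
   (M+0) peak. Two corrections, both computed from the molecular formula
   with standard natural isotope abundances (C/H/N/O/P/S, envelope
   truncated at M+2): *type II* subtracts the estimated M+2 contribution
   of the same-class species with one more double bond (whose M+2 sits
   ~8.9 mDa below the analyte M+0 and is unresolved at typical TOF
   resolution); *type I* then divides by the monoisotopic fraction so the
   corrected intensity represents the whole envelope. Corrected
   intensities are floored at zero. The exact correction used by the
   original in-house software is unpublished; this scheme is the package's
   own documented stand-in, validated by round trip against the spectrum
   generator (noise-free recovery to machine precision; within 15% with
   isotopes, jitter and noise enabled — both are asserted by tests).
4. **Internal-standard ratioing.** Concentration = corrected intensity of
   the lipid divided by corrected intensity of the class internal
   standard, times the spiked IS concentration (nmol/mL). If the IS of a
   class is absent or zero, all species of that class are reported
   *missing*, never zero — this distinction is what makes the presence
   filter well defined.

Species shorthand follows the class + carbons:double-bonds convention
(e.g. `SM 41:1`); neutral formulas are built from fixed per-class
composition rules and ionized as [M+H]+.

## Preprocessing

* **Presence filter** (`min_presence = 0.25`): a species is retained iff
  it is measured (non-missing, positive) in at least 25% of samples. The
  boundary is retained — exclusion applies to species present in *less
  than* 25%.
* **Imputation** (`factor = 0.8`): zeros and missing cells are replaced
  by 80% of the species' minimum positive value across *all* samples (not
  per group), making the matrix log-safe. Filtering always precedes
  imputation, so imputation can never rescue an excluded species.
* **NIST harmonization**: per method, concentrations are scaled by
  (cross-method mean of the NIST SRM 1950 value for that species) /
  (this method's NIST value). Anchoring to the cross-method mean keeps
  the nmol/mL scale; a single method is a no-op. Per-gender normalization
  is achieved by applying the function per gender stratum.
* **Transformation**: natural log (any fixed base is equivalent after
  scaling; natural log is frozen for reproducibility), column centering,
  and unit-variance (divide by sd) or Pareto (divide by √sd) scaling.
  Pareto is the default — it damps the leverage of high-variance abundant
  species without flattening the variance structure entirely, which is
  the usual choice for concentration data. The training parameters are
  stored and applied verbatim to validation samples; there is no
  re-centering on validation data.
* **Validation split**: within each group × gender stratum, samples are
  permuted with a fixed seed and every 6th position goes to validation.
  The real study's accrual order is unknown, so the published per-phase
  training/validation counts are *not* reproduced — the rule, not the
  realized counts, is what the package implements.

## OPLS-DA

The classifier is single-response OPLS in the NIPALS formulation. With
centered, scaled X and centered binary y:

* predictive weight w ∝ Xᵀy (unit norm); score t = Xw; loading
  p = Xᵀt/tᵀt; response loading q = yᵀt/tᵀt;
* each orthogonal component takes w_o ∝ p − (wᵀp/wᵀw)w, score t_o = Xw_o,
  loading p_o, and deflates X by t_o p_oᵀ — removing structured variation
  uncorrelated with the class;
* the final predictive component is computed on the deflated X, and the
  predictive score is oriented so the case-class mean is positive (a
  frozen sign convention; PCA likewise orients each loading so its
  largest-magnitude entry is positive).

With zero orthogonal components the model *is* 1-component PLS1, and a
test asserts prediction agreement with an independently coded PLS1 to
1e-8. Prediction of new samples removes the orthogonal variation with the
stored w_o/p_o sequence, then ŷ = t·q + ȳ. Classification is cancer iff
ŷ > 0.5; exactly 0.5 is non-cancer.

**Model quality.** R²Y is the training fraction of class variation
explained; Q² = 1 − PRESS/SS(y − ȳ) under 7-fold cross validation with
round-robin fold assignment on a seeded permutation (the reference
software's fold scheme is unspecified; round-robin is frozen here). Every
fold refits everything including the transformation parameters. The
orthogonal-component count is chosen automatically: components are added
while Q² improves by more than 0.01 — with too few components class
separation is incomplete, with too many the model overfits and Q² stops
improving. A cap (`max_orthogonal = 5`) bounds the search.

**VIP** sums each species' squared normalized weight over the predictive
and orthogonal components, weighted by the component's share of explained
response variation; since orthogonal components explain ~0 response
variation, this is numerically close to predictive-only VIP. Mean squared
VIP is exactly 1 (asserted). **S-plot** coordinates are the covariance
and Pearson correlation of each species with the predictive score;
downregulated species appear negative. **ROC/AUC** uses the rank
(Mann-Whitney) formulation, so ties count one half and the value equals
the trapezoid area under the tie-aware curve.

## Univariate statistics

The Welch unequal-variance t-test (two-sided) is computed per species,
Bonferroni-corrected with m = the number of species tested in the
stratum. The relevance rule is the strict conjunction *p* < 0.05, VIP > 1
and fold change ≥ 20%; the fold-change criterion is symmetric,
max(r, 1/r) ≥ 1.2, so a ratio of 0.80 (25% change) passes while 1.19
fails and 1.20 passes. Box-plot summaries use type-7 quartiles and — by
the study's stated convention — whiskers spanning 1.5 IQR *from the
median*, clipped to the data range; the more common Tukey from-quartile
convention is available as a switch. Cross-method agreement is the
per-sample RSD (sd/mean × 100) across methods after NIST harmonization.

## CA 19-9

Values strictly over 37 U/mL are classified PDAC. For the combined model,
CA 19-9 is appended as one additional concentration column sharing the
same log/scale treatment, using a both-gender model (the clinical cutoff
does not differ by gender). How exactly the original analysis combined
the two is unstated; this append-one-variable interpretation is the
package's design choice and is flagged as such. A constant CA 19-9
column is dropped, making the combined model identical to lipid-only.

## Survival

Concentrations are dichotomized at the species median over all samples:
code 1 strictly above, 0 otherwise — ties go to 0 by default because the
convention defines only strict inequalities (switchable). Kaplan–Meier
estimation, the two-sided log-rank test and Cox proportional-hazards
fits are delegated to the `survival` package (Breslow tie handling by
default, Efron optional); tests validate them against hand-computed
product-limit and log-rank oracles, and against the Cox score test on
tie-free data. Per-lipid models are univariate by default, with a joint
model available, since the original forest plot's structure is ambiguous.
Hazard ratios above 1 mean poorer survival for code 1; confidence
intervals are exp(β ± 1.96·SE). Collinear covariates and separation are
refused with explicit errors.

## What the synthetic generator emulates — and what it does not

Concentrations are lognormal per species with a within-group coefficient
of variation (default 0.30, a typical biological CV for serum lipids);
the case effect multiplies the geometric mean, so the configured fold
change is the T/N geometric-mean ratio — recovered empirically to within
5% at n = 2000/group (asserted). Baseline geometric means span 0.05–500
nmol/mL, the dynamic range of quantified serum lipids. Pancreatitis
samples are drawn from the control distribution, mirroring the
observation that their concentrations resemble controls. The default
marker panel is the seven species SM 41:1, SM 42:1, SM 39:1, Cer 41:1,
Cer 42:1, LPC 18:2 and PC O-36:3, all downregulated at geometric-mean
ratios 0.45–0.65 — effect sizes consistent with fold changes reported for
these markers. Tumor stage is assigned independently of the lipid effect
(stage did not cluster in the study's score plots). CA 19-9 is lognormal
with a higher location in cases (case median 100 U/mL, control median 8,
giving ~75% of cases over the 37 U/mL cutoff — in the range of reported
CA 19-9 sensitivity). Survival times are exponential with hazard
h₀·exp(Σβⱼzⱼ) on the binary lipid codes, censored at 60 months, with
h₀ = 0.04/month (median survival under 2 years at baseline, typical of
PDAC). None of these distribution parameters are published values — the
study reports no concentration distributions — so they are package
defaults, stated here and in `cohort_config()`.

The spectrum generator places peaks at the database m/z with truncated
Gaussian jitter (default SD 0.5 mDa, bounded at 3 SD), intensities equal
to concentration × response factor (default 5 × 10⁴ counts per nmol/mL),
optional M+0/M+1/M+2 isotopologues with abundances from the formula, IS
peaks at the spiked concentration, and uniform noise peaks below three
times the noise floor. Centroids closer than 10 mDa are merged with an
intensity-weighted m/z, which is how the unresolved M+2 overlap between
double-bond neighbours arises.

Passing tests on this generator demonstrate the pipeline's correctness
under its stated statistical assumptions; they do not demonstrate
performance on real sera. The generator has no chromatographic peak
shapes, no profile-mode spectra, no batch effects beyond a single drift
term, no correlation structure between lipid species (real lipid classes
co-regulate), and gender affects lipid levels only through an optional
multiplicative offset (default: none).

## Numerical choices and degenerate inputs

* An unobserved species is *missing*, never zero; zeros only arise from
  explicit zero intensities.
* Zero-variance species are centered and scaled by 1 with a warning.
* A merged centroid drifts toward the heavier contributor: if an
  interfering M+2 is much more abundant than the analyte M+0 (ratio above
  roughly 10:1 given the 8.9 mDa spacing and 5 mDa tolerance), the
  centroid leaves the matching window and the analyte is lost — this is a
  faithful consequence of unresolved isobars, so round-trip accuracy
  checks use fixtures with concentrations of comparable magnitude
  (log-uniform 5–50 nmol/mL).
* Cross-validation folds that would leave a single class in a training
  part are redrawn once, then error.
* Fitting problem sizes in the tests and the acceptance script (cohorts
  of up to 600 samples × 157 species, 10 replicate cohorts; 100-replicate
  recovery simulations at n = 500) were chosen so each statistical claim
  is measured with adequate precision while a full run remains a
  desk-scale computation.

## Known limitations

* The isotope-correction scheme is a stand-in for unpublished vendor
  logic; only M+0..M+2 are modelled, and chained overlaps (Δdb ≥ 2) are
  ignored.
* Exact numeric agreement with the commercial OPLS-DA implementation is
  not a goal; the algorithm follows the published single-response NIPALS
  formulation, and component counts are selected by cross validation
  rather than read from the original models.
* No raw vendor-file or mzML parsing, no centroiding, no lock-mass or
  chromatographic alignment — inputs are already centroided per-class
  peak lists.
* No multiclass OPLS-DA, no pathway enrichment, no automatic outlier
  exclusion (QC flags are advisory by contract).
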