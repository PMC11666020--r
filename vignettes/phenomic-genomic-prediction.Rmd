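---
title: "Phenomic and genomic prediction in multi-environment trials: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenomic and genomic prediction in multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Phenomic prediction (PP) replaces the marker-based genomic relationship
matrix (GRM) of genomic prediction (GP) with a hyperspectral relationship
matrix (HRM) computed from near-infrared reflectance spectra of harvested
tissue. Because NIRS is cheap and non-destructive, PP is attractive for
breeding programs with limited genotyping capacity, but its accuracy
depends on factors — training-population size, the number of environments
supplying spectra, genotype-by-environment (G×E) structure — that this
package makes explorable end to end: from plot-level phenotypes and
spectra to relationship matrices, Bayesian kernel prediction models, and
sparse-testing cross-validation.

The setting mirrored throughout is a rice diversity panel of 190
accessions grown in four environments formed by crossing two seasons with
two nitrogen-fertilization levels (labels `2015-HN`, `2015-LN`,
`2016-HN`, `2016-LN`), in a split-block design with two replicates of 14
blocks, genotyped at ~38k SNPs and phenotyped for six traits, with grain
NIRS at 1,500 wavelengths (1,000–2,500 nm). Since that dataset is not
public, a synthetic-data module generates data with the same statistical
skeleton at any scale.

## Models

**Plot-level variance decomposition.** For each trait, REML (via lme4,
the engine used for every mixed model in the package) fits

y = µ + Year + Nitro + Rep(Nitro(Year)) + Bl(Rep(Nitro(Year))) + geno +
geno:Year + geno:Nitro + e,

with fixed year, nitrogen and replicate effects and random block,
genotype and interaction effects. Broad-sense heritability is the
plug-in

H² = σ²g / (σ²g + σ²g:Year/N_Year + σ²g:Nitro/N_Nitro + σ²e/N_R),

where the N are harmonic means over genotypes of realized counts of
years, nitrogen levels and total replicates. `decompose_variance()`
computes the components and counts; `broad_sense_heritability()` the
plug-in.

**BLUEs.** Within each environment, genotype best linear unbiased
estimates come from y = µ + geno (fixed) + Bl(Rep) + Rep (random) + e,
reported on the trait scale (intercept added back). These BLUEs are both
the response of the prediction models and the reference against which
predictive ability is scored.

**Spectra.** Preprocessing supports SNV, detrend, Savitzky–Golay
smoothing and first/second derivatives of SNV-normalized spectra; the
second derivative (`der2`) is the pipeline default because it removes
smooth additive environment baselines. Per wavelength and environment,
r = µ + block(Rep) + geno + e (all random) yields genotype BLUPs; the
matrix Sp* of BLUPs gives the HRM H = Sp\*Sp\*′/L with L the number of
retained wavelengths. Wavelength heritability is σ²g/(σ²g + σ²e/N_R).
The GRM is VanRaden's K = ZZ′ / 2Σp(1−p).

**Prediction models.** On a stacked (genotype, environment) response of
BLUEs, three model families are built by `build_kernels()`:

* SM — single environment, one kernel (K for GP, that environment's H
  for PP);
* MM — multi-environment with environment fixed effects and main
  genetic kernels of structure J⊗K (uniform genotype effect across
  environments); for PP, one main kernel per NIRS dataset (environment);
* MDs — MM plus block-diagonal I⊗K deviation kernels, one variance per
  information source: the G×E model.

GP+PP takes the union of genomic and phenomic kernels — two separate
random effects, never a blended matrix. `fit_gibbs()` samples the model
(flat fixed-effect priors, scaled-inverse-chi-squared variance priors,
random effects in each kernel's eigenbasis, masked responses imputed by
data augmentation); `solve_blup()` is the closed-form mixed-model-
equations counterpart used as an oracle in the tests, itself verified
against dense GLS inversion.

**Cross-validation.** `make_scenarios()` reproduces the 14-scenario
design: scenarios 1–4 are single-environment 2- or 5-fold CV; 5–10 put
one full environment plus 0/10/50/80% of a target environment in the
training set; 11–14 put two full environments plus 0/50/80% of a third.
Predictive ability (PA) is the Pearson correlation between predictions
and the BLUEs of the validation genotypes, pooled over folds within a
replicate and averaged over replicates (default 10). Partitions depend
only on (scenario, replicate), so models are compared on identical
training sets. `compare_models()` works on Fisher's z = atanh(r), with
factor-level means back-transformed and Tukey-adjusted pairwise
contrasts.

## Chain settings and priors

The published chain (burn-in 10,000, 70,000 iterations, thinning 10) is
`chain_preset("paper")`. Tests and desk-scale studies use
`chain_preset("fast")` (500 / 3,000 / 5), which on problems up to 800
stacked responses reproduces closed-form predictions to within
Monte-Carlo error (tested). Priors: scaled-inverse-chi-squared with 5
degrees of freedom for every variance; the prior scale splits the sample
variance of the observed response half to the genetic kernels (evenly),
half to the residual (`prior_r2 = 0.5`). Because kernels arrive on
arbitrary scales (a derivative-spectra HRM has diagonals of order 1e-8),
each kernel's prior scale and initial value are expressed relative to
its mean diagonal; this affects only prior elicitation, not the model.
Kernel eigenvalues below 1e-10 of the leading one are truncated;
eigenvalues below −1e-8 (relative) raise an error, small negatives are
clipped to zero.

## What the synthetic-data generator emulates

`simulate_genotypes()` draws per-marker allele frequencies uniformly in
the MAF range and dosages binomially; with `n_families > 1` it uses the
Balding–Nichols model to create related families (default off). The
structured panel (10 families, Fst 0.45 at 100 genotypes and 300
markers) is the reference study condition: an unrelated panel has a
pure-noise GRM off-diagonal, which caps genomic accuracy at the
marker-capacity bound √(n/(n+m)) and makes multi-environment information
gains invisible — unlike any real diversity panel.

`simulate_phenotypes()` builds plot values as environment mean +
additive genetic value + genotype:year + genotype:nitrogen + block +
residual. The six default `trait_spec`s (DF, PH, TGW, GY, HI, GNC)
use variance fractions that land broad-sense heritabilities between
~0.55 (GY) and ~0.94 (PH, TGW), genotypic variance fractions between
~22% and ~81%, and between-environment BLUE correlations of ~0.85–0.93
for high-heritability traits and ~0.35–0.6 for GY/GNC — the ranges
reported for the rice panel. Absolute variance scales follow each
trait's phenotypic standard deviation; only fractions matter
structurally. Interaction deviations are themselves polygenic (fresh
random QTL per year/nitrogen level, independent across levels): the
G×E kernels of the MDs model assume marker-correlated deviations, and
genotype-i.i.d. deviations would make sparse-testing gains impossible by
construction.

`simulate_spectra()` builds reflectance as baseline + genetic curve +
wavelength-smooth environment shift (Gaussian-process draw, length-scale
100 nm, so derivative preprocessing attenuates it) + scalar block effect
+ white noise. The genetic curve combines `rank` (default 20)
marker-driven latent factors with smooth loadings, a dense per-genotype
fingerprint (`dense_share`), and — when trait genetic values are
supplied — a leading factor correlated `trait_cor` with the trait and
carrying `trait_share` of the spectral genetic variance on average.
The per-wavelength genetic scale is set so the plug-in wavelength
heritability matches `target_h2_profile` for raw spectra at the design's
replicate number (verified within [0.6, 0.95] of a 0.8 target).

Three generator parameters deserve comment because they decide which
qualitative phenomena exist at all:

* `trait_cor` (default 0.6) bounds single-environment PP accuracy: a
  trait lying exactly in the spectral genetic span is predictable from
  spectra almost regardless of its variance share, which is not how real
  agronomic traits behave.
* `dense_share` (default 0.3) makes the HRM diagonal-dominant. This is
  the mechanism behind sparse testing with spectra: a genotype's own
  record in one environment transfers to another through its spectral
  fingerprint even when spectra are weakly informative about the trait
  across genotypes.
* Non-trait factors are residualized against the trait's genetic values,
  so spectra–trait overlap is exactly the configured amount rather than
  a chance alignment of random marker combinations.

What the generator does **not** emulate: linkage disequilibrium decay
along chromosomes, non-additive genetic effects, heteroscedastic or
wavelength-correlated measurement noise, scan-level technical
replicates, and unstructured between-environment genetic covariance.
Passing tests therefore show the pipeline's statistical machinery is
correct and that the study's qualitative findings follow from its
assumed mechanisms — not that those mechanisms are the right model of
any particular real dataset.

## Study conditions used by tests and the acceptance script

Desk-scale sizes keep every run in minutes on one core: 100 genotypes,
300 markers, four environments with 2 replicates and 5 blocks, 301
wavelengths (5 nm step), `der2` with window 37 by default (17 in the
fast studies, where the grid step is coarser), fast chain, 2–3
replicates per scenario, ten seeds for majority-vote properties. The
qualitative findings checked this way: sparse-testing inclusion of the
target environment raises PA (GY-like trait); PP's accuracy gain from a
second training environment exceeds GP's, with PP approaching GP at two
environments; PA plateaus from two to three environments.

## Numerical and design choices

* Tukey hinges (`fivenum`) for the outlier fences, not interpolated
  quantiles — the boxplot-statistics convention; the two differ on small
  samples. Outliers are flagged, never removed.
* "Normalization" is interpreted as SNV; "detrend" as SNV followed by
  second-order polynomial baseline removal; derivatives use
  Savitzky–Golay (default window 37 points, order 2) on SNV-normalized
  spectra, trimming half a window at each edge (the trimmed grid is what
  L in the HRM counts).
* Technical-replicate averaging of NIRS scans is assumed done upstream.
* Per-wavelength models are fitted independently; a wavelength with zero
  variance yields zero BLUPs and zero heritability.
* Heterozygote calls in the SNP filter are counted against the
  heterozygosity threshold first, then set to missing in retained
  markers; MAF uses observed allele frequencies before that conversion.
  Residual missing dosages are mean-imputed inside the GRM with a
  warning; synthetic data never triggers this.
* BLUEs are reported with the intercept added back so files are on the
  trait scale; correlations are invariant to this.
* Rows with missing trait values are dropped per trait before fitting.
* In PP sparse-testing scenarios the target environment's HRM enters the
  kernel set only when some of that environment's genotypes are in the
  training set (`include_target_hrm = "auto"`); both forced settings are
  available.
* A fully masked environment (the 0% scenarios) leaves its fixed effect
  anchored only by data augmentation; within-environment rankings, and
  hence PA, are unaffected.
* The environment fixed effect is the year-by-nitrogen cell (4 levels).
* Replicate r of scenario s derives its partition seed as
  master_seed + 1000·s + r; fits derive chain seeds from the partition
  seed, so every stochastic output is reproducible from the manifest.

## Known limitations

Single-chain inference (no cross-chain convergence diagnostics beyond
effective sample size); no unstructured between-environment covariance
models; no marker-effect (Bayesian alphabet) models; the variance
decomposition model is taken as fixed rather than selected by AIC; the
synthetic genotype model has no LD, so marker-capacity effects are
governed by marker count rather than effective segment number.
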