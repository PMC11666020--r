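# phenogp

Phenomic and genomic prediction for multi-environment plant breeding
trials.

Phenomic prediction (PP) replaces the SNP-based genomic relationship
matrix (GRM) of genomic prediction (GP) with a *hyperspectral
relationship matrix* (HRM) built from near-infrared (NIRS) reflectance
spectra of harvested tissue — a cheap, non-destructive proxy for
genotype similarity. `phenogp` implements the full comparison pipeline
for a multi-environment trial (years × nitrogen treatments):

* **Phenotypes** — Tukey outlier flagging, REML variance decomposition
  (`y = µ + Year + Nitro + Rep(Nitro(Year)) + Bl(Rep) + geno +
  geno:Year + geno:Nitro + e`), broad-sense heritability
  `H² = σ²g / (σ²g + σ²g:Y/N_Year + σ²g:N/N_Nitro + σ²e/N_R)`, and
  per-environment genotype BLUEs with between-environment correlations.
* **Spectra** — SNV / detrend / Savitzky–Golay derivative
  preprocessing, per-wavelength genotype BLUPs
  (`r = µ + block(Rep) + geno + e`), wavelength heritability, and
  `H = Sp*Sp*′/L`.
* **Relationship matrices** — SNP QC (call rate ≥ 80%, heterozygosity
  ≤ 20%, MAF ≥ 2.5%), VanRaden `K = ZZ′ / 2Σpⱼ(1−pⱼ)`, HRM, alignment
  utilities.
* **Prediction** — single-environment (SM) and multi-environment
  kernel models without (MM, genetic covariance `J⊗K`) and with G×E
  deviations (MDs, adding block-diagonal `I⊗K`), for GP, PP (one
  kernel per NIRS dataset) and combined GP+PP, fitted by a Gibbs
  sampler with a closed-form BLUP oracle (`solve_blup`).
* **Cross-validation** — the 14 standard scenarios (k-fold within an
  environment; sparse testing with 0–80% of a target environment in
  training), replicated predictive ability (Pearson r against BLUEs),
  and model comparison on Fisher's z scale with Tukey contrasts.
* **Synthetic data** — generators for structured genotype panels,
  split-block trial designs, six default traits with realistic variance
  fractions, and plot-level spectra with controllable wavelength
  heritability and spectra–trait overlap, so the whole pipeline is
  testable without the (undeposited) field dataset it emulates.

## Worked example

```r
library(phenogp)

# a related 100-line panel in a 2-year x 2-nitrogen split-block trial
geno   <- simulate_genotypes(100, 300, seed = 1, n_families = 10, fst = 0.45)
design <- simulate_trial_design(100, n_years = 2, n_nitro = 2,
                                n_reps = 2, n_blocks = 5, seed = 2)
trait  <- default_trait_specs()$GY   # grain-yield-like trait
trait$n_qtl <- 100L
sim    <- simulate_phenotypes(geno, design, trait, seed = 3)

vc <- decompose_variance(sim$records)
tidy(vc)
#> # A tibble: 5 × 3
#>   component  estimate proportion
#>   <chr>         <dbl>      <dbl>
#> 1 geno        469403.      0.199
#> 2 geno:year   400816.      0.170
#> 3 geno:nitro  293563.      0.125
#> 4 block(rep)  292258.      0.124
#> 5 residual    897615.      0.381
broad_sense_heritability(vc)
#> [1] 0.5053897
```

About 20% of the plot variance is genotypic with sizeable
genotype-by-year and genotype-by-nitrogen interaction — the low-
heritability, high-G×E regime typical of grain yield (H² ≈ 0.51 here).

```r
blues <- compute_blues(sim$records)
K  <- grm_vanraden(geno)
sc <- make_scenarios()     # the 14 standard CV scenarios
pa <- run_cv_scenario(sc[5, ], model = "MDs", info = "GP",
                      blues = blues, grm = K,
                      chain = chain_preset("fast"),
                      n_replicates = 3, master_seed = 1)
summarise_pa(pa)
#> # A tibble: 4 × 7
#>   scenario_id model info  fraction mean_pa  sd_pa     n
#>         <int> <chr> <chr> <chr>      <dbl>  <dbl> <int>
#> 1           5 MDs   GP    0%         0.566 0.0298     3
#> 2           5 MDs   GP    10%        0.596 0.0315     3
#> 3           5 MDs   GP    50%        0.629 0.0364     3
#> 4           5 MDs   GP    80%        0.596 0.121      3
```

Scenario 5 trains on all of `2015-HN` plus a growing fraction of
`2015-LN` and predicts the rest of `2015-LN`: predictive ability rises
as target-environment plots enter the training set (0.57 at 0% to
~0.6–0.63 beyond 10%), the sparse-testing effect the G×E model (MDs)
is designed to exploit.

The umbrella entry point `run_pipeline(pipeline_config(...))` runs
simulation → phenotype analysis → spectra → relationship matrices →
cross-validation → comparison, writes every result as CSV plus a JSON
manifest of seeds and checksums, and skips completed stages on re-runs.

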