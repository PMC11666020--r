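test_that("genotype simulation has the right domain, shape and determinism", {
  g <- simulate_genotypes(190, 500, c(0.042, 0.5), seed = 1)
  expect_equal(dim(g), c(190L, 500L))
  expect_true(all(g$dosage %in% 0:2))
  expect_true(all(g$maf >= 0 & g$maf <= 0.5))
  g2 <- simulate_genotypes(190, 500, c(0.042, 0.5), seed = 1)
  expect_identical(g$dosage, g2$dosage)
  g3 <- simulate_genotypes(190, 500, c(0.042, 0.5), seed = 2)
  expect_false(identical(g$dosage, g3$dosage))

  tiny <- simulate_genotypes(2, 1, c(0.5, 0.5), seed = 99)
  expect_true(all(tiny$dosage %in% 0:2))

  expect_error(simulate_genotypes(10, 5, c(0.4, 0.1)), "interval")
  expect_error(simulate_genotypes(10, 5, c(0, 0.5)), "within")
})

test_that("mean dosage at p = 0.5 is binomial-consistent", {
  g <- simulate_genotypes(5000, 1, c(0.5, 0.5), seed = 7)
  # binomial(2, .5): mean 1, sd sqrt(0.5); MC bound of 3 standard errors
  se <- sqrt(0.5) / sqrt(5000)
  expect_lt(abs(mean(g$dosage) - 1), 3 * se)
})

test_that("family structure raises relatedness within families", {
  g <- simulate_genotypes(60, 400, seed = 3, n_families = 6, fst = 0.4)
  K <- grm_vanraden(g)
  fam <- rep_len(1:6, 60)
  same <- outer(fam, fam, "==") & upper.tri(K)
  diff <- !outer(fam, fam, "==") & upper.tri(K)
  expect_gt(mean(K[same]), mean(K[diff]))
})

test_that("trial design covers every genotype once per replicate per environment", {
  d <- simulate_trial_design(190, 2, 2, 2, 14, seed = 1)
  expect_equal(nrow(d), 190 * 2 * 2 * 2)
  counts <- d |> count(.data$genotype, .data$env, .data$rep)
  expect_true(all(counts$n == 1))
  expect_equal(length(unique(d$env)), 4L)
  expect_false(any(duplicated(d$plot)))
  # block labels nested within (env, rep): 14 per cell
  blocks <- d |> distinct(.data$env, .data$rep, .data$block) |>
    count(.data$env, .data$rep)
  expect_true(all(blocks$n == 14))

  single <- simulate_trial_design(1, 1, 1, 1, 1, seed = 1)
  expect_equal(nrow(single), 1L)

  d2 <- simulate_trial_design(10, 1, 1, 2, 2, seed = 3)
  expect_true(all((d2 |> count(.data$genotype))$n == 2))

  # uneven padding: 10 genotypes in 3 blocks -> sizes 4/3/3, nobody dropped
  d3 <- simulate_trial_design(10, 1, 1, 1, 3, seed = 4)
  expect_equal(sort(as.integer(table(d3$block)), decreasing = TRUE),
               c(4L, 3L, 3L))
  expect_setequal(unique(d3$genotype), sprintf("G%03d", 1:10))
})

test_that("phenotype simulation honors degenerate variance settings", {
  g <- simulate_genotypes(12, 50, seed = 1)
  d <- simulate_trial_design(12, 2, 2, 2, 2, seed = 2)
  envs <- unique(d$env)
  mus <- setNames(rep(10, 4), envs)

  allzero <- trait_spec("t0", 0, 0, 0, 0, 0, env_means = mus, n_qtl = 10)
  sim0 <- simulate_phenotypes(g, d, allzero, seed = 3)
  expect_true(all(sim0$records$value == 10))

  genonly <- trait_spec("t1", 1, 0, 0, 0, 0, env_means = mus, n_qtl = 10)
  sim1 <- simulate_phenotypes(g, d, genonly, seed = 3)
  reps <- sim1$records |>
    group_by(.data$genotype, .data$env) |>
    summarise(spread = diff(range(.data$value)), .groups = "drop")
  expect_true(all(reps$spread < 1e-12))
  # genetic variance scaled exactly to the spec
  expect_equal(var(sim1$truth$genetic_values), 1, tolerance = 1e-10)
})

test_that("component sample variances converge to the spec at n = 2000", {
  g <- simulate_genotypes(2000, 60, seed = 5)
  d <- simulate_trial_design(2000, 2, 2, 1, 4, seed = 6)
  spec <- trait_spec("t", 4, 2, 1, 0.5, 1.5,
                     env_means = setNames(rep(0, 4), unique(d$env)),
                     n_qtl = 50)
  sim <- simulate_phenotypes(g, d, spec, seed = 7)
  expect_equal(var(sim$truth$genetic_values), 4, tolerance = 1e-10)
  expect_equal(mean(apply(sim$truth$geno_year, 2, var)), 2, tolerance = 0.2)
  expect_equal(mean(apply(sim$truth$geno_nitro, 2, var)), 1, tolerance = 0.1)
  resid <- sim$records$value -
    sim$truth$genetic_values[sim$records$genotype] -
    sim$truth$geno_year[cbind(sim$records$genotype,
                              as.character(sim$records$year))] -
    sim$truth$geno_nitro[cbind(sim$records$genotype, sim$records$nitro)]
  # residual = block + e after removing genetic parts and the zero means
  expect_equal(var(resid), 2.0, tolerance = 0.2)
})

test_that("plug-in H2 of realized components is centered on the design value", {
  h2 <- sapply(1:10, function(s) {
    g <- simulate_genotypes(200, 50, seed = s)
    d <- simulate_trial_design(200, 1, 1, 1, 4, seed = s + 50)
    spec <- trait_spec("t", 1, 0, 0, 0, 1,
                       env_means = setNames(0, unique(d$env)), n_qtl = 30)
    sim <- simulate_phenotypes(g, d, spec, seed = s + 100)
    ve <- var(sim$records$value - sim$truth$genetic_values[sim$records$genotype])
    1 / (1 + ve)
  })
  expect_lt(abs(mean(h2) - 0.5), 0.1)
})

test_that("spectra replicates are identical when all plot-level noise is off", {
  g <- simulate_genotypes(10, 40, seed = 1)
  d <- simulate_trial_design(10, 1, 2, 2, 2, seed = 2)
  spec <- spectra_spec(wavelength_grid = seq(1000, 1195, by = 5),
                       target_h2_profile = 0.8, noise_sd = 0,
                       env_shift_sd = 0, block_sd = 0)
  sp <- simulate_spectra(g, d, spec, seed = 3)
  spread <- sp |>
    group_by(.data$genotype, .data$env) |>
    summarise(across(starts_with("wl_"), function(x) diff(range(x))),
              .groups = "drop")
  expect_true(all(as.matrix(spread[, -(1:2)]) < 1e-12))
})

test_that("zero genetic loading gives zero wavelength heritability", {
  g <- simulate_genotypes(40, 60, seed = 1)
  d <- simulate_trial_design(40, 1, 1, 2, 2, seed = 2)
  spec <- spectra_spec(wavelength_grid = seq(1000, 1100, by = 5),
                       target_h2_profile = 0.8, genetic_loading = 0,
                       noise_sd = 0.05, env_shift_sd = 0)
  sp <- simulate_spectra(g, d, spec, seed = 3)
  bl <- spectra_blups(sp, unique(d$env))
  expect_lt(median(bl$varcomp$h2), 0.15)
})

test_that("realized wavelength heritability tracks the target profile", {
  meds <- sapply(1:5, function(s) {
    g <- simulate_genotypes(50, 100, seed = s)
    d <- simulate_trial_design(50, 1, 2, 2, 4, seed = s + 10)
    spec <- spectra_spec(wavelength_grid = seq(1000, 1390, by = 10),
                         target_h2_profile = 0.8, noise_sd = 0.05,
                         env_shift_sd = 0.05)
    sp <- simulate_spectra(g, d, spec, seed = s + 20)
    bl <- spectra_blups(sp, unique(d$env)[1])
    median(bl$varcomp$h2)
  })
  expect_true(all(meds > 0.6 & meds < 0.95))
})

test_that("trait genetic values align with the leading spectral component", {
  hits <- sapply(1:5, function(s) {
    g <- simulate_genotypes(60, 100, seed = s)
    d <- simulate_trial_design(60, 1, 1, 2, 2, seed = s + 10)
    spec0 <- trait_spec("t", 1, 0, 0, 0, 0.5,
                        env_means = setNames(0, unique(d$env)), n_qtl = 50)
    sim <- simulate_phenotypes(g, d, spec0, seed = s + 20)
    sspec <- spectra_spec(wavelength_grid = seq(1000, 1495, by = 5),
                          target_h2_profile = 0.8, noise_sd = 0.02,
                          trait_cor = 0.9, trait_share = 0.4,
                          dense_share = 0.2)
    sp <- simulate_spectra(g, d, sspec, seed = s + 30,
                           genetic_values = sim$truth$genetic_values)
    G <- attr(sp, "truth")$genetic_spectra
    pc1 <- prcomp(G, center = TRUE)$x[, 1]
    abs(cor(pc1, sim$truth$genetic_values[rownames(G)]))
  })
  expect_true(all(hits > 0.2))
})

test_that("simulation is deterministic end to end", {
  run <- function() {
    g <- simulate_genotypes(15, 30, seed = 11)
    d <- simulate_trial_design(15, 2, 2, 2, 3, seed = 12)
    spec <- default_trait_specs()$GY
    spec$n_qtl <- 20L
    sim <- simulate_phenotypes(g, d, spec, seed = 13)
    sp <- simulate_spectra(g, d,
                           spectra_spec(wavelength_grid = seq(1000, 1100, 10)),
                           seed = 14)
    list(sim$records$value, spectra_matrix(sp))
  }
  expect_identical(run(), run())
})
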