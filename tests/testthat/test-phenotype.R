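make_records <- function(values, env = "2015-HN", trait = "t") {
  tibble(
    genotype = sprintf("G%02d", seq_along(values)),
    year = 2015L, nitro = "HN", env = env, rep = 1L, block = 1L,
    trait = trait, value = values
  )
}

test_that("outlier flags follow the Tukey boxplot rule per environment", {
  # hand enumeration: fivenum of {1..9, 100} has hinges 3 and 8, hinge
  # spread 5, fences [-4.5, 15.5] -> only 100 flagged
  r <- flag_outliers(make_records(c(1:9, 100)))
  expect_equal(sum(r$outlier), 1L)
  expect_true(r$outlier[r$value == 100])

  const <- flag_outliers(make_records(rep(5, 10)))
  expect_equal(sum(const$outlier), 0L)

  expect_warning(flag_outliers(make_records(c(1, 2, 3))), "4 observations")

  # per-environment grouping: the same value can be an outlier in one
  # environment only
  two <- bind_rows(make_records(c(1:9, 100), env = "E1"),
                   make_records(c(96:104, 100), env = "E2"))
  f <- flag_outliers(two)
  expect_equal(sum(f$outlier[f$env == "E1"]), 1L)
  expect_equal(sum(f$outlier[f$env == "E2"]), 0L)
})

test_that("broad-sense heritability is the exact plug-in formula", {
  vc <- list(var_geno = 4, var_geno_year = 1, var_geno_nitro = 1,
             var_resid = 4,
             harmonic_means = list(N_Year = 2, N_Nitro = 2, N_R = 4))
  expect_equal(broad_sense_heritability(vc), 4 / 6, tolerance = 1e-12)

  vc$var_geno_year <- 0; vc$var_geno_nitro <- 0; vc$var_resid <- 0
  expect_equal(broad_sense_heritability(vc), 1.0)

  vc$var_geno <- 0
  expect_error(broad_sense_heritability(vc), "undefined")

  vc2 <- list(var_geno = 0, var_geno_year = 1, var_geno_nitro = 1,
              var_resid = 4,
              harmonic_means = list(N_Year = 2, N_Nitro = 2, N_R = 4))
  expect_equal(broad_sense_heritability(vc2), 0.0)
})

test_that("REML matches the expected-mean-squares closed form on balanced one-way data", {
  set.seed(42)
  g <- 15; r <- 4
  group <- factor(rep(seq_len(g), each = r))
  y <- rnorm(g, sd = 2)[group] + rnorm(g * r)
  ems <- ems_oneway(y, group)
  stopifnot(ems["sigma2_g"] > 0)  # interior solution, REML == EMS
  fit <- phenogp:::varcomp_reml(y ~ (1 | group),
                                data = data.frame(y = y, group = group))
  expect_equal(unname(fit$components["group"]),
               unname(ems["sigma2_g"]), tolerance = 1e-6)
  expect_equal(unname(fit$components["Residual"]),
               unname(ems["sigma2_e"]), tolerance = 1e-6)
})

test_that("variance decomposition recovers simulation truth", {
  g <- simulate_genotypes(300, 60, seed = 1)
  d <- simulate_trial_design(300, 2, 2, 2, 5, seed = 2)
  spec <- trait_spec("t", 1, 0, 0, 0, 1,
                     env_means = setNames(rep(0, 4), unique(d$env)),
                     n_qtl = 40)
  sim <- simulate_phenotypes(g, d, spec, seed = 3)
  vc <- decompose_variance(sim$records)
  expect_true(vc$converged)
  expect_gt(vc$var_geno, 0.8); expect_lt(vc$var_geno, 1.2)
  expect_lt(vc$var_geno_year, 0.1)
  expect_lt(vc$var_geno_nitro, 0.1)
  expect_equal(vc$harmonic_means$N_Year, 2)
  expect_equal(vc$harmonic_means$N_Nitro, 2)
  expect_equal(vc$harmonic_means$N_R, 8)
  h2 <- broad_sense_heritability(vc)
  expect_gt(h2, 0.8)  # 1 / (1 + 1/8) = 0.889 at the true components
})

test_that("H2 is invariant to rescaling the data", {
  g <- simulate_genotypes(80, 40, seed = 4)
  d <- simulate_trial_design(80, 2, 2, 2, 3, seed = 5)
  spec <- trait_spec("t", 2, 0.5, 0.5, 0.3, 1,
                     env_means = setNames(rep(0, 4), unique(d$env)),
                     n_qtl = 30)
  sim <- simulate_phenotypes(g, d, spec, seed = 6)
  vc1 <- decompose_variance(sim$records)
  scaled <- sim$records |> mutate(value = .data$value * 3)
  vc2 <- decompose_variance(scaled)
  expect_equal(vc2$var_geno, vc1$var_geno * 9, tolerance = 1e-4)
  expect_equal(broad_sense_heritability(vc2),
               broad_sense_heritability(vc1), tolerance = 1e-6)
})

test_that("variance decomposition rejects or degenerates on edge cases", {
  d <- simulate_trial_design(6, 2, 2, 2, 2, seed = 1)
  one <- d |> mutate(trait = "t", value = rnorm(n())) |>
    filter(.data$genotype == "G001")
  expect_error(decompose_variance(one), "2 genotype")

  const <- d |> mutate(trait = "t", value = 7)
  vc <- decompose_variance(const)
  expect_equal(vc$var_geno, 0)
  expect_equal(vc$var_resid, 0)
})

test_that("BLUEs equal genotype means in the absence of block structure noise", {
  g <- simulate_genotypes(20, 30, seed = 1)
  d <- simulate_trial_design(20, 1, 1, 2, 2, seed = 2)
  spec <- trait_spec("t", 1, 0, 0, 0, 0,
                     env_means = setNames(5, unique(d$env)), n_qtl = 10)
  sim <- simulate_phenotypes(g, d, spec, seed = 3)
  b <- compute_blues(sim$records)
  means <- sim$records |>
    group_by(.data$genotype) |>
    summarise(m = mean(.data$value))
  expect_equal(b$blue[match(means$genotype, b$genotype)], means$m,
               tolerance = 1e-6)

  # single plot per genotype, one rep/block: BLUE is the value itself
  d1 <- simulate_trial_design(10, 1, 1, 1, 1, seed = 4)
  sim1 <- simulate_phenotypes(g, d1,
                              trait_spec("t", 1, 0, 0, 0, 0.5,
                                         env_means = setNames(0, unique(d1$env)),
                                         n_qtl = 5),
                              seed = 5)
  b1 <- compute_blues(sim1$records)
  expect_equal(b1$blue[match(sim1$records$genotype, b1$genotype)],
               sim1$records$value, tolerance = 1e-8)
})

test_that("BLUEs recover known genotype effects", {
  g <- simulate_genotypes(100, 60, seed = 7)
  d <- simulate_trial_design(100, 1, 1, 2, 4, seed = 8)
  spec <- trait_spec("t", 1, 0, 0, 0.05, 0.1,
                     env_means = setNames(0, unique(d$env)), n_qtl = 40)
  sim <- simulate_phenotypes(g, d, spec, seed = 9)
  b <- compute_blues(sim$records)
  expect_gt(cor(b$blue, sim$truth$genetic_values[b$genotype]), 0.95)
})

test_that("environment correlations behave on exact and simulated input", {
  base <- tibble(genotype = sprintf("G%02d", 1:20), trait = "t",
                 blue = rnorm(20), se = 0.1)
  b <- bind_rows(base |> mutate(env = "E1"),
                 base |> mutate(env = "E2"),
                 base |> mutate(env = "E3", blue = -.data$blue))
  r <- env_correlations(b)
  expect_equal(r$r[r$env1 == "E1" & r$env2 == "E2"], 1.0)
  expect_equal(r$r[r$env1 == "E1" & r$env2 == "E3"], -1.0)

  const <- bind_rows(base |> mutate(env = "E1"),
                     base |> mutate(env = "E2", blue = 1))
  expect_true(is.na(env_correlations(const)$r))

  # cross-environment genetic correlation 0.8, H2 = 0.9
  rs <- sapply(1:10, function(s) {
    set.seed(s)
    common <- rnorm(100)
    mk <- function() sqrt(0.8) * common + sqrt(0.2) * rnorm(100) +
      rnorm(100, sd = sqrt(1 / 0.9 - 1))
    bb <- bind_rows(
      tibble(genotype = sprintf("G%03d", 1:100), trait = "t",
             env = "E1", blue = mk(), se = 0.1),
      tibble(genotype = sprintf("G%03d", 1:100), trait = "t",
             env = "E2", blue = mk(), se = 0.1)
    )
    env_correlations(bb)$r
  })
  expect_gt(mean(rs), 0.6)
  expect_lt(mean(rs), 0.9)
})

test_that("tidy and glance summarise a variance decomposition", {
  g <- simulate_genotypes(40, 30, seed = 1)
  d <- simulate_trial_design(40, 2, 2, 2, 2, seed = 2)
  spec <- trait_spec("t", 1, 0.2, 0.2, 0.1, 1,
                     env_means = setNames(rep(0, 4), unique(d$env)),
                     n_qtl = 20)
  vc <- decompose_variance(simulate_phenotypes(g, d, spec, seed = 3)$records)
  td <- tidy(vc)
  expect_equal(nrow(td), 5L)
  expect_equal(sum(td$proportion), 1, tolerance = 1e-10)
  gl <- glance(vc)
  expect_true(gl$H2 >= 0 && gl$H2 <= 1)
  expect_equal(gl$N_R, 8)
})
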