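# Shared in-code fixtures. Everything is generated at test time; sizes
# are kept small so single fits run in well under a second.

suppressMessages({
  library(dplyr)
  library(tidyr)
})

`%||%` <- function(x, y) if (is.null(x)) y else x

# A small related panel plus its GRM.
make_panel <- function(n_geno = 40, n_markers = 200, seed = 1,
                       n_families = 8, fst = 0.4) {
  geno <- simulate_genotypes(n_geno, n_markers, seed = seed,
                             n_families = n_families, fst = fst)
  list(geno = geno, K = grm_vanraden(geno))
}

# Stacked (genotype, env) index over a kinship's genotypes.
make_index <- function(K, envs) {
  crossing(env = envs, genotype = rownames(K)) |>
    arrange(match(env, envs), genotype)
}

# Draw y from a multi-environment kernel model at given variances.
draw_response <- function(index, K, v_main, v_gxe, v_resid, seed,
                          env_effects = NULL) {
  set.seed(seed)
  envs <- unique(index$env)
  ids <- rownames(K)
  L <- t(chol(as.matrix(K) + diag(1e-8, nrow(K))))
  gmain <- drop(L %*% rnorm(nrow(K))) * sqrt(v_main)
  names(gmain) <- ids
  y <- numeric(nrow(index))
  for (e in envs) {
    ge <- drop(L %*% rnorm(nrow(K))) * sqrt(v_gxe)
    names(ge) <- ids
    i <- which(index$env == e)
    mu <- if (is.null(env_effects)) 0 else env_effects[[e]]
    y[i] <- mu + gmain[index$genotype[i]] + ge[index$genotype[i]] +
      rnorm(length(i), sd = sqrt(v_resid))
  }
  y
}

# Dense GLS predictor: the brute-force oracle for solve_blup. Builds the
# full joint covariance and predicts masked positions by conditional
# expectation -- a completely different route from the mixed-model
# equations.
gls_oracle <- function(y, kernels, variances) {
  n <- length(y)
  obs <- !is.na(y)
  X <- kernels$X
  V <- diag(variances[["residual"]], n)
  G <- matrix(0, n, n)
  for (k in kernels$kernels) {
    G <- G + variances[[k$label]] * as.matrix(k$matrix)
  }
  V <- V + G
  Vo <- V[obs, obs]
  Xo <- X[obs, , drop = FALSE]
  beta <- solve(t(Xo) %*% solve(Vo, Xo), t(Xo) %*% solve(Vo, y[obs]))
  r <- y[obs] - Xo %*% beta
  drop(X %*% beta + G[, obs] %*% solve(Vo, r))
}

# Expected-mean-squares closed form for the balanced one-way random
# model: sigma2_e = MSW, sigma2_g = (MSB - MSW) / r.
ems_oneway <- function(y, group) {
  r <- length(y) / length(unique(group))
  means <- tapply(y, group, mean)
  msb <- r * sum((means - mean(y))^2) / (length(means) - 1)
  msw <- sum((y - means[group])^2) / (length(y) - length(means))
  c(sigma2_g = (msb - msw) / r, sigma2_e = msw)
}

# Default qualitative-study conditions (shared with the acceptance
# checks): a structured 100-line panel in the standard 4-environment
# trial.
qual_dataset <- function(seed, trait = "PH", wl_step = 5) {
  geno <- simulate_genotypes(100, 300, seed = seed, n_families = 10,
                             fst = 0.45)
  design <- simulate_trial_design(100, 2, 2, 2, 5, seed = seed + 100)
  tsp <- default_trait_specs()[[trait]]
  tsp$n_qtl <- 100L
  sim <- simulate_phenotypes(geno, design, tsp, seed = seed + 200)
  sspec <- spectra_spec(
    wavelength_grid = seq(1000, 2500, by = wl_step),
    target_h2_profile = 0.85, noise_sd = 0.02, env_shift_sd = 0.1,
    block_sd = 0.02, trait_share = 0.2, trait_cor = 0.5, rank = 20,
    dense_share = 0.6
  )
  spectra <- simulate_spectra(geno, design, sspec, seed = seed + 300,
                              genetic_values = sim$truth$genetic_values)
  list(geno = geno, design = design, sim = sim, spectra = spectra)
}

qual_hrms <- function(dat, window = 17) {
  pre <- preprocess_spectra(dat$spectra, "der2", window = window)
  envs <- unique(dat$design$env)
  setNames(lapply(envs, function(e) hrm(spectra_blups(pre, e))), envs)
}
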