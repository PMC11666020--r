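#' Specify simulated NIRS spectra
#'
#' Controls the generative model for plot-level reflectance curves: a
#' smooth genotype-specific genetic signal built from low-rank marker
#' factors, an additive wavelength-smooth environment shift, a scalar
#' block effect, and white measurement noise. The per-wavelength genetic
#' variance is set so the plug-in wavelength heritability (with the
#' design's replicate count) matches `target_h2_profile`.
#'
#' @param wavelength_grid Numeric nm grid (evenly spaced); default the
#'   1,000-2,500 nm range at 1 nm.
#' @param target_h2_profile Per-wavelength heritability target in `[0,1]`,
#'   recycled to the grid length.
#' @param genetic_loading Strength in `[0,1]` of the genetic signal; 0
#'   removes all genetic variance from the spectra.
#' @param env_shift_sd SD of the smooth additive per-environment shift.
#' @param noise_sd Residual (plot x wavelength) SD.
#' @param block_sd SD of the scalar block effect.
#' @param rank Number of latent marker-driven factors behind the genetic
#'   signal; low rank makes the hyperspectral relationship matrix a noisy
#'   proxy of the genomic one.
#' @param trait_share Average fraction of the spectral genetic variance
#'   carried by the leading latent factor (the trait-linked one when
#'   `genetic_values` is supplied to [simulate_spectra()]).
#' @param trait_cor Correlation between the leading latent factor and
#'   the trait's genetic values; spectra capture a trait's genetics only
#'   partially, and this sets how much. 1 puts the trait exactly in the
#'   spectral genetic span.
#' @param dense_share Fraction of the spectral genetic variance that is a
#'   dense per-genotype fingerprint (independent across genotypes and
#'   wavelengths) rather than the shared low-rank factors. The
#'   fingerprint makes the hyperspectral relationship matrix
#'   diagonal-dominant, which is what lets sparse-testing designs carry a
#'   genotype's own record across environments.
#' @return A `spectra_spec` list.
#' @export
spectra_spec <- function(wavelength_grid = seq(1000, 2500, by = 1),
                         target_h2_profile = 0.5, genetic_loading = 1,
                         env_shift_sd = 0.1, noise_sd = 0.05,
                         block_sd = 0, rank = 20L, trait_share = 0.25,
                         trait_cor = 0.6, dense_share = 0.3) {
  h2 <- rep_len(target_h2_profile, length(wavelength_grid))
  if (any(h2 < 0 | h2 > 1)) abort("`target_h2_profile` must lie in [0, 1]")
  structure(
    list(
      n_wavelengths = length(wavelength_grid),
      wavelength_grid = wavelength_grid,
      target_h2_profile = h2,
      genetic_loading = genetic_loading,
      env_shift_sd = env_shift_sd,
      noise_sd = noise_sd,
      block_sd = block_sd,
      rank = check_scalar_count(rank, "rank"),
      trait_share = trait_share,
      trait_cor = trait_cor,
      dense_share = dense_share
    ),
    class = "spectra_spec"
  )
}

new_spectra_set <- function(df, wavelengths, preprocessing = character()) {
  structure(df, wavelengths = wavelengths, preprocessing = preprocessing,
            class = c("spectra_set", class(tibble())))
}

#' @export
print.spectra_set <- function(x, ...) {
  wl <- attr(x, "wavelengths")
  cat(sprintf(
    "<spectra_set> %d plot spectra, %d wavelengths (%.0f-%.0f nm)%s\n",
    nrow(x), length(wl), min(wl), max(wl),
    if (length(attr(x, "preprocessing")))
      paste0(", preprocessing: ",
             paste(attr(x, "preprocessing"), collapse = " -> "))
    else ""
  ))
  NextMethod()
}

#' Extract the wavelength grid of a spectra set
#' @param spectra A `spectra_set`.
#' @return Numeric vector of wavelengths (nm).
#' @export
wavelengths <- function(spectra) attr(spectra, "wavelengths")

# Reflectance columns of a spectra_set as a plain matrix.
spectra_matrix <- function(spectra) {
  as.matrix(spectra[, grep("^wl_", names(spectra)), drop = FALSE])
}

#' Simulate plot-level reflectance spectra
#'
#' Generates one reflectance curve per plot of the design:
#' baseline + genetic curve + environment shift + block effect + noise.
#' The genetic curve of a genotype is a linear combination of `rank`
#' marker-driven latent factors with wavelength-smooth loadings, scaled
#' per wavelength to hit `spec$target_h2_profile`; if `genetic_values`
#' are supplied (a trait's true additive values) they are embedded as the
#' leading factor so spectra and trait share genetic signal.
#'
#' @param geno A `genotype_matrix`.
#' @param design Trial-design tibble.
#' @param spec A [spectra_spec()].
#' @param seed Integer seed.
#' @param genetic_values Optional named numeric vector of true trait
#'   genetic values used as the leading latent factor.
#' @return A `spectra_set` tibble (genotype, env, rep, block, `wl_*`
#'   columns) with the true genetic spectra matrix in attribute `truth`.
#' @export
simulate_spectra <- function(geno, design, spec, seed = 1L,
                             genetic_values = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(spec, "spectra_spec"))
  ids <- rownames(geno$dosage)
  grid <- spec$wavelength_grid
  L <- spec$n_wavelengths
  n_reps <- design |>
    count(.data$genotype, .data$env) |>
    summarise(m = harmonic_mean(.data$n)) |>
    pull(.data$m)
  with_seed(seed, {
    # latent marker-driven factors, standardized across the panel
    Z <- scale(geno$dosage, center = TRUE, scale = FALSE)
    f <- sapply(seq_len(spec$rank), function(r) {
      raw <- drop(Z %*% rnorm(ncol(Z)))
      if (sd(raw) > 0) (raw - mean(raw)) / sd(raw) else raw
    })
    if (!is.null(genetic_values)) {
      gv <- genetic_values[ids]
      if (sd(gv) > 0) {
        gvs <- (gv - mean(gv)) / sd(gv)
        # residualize every factor against the trait signal so the
        # spectra-trait overlap is controlled, not a chance alignment of
        # random marker combinations
        for (r in seq_len(spec$rank)) {
          res <- f[, r] - gvs * sum(f[, r] * gvs) / sum(gvs^2)
          if (sd(res) > 0) f[, r] <- (res - mean(res)) / sd(res)
        }
        # leading factor: trait signal attenuated to `trait_cor`
        tc <- min(max(spec$trait_cor, 0), 1)
        f[, 1] <- tc * gvs + sqrt(1 - tc^2) * f[, 1]
      }
    }
    # smooth loadings; the leading factor's rows are rescaled so it
    # carries `trait_share` of the genetic variance on average across
    # wavelengths, then the combined signal is standardized per wavelength
    B <- smooth_rows(matrix(rnorm(spec$rank * L), spec$rank, L), grid,
                     length_scale = 75)
    if (spec$rank > 1L && spec$trait_share > 0 && spec$trait_share < 1) {
      w1 <- sum(B[1, ]^2)
      wr <- sum(B[-1, , drop = FALSE]^2)
      B[1, ] <- B[1, ] * sqrt(spec$trait_share / (1 - spec$trait_share) *
                                wr / w1)
    }
    g0 <- f %*% B
    csd <- apply(g0, 2, sd)
    csd[csd == 0] <- 1
    g0 <- sweep(g0, 2, csd, "/")
    if (spec$dense_share > 0) {
      dense <- matrix(rnorm(nrow(g0) * L), nrow(g0), L)
      g0 <- sqrt(1 - spec$dense_share) * g0 + sqrt(spec$dense_share) * dense
    }
    h2 <- pmin(spec$target_h2_profile, 0.999)
    sigma_g <- if (spec$noise_sd > 0) {
      sqrt(h2 / (1 - h2) * spec$noise_sd^2 / n_reps)
    } else {
      sqrt(h2)
    }
    G <- spec$genetic_loading * sweep(g0, 2, sigma_g, "*")
    rownames(G) <- ids
    baseline <- 0.5 + 0.2 * drop(smooth_rows(matrix(rnorm(L), 1), grid, 200))
    envs <- unique(design$env)
    shift <- smooth_rows(matrix(rnorm(length(envs) * L), length(envs), L),
                         grid, 100) * spec$env_shift_sd
    rownames(shift) <- envs
    blocks <- design |> distinct(.data$env, .data$rep, .data$block)
    blocks$beffect <- rnorm(nrow(blocks), sd = spec$block_sd)
    d2 <- design |> left_join(blocks, by = c("env", "rep", "block"))
    refl <- matrix(baseline, nrow(d2), L, byrow = TRUE) +
      G[d2$genotype, , drop = FALSE] +
      shift[d2$env, , drop = FALSE] +
      d2$beffect +
      matrix(rnorm(nrow(d2) * L, sd = spec$noise_sd), nrow(d2), L)
    colnames(refl) <- sprintf("wl_%d", round(grid))
    out <- bind_cols(
      d2 |> select("genotype", "env", "rep", "block"),
      as_tibble(refl)
    )
    res <- new_spectra_set(out, wavelengths = grid)
    attr(res, "truth") <- list(genetic_spectra = G, sigma_g = sigma_g,
                               env_shift = shift)
    res
  })
}
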