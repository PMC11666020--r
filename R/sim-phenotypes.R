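#' Specify a simulated trait
#'
#' Bundles the variance components and environment means that drive
#' [simulate_phenotypes()]. The five variances correspond to the terms of
#' the plot-level variance-decomposition model: genotype main effect,
#' genotype-by-year and genotype-by-nitrogen deviations, block nested in
#' replicate within environment, and the plot residual.
#'
#' @param name Trait label.
#' @param var_geno,var_geno_year,var_geno_nitro,var_block,var_resid
#'   Non-negative variances, in squared trait units.
#' @param env_means Named numeric vector of per-environment means
#'   (names are environment labels such as "2015-HN").
#' @param n_qtl Number of causal markers behind the additive genetic value.
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(name, var_geno, var_geno_year = 0, var_geno_nitro = 0,
                       var_block = 0, var_resid = 0, env_means, n_qtl = 100L) {
  vars <- c(var_geno, var_geno_year, var_geno_nitro, var_block, var_resid)
  if (any(!is.finite(vars)) || any(vars < 0)) {
    abort("all trait variances must be finite and >= 0")
  }
  structure(
    list(
      name = name, var_geno = var_geno, var_geno_year = var_geno_year,
      var_geno_nitro = var_geno_nitro, var_block = var_block,
      var_resid = var_resid, env_means = env_means,
      n_qtl = check_scalar_count(n_qtl, "n_qtl")
    ),
    class = "trait_spec"
  )
}

#' Default trait specifications for the six-trait rice-like panel
#'
#' Variance fractions and environment means chosen so that simulated
#' broad-sense heritabilities, variance decompositions and
#' between-environment correlations fall in the ranges typical of an
#' upland-rice diversity panel grown in four year-by-nitrogen
#' environments: days to flowering (DF), plant height (PH), thousand-grain
#' weight (TGW), grain yield (GY), harvest index (HI) and grain nitrogen
#' content (GNC). Absolute variance scales follow each trait's phenotypic
#' standard deviation; only the fractions are structurally meaningful.
#'
#' @param environments Character vector of the four environment labels.
#' @return Named list of [trait_spec()] objects.
#' @export
default_trait_specs <- function(environments = c("2015-HN", "2015-LN",
                                                 "2016-HN", "2016-LN")) {
  stopifnot(length(environments) == 4L)
  # (mean, sd, fractions geno/gxY/gxN/block/resid, year shift, HN shift)
  tab <- list(
    DF  = list(93.2, 7.22, c(.62, .08, .02, .04, .24), yr = -1.0, hn = 0.0, qtl = 60L),
    PH  = list(102.5, 16.6, c(.75, .03, .02, .05, .15), yr = 8.0, hn = 15.7, qtl = 120L),
    TGW = list(28.2, 4.53, c(.81, .02, .01, .02, .14), yr = 1.2, hn = -0.51, qtl = 120L),
    GY  = list(4162, 1490, c(.22, .15, .10, .10, .43), yr = 600, hn = 1111, qtl = 200L),
    HI  = list(0.46, 0.08, c(.45, .08, .05, .05, .37), yr = 0.02, hn = -0.04, qtl = 150L),
    GNC = list(1.56, 0.18, c(.25, .10, .10, .10, .45), yr = 0.05, hn = 0.40, qtl = 80L)
  )
  yrs <- as.integer(substr(environments, 1, 4))
  hn <- grepl("HN", environments)
  imap(tab, function(d, nm) {
    v <- d[[2]]^2 * d[[3]]
    mu <- d[[1]] + d$yr * (yrs - mean(yrs)) / diff(range(yrs)) * 2 +
      d$hn * (hn - mean(hn))
    trait_spec(nm, v[1], v[2], v[3], v[4], v[5],
               env_means = setNames(mu, environments), n_qtl = d$qtl)
  })
}

#' Simulate plot-level phenotypes from a trial design
#'
#' Builds each plot value as environment mean + additive genetic value
#' (from `n_qtl` randomly chosen markers, effects rescaled so the realized
#' genetic variance across the panel equals `var_geno`) + independent
#' genotype-by-year and genotype-by-nitrogen deviations + block effect +
#' residual, each drawn normal with the spec's variance. The generating
#' component values are returned so recovery tests can compare estimates
#' against truth.
#'
#' @param geno A `genotype_matrix`.
#' @param design A trial-design tibble from [simulate_trial_design()].
#' @param spec A [trait_spec()].
#' @param seed Integer seed.
#' @return List of class `trait_sim` with `records` (tibble: genotype,
#'   year, nitro, env, rep, block, trait, value) and `truth` (genetic
#'   values and interaction deviations per genotype).
#' @export
simulate_phenotypes <- function(geno, design, spec, seed = 1L) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(spec, "trait_spec"))
  ids <- rownames(geno$dosage)
  if (!all(unique(design$genotype) %in% ids)) {
    abort("design contains genotypes absent from `geno`")
  }
  envs <- unique(design$env)
  if (!all(envs %in% names(spec$env_means))) {
    abort("`spec$env_means` must name every environment in the design")
  }
  if (spec$n_qtl > ncol(geno$dosage)) abort("n_qtl exceeds marker count")
  years <- sort(unique(design$year))
  nitros <- sort(unique(design$nitro))
  with_seed(seed, {
    gv <- additive_values(geno, spec$n_qtl, spec$var_geno)
    # interaction deviations are polygenic too (fresh random QTL per
    # environment level, independent across levels): genotypes related
    # through the markers share G-by-E response, which is what the
    # prediction models' I (x) K deviation kernels assume
    g_year <- sapply(as.character(years), function(yy) {
      additive_values(geno, spec$n_qtl, spec$var_geno_year)
    })
    g_nitro <- sapply(nitros, function(nn) {
      additive_values(geno, spec$n_qtl, spec$var_geno_nitro)
    })
    rownames(g_year) <- rownames(g_nitro) <- ids
    blocks <- design |> distinct(.data$env, .data$rep, .data$block)
    blocks$effect <- rnorm(nrow(blocks), sd = sqrt(spec$var_block))
    rec <- design |>
      left_join(blocks, by = c("env", "rep", "block")) |>
      mutate(
        trait = spec$name,
        value = unname(spec$env_means[.data$env]) +
          gv[.data$genotype] +
          g_year[cbind(.data$genotype, as.character(.data$year))] +
          g_nitro[cbind(.data$genotype, .data$nitro)] +
          .data$effect +
          rnorm(n(), sd = sqrt(spec$var_resid))
      ) |>
      mutate(value = unname(.data$value)) |>
      select("genotype", "year", "nitro", "env", "rep", "block",
             "trait", "value")
    structure(
      list(
        records = rec,
        truth = list(
          genetic_values = gv,
          geno_year = g_year,
          geno_nitro = g_nitro,
          block_effects = blocks
        ),
        spec = spec
      ),
      class = "trait_sim"
    )
  })
}

# Additive genetic values from n_qtl markers, rescaled to hit var_geno
# exactly across the panel (zero markers' variance => all-zero values).
additive_values <- function(geno, n_qtl, var_geno) {
  ids <- rownames(geno$dosage)
  qtl <- sample(ncol(geno$dosage), n_qtl)
  beta <- rnorm(n_qtl)
  Z <- scale(geno$dosage[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
  raw <- drop(Z %*% beta)
  s <- sd(raw)
  gv <- if (s > 0 && var_geno > 0) raw * sqrt(var_geno) / s else raw * 0
  setNames(gv, ids)
}

#' @export
print.trait_sim <- function(x, ...) {
  cat(sprintf("<trait_sim> trait '%s': %d plot records, %d genotypes\n",
              x$spec$name, nrow(x$records),
              length(x$truth$genetic_values)))
  invisible(x)
}
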