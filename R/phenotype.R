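#' Flag outlying plot values per environment
#'
#' Tukey boxplot rule applied separately within each environment (and
#' trait): a value is flagged when it falls outside the hinges by more
#' than `coef` times the hinge spread. Hinges are Tukey's (the boxplot
#' convention), which differ from interpolated quantiles on small
#' samples. Records are only flagged, never removed.
#'
#' @param records Phenotype tibble with columns `genotype`, `env`,
#'   `trait`, `value`.
#' @param coef Fence coefficient; default 1.5.
#' @return The input with a logical `outlier` column appended.
#' @export
flag_outliers <- function(records, coef = 1.5) {
  stopifnot(is.numeric(coef), coef > 0)
  records |>
    group_by(.data$env, .data$trait) |>
    mutate(outlier = {
      v <- .data$value
      ok <- !is.na(v)
      if (sum(ok) < 4L) {
        warn(sprintf("group %s/%s has < 4 observations; no outliers flagged",
                     .data$env[1], .data$trait[1]))
        rep(FALSE, length(v))
      } else {
        h <- fivenum(v[ok])
        iqr <- h[4] - h[2]
        !is.na(v) & (v < h[2] - coef * iqr | v > h[4] + coef * iqr)
      }
    }) |>
    ungroup()
}

# Shared REML engine: fit a mixed model by REML via lme4 and return the
# variance components as a named vector plus the fit object. All modules
# route their variance-component estimation through here so phenotype and
# spectra analyses use one engine.
varcomp_reml <- function(formula, data, control = NULL) {
  ctrl <- control %||% lme4::lmerControl(
    check.conv.singular = "ignore",
    calc.derivs = FALSE
  )
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(formula, data = data, REML = TRUE, control = ctrl)
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comps <- setNames(vc$vcov, vc$grp)
  conv <- is.null(fit@optinfo$conv$lme4$messages) ||
    !any(grepl("failed to converge", fit@optinfo$conv$lme4$messages))
  list(fit = fit, components = comps, converged = conv)
}

#' Decompose phenotypic variance of a multi-environment trial
#'
#' Fits, by REML, the plot-level mixed model with fixed year, nitrogen
#' and replicate-within-(nitrogen-within-year) effects and random
#' block-within-replicate, genotype, genotype-by-year and
#' genotype-by-nitrogen effects plus the residual. Also computes the
#' harmonic means of the numbers of years, nitrogen treatments and
#' replicates per genotype realized in the data, as needed by the
#' broad-sense heritability plug-in.
#'
#' @param records Phenotype tibble for one trait with columns `genotype`,
#'   `year`, `nitro`, `rep`, `block`, `value` (rows with missing values
#'   are dropped).
#' @return An object of class `varcomp` with components `var_geno`,
#'   `var_geno_year`, `var_geno_nitro`, `var_block`, `var_resid`,
#'   `harmonic_means`, `fixed_effects`, `converged`.
#' @export
decompose_variance <- function(records) {
  records <- records |> filter(!is.na(.data$value))
  if (length(unique(records$genotype)) < 2L) {
    abort("at least 2 genotype levels are required")
  }
  for (f in c("year", "nitro")) {
    if (length(unique(records[[f]])) < 2L) {
      abort(sprintf("at least 2 `%s` levels are required", f))
    }
  }
  d <- records |>
    mutate(
      year_f = factor(.data$year), nitro_f = factor(.data$nitro),
      rep_f = interaction(.data$year, .data$nitro, .data$rep, drop = TRUE),
      block_f = interaction(.data$year, .data$nitro, .data$rep, .data$block,
                            drop = TRUE),
      geno_f = factor(.data$genotype),
      gy = interaction(.data$genotype, .data$year, drop = TRUE),
      gn = interaction(.data$genotype, .data$nitro, drop = TRUE)
    )
  if (sd(d$value) == 0) {
    comps <- c(var_geno = 0, var_geno_year = 0, var_geno_nitro = 0,
               var_block = 0, var_resid = 0)
    fx <- c(`(Intercept)` = d$value[1])
    conv <- TRUE
  } else {
    res <- varcomp_reml(
      value ~ year_f + nitro_f + rep_f +
        (1 | block_f) + (1 | geno_f) + (1 | gy) + (1 | gn),
      data = d
    )
    cc <- res$components
    comps <- c(
      var_geno = unname(cc["geno_f"]),
      var_geno_year = unname(cc["gy"]),
      var_geno_nitro = unname(cc["gn"]),
      var_block = unname(cc["block_f"]),
      var_resid = unname(cc["Residual"])
    )
    fx <- lme4::fixef(res$fit)
    conv <- res$converged
  }
  hm <- list(
    N_Year = harmonic_mean(
      (d |> count(.data$genotype, .data$year) |> count(.data$genotype))$n),
    N_Nitro = harmonic_mean(
      (d |> count(.data$genotype, .data$nitro) |> count(.data$genotype))$n),
    N_R = harmonic_mean((d |> count(.data$genotype))$n)
  )
  structure(
    c(as.list(comps),
      list(harmonic_means = hm, fixed_effects = fx, converged = conv)),
    class = "varcomp"
  )
}

#' @export
print.varcomp <- function(x, ...) {
  cat("<varcomp> REML variance components\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @export
tidy.varcomp <- function(x, ...) {
  est <- c(x$var_geno, x$var_geno_year, x$var_geno_nitro, x$var_block,
           x$var_resid)
  tibble(
    component = c("geno", "geno:year", "geno:nitro", "block(rep)", "residual"),
    estimate = est,
    proportion = if (sum(est) > 0) est / sum(est) else rep(NA_real_, 5)
  )
}

#' @export
glance.varcomp <- function(x, ...) {
  tibble(
    H2 = broad_sense_heritability(x),
    N_Year = x$harmonic_means$N_Year,
    N_Nitro = x$harmonic_means$N_Nitro,
    N_R = x$harmonic_means$N_R,
    converged = x$converged
  )
}

#' Broad-sense heritability from variance components
#'
#' Plug-in estimator
#' \deqn{H^2 = \sigma^2_{geno} / (\sigma^2_{geno} +
#'   \sigma^2_{geno:Year}/N_{Year} + \sigma^2_{geno:Nitro}/N_{Nitro} +
#'   \sigma^2_e/N_R)}
#' with the harmonic means of the realized numbers of years, nitrogen
#' treatments and replicates per genotype.
#'
#' @param vc A `varcomp` object, or a named list with fields `var_geno`,
#'   `var_geno_year`, `var_geno_nitro`, `var_resid` and `harmonic_means`
#'   (list with `N_Year`, `N_Nitro`, `N_R`).
#' @return H-squared in `[0, 1]`.
#' @export
broad_sense_heritability <- function(vc) {
  hm <- vc$harmonic_means
  denom <- vc$var_geno + vc$var_geno_year / hm$N_Year +
    vc$var_geno_nitro / hm$N_Nitro + vc$var_resid / hm$N_R
  if (denom == 0) abort("all variance components are zero; H2 is undefined")
  vc$var_geno / denom
}

#' Per-environment genotype BLUEs
#'
#' Within each environment, fits the mixed model with genotype as a fixed
#' effect and replicate and block-within-replicate as random effects, and
#' reports the genotype best linear unbiased estimates on the trait scale
#' (intercept added back), with standard errors.
#'
#' @param records Phenotype tibble for one trait (columns `genotype`,
#'   `env`, `rep`, `block`, `value`); may span several environments.
#' @return Tibble with columns `genotype`, `env`, `trait`, `blue`, `se`.
#' @export
compute_blues <- function(records) {
  records |>
    filter(!is.na(.data$value)) |>
    group_by(.data$env, .data$trait) |>
    group_map(function(d, key) {
      d <- d |> mutate(
        geno_f = factor(.data$genotype),
        rep_f = factor(.data$rep),
        block_f = interaction(.data$rep, .data$block, drop = TRUE)
      )
      if (nlevels(d$rep_f) > 1L || nlevels(d$block_f) > 1L) {
        fit <- suppressMessages(suppressWarnings(lme4::lmer(
          value ~ 0 + geno_f + (1 | rep_f) + (1 | block_f),
          data = d,
          control = lme4::lmerControl(check.conv.singular = "ignore",
                                      calc.derivs = FALSE)
        )))
        est <- lme4::fixef(fit)
        se <- sqrt(Matrix::diag(vcov(fit)))
      } else {
        fit <- lm(value ~ 0 + geno_f, data = d)
        est <- coef(fit)
        se <- sqrt(diag(vcov(fit)))
        se[is.nan(se)] <- NA_real_
      }
      tibble(
        genotype = sub("^geno_f", "", names(est)),
        env = key$env, trait = key$trait,
        blue = unname(est), se = unname(se)
      )
    }) |>
    list_rbind() |>
    arrange(.data$trait, .data$env, .data$genotype)
}

#' Pearson correlations of genotype BLUEs between environments
#'
#' For each trait, computes pairwise-complete Pearson correlations (and
#' p-values) between the per-environment BLUE vectors over the genotypes
#' common to each environment pair.
#'
#' @param blues A BLUE tibble from [compute_blues()].
#' @return Tibble with columns `trait`, `env1`, `env2`, `r`, `p_value`, `n`.
#' @export
env_correlations <- function(blues) {
  blues |>
    group_by(.data$trait) |>
    group_map(function(d, key) {
      wide <- d |>
        select("genotype", "env", "blue") |>
        pivot_wider(names_from = "env", values_from = "blue")
      envs <- setdiff(names(wide), "genotype")
      if (length(envs) < 2L) return(tibble())
      utils::combn(envs, 2L, simplify = FALSE) |>
        map(function(pr) {
          x <- wide[[pr[1]]]; y <- wide[[pr[2]]]
          ok <- complete.cases(x, y)
          n <- sum(ok)
          if (n < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
            tibble(trait = key$trait, env1 = pr[1], env2 = pr[2],
                   r = NA_real_, p_value = NA_real_, n = n)
          } else {
            ct <- cor.test(x[ok], y[ok])
            tibble(trait = key$trait, env1 = pr[1], env2 = pr[2],
                   r = unname(ct$estimate), p_value = ct$p.value, n = n)
          }
        }) |>
        list_rbind()
    }) |>
    list_rbind()
}
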