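#' The standard sparse-testing cross-validation scenarios
#'
#' Builds the 14 scenario definitions of the four-environment study
#' design: scenarios 1-4 are single-environment k-fold cross-validations
#' (k = 2 or 5); scenarios 5-10 put one full environment in the training
#' population plus 0/10/50/80% of a target environment; scenarios 11-14
#' put two full environments in the training population plus 0/50/80% of
#' the third. The remainder of the target environment is always the
#' validation population.
#'
#' @param environments Ordered character vector of exactly 4 environment
#'   labels (year x nitrogen cells).
#' @return Tibble with columns `scenario_id`, `n_env`, `full_tp_envs`
#'   (list), `target_env`, `fractions` (list), `k_folds` (list).
#' @export
make_scenarios <- function(environments = c("2015-HN", "2015-LN",
                                            "2016-HN", "2016-LN")) {
  if (length(environments) != 4L || anyDuplicated(environments)) {
    abort("exactly 4 distinct environments are required")
  }
  e <- environments
  single <- tibble(
    scenario_id = 1:4, n_env = 1L,
    full_tp_envs = map(1:4, function(i) character()),
    target_env = e,
    fractions = map(1:4, function(i) numeric()),
    k_folds = map(1:4, function(i) c(2L, 5L))
  )
  two <- tibble(
    scenario_id = 5:10, n_env = 2L,
    full_tp_envs = map(c(1, 2, 1, 3, 4, 2), function(i) e[i]),
    target_env = e[c(2, 1, 3, 4, 3, 4)],
    fractions = map(5:10, function(i) c(0, 0.10, 0.50, 0.80)),
    k_folds = map(5:10, function(i) integer())
  )
  three <- tibble(
    scenario_id = 11:14, n_env = 3L,
    full_tp_envs = list(e[c(1, 2)], e[c(1, 2)], e[c(1, 4)], e[c(2, 3)]),
    target_env = e[c(3, 4, 3, 4)],
    fractions = map(11:14, function(i) c(0, 0.50, 0.80)),
    k_folds = map(11:14, function(i) integer())
  )
  bind_rows(single, two, three)
}

#' Partition genotypes into training and validation sets
#'
#' Either a random k-fold split (each genotype lands in exactly one
#' validation fold) or a simple random draw of a training fraction.
#' Deterministic given `seed`.
#'
#' @param genotype_ids Character vector.
#' @param fraction Training fraction of the target environment (sparse
#'   testing); exactly one of `fraction`/`k` must be given.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return For k-fold: tibble `genotype`, `fold`. For a fraction: tibble
#'   `genotype`, `in_tp`.
#' @export
partition_population <- function(genotype_ids, fraction = NULL, k = NULL,
                                 seed = 1L) {
  n <- length(genotype_ids)
  if (!is.null(k)) {
    k <- check_scalar_count(k, "k", min = 2L)
    with_seed(seed, {
      fold <- sample(rep_len(seq_len(k), n))
      tibble(genotype = genotype_ids, fold = fold)
    })
  } else if (!is.null(fraction)) {
    if (fraction < 0 || fraction >= 1) {
      abort("`fraction` must be in [0, 1): the validation set cannot be empty")
    }
    n_tp <- round(fraction * n)
    if (n_tp >= n) abort("training fraction leaves an empty validation set")
    with_seed(seed, {
      tp <- sample(n, n_tp)
      tibble(genotype = genotype_ids, in_tp = seq_len(n) %in% tp)
    })
  } else {
    abort("supply `fraction` or `k`")
  }
}

#' Predictive ability
#'
#' Pearson correlation between predicted values and observed BLUEs of the
#' validation set. Undefined (returned as `NA` with a warning) when
#' fewer than 3 pairs remain or either vector is constant.
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return A single correlation, or `NA`.
#' @export
predictive_ability <- function(predicted, observed) {
  ok <- complete.cases(predicted, observed)
  if (sum(ok) < 3L) {
    warn("fewer than 3 prediction pairs; predictive ability undefined")
    return(NA_real_)
  }
  if (sd(predicted[ok]) == 0 || sd(observed[ok]) == 0) {
    warn("constant predictions or observations; predictive ability undefined")
    return(NA_real_)
  }
  cor(predicted[ok], observed[ok])
}

#' Run one cross-validation scenario with replication
#'
#' For every replicate and fraction (or fold count), hides the validation
#' population's responses in the target environment, builds the model's
#' kernel set, fits it by Gibbs sampling, predicts the validation
#' genotypes and computes the predictive ability against their BLUEs.
#' Partitions depend only on (scenario, replicate), so different models
#' run on identical training sets and comparisons are paired. A leakage
#' guard asserts that no validation response is visible to the sampler.
#'
#' For phenomic information the hyperspectral matrix of the target
#' environment enters the kernel set only when some of that environment's
#' genotypes are in the training set (`include_target_hrm = "auto"`);
#' set `"always"`/`"never"` to force either choice.
#'
#' @param scenario One row of [make_scenarios()] (data frame or list).
#' @param model `"SM"`, `"MM"` or `"MDs"` (single-environment scenarios
#'   always use SM).
#' @param info `"GP"`, `"PP"` or `"GP+PP"`.
#' @param blues Tibble `genotype`, `env`, `blue` for one trait.
#' @param grm,hrms Relationship matrices as in [build_kernels()].
#' @param chain A `chain_params`; its seed is re-derived per fit.
#' @param n_replicates Number of replicated partitions (default 10).
#' @param fractions Optional subset of the scenario's fractions (or, for
#'   single-environment scenarios, fold counts) to run.
#' @param master_seed Base seed; replicate r of scenario s draws its
#'   partition from `master_seed + 1000 * s + r`.
#' @param include_target_hrm `"auto"`, `"always"` or `"never"`.
#' @return Tibble `scenario_id`, `model`, `info`, `fraction`, `replicate`,
#'   `pa`, `n_vp`.
#' @export
run_cv_scenario <- function(scenario, model = "MDs", info = "GP",
                            blues, grm = NULL, hrms = NULL,
                            chain = chain_preset("fast"),
                            n_replicates = 10L, fractions = NULL,
                            master_seed = 1L,
                            include_target_hrm = c("auto", "always",
                                                   "never")) {
  include_target_hrm <- match.arg(include_target_hrm)
  sc <- as.list(as.data.frame(scenario[1, , drop = FALSE]))
  sc$full_tp_envs <- scenario$full_tp_envs[[1]]
  sc$fractions <- scenario$fractions[[1]]
  sc$k_folds <- scenario$k_folds[[1]]
  single <- length(sc$full_tp_envs) == 0L
  if (single) model <- "SM"
  target <- sc$target_env
  envs <- c(sc$full_tp_envs, target)
  b <- blues |> filter(.data$env %in% envs)
  ids <- b |>
    count(.data$genotype) |>
    filter(.data$n == length(envs)) |>
    pull(.data$genotype)
  if (length(ids) < 10L) abort("too few genotypes with BLUEs in all environments")
  index <- crossing(env = envs, genotype = ids) |>
    arrange(match(.data$env, envs), .data$genotype)
  yfull <- (b |>
    right_join(index, by = c("genotype", "env")) |>
    arrange(match(.data$env, envs), .data$genotype))$blue
  levels_run <- if (single) {
    if (is.null(fractions)) sc$k_folds else fractions
  } else {
    fr <- if (is.null(fractions)) sc$fractions else fractions
    if (!all(fr %in% sc$fractions)) abort("fraction not defined for scenario")
    fr
  }
  target_rows <- which(index$env == target)
  out <- list()
  for (r in seq_len(n_replicates)) {
    part_seed <- as.integer(master_seed + 1000 * sc$scenario_id + r)
    for (lev in levels_run) {
      if (single) {
        folds <- partition_population(ids, k = lev, seed = part_seed)
        pred <- rep(NA_real_, length(ids))
        names(pred) <- ids
        hrms_sm <- if (is.null(hrms)) NULL else hrms[names(hrms) == target]
        for (f in sort(unique(folds$fold))) {
          vp <- folds$genotype[folds$fold == f]
          y <- yfull
          y[index$genotype %in% vp] <- NA
          fit <- fit_one(index, model, info, grm, hrms_sm, target, y,
                         chain, part_seed * 10L + f)
          pr <- predict(fit, tibble(genotype = vp, env = target))
          pred[pr$genotype] <- pr$predicted
        }
        pa <- predictive_ability(pred[ids], yfull[match(ids, index$genotype)])
        out[[length(out) + 1L]] <- tibble(
          scenario_id = sc$scenario_id, model = model, info = info,
          fraction = paste0("k", lev), replicate = r, pa = pa,
          n_vp = length(ids)
        )
      } else {
        part <- partition_population(ids, fraction = lev, seed = part_seed)
        vp <- part$genotype[!part$in_tp]
        y <- yfull
        mask <- target_rows[index$genotype[target_rows] %in% vp]
        y[mask] <- NA
        # leakage guard: every VP response in the target env is hidden
        stopifnot(all(is.na(y[index$env == target &
                                index$genotype %in% vp])))
        use_hrms <- hrms
        if (!is.null(hrms)) {
          keep <- names(hrms) %in% sc$full_tp_envs |
            (names(hrms) == target &
               (include_target_hrm == "always" ||
                  (include_target_hrm == "auto" && lev > 0)))
          use_hrms <- hrms[keep]
        }
        fit <- fit_one(index, model, info, grm, use_hrms, target, y,
                       chain, part_seed * 10L)
        pr <- predict(fit, tibble(genotype = vp, env = target))
        pa <- predictive_ability(
          pr$predicted, yfull[mask][match(pr$genotype,
                                          index$genotype[mask])]
        )
        out[[length(out) + 1L]] <- tibble(
          scenario_id = sc$scenario_id, model = model, info = info,
          fraction = sprintf("%d%%", round(100 * lev)), replicate = r,
          pa = pa, n_vp = length(vp)
        )
      }
    }
  }
  list_rbind(out)
}

fit_one <- function(index, model, info, grm, hrms, target, y, chain,
                    fit_seed) {
  ks <- build_kernels(index, model = model, info = info, grm = grm,
                      hrms = hrms)
  ch <- chain
  ch$seed <- as.integer(abs(fit_seed) %% 2147483000)
  fit_gibbs(y, ks, chain = ch)
}

#' Summarise replicated predictive abilities
#'
#' @param pa A tibble from [run_cv_scenario()] (rows may be pooled over
#'   scenarios/models).
#' @return Tibble of mean, SD and replicate count per
#'   scenario/model/info/fraction cell.
#' @export
summarise_pa <- function(pa) {
  pa |>
    group_by(.data$scenario_id, .data$model, .data$info, .data$fraction) |>
    summarise(
      mean_pa = mean(.data$pa, na.rm = TRUE),
      sd_pa = sd(.data$pa, na.rm = TRUE),
      n = sum(!is.na(.data$pa)),
      .groups = "drop"
    )
}

#' Compare predictive abilities on Fisher's z scale
#'
#' Applies the variance-stabilizing z-transformation `atanh(r)` to each
#' predictive ability, fits a fixed-effects linear model on the requested
#' factors, and reports back-transformed factor-level means plus
#' Tukey-adjusted pairwise contrasts. Correlations at exactly |r| = 1 are
#' clipped to 1 - 1e-12 with a warning.
#'
#' @param pa Tibble containing a `pa` column and the factor columns.
#' @param factors Character vector of column names to compare (e.g.
#'   `"info"`, `"model"`, `"fraction"`, `"scenario_id"`).
#' @return List of class `pa_comparison` with `means` (factor-level mean
#'   PA, back-transformed) and `contrasts` (pairwise differences on the z
#'   scale with adjusted p-values).
#' @export
compare_models <- function(pa, factors) {
  stopifnot(all(factors %in% names(pa)))
  d <- pa |> filter(!is.na(.data$pa))
  if (any(abs(d$pa) >= 1)) {
    warn("|r| = 1 clipped to 1 - 1e-12 before z-transformation")
    d$pa <- pmin(pmax(d$pa, -1 + 1e-12), 1 - 1e-12)
  }
  d$z <- atanh(d$pa)
  for (f in factors) d[[f]] <- factor(d[[f]])
  nlev <- map_dbl(factors, function(f) nlevels(d[[f]]))
  if (all(nlev < 2)) abort("at least one factor must have >= 2 levels")
  factors <- factors[nlev >= 2]
  fml <- as.formula(paste("z ~", paste(factors, collapse = " + ")))
  fit <- lm(fml, data = d)
  means <- list()
  contrasts <- list()
  for (f in factors) {
    em <- emmeans::emmeans(fit, specs = f)
    ms <- as.data.frame(em)
    means[[f]] <- tibble(
      factor = f, level = as.character(ms[[1]]),
      mean_z = ms$emmean, mean_pa = tanh(ms$emmean), se_z = ms$SE
    )
    ct <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = "tukey"))
    contrasts[[f]] <- tibble(
      factor = f, contrast = as.character(ct$contrast),
      estimate_z = ct$estimate, se = ct$SE, p_value = ct$p.value
    )
  }
  structure(
    list(means = list_rbind(means), contrasts = list_rbind(contrasts),
         model = fit),
    class = "pa_comparison"
  )
}

#' @export
print.pa_comparison <- function(x, ...) {
  cat("<pa_comparison> factor-level means (back-transformed):\n")
  print(x$means, ...)
  cat("pairwise contrasts (z scale, Tukey-adjusted):\n")
  print(x$contrasts, ...)
  invisible(x)
}
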