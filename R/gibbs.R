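#' Chain settings for the Gibbs sampler
#'
#' @param burn_in Burn-in iterations.
#' @param n_iter Total iterations (must exceed `burn_in`).
#' @param thin Thinning interval.
#' @param seed Integer seed; identical seeds give identical chains.
#' @param prior_df Degrees of freedom of the scaled-inverse-chi-squared
#'   variance priors.
#' @param prior_r2 Fraction of the sample variance of the observed
#'   response assigned a priori to the genetic kernels (split evenly),
#'   the remainder to the residual.
#' @return A `chain_params` list.
#' @export
chain_params <- function(burn_in = 10000L, n_iter = 70000L, thin = 10L,
                         seed = 1L, prior_df = 5, prior_r2 = 0.5) {
  burn_in <- check_scalar_count(burn_in, "burn_in", min = 0L)
  n_iter <- check_scalar_count(n_iter, "n_iter")
  thin <- check_scalar_count(thin, "thin")
  if (burn_in >= n_iter) abort("`burn_in` must be smaller than `n_iter`")
  structure(
    list(burn_in = burn_in, n_iter = n_iter, thin = thin,
         seed = as.integer(seed), prior_df = prior_df, prior_r2 = prior_r2),
    class = "chain_params"
  )
}

#' @rdname chain_params
#' @param preset `"paper"` (10,000 / 70,000 / 10, the published settings)
#'   or `"fast"` (500 / 3,000 / 5, for desk-scale runs and tests).
#' @param ... Overrides passed on to [chain_params()].
#' @export
chain_preset <- function(preset = c("fast", "paper"), ...) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    paper = list(burn_in = 10000L, n_iter = 70000L, thin = 10L),
    fast = list(burn_in = 500L, n_iter = 3000L, thin = 5L)
  )
  do.call(chain_params, utils::modifyList(defaults, list(...)))
}

# Eigendecompose a kernel: raise on clearly negative eigenvalues, clip
# tiny negatives, truncate the basis at 1e-10 of the leading eigenvalue.
kernel_eigen <- function(K, label) {
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  dmax <- max(eg$values, 0)
  if (min(eg$values) < -1e-8 * max(dmax, 1)) {
    abort(sprintf("kernel '%s' is not PSD (min eigenvalue %.3e)",
                  label, min(eg$values)))
  }
  keep <- eg$values > 1e-10 * max(dmax, .Machine$double.eps)
  if (!any(keep)) abort(sprintf("kernel '%s' has no positive eigenvalues", label))
  list(U = eg$vectors[, keep, drop = FALSE], d = eg$values[keep])
}

#' Fit a kernel prediction model by Gibbs sampling
#'
#' Bayesian linear mixed model with flat-prior fixed effects, one normal
#' random-effect vector per kernel (variance `sigma2_k` times the kernel)
#' and scaled-inverse-chi-squared priors on all variances. Random effects
#' are sampled in each kernel's (truncated) eigenbasis; masked responses
#' (`NA` in `y`) are imputed each sweep from their conditional
#' distribution and predictions at those positions are posterior means of
#' the model's fitted part.
#'
#' @param y Numeric stacked response aligned with `kernels$index`; `NA`
#'   marks masked (to-be-predicted) positions.
#' @param kernels A `kernel_set` from [build_kernels()].
#' @param chain A `chain_params` object.
#' @param fixed_variances Optional named list pinning variance components
#'   (kernel labels and/or `"residual"`) at given values — the
#'   degenerate-prior limit, used for oracle checks.
#' @return Object of class `kernel_fit`.
#' @export
fit_gibbs <- function(y, kernels, chain = chain_preset("fast"),
                      fixed_variances = NULL) {
  stopifnot(inherits(kernels, "kernel_set"), inherits(chain, "chain_params"))
  n <- nrow(kernels$index)
  if (length(y) != n) abort("`y` length must match the stacked index")
  obs <- !is.na(y)
  if (!any(obs)) abort("all responses are masked")
  by_env <- tapply(obs, kernels$index$env, any)
  if (!all(by_env)) {
    # a fully masked environment (sparse-testing 0% scenarios) leaves its
    # fixed effect anchored only by the imputation; within-environment
    # prediction rankings are unaffected
    inform(paste0("environment(s) fully masked: ",
                  paste(names(by_env)[!by_env], collapse = ", ")))
  }
  labels <- map_chr(kernels$kernels, "label")
  eigs <- map2(kernels$kernels, labels,
               function(k, lb) kernel_eigen(k$matrix, lb))
  K <- length(eigs)
  nu <- chain$prior_df
  vy <- var(y[obs])
  if (!is.finite(vy) || vy == 0) vy <- 1
  # prior scales target a mean split of var(y); each kernel's scale is
  # expressed relative to its own mean diagonal so kernels of any
  # magnitude (e.g. derivative-scale HRMs) start in the right regime
  mdiag <- map_dbl(kernels$kernels, function(k) mean(diag(k$matrix)))
  mdiag[mdiag <= 0] <- 1
  S_k <- chain$prior_r2 * vy / K * max(nu - 2, 1) / nu / mdiag
  S_e <- (1 - chain$prior_r2) * vy * max(nu - 2, 1) / nu
  init_sig <- chain$prior_r2 * vy / K / mdiag
  init_sige <- (1 - chain$prior_r2) * vy
  fixed <- rep(0, K)
  fix_resid <- FALSE
  if (!is.null(fixed_variances)) {
    for (nm in names(fixed_variances)) {
      if (nm == "residual") {
        fix_resid <- TRUE
        init_sige <- fixed_variances[[nm]]
      } else {
        i <- match(nm, labels)
        if (is.na(i)) abort(sprintf("unknown kernel label '%s'", nm))
        fixed[i] <- 1
        init_sig[i] <- fixed_variances[[nm]]
      }
    }
  }
  res <- with_seed(chain$seed, gibbs_kernel_cpp(
    y = ifelse(obs, y, 0), miss = which(!obs) - 1L, X = kernels$X,
    U = map(eigs, "U"), d = map(eigs, "d"),
    burn = chain$burn_in, niter = chain$n_iter, thin = chain$thin,
    nu = nu, S = S_k, S_e = S_e,
    fixed = fixed, init_sig = init_sig, init_sige = init_sige,
    fix_resid = fix_resid
  ))
  chains <- res$sigma_chain
  colnames(chains) <- c(labels, "residual")
  vtab <- tibble(
    component = colnames(chains),
    estimate = colMeans(chains),
    std_dev = apply(chains, 2, sd),
    ess = apply(chains, 2, ess_chain)
  )
  preds <- kernels$index |>
    mutate(observed = y, fitted = drop(res$fitted_mean),
           masked = !obs)
  structure(
    list(
      variances = vtab,
      beta = setNames(drop(res$beta_mean), colnames(kernels$X)),
      effects = setNames(map(res$u_mean, drop), labels),
      fitted = preds,
      retained = res$n_kept,
      chain = chain,
      sigma_chain = chains,
      kernels = list(labels = labels, model = kernels$model,
                     info = kernels$info)
    ),
    class = "kernel_fit"
  )
}

# Effective sample size via initial positive autocorrelations.
ess_chain <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  pos <- which(ac <= 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(ac))
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf(
    "<kernel_fit> %s/%s: %d responses (%d masked), %d retained samples\n",
    x$kernels$model, x$kernels$info, nrow(x$fitted),
    sum(x$fitted$masked), x$retained
  ))
  print(x$variances, ...)
  invisible(x)
}

#' @export
tidy.kernel_fit <- function(x, ...) x$variances

#' @export
glance.kernel_fit <- function(x, ...) {
  tibble(
    n = nrow(x$fitted),
    n_masked = sum(x$fitted$masked),
    retained = x$retained,
    sigma2_resid = x$variances$estimate[x$variances$component == "residual"],
    model = x$kernels$model,
    info = x$kernels$info
  )
}

#' Predictions at chosen (genotype, environment) targets
#'
#' @param object A `kernel_fit`.
#' @param targets Data frame with columns `genotype` and `env`; every
#'   target must occur in the fitted stacked index.
#' @param ... Unused.
#' @return Tibble `genotype`, `env`, `predicted`.
#' @export
predict.kernel_fit <- function(object, targets, ...) {
  if (nrow(as.data.frame(targets)) == 0L) {
    return(tibble(genotype = character(), env = character(),
                  predicted = numeric()))
  }
  key <- paste(object$fitted$genotype, object$fitted$env, sep = "\r")
  tkey <- paste(targets$genotype, targets$env, sep = "\r")
  i <- match(tkey, key)
  if (anyNA(i)) {
    abort(paste0("target(s) outside the stacked index: ",
                 paste(head(tkey[is.na(i)], 5), collapse = "; ")))
  }
  tibble(genotype = targets$genotype, env = targets$env,
         predicted = object$fitted$fitted[i])
}

#' Closed-form BLUP solution at fixed variances
#'
#' Solves Henderson's mixed-model equations for the model of a
#' `kernel_set` at user-supplied variance components, working in each
#' kernel's scaled eigenbasis. Serves as the deterministic counterpart of
#' [fit_gibbs()]: with the same variances, the sampler's posterior-mean
#' predictions converge to this solution.
#'
#' @param y Stacked response with `NA` at masked positions.
#' @param kernels A `kernel_set`.
#' @param variances Named vector/list: one strictly positive value per
#'   kernel label plus `"residual"`.
#' @return Tibble `genotype`, `env`, `observed`, `fitted`, `masked`, plus
#'   attributes `beta` and `effects`.
#' @export
solve_blup <- function(y, kernels, variances) {
  stopifnot(inherits(kernels, "kernel_set"))
  labels <- map_chr(kernels$kernels, "label")
  need <- c(labels, "residual")
  if (!all(need %in% names(variances))) {
    abort(paste0("`variances` must name: ", paste(need, collapse = ", ")))
  }
  v <- unlist(variances)[need]
  if (any(v <= 0)) abort("all variances must be strictly positive")
  obs <- !is.na(y)
  X <- kernels$X
  eigs <- map2(kernels$kernels, labels,
               function(k, lb) kernel_eigen(k$matrix, lb))
  Z <- map(eigs, function(e) e$U %*% diag(sqrt(e$d), length(e$d)))
  W <- do.call(cbind, c(list(X[obs, , drop = FALSE]),
                        map(Z, function(z) z[obs, , drop = FALSE])))
  pen <- c(rep(0, ncol(X)),
           unlist(map2(eigs, seq_along(eigs), function(e, k) {
             rep(v[["residual"]] / v[[labels[k]]], length(e$d))
           })))
  C <- crossprod(W) + diag(pen, length(pen))
  rhs <- crossprod(W, y[obs])
  sol <- tryCatch(solve(C, rhs), error = function(err) {
    warn("singular mixed-model equations; adding ridge jitter 1e-8")
    solve(C + diag(1e-8, nrow(C)), rhs)
  })
  p <- ncol(X)
  beta <- sol[seq_len(p)]
  fitted <- unname(drop(X %*% beta))
  effects <- list()
  off <- p
  for (k in seq_along(Z)) {
    r <- ncol(Z[[k]])
    a <- sol[off + seq_len(r)]
    effects[[labels[k]]] <- unname(drop(Z[[k]] %*% a))
    fitted <- fitted + effects[[labels[k]]]
    off <- off + r
  }
  out <- kernels$index |>
    mutate(observed = y, fitted = fitted, masked = !obs)
  attr(out, "beta") <- setNames(beta, colnames(X))
  attr(out, "effects") <- effects
  out
}
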