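#' Preprocess reflectance spectra
#'
#' Row-wise chemometric transforms applied to a `spectra_set`:
#' \describe{
#'   \item{smooth}{Savitzky-Golay smoothing (polynomial order `p`, window
#'     `n` points).}
#'   \item{snv, normalize}{standard normal variate: each spectrum centered
#'     and scaled to unit SD ("normalization" is taken as SNV).}
#'   \item{detrend}{SNV followed by removal of a second-order polynomial
#'     baseline in wavelength.}
#'   \item{der1, der2}{first/second Savitzky-Golay derivative of the
#'     SNV-normalized spectrum; the wavelength grid is trimmed by half a
#'     window at each edge where the derivative filter is incomplete.}
#' }
#' The applied transform and its parameters are appended to the
#' `preprocessing` attribute. The derivative transforms are the default
#' route of the pipeline (`der2`).
#'
#' @param spectra A `spectra_set`.
#' @param method One of `"smooth"`, `"snv"`, `"normalize"`, `"detrend"`,
#'   `"der1"`, `"der2"`.
#' @param window Savitzky-Golay window length (odd, points); default 37.
#' @param poly_order Savitzky-Golay polynomial order; default 2.
#' @return A new `spectra_set` (possibly with a trimmed wavelength grid).
#' @export
preprocess_spectra <- function(spectra, method = c("der2", "der1", "snv",
                                                   "normalize", "detrend",
                                                   "smooth"),
                               window = 37L, poly_order = 2L) {
  method <- match.arg(method)
  grid <- wavelengths(spectra)
  X <- spectra_matrix(spectra)
  meta <- spectra[, setdiff(names(spectra), colnames(X)), drop = FALSE]
  tag <- method
  if (method %in% c("smooth", "der1", "der2")) {
    if (window %% 2L == 0L) abort("`window` must be odd")
    if (window > ncol(X)) abort("Savitzky-Golay window exceeds spectrum length")
    steps <- diff(grid)
    if (any(abs(steps - steps[1]) > 1e-8 * abs(steps[1]))) {
      abort("derivative/smoothing methods need an evenly spaced grid")
    }
    tag <- sprintf("%s(window=%d,poly=%d)", method, window, poly_order)
  }
  out <- switch(
    method,
    snv = ,
    normalize = snv_rows(X),
    detrend = detrend_rows(snv_rows(X), grid),
    smooth = t(apply(X, 1, signal::sgolayfilt, p = poly_order, n = window,
                     m = 0, ts = grid[2] - grid[1])),
    der1 = sg_derivative(snv_rows(X), grid, window, poly_order, m = 1L),
    der2 = sg_derivative(snv_rows(X), grid, window, poly_order, m = 2L)
  )
  if (method %in% c("der1", "der2")) {
    half <- (window - 1L) %/% 2L
    grid <- grid[(half + 1L):(length(wavelengths(spectra)) - half)]
  }
  colnames(out) <- sprintf("wl_%d", round(grid))
  new_spectra_set(
    bind_cols(as_tibble(meta), as_tibble(out)),
    wavelengths = grid,
    preprocessing = c(attr(spectra, "preprocessing"), tag)
  )
}

snv_rows <- function(X) {
  mu <- rowMeans(X)
  s <- apply(X, 1, sd)
  s[s == 0] <- 1
  (X - mu) / s
}

detrend_rows <- function(X, grid) {
  gs <- (grid - mean(grid)) / sd(grid)  # standardized for conditioning
  B <- cbind(1, gs, gs^2)
  # residual-maker applied row-wise: X - fitted quadratic baseline
  H <- B %*% solve(crossprod(B), t(B))
  X - X %*% t(H)
}

sg_derivative <- function(X, grid, window, poly_order, m) {
  ts <- grid[2] - grid[1]
  half <- (window - 1L) %/% 2L
  D <- t(apply(X, 1, signal::sgolayfilt, p = poly_order, n = window,
               m = m, ts = ts))
  D[, (half + 1L):(ncol(X) - half), drop = FALSE]
}

#' Per-wavelength genotype BLUPs for one environment
#'
#' For each wavelength independently, fits the mixed model
#' `reflectance ~ intercept + (1|block(rep)) + (1|genotype)` by REML and
#' extracts the genotype BLUPs and the genotype/residual variance
#' components. The BLUP matrix `Sp*` (genotypes x wavelengths, columns
#' mean-zero by construction) is the input of the hyperspectral
#' relationship matrix. Wavelengths with zero variance get all-zero BLUPs
#' and zero heritability.
#'
#' @param spectra A preprocessed `spectra_set` restricted to (or filtered
#'   for) one environment.
#' @param environment Environment label to analyse (must match `env`
#'   column values).
#' @return Object of class `spectral_blups`: list with `sp` (BLUP
#'   matrix), `varcomp` tibble (wavelength, var_geno, var_block,
#'   var_resid, h2), `environment`, `n_wavelengths`, `N_R`.
#' @export
spectra_blups <- function(spectra, environment) {
  d <- spectra |> filter(.data$env == environment)
  if (nrow(d) == 0L) {
    abort(sprintf("no spectra for environment '%s'", environment))
  }
  grid <- wavelengths(spectra)
  X <- spectra_matrix(d)
  geno_f <- factor(d$genotype)
  block_f <- interaction(d$rep, d$block, drop = TRUE)
  n_r <- harmonic_mean(as.vector(table(geno_f)))
  ids <- levels(geno_f)
  base <- data.frame(y = X[, 1], geno_f = geno_f, block_f = block_f)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  template <- NULL
  sp <- matrix(0, length(ids), ncol(X), dimnames = list(ids, colnames(X)))
  vg <- vb <- ve <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    yj <- X[, j]
    if (sd(yj) == 0) next
    fit <- suppressMessages(suppressWarnings(
      if (is.null(template)) {
        base$y <- yj
        template <- lme4::lmer(y ~ (1 | geno_f) + (1 | block_f),
                               data = base, REML = TRUE, control = ctrl)
        template
      } else {
        lme4::refit(template, newresp = yj)
      }
    ))
    vc <- as.data.frame(lme4::VarCorr(fit))
    cc <- setNames(vc$vcov, vc$grp)
    vg[j] <- cc[["geno_f"]]
    vb[j] <- cc[["block_f"]]
    ve[j] <- cc[["Residual"]]
    bl <- lme4::ranef(fit)$geno_f
    sp[rownames(bl), j] <- bl[, 1]
  }
  h2 <- ifelse(vg + ve / n_r > 0, vg / (vg + ve / n_r), 0)
  structure(
    list(
      sp = sp,
      varcomp = tibble(wavelength = grid, var_geno = vg, var_block = vb,
                       var_resid = ve, h2 = h2),
      environment = environment,
      n_wavelengths = ncol(X),
      N_R = n_r
    ),
    class = "spectral_blups"
  )
}

#' @export
print.spectral_blups <- function(x, ...) {
  cat(sprintf(
    "<spectral_blups> env %s: %d genotypes x %d wavelengths, median H2 %.2f\n",
    x$environment, nrow(x$sp), x$n_wavelengths, median(x$varcomp$h2)
  ))
  invisible(x)
}

#' Wavelength heritability
#'
#' Plug-in of \eqn{H^2 = \sigma^2_{geno} / (\sigma^2_{geno} +
#' \sigma^2_e/N_R)} per wavelength, with `N_R` the harmonic mean of
#' replicates per genotype. Zero-denominator wavelengths are reported as
#' 0 by convention.
#'
#' @param blups A `spectral_blups` object.
#' @return Tibble with columns `wavelength`, `h2`.
#' @export
wavelength_heritability <- function(blups) {
  blups$varcomp |> select("wavelength", "h2")
}

#' @rdname wavelength_heritability
#' @param var_geno,var_resid,n_r Scalars (or vectors) for a direct
#'   plug-in evaluation without a fitted object.
#' @export
wavelength_h2 <- function(var_geno, var_resid, n_r) {
  denom <- var_geno + var_resid / n_r
  ifelse(denom > 0, var_geno / denom, 0)
}
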