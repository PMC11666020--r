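#' Filter SNP markers on call rate, heterozygosity and MAF
#'
#' Removes markers with call rate below `1 - max_missing`, heterozygosity
#' rate above `max_het`, or minor allele frequency below `min_maf`
#' (computed on non-missing calls before any conversion). Heterozygous
#' calls of the retained markers are then set to missing, matching the
#' usual QC for predominantly inbred material.
#'
#' @param geno A `genotype_matrix`; dosage 1 is treated as heterozygous.
#' @param max_missing Maximum missing fraction (call rate threshold);
#'   default 0.20.
#' @param max_het Maximum heterozygosity rate; default 0.20.
#' @param min_maf Minimum minor allele frequency; default 0.025.
#' @return A filtered `genotype_matrix` with a `filter_report` attribute
#'   (tibble of counts removed per criterion and retained).
#' @export
filter_snps <- function(geno, max_missing = 0.20, max_het = 0.20,
                        min_maf = 0.025) {
  stopifnot(inherits(geno, "genotype_matrix"))
  M <- geno$dosage
  miss <- colMeans(is.na(M))
  het <- colMeans(M == 1, na.rm = TRUE)
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  fail_call <- miss > max_missing
  fail_het <- !is.na(het) & het > max_het
  fail_maf <- is.na(maf) | maf < min_maf
  keep <- !(fail_call | fail_het | fail_maf)
  if (!any(keep)) abort("no markers pass the SNP filters")
  M2 <- M[, keep, drop = FALSE]
  M2[M2 == 1L] <- NA
  out <- new_genotype_matrix(M2, map = geno$map[keep, , drop = FALSE])
  attr(out, "filter_report") <- tibble(
    criterion = c("call_rate", "heterozygosity", "maf", "retained"),
    n = c(sum(fail_call), sum(fail_het), sum(fail_maf), sum(keep))
  )
  out
}

new_kinship <- function(mat, kind, provenance = list()) {
  stopifnot(nrow(mat) == ncol(mat))
  structure(mat, kind = kind, provenance = provenance,
            class = c("kinship", "matrix", "array"))
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("<kinship:%s> %d x %d (mean diag %.3f)\n",
              attr(x, "kind"), nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

# Symmetry + PSD validation; eigenvalues in (-tol, 0) clipped to zero.
check_kinship <- function(K, tol = 1e-8) {
  if (max(abs(K - t(K))) > 1e-10 * max(1, max(abs(K)))) {
    abort("kinship matrix is not symmetric")
  }
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (min(ev) < -tol * scale) {
    abort(sprintf("kinship matrix is not PSD (min eigenvalue %.3e)", min(ev)))
  }
  invisible(TRUE)
}

#' VanRaden genomic relationship matrix
#'
#' \deqn{K = ZZ' / (2 \sum_j p_j (1 - p_j))} with `Z` the dosage matrix
#' column-centered by `2 p_j` and `p_j` the observed allele frequency of
#' marker `j`. Monomorphic markers contribute zero to the numerator and
#' are excluded from the denominator. Residual missing dosages are
#' mean-imputed per marker with a warning.
#'
#' @param geno A `genotype_matrix` (or plain dosage matrix).
#' @return A `kinship` matrix of kind `"genomic"`.
#' @export
grm_vanraden <- function(geno) {
  M <- if (inherits(geno, "genotype_matrix")) geno$dosage else as.matrix(geno)
  if (anyNA(M)) {
    warn("missing dosages mean-imputed per marker")
    mu <- colMeans(M, na.rm = TRUE)
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- mu[idx[, 2]]
  }
  p <- colMeans(M) / 2
  # a marker counts as informative only if its dosages actually vary
  poly <- (colMeans(M^2) - colMeans(M)^2) > 0
  if (!any(poly)) abort("all markers are monomorphic; GRM is undefined")
  Z <- sweep(M, 2, 2 * p, "-")
  Z[, !poly] <- 0
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  K <- tcrossprod(Z) / denom
  new_kinship(K, "genomic",
              provenance = list(n_markers = sum(poly), denom = denom))
}

#' Hyperspectral relationship matrix
#'
#' \deqn{H = Sp^* Sp^{*\prime} / L} where `Sp*` is the genotype-by-
#' wavelength matrix of NIRS genotype BLUPs of one environment and `L`
#' the number of wavelengths. BLUPs are used exactly as produced (they
#' are mean-zero by construction, so `H` is already a centered
#' cross-product); optional per-wavelength unit-variance scaling is
#' available but off by default.
#'
#' @param blups A `spectral_blups` object, or a plain BLUP matrix.
#' @param scale_wavelengths If `TRUE`, scale each wavelength column to
#'   unit variance first.
#' @return A `kinship` matrix of kind `"hyperspectral"`.
#' @export
hrm <- function(blups, scale_wavelengths = FALSE) {
  sp <- if (inherits(blups, "spectral_blups")) blups$sp else as.matrix(blups)
  environment <- if (inherits(blups, "spectral_blups")) blups$environment else NA
  if (ncol(sp) < 1L) abort("Sp* must have at least one wavelength")
  if (scale_wavelengths) {
    s <- apply(sp, 2, sd)
    s[s == 0] <- 1
    sp <- sweep(sp, 2, s, "/")
  }
  H <- tcrossprod(sp) / ncol(sp)
  new_kinship(H, "hyperspectral",
              provenance = list(environment = environment, L = ncol(sp)))
}

#' Align kinship matrices to a common genotype order
#'
#' Subsets and reorders each matrix to `id_list`, preserving symmetry.
#'
#' @param matrices A list of `kinship` (or plain square) matrices with
#'   dimnames.
#' @param id_list Character vector of genotype ids; every id must be
#'   present in every matrix.
#' @return List of aligned matrices.
#' @export
align_kinships <- function(matrices, id_list) {
  map(matrices, function(K) {
    missing <- setdiff(id_list, rownames(K))
    if (length(missing)) {
      abort(paste0("genotype(s) absent from kinship matrix: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    out <- K[id_list, id_list, drop = FALSE]
    if (inherits(K, "kinship")) {
      new_kinship(out, attr(K, "kind"), attr(K, "provenance"))
    } else out
  })
}
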