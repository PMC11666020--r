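#' Build the kernel set of a prediction model
#'
#' Assembles the fixed design and the random-effect covariance kernels of
#' a single- or multi-environment kernel prediction model on a stacked
#' (genotype, environment) index:
#' \describe{
#'   \item{SM}{single environment; one kernel per information source
#'     (`K` for GP, the environment's `H` for PP).}
#'   \item{MM}{multi-environment main-effects model: environment fixed
#'     effects plus, per source, a main genetic kernel with
#'     \eqn{J \otimes K} structure (uniform genetic effect across
#'     environments) restricted to the stacked index.}
#'   \item{MDs}{MM plus, per main kernel, a block-diagonal
#'     \eqn{I \otimes K} genotype-by-environment deviation kernel with a
#'     single variance per source.}
#' }
#' Phenomic information contributes one main (and, under MDs, one G-by-E)
#' kernel per available NIRS dataset (one hyperspectral matrix per
#' measured environment); combined GP+PP is the union of the genomic and
#' phenomic kernels.
#'
#' @param index Tibble with columns `genotype` and `env` defining the
#'   stacked response order.
#' @param model `"SM"`, `"MM"` or `"MDs"`.
#' @param info `"GP"`, `"PP"` or `"GP+PP"`.
#' @param grm Genomic `kinship` matrix (required for GP).
#' @param hrms Named list of per-environment hyperspectral `kinship`
#'   matrices (required for PP); names are the NIRS dataset environments
#'   and must all occur in the index.
#' @return Object of class `kernel_set`: list with `index`, `X` (fixed
#'   design), `kernels` (list of `label`/`matrix`/`family`), `model`,
#'   `info`.
#' @export
build_kernels <- function(index, model = c("MDs", "MM", "SM"),
                          info = c("GP", "PP", "GP+PP"),
                          grm = NULL, hrms = NULL) {
  model <- match.arg(model)
  info <- match.arg(info)
  stopifnot(all(c("genotype", "env") %in% names(index)))
  envs <- unique(index$env)
  if (model == "SM" && length(envs) != 1L) {
    abort("SM requires exactly one environment in the index")
  }
  use_gp <- info %in% c("GP", "GP+PP")
  use_pp <- info %in% c("PP", "GP+PP")
  if (use_gp && is.null(grm)) abort("GP requires `grm`")
  if (use_pp && (is.null(hrms) || length(hrms) == 0L)) {
    abort("PP requires at least one hyperspectral matrix in `hrms`")
  }
  if (use_pp) {
    bad <- setdiff(names(hrms), envs)
    if (length(bad)) {
      abort(paste0("hyperspectral matrix for environment(s) not in index: ",
                   paste(bad, collapse = ", ")))
    }
  }
  g <- index$genotype
  e <- index$env
  same_env <- outer(e, e, "==")
  X <- if (length(envs) > 1L) {
    model.matrix(~ factor(e, levels = envs))
  } else {
    matrix(1, nrow(index), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  expand_main <- function(K) {
    missing <- setdiff(unique(g), rownames(K))
    if (length(missing)) {
      abort(paste0("kinship lacks genotype(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    unname(K[g, g, drop = FALSE])
  }
  kernels <- list()
  add <- function(label, mat, family) {
    kernels[[length(kernels) + 1L]] <<- list(label = label, matrix = mat,
                                             family = family)
  }
  if (use_gp) {
    Kx <- expand_main(grm)
    add("G_main", Kx, "main_genomic")
    if (model == "MDs") add("G_gxe", Kx * same_env, "gxe_genomic")
  }
  if (use_pp) {
    for (d in names(hrms)) {
      Hx <- expand_main(hrms[[d]])
      add(paste0("H_main_", d), Hx, "main_phenomic")
      if (model == "MDs") {
        add(paste0("H_gxe_", d), Hx * same_env, "gxe_phenomic")
      }
    }
  }
  structure(
    list(index = as_tibble(index[, c("genotype", "env")]), X = X,
         kernels = kernels, model = model, info = info),
    class = "kernel_set"
  )
}

#' @export
print.kernel_set <- function(x, ...) {
  cat(sprintf("<kernel_set> %s/%s: %d stacked responses, %d kernels (%s)\n",
              x$model, x$info, nrow(x$index), length(x$kernels),
              paste(map_chr(x$kernels, "label"), collapse = ", ")))
  invisible(x)
}
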