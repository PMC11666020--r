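#' Simulate a biallelic dosage matrix
#'
#' Draws per-marker allele frequencies uniformly in `maf_range` and then
#' genotype dosages as binomial(2, p) per individual, mimicking a diverse
#' inbred-line panel after SNP calling. The result is the raw material for
#' the VanRaden genomic relationship matrix and for trait/spectra
#' simulation.
#'
#' @param n_geno Number of accessions (rows).
#' @param n_markers Number of SNP markers (columns).
#' @param maf_range Length-2 numeric interval in (0, 0.5] from which each
#'   marker's allele frequency is drawn.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param n_families Number of subpopulations/families. The default 1
#'   draws every individual from the same Hardy-Weinberg population
#'   (unrelated panel); larger values create related groups via the
#'   Balding-Nichols model, emulating the structure of a breeding panel.
#' @param fst Differentiation between families in (0, 1); ignored when
#'   `n_families = 1`.
#' @return A `genotype_matrix`: list with `dosage` (n_geno x n_markers
#'   integer matrix in \{0,1,2\}), `map` (tibble of marker metadata) and
#'   `maf` (realized minor-allele frequency per marker).
#' @export
simulate_genotypes <- function(n_geno, n_markers, maf_range = c(0.042, 0.5),
                               seed = 1L, n_families = 1L, fst = 0.3) {
  n_geno <- check_scalar_count(n_geno, "n_geno", min = 2L)
  n_markers <- check_scalar_count(n_markers, "n_markers", min = 1L)
  if (length(maf_range) != 2L || maf_range[2] < maf_range[1]) {
    abort("`maf_range` must be an interval c(min, max) with max >= min")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) {
    abort("`maf_range` must lie within (0, 0.5]")
  }
  n_families <- check_scalar_count(n_families, "n_families")
  with_seed(seed, {
    p <- runif(n_markers, maf_range[1], maf_range[2])
    if (n_families > 1L) {
      if (fst <= 0 || fst >= 1) abort("`fst` must be in (0, 1)")
      fam <- rep_len(seq_len(n_families), n_geno)
      a <- p * (1 - fst) / fst
      bpar <- (1 - p) * (1 - fst) / fst
      dosage <- matrix(0L, n_geno, n_markers)
      for (fm in seq_len(n_families)) {
        pf <- stats::rbeta(n_markers, a, bpar)
        rows <- which(fam == fm)
        dosage[rows, ] <- matrix(
          rbinom(length(rows) * n_markers, 2L, rep(pf, each = length(rows))),
          nrow = length(rows)
        )
      }
    } else {
      dosage <- matrix(
        rbinom(n_geno * n_markers, size = 2L, prob = rep(p, each = n_geno)),
        nrow = n_geno, ncol = n_markers
      )
    }
    ids <- sprintf("G%03d", seq_len(n_geno))
    markers <- sprintf("M%06d", seq_len(n_markers))
    dimnames(dosage) <- list(ids, markers)
    obs_p <- colMeans(dosage) / 2
    new_genotype_matrix(
      dosage,
      map = tibble(
        marker = markers,
        chrom = rep_len(sprintf("chr%02d", 1:12), n_markers),
        pos = seq_len(n_markers) * 1000L,
        ref = "A", alt = "T",
        sim_freq = p
      ),
      maf = pmin(obs_p, 1 - obs_p)
    )
  })
}

new_genotype_matrix <- function(dosage, map, maf = NULL) {
  if (is.null(maf)) {
    obs_p <- colMeans(dosage, na.rm = TRUE) / 2
    maf <- pmin(obs_p, 1 - obs_p)
  }
  structure(
    list(dosage = dosage, map = map, maf = unname(maf)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d individuals x %d markers (median MAF %.3f, %.2f%% missing)\n",
    nrow(x$dosage), ncol(x$dosage), median(x$maf, na.rm = TRUE),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Simulate a split-block multi-environment trial design
#'
#' Lays out a randomized trial with the structure of a two-factor
#' (year x nitrogen) multi-environment experiment: within every
#' environment, each replicate is divided into blocks and every genotype
#' is plotted exactly once per replicate. Genotype-to-block allocation is
#' re-randomized independently per replicate and environment.
#'
#' @param n_geno Number of genotypes.
#' @param n_years,n_nitro Numbers of years and nitrogen levels; their
#'   crossing defines the environments.
#' @param n_reps Replicates per environment.
#' @param n_blocks Blocks per replicate; block sizes are padded unevenly
#'   when `n_geno` is not divisible, never dropping genotypes.
#' @param seed Integer seed.
#' @return A tibble with one row per plot: `plot`, `genotype`, `year`,
#'   `nitro`, `env`, `rep`, `block`.
#' @export
simulate_trial_design <- function(n_geno, n_years = 2L, n_nitro = 2L,
                                  n_reps = 2L, n_blocks = 14L, seed = 1L) {
  n_geno <- check_scalar_count(n_geno, "n_geno")
  n_years <- check_scalar_count(n_years, "n_years")
  n_nitro <- check_scalar_count(n_nitro, "n_nitro")
  n_reps <- check_scalar_count(n_reps, "n_reps")
  n_blocks <- check_scalar_count(n_blocks, "n_blocks")
  ids <- sprintf("G%03d", seq_len(n_geno))
  years <- 2014L + seq_len(n_years)
  nitros <- c("HN", "LN", sprintf("N%d", seq_len(max(0L, n_nitro - 2L)) + 2L))[seq_len(n_nitro)]
  block_sizes <- rep(n_geno %/% n_blocks, n_blocks)
  rem <- n_geno %% n_blocks
  if (rem > 0) block_sizes[seq_len(rem)] <- block_sizes[seq_len(rem)] + 1L
  with_seed(seed, {
    rows <- crossing(year = years, nitro = nitros, rep = seq_len(n_reps)) |>
      purrr::pmap(function(year, nitro, rep) {
        tibble(
          genotype = sample(ids),
          year = year, nitro = nitro, rep = rep,
          block = rep.int(seq_len(n_blocks), block_sizes)
        )
      }) |>
      list_rbind()
    rows |>
      mutate(
        env = env_label(.data$year, .data$nitro),
        plot = sprintf("P%05d", row_number())
      ) |>
      select("plot", "genotype", "year", "nitro", "env", "rep", "block")
  })
}
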