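# Readers and writers for the pipeline's plain-text formats. All CSVs
# are UTF-8, comma-delimited, '.' decimal; genotype ids are opaque
# strings.

#' Write / read a dosage matrix as CSV
#'
#' First column `genotype`, remaining columns one per marker.
#'
#' @param geno A `genotype_matrix`.
#' @param path Output file.
#' @export
write_genotypes_csv <- function(geno, path) {
  df <- data.frame(genotype = rownames(geno$dosage), geno$dosage,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_csv
#' @param format `"csv"` or `"vcf"` (auto-detected from the extension by
#'   default).
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "csv")
  if (format == "vcf") return(read_genotypes_vcf(path))
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "genotype") abort("first CSV column must be 'genotype'")
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$genotype
  storage.mode(M) <- "integer"
  new_genotype_matrix(
    M,
    map = tibble(marker = colnames(M), chrom = NA_character_,
                 pos = NA_integer_, ref = NA_character_,
                 alt = NA_character_)
  )
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    inform(sprintf("skipping %d multiallelic site(s)", sum(multi)))
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1")] <- 2L
  fix <- vcfR::getFIX(v)
  new_genotype_matrix(
    t(dos),
    map = tibble(
      marker = if (all(is.na(fix[, "ID"]))) {
        paste0(fix[, "CHROM"], "_", fix[, "POS"])
      } else fix[, "ID"],
      chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
      ref = fix[, "REF"], alt = fix[, "ALT"]
    )
  )
}

#' Write a dosage matrix as a biallelic VCF
#'
#' Minimal VCF 4.2 with a GT field; dosage 0/1/2 becomes 0/0, 0/1, 1/1
#' and missing becomes ./..
#'
#' @param geno A `genotype_matrix`.
#' @param path Output file (plain text).
#' @export
write_genotypes_vcf <- function(geno, path) {
  M <- geno$dosage
  map <- geno$map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(M)), collapse = "\t")
  ), con)
  code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(M))) {
    gt <- ifelse(is.na(M[, j]), "./.", code[M[, j] + 1L])
    writeLines(paste(c(
      map$chrom[j] %||% "chr1", map$pos[j] %||% j, map$marker[j],
      map$ref[j] %||% "A", map$alt[j] %||% "T", ".", "PASS", ".", "GT", gt
    ), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write / read long-format phenotype records
#'
#' Columns: genotype, year, nitro, env, rep, block, trait, value.
#'
#' @param records Phenotype tibble.
#' @param path CSV file.
#' @export
write_phenotypes <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @param environments Optional character vector of valid environment
#'   labels; unknown labels raise an error listing the valid ones.
#' @export
read_phenotypes <- function(path, environments = NULL) {
  df <- as_tibble(read.csv(path))
  need <- c("genotype", "year", "nitro", "env", "rep", "block", "trait",
            "value")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("phenotype file lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!is.null(environments)) {
    bad <- setdiff(unique(df$env), environments)
    if (length(bad)) {
      abort(sprintf("unknown environment label(s) %s; valid labels: %s",
                    paste(bad, collapse = ", "),
                    paste(environments, collapse = ", ")))
    }
  }
  dup <- df |>
    count(.data$genotype, .data$env, .data$rep, .data$trait) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("duplicated (genotype, env, rep, trait) records, e.g. %s/%s",
                  dup$genotype[1], dup$env[1]))
  }
  df
}

#' Write / read wide-format spectra
#'
#' One row per plot; metadata columns (genotype, env, rep, block)
#' followed by `wl_<nm>` reflectance columns on an evenly spaced grid.
#'
#' @param spectra A `spectra_set`.
#' @param path CSV file.
#' @export
write_spectra <- function(spectra, path) {
  write.csv(as.data.frame(spectra), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  df <- as_tibble(read.csv(path))
  wl_cols <- grep("^wl_", names(df), value = TRUE)
  if (length(wl_cols) < 2L) abort("no wl_<nm> reflectance columns found")
  wl <- as.numeric(sub("^wl_", "", wl_cols))
  steps <- diff(wl)
  if (any(steps <= 0)) abort("wavelength columns are not increasing")
  gap <- which(abs(steps - steps[1]) > 1e-8)
  if (length(gap)) {
    abort(sprintf("wavelength grid has a gap: column wl_%g is missing",
                  wl[gap[1]] + steps[1]))
  }
  new_spectra_set(df, wavelengths = wl)
}

#' Write / read a kinship matrix
#'
#' CSV with a header row of genotype ids plus a sidecar `<path>.json`
#' holding kind and provenance.
#'
#' @param K A `kinship` matrix.
#' @param path CSV file.
#' @export
write_kinship <- function(K, path) {
  df <- data.frame(genotype = rownames(K), as.data.frame(unclass(K)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(kind = attr(K, "kind"),
         provenance = attr(K, "provenance")),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$genotype
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  new_kinship(M, kind = meta$kind %||% "unknown",
              provenance = meta$provenance %||% list())
}
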