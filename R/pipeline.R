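#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], with
#' desk-scale defaults (a 50-genotype fixture). Any entry can be
#' overridden via `...`; a YAML file with the same field names can be
#' loaded with [read_config()].
#'
#' @param ... Named overrides.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    out_dir = "phenogp_run",
    seed = 1L,
    n_geno = 50L,
    n_markers = 300L,
    n_families = 10L,
    fst = 0.45,
    n_years = 2L, n_nitro = 2L, n_reps = 2L, n_blocks = 5L,
    wavelength_step = 15,          # nm; 1500/15 = 101 wavelengths
    spectra_h2 = 0.85,
    spectra_env_shift_sd = 0.1,
    spectra_noise_sd = 0.02,
    spectra_block_sd = 0.02,
    spectra_loading = 1,
    spectra_trait_share = 0.2,
    spectra_trait_cor = 0.5,
    spectra_dense_share = 0.6,
    preprocess = "der2",
    sg_window = 17L,
    traits = c("GY", "PH"),
    cv_trait = "PH",
    scenarios = c(1L, 5L),
    models = "MDs",
    infos = c("GP", "PP"),
    n_replicates = 2L,
    chain = "fast",
    log = TRUE
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
  }
  structure(utils::modifyList(cfg, over), class = "run_config")
}

#' @rdname pipeline_config
#' @param path YAML file of config fields.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

pipeline_log <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$log)) message(sprintf(paste0("[phenogp] ", fmt), ...))
}

#' Run the full prediction pipeline on simulated data
#'
#' End-to-end umbrella: simulate genotypes, trial design, phenotypes and
#' spectra; compute variance components, heritabilities, per-environment
#' BLUEs and environment correlations; preprocess spectra and derive
#' per-environment spectral BLUPs and wavelength heritabilities; build
#' the genomic and hyperspectral relationship matrices; run the selected
#' cross-validation scenarios; and compare predictive abilities. All
#' outputs are written as CSV under `cfg$out_dir`, and a JSON manifest
#' records the config, seeds and per-file checksums. A rerun with an
#' unchanged config and intact outputs skips completed stages.
#'
#' @param cfg A `run_config` from [pipeline_config()] or [read_config()].
#' @param force Rerun all stages even when outputs are up to date.
#' @return The manifest (list), invisibly.
#' @export
run_pipeline <- function(cfg = pipeline_config(), force = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  scen_all <- make_scenarios()
  bad <- setdiff(cfg$scenarios, scen_all$scenario_id)
  if (length(bad)) {
    abort(paste0("unknown scenario id(s): ", paste(bad, collapse = ", ")))
  }
  if (!cfg$cv_trait %in% cfg$traits) {
    abort("`cv_trait` must be one of `traits`")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  prev <- if (!force && file.exists(manifest_path)) {
    tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
  } else NULL
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)
  same_cfg <- !is.null(prev) && identical(as.character(prev$config_json),
                                          as.character(cfg_json))
  files <- list()
  stages <- list()
  path <- function(...) file.path(cfg$out_dir, paste0(...))
  stage_done <- function(name, outs) {
    if (!same_cfg) return(FALSE)
    rec <- prev$checksums[unlist(outs)]
    if (any(vapply(rec, is.null, TRUE))) return(FALSE)
    all(file.exists(file.path(cfg$out_dir, names(rec)))) &&
      identical(unname(unlist(rec)),
                unname(tools::md5sum(file.path(cfg$out_dir, names(rec)))))
  }

  # --- stage 1: simulation -------------------------------------------------
  specs <- lapply(default_trait_specs()[cfg$traits], function(sp) {
    sp$n_qtl <- min(sp$n_qtl, cfg$n_markers)
    sp
  })
  grid <- seq(1000, 2500, by = cfg$wavelength_step)
  sspec <- spectra_spec(
    wavelength_grid = grid, target_h2_profile = cfg$spectra_h2,
    genetic_loading = cfg$spectra_loading,
    env_shift_sd = cfg$spectra_env_shift_sd,
    noise_sd = cfg$spectra_noise_sd, block_sd = cfg$spectra_block_sd,
    trait_share = cfg$spectra_trait_share,
    trait_cor = cfg$spectra_trait_cor,
    dense_share = cfg$spectra_dense_share
  )
  geno <- simulate_genotypes(cfg$n_geno, cfg$n_markers,
                             seed = derive_seed(cfg$seed, 1),
                             n_families = cfg$n_families, fst = cfg$fst)
  design <- simulate_trial_design(cfg$n_geno, cfg$n_years, cfg$n_nitro,
                                  cfg$n_reps, cfg$n_blocks,
                                  seed = derive_seed(cfg$seed, 2))
  sims <- imap(specs, function(sp, nm) {
    simulate_phenotypes(geno, design, sp,
                        seed = derive_seed(cfg$seed, 10 + match(nm, names(specs))))
  })
  records <- list_rbind(map(sims, "records"))
  spectra <- simulate_spectra(
    geno, design, sspec, seed = derive_seed(cfg$seed, 3),
    genetic_values = sims[[cfg$cv_trait]]$truth$genetic_values
  )
  sim_files <- c("genotypes.csv", "design.csv", "phenotypes.csv",
                 "spectra.csv")
  if (stage_done("simulate", sim_files)) {
    pipeline_log(cfg, "simulate: up to date, skipped")
    stages$simulate <- "skipped"
  } else {
    write_genotypes_csv(geno, path("genotypes.csv"))
    write.csv(design, path("design.csv"), row.names = FALSE, quote = FALSE)
    write_phenotypes(records, path("phenotypes.csv"))
    write_spectra(spectra, path("spectra.csv"))
    pipeline_log(cfg, "simulate: %d genotypes, %d plots", cfg$n_geno,
                 nrow(design))
    stages$simulate <- "run"
  }
  files <- c(files, sim_files)

  # --- stage 2: phenotype analysis ----------------------------------------
  vc_tabs <- imap(sims, function(s, nm) {
    vc <- decompose_variance(s$records)
    tidy(vc) |> mutate(trait = nm, H2 = broad_sense_heritability(vc))
  })
  blues <- compute_blues(records)
  corr <- env_correlations(blues)
  pheno_files <- c("varcomp.csv", "blues.csv", "env_correlations.csv")
  if (stage_done("phenotype", pheno_files)) {
    pipeline_log(cfg, "phenotype: up to date, skipped")
    stages$phenotype <- "skipped"
  } else {
    write.csv(list_rbind(vc_tabs), path("varcomp.csv"), row.names = FALSE)
    write.csv(blues, path("blues.csv"), row.names = FALSE)
    write.csv(corr, path("env_correlations.csv"), row.names = FALSE)
    pipeline_log(cfg, "phenotype: H2 = %s",
                 paste(sprintf("%s %.2f", names(vc_tabs),
                               map_dbl(vc_tabs, function(t) t$H2[1])),
                       collapse = ", "))
    stages$phenotype <- "run"
  }
  files <- c(files, pheno_files)

  # --- stage 3: spectra ----------------------------------------------------
  prep <- preprocess_spectra(spectra, method = cfg$preprocess,
                             window = cfg$sg_window)
  envs <- unique(design$env)
  blups <- setNames(map(envs, function(ev) spectra_blups(prep, ev)), envs)
  h2_tab <- imap(blups, function(b, ev) {
    wavelength_heritability(b) |> mutate(env = ev)
  }) |> list_rbind()
  spec_files <- c(sprintf("spblups_%s.csv", envs), "wavelength_h2.csv")
  if (stage_done("spectra", spec_files)) {
    pipeline_log(cfg, "spectra: up to date, skipped")
    stages$spectra <- "skipped"
  } else {
    for (ev in envs) {
      sp <- blups[[ev]]$sp
      write.csv(data.frame(genotype = rownames(sp), sp,
                           check.names = FALSE),
                path(sprintf("spblups_%s.csv", ev)), row.names = FALSE)
    }
    write.csv(h2_tab, path("wavelength_h2.csv"), row.names = FALSE)
    pipeline_log(cfg, "spectra: median wavelength H2 %.2f",
                 median(h2_tab$h2))
    stages$spectra <- "run"
  }
  files <- c(files, spec_files)

  # --- stage 4: relationship matrices --------------------------------------
  K <- grm_vanraden(geno)
  hrms <- map(blups, hrm)
  kin_files <- c("grm.csv", sprintf("hrm_%s.csv", envs))
  if (stage_done("kinship", kin_files)) {
    pipeline_log(cfg, "kinship: up to date, skipped")
    stages$kinship <- "skipped"
  } else {
    write_kinship(K, path("grm.csv"))
    for (ev in envs) write_kinship(hrms[[ev]], path(sprintf("hrm_%s.csv", ev)))
    pipeline_log(cfg, "kinship: GRM mean diag %.3f", mean(diag(K)))
    stages$kinship <- "run"
  }
  files <- c(files, kin_files)

  # --- stage 5: cross-validation -------------------------------------------
  b1 <- blues |> filter(.data$trait == cfg$cv_trait)
  chain <- chain_preset(cfg$chain)
  pa <- list()
  for (sid in cfg$scenarios) {
    sc <- scen_all[scen_all$scenario_id == sid, ]
    for (model in cfg$models) {
      for (info in cfg$infos) {
        res <- run_cv_scenario(
          sc, model = model, info = info, blues = b1, grm = K,
          hrms = hrms, chain = chain, n_replicates = cfg$n_replicates,
          master_seed = cfg$seed
        )
        pa[[length(pa) + 1L]] <- res
        pipeline_log(cfg, "cv: scenario %d %s/%s mean PA %.3f", sid,
                     model, info, mean(res$pa, na.rm = TRUE))
      }
    }
  }
  pa <- list_rbind(pa)
  cv_files <- c("pa.csv", "pa_summary.csv")
  if (stage_done("cv", cv_files)) {
    pipeline_log(cfg, "cv: up to date, skipped")
    stages$cv <- "skipped"
  } else {
    write.csv(pa, path("pa.csv"), row.names = FALSE)
    write.csv(summarise_pa(pa), path("pa_summary.csv"), row.names = FALSE)
    stages$cv <- "run"
  }
  files <- c(files, cv_files)

  # --- stage 6: comparison --------------------------------------------------
  cmp_files <- "pa_comparison.csv"
  cmp <- if (length(unique(pa$info)) > 1L) compare_models(pa, "info") else NULL
  if (stage_done("compare", cmp_files)) {
    stages$compare <- "skipped"
  } else {
    if (!is.null(cmp)) {
      write.csv(bind_rows(
        cmp$means |> mutate(what = "mean"),
        cmp$contrasts |>
          rename(level = "contrast", mean_z = "estimate_z") |>
          mutate(what = "contrast")
      ), path("pa_comparison.csv"), row.names = FALSE)
    } else {
      write.csv(tibble(note = "single info level; no comparison"),
                path("pa_comparison.csv"), row.names = FALSE)
    }
    stages$compare <- "run"
  }
  files <- c(files, cmp_files)

  # --- manifest -------------------------------------------------------------
  outs <- unlist(files)
  sums <- tools::md5sum(file.path(cfg$out_dir, outs))
  names(sums) <- outs
  manifest <- list(
    package_version = as.character(packageVersion("phenogp")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg),
    config_json = as.character(cfg_json),
    seed = cfg$seed,
    stages = stages,
    checksums = as.list(sums)
  )
  tmp <- paste0(manifest_path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, manifest_path)
  invisible(manifest)
}
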