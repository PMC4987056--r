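#' Pipeline configuration
#'
#' Bundles every parameter of an end-to-end run (study design, acquisition,
#' preprocessing, chemometrics and statistics settings, seed, output
#' directory) into a serializable list. The configuration round-trips
#' losslessly through JSON via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param outdir output directory (created if missing).
#' @param seed master seed; all stage seeds derive from it.
#' @param material `"plasma"` or `"urine"`.
#' @param timepoints time points to simulate.
#' @param contrast two time points compared by PLS-DA and fold-change
#'   analysis.
#' @param design a [study_design()].
#' @param acq an [acquisition_params()] list.
#' @param noise_sd within-animal log-scale concentration noise.
#' @param folds,reps,nperm cross-validation segments, CV repetitions and
#'   label permutations for the misclassification test.
#' @param tsp_conc TSP concentration (mM).
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1, material = "plasma",
                            timepoints = c("t1", "t2"),
                            contrast = c("t1", "t2"),
                            design = study_design(),
                            acq = acquisition_params(),
                            noise_sd = 0.25, folds = 7L, reps = 50L,
                            nperm = 50L, tsp_conc = acq$tsp_conc) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 material = material, timepoints = timepoints,
                 contrast = contrast,
                 groups = design$groups, availability = design$availability,
                 survival_prob = design$survival_prob,
                 asystole_unit = design$asystole_unit,
                 rosc_unit = design$rosc_unit,
                 acq = acq[setdiff(names(acq), "background")],
                 background = isTRUE(acq$background),
                 noise_sd = noise_sd, folds = as.integer(folds),
                 reps = as.integer(reps), nperm = as.integer(nperm),
                 tsp_conc = tsp_conc),
            class = "pipeline_config")
}

#' Small two-group demo design
#' @param n_per_group animals per group (two groups, full availability).
#' @return a [study_design()].
#' @export
demo_design <- function(n_per_group = 10L) {
  g <- group_design_table()[1:2, ]
  g$n <- as.integer(n_per_group)
  av <- sample_availability_table()[1:2, ]
  for (cn in setdiff(names(av), c("group", "n"))) av[[cn]] <- n_per_group
  av$n <- as.integer(n_per_group)
  study_design(groups = g, availability = av, survival_prob = 1)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  for (f in c("folds", "reps", "nperm")) cfg[[f]] <- as.integer(cfg[[f]])
  structure(cfg, class = "pipeline_config")
}

config_design <- function(config) {
  # availability is already stored as rates; reconstruct without re-dividing
  d <- study_design(groups = as.data.frame(config$groups),
                    timepoints = config$timepoints,
                    survival_prob = config$survival_prob,
                    asystole_unit = config$asystole_unit,
                    rosc_unit = config$rosc_unit)
  av <- as.data.frame(config$availability)
  d$availability <- av
  d
}

config_acq <- function(config) {
  a <- config$acq
  a$background <- config$background
  a$phase_range <- as.numeric(a$phase_range)
  a$offset_range <- as.numeric(a$offset_range)
  a$baseline <- as.numeric(a$baseline)
  a
}

stage_outputs <- function(outdir) {
  list(simulate = file.path(outdir, c("animals.csv", "sample_manifest.csv",
                                      "true_concentrations.csv")),
       spectra = file.path(outdir, "spectra"),
       preprocess = file.path(outdir, c("qc.csv")),
       quantify = file.path(outdir, c("quantified.csv", "units.csv")),
       unistats = file.path(outdir, "fold_changes.csv"),
       chemometrics = file.path(outdir, "plsda_summary.json"),
       corrstruct = file.path(outdir, c("correlation_matrix.csv")))
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate -> render -> preprocess -> quantify -> chemometrics
#' (PLS-DA on the contrast) -> unistats (paired fold changes) -> corrstruct
#' stages, writing CSV/JSON outputs and a manifest (seed, package version,
#' md5 of every output) into the output directory. A stage whose output
#' files already exist is skipped unless an upstream stage was recomputed,
#' so deleting an intermediate file triggers only downstream recomputation.
#' Rerunning with the same configuration reproduces all numeric outputs
#' exactly.
#'
#' @param config a [pipeline_config()].
#' @param force recompute everything.
#' @return list with `manifest`, the per-stage `ran` flags and key results.
#' @export
run_pipeline <- function(config, force = FALSE) {
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outs <- stage_outputs(outdir)
  panel <- metabolite_panel(config$material)
  acq <- config_acq(config)
  design <- config_design(config)
  ran <- c(simulate = FALSE, spectra = FALSE, preprocess = FALSE,
           quantify = FALSE, chemometrics = FALSE, unistats = FALSE,
           corrstruct = FALSE)
  missing_any <- function(fs) !all(file.exists(fs))

  # -- simulate ------------------------------------------------------------
  if (force || missing_any(outs$simulate)) {
    cohort <- sample_cohort(design, seed = config$seed)
    model <- concentration_model(
      if (config$material == "plasma") plasma_reference_table()
      else urine_reference_table(), noise_sd = config$noise_sd)
    conc <- sample_concentrations(model, cohort,
                                  timepoints = config$timepoints,
                                  seed = config$seed + 1L)
    utils::write.csv(cohort$animals, outs$simulate[1], row.names = FALSE)
    utils::write.csv(cohort$manifest, outs$simulate[2], row.names = FALSE)
    utils::write.csv(conc, outs$simulate[3], row.names = FALSE)
    ran["simulate"] <- TRUE
  } else {
    cohort <- list(animals = utils::read.csv(outs$simulate[1]),
                   manifest = utils::read.csv(outs$simulate[2]))
    conc <- utils::read.csv(outs$simulate[3])
  }

  # -- render spectra ------------------------------------------------------
  spec_dir <- outs$spectra
  expected_files <- function() {
    man <- cohort$manifest
    ok <- man$available & man$material == config$material &
      man$timepoint %in% config$timepoints
    file.path(spec_dir, paste0(man$sample_id[ok], ".txt"))
  }
  if (ran["simulate"] || force || missing_any(expected_files())) {
    dir.create(spec_dir, showWarnings = FALSE)
    man <- cohort$manifest
    ok <- which(man$available & man$material == config$material &
                  man$timepoint %in% config$timepoints)
    for (i in ok) {
      sp <- simulate_spectra(conc, cohort, panel,
                             timepoint = man$timepoint[i], acq = acq,
                             seed = config$seed + 13L * i,
                             animals = man$animal[i])[[1]]
      write_spectrum(sp, file.path(spec_dir, paste0(man$sample_id[i], ".txt")))
    }
    ran["spectra"] <- TRUE
  }

  # -- preprocess + quantify ----------------------------------------------
  if (any(ran) || force || missing_any(c(outs$preprocess, outs$quantify))) {
    files <- expected_files()
    spectra <- lapply(files, read_spectrum)
    names(spectra) <- sub("\\.txt$", "", basename(files))
    pre <- lapply(spectra, preprocess_spectrum)
    utils::write.csv(qc_table(pre), outs$preprocess[1], row.names = FALSE)
    qm <- quantify_cohort(pre, panel, tsp_conc = config$tsp_conc,
                          linewidth = acq$linewidth,
                          j_doublet = acq$j_doublet,
                          j_triplet = acq$j_triplet,
                          j_multiplet = acq$j_multiplet)
    qdf <- data.frame(sample_id = rownames(qm), qm, check.names = FALSE,
                      row.names = NULL)
    utils::write.csv(qdf, outs$quantify[1], row.names = FALSE)
    utils::write.csv(data.frame(metabolite = colnames(qm),
                                unit = attr(qm, "units")),
                     outs$quantify[2], row.names = FALSE)
    ran["preprocess"] <- ran["quantify"] <- TRUE
  } else {
    qdf <- utils::read.csv(outs$quantify[1], check.names = FALSE)
    qm <- as.matrix(qdf[, -1, drop = FALSE])
    rownames(qm) <- qdf$sample_id
  }

  # sample annotation from ids "<animal>_<material>_<tp>"
  parts <- strsplit(rownames(qm), "_")
  animal <- vapply(parts, `[[`, "", 1)
  tp <- vapply(parts, `[[`, "", 3)

  # -- chemometrics: PLS-DA on the contrast --------------------------------
  result <- list()
  if (any(ran) || force || missing_any(outs$chemometrics)) {
    sel <- tp %in% config$contrast
    Xl <- log_transform(qm[sel, , drop = FALSE])
    lab <- tp[sel]
    fit <- pls_fit(Xl, lab, ncomp = 1L)
    set.seed(config$seed + 7L)
    cv <- cross_validate(Xl, lab, folds = config$folds, ncomp = 1L,
                         ordering = sample.int(nrow(Xl)))
    perm <- nmc_permutation_null(Xl, lab, folds = config$folds, ncomp = 1L,
                                 reps = config$reps, nperm = config$nperm,
                                 seed = config$seed + 2L)
    summary <- list(contrast = config$contrast, r2 = fit$r2[1],
                    q2 = cv$q2[1], nmc_median = perm$observed$median,
                    nmc_ci = perm$observed$ci,
                    null_median = stats::median(perm$null),
                    p_empirical = perm$p_empirical,
                    p_ranksum = perm$p_ranksum)
    jsonlite::write_json(summary, outs$chemometrics, auto_unbox = TRUE,
                         digits = NA)
    result$plsda <- summary
    ran["chemometrics"] <- TRUE
  } else {
    result$plsda <- jsonlite::read_json(outs$chemometrics,
                                        simplifyVector = TRUE)
  }

  # -- unistats: paired fold changes over the contrast ---------------------
  if (any(ran) || force || missing_any(outs$unistats)) {
    a <- config$contrast[1]; b <- config$contrast[2]
    qa <- qm[tp == a, , drop = FALSE]; rownames(qa) <- animal[tp == a]
    qb <- qm[tp == b, , drop = FALSE]; rownames(qb) <- animal[tp == b]
    fc <- paired_fold_change(log_transform(qa), log_transform(qb))
    utils::write.csv(fc, outs$unistats, row.names = FALSE)
    result$fold_changes <- fc
    ran["unistats"] <- TRUE
  } else {
    result$fold_changes <- utils::read.csv(outs$unistats)
  }

  # -- corrstruct ----------------------------------------------------------
  if (any(ran) || force || missing_any(outs$corrstruct)) {
    cm <- all_pairs_pearson(log_transform(qm),
                            materials = rep(config$material, ncol(qm)))
    cm <- cluster_order(cm, scope = "all")
    utils::write.csv(ordered_correlations(cm), outs$corrstruct[1])
    result$correlations <- cm
    ran["corrstruct"] <- TRUE
  }

  # -- manifest ------------------------------------------------------------
  cfg_path <- file.path(outdir, "config.json")
  write_pipeline_config(config, cfg_path)
  files <- c(unlist(outs[names(outs) != "spectra"]), cfg_path)
  files <- files[file.exists(files)]
  manifest <- list(
    package = "asphyxNMR",
    version = as.character(utils::packageVersion("asphyxNMR")),
    seed = config$seed,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(list(manifest = manifest, ran = ran), result))
}
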