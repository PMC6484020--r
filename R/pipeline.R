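# End-to-end orchestration: the mechanism analysis (filter -> contact map
# -> helix RMSD -> interaction distances -> correlations -> 2D KDE) and
# the enzymology analysis (normalise -> kcat -> fold change ->
# dose-response -> FP), with machine-readable JSON reports. All outputs
# are plain TSV/CSV/JSON/PNG.

#' Read a run configuration from YAML or JSON
#'
#' @param path config file; keys mirror the arguments of
#'   [run_mechanism()] / [run_enzymology()].
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

# stable hash of the effective configuration, recorded in every report
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = 12,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

.resolve_scenario <- function(config) {
  preset <- config$scenario %||% "mutant_like"
  n <- config$n_frames %||% 2500L
  seed <- config$seed %||% 1L
  if (is.character(preset)) {
    switch(preset,
      mutant_like = mutant_like_scenario(n_frames = n, seed = seed),
      wt_like = wt_like_scenario(n_frames = n, seed = seed),
      stop("unknown scenario preset '", preset, "'")
    )
  } else {
    do.call(trajectory_scenario,
            c(list(n_frames = n, seed = seed), preset))
  }
}

#' Run the mechanism analysis end to end
#'
#' Stages: obtain an ensemble (from `ensemble_path`/`reference_path` or by
#' simulating the configured scenario), remove unbound-ligand frames,
#' compute the enzyme-ligand contact map, the helix RMSD series, the named
#' interaction distance series d1/d2/d3 with median/MAD summaries and
#' occupancies, the pairwise correlations r(d1,d3) and r(d2,d3), and the
#' 2D kernel density estimates. Writes TSV/CSV/PNG outputs plus
#' `report.json` under `config$outdir`.
#'
#' @param config list with keys `outdir`, `seed`, `scenario` (preset name
#'   `"mutant_like"`/`"wt_like"` or a parameter list), `n_frames`,
#'   optional `ensemble_path`/`reference_path`/`regions_path`, and
#'   optional thresholds `filter_threshold_nm` (0.8),
#'   `saltbridge_cutoff_nm` (0.4), `cation_pi_cutoff_nm` (0.6).
#' @return The run report (list), invisibly written as JSON.
#' @export
run_mechanism <- function(config) {
  outdir <- config$outdir %||% stop("config needs an outdir")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  thr <- config$filter_threshold_nm %||% 0.8
  sb_cut <- config$saltbridge_cutoff_nm %||% 0.4
  cp_cut <- config$cation_pi_cutoff_nm %||% 0.6
  hash <- .config_hash(config)
  outputs <- list()
  headline <- list()

  if (!is.null(config$ensemble_path)) {
    regions <- if (!is.null(config$regions_path)) {
      read_regions(config$regions_path)
    } else list()
    reference <- read_structure(config$reference_path, regions = regions)
    ensemble <- read_ensemble(config$ensemble_path, regions = regions)
  } else {
    reference <- build_reference_complex()
    scenario <- .resolve_scenario(config)
    ensemble <- simulate_trajectory(scenario, reference)
  }
  message(sprintf("[mechanism] ensemble: %d frames, %d atoms",
                  n_frames(ensemble), nrow(ensemble$topology$atoms)))

  flt <- filter_unbound_frames(ensemble, reference, threshold_nm = thr)
  kept_fraction <- mean(flt$mask$kept)
  if (kept_fraction < 0.5) {
    warning(sprintf("only %.0f%% of frames kept by the unbound-ligand filter",
                    100 * kept_fraction))
  }
  outputs$frame_mask <- file.path(outdir, "frame_mask.csv")
  write_frame_mask(flt$mask, outputs$frame_mask)
  headline$kept_frame_fraction <- kept_fraction
  if (is.null(flt$ensemble)) {
    stop("stage filter: all frames removed; partial outputs in ", outdir)
  }
  bound <- flt$ensemble
  message(sprintf("[mechanism] filter: kept %d/%d frames (%.1f%%)",
                  n_frames(bound), n_frames(ensemble), 100 * kept_fraction))

  cm <- contact_map(bound, chain_a = "E", chain_b = "L",
                    residues_a = c(130L, 160L))
  outputs$contact_map <- file.path(outdir, "contact_map.tsv")
  write_contact_map(cm, outputs$contact_map)
  outputs$contact_map_png <- file.path(outdir, "contact_map.png")
  plot_contact_map(cm, outputs$contact_map_png)
  amin <- arrayInd(which.min(cm$values), dim(cm$values))
  headline$closest_contact <- sprintf("%s--%s", cm$rows[amin[1]],
                                      cm$cols[amin[2]])
  headline$closest_contact_nm <- min(cm$values)

  helix <- region_rmsd(bound, reference, fit_role = "enzyme",
                       measure_role = "srm_helix", atom_filter = "CA")
  outputs$helix_rmsd <- file.path(outdir, "helix_rmsd.csv")
  write.csv(data.frame(time_ns = helix$times, rmsd_nm = helix$values),
            outputs$helix_rmsd, row.names = FALSE)
  hs <- summarize_series(helix$values)
  headline$helix_rmsd_median_nm <- hs$median
  headline$helix_rmsd_mad_nm <- hs$mad
  # fraction of bound frames with a partially unfolded helix (RMSD above
  # the folded band)
  headline$helix_unfolded_fraction <- mean(helix$values > 0.35)

  groups <- reference_interaction_groups(bound$topology)
  series <- lapply(names(groups), function(lbl) {
    g <- groups[[lbl]]
    distance_series(bound, g$group_a, g$group_b, mode = g$mode, label = lbl)
  })
  names(series) <- names(groups)
  dist_df <- data.frame(time_ns = bound$times,
                        d1 = series$d1$values, d2 = series$d2$values,
                        d3 = series$d3$values)
  outputs$distances <- file.path(outdir, "distances.csv")
  write.csv(dist_df, outputs$distances, row.names = FALSE)
  summaries <- do.call(rbind, lapply(series, function(s) {
    data.frame(label = s$label, median_nm = s$summary$median,
               mad_nm = s$summary$mad)
  }))
  summaries$occupancy <- c(occupancy(series$d1, sb_cut),
                           occupancy(series$d2, cp_cut),
                           occupancy(series$d3, sb_cut))
  summaries$cutoff_nm <- c(sb_cut, cp_cut, sb_cut)
  outputs$summaries <- file.path(outdir, "distance_summaries.csv")
  write.csv(summaries, outputs$summaries, row.names = FALSE)
  headline$d1_median_nm <- series$d1$summary$median
  headline$d1_occupancy <- summaries$occupancy[1]
  headline$d2_occupancy <- summaries$occupancy[2]
  for (lbl in names(series)) {
    outputs[[paste0(lbl, "_distribution_png")]] <-
      file.path(outdir, paste0(lbl, "_distribution.png"))
    plot_distance_distribution(series[[lbl]],
                               outputs[[paste0(lbl, "_distribution_png")]])
  }

  r13 <- pearson_r(series$d1, series$d3)
  r23 <- pearson_r(series$d2, series$d3)
  outputs$correlations <- file.path(outdir, "correlations.csv")
  write.csv(data.frame(pair = c("d1~d3", "d2~d3"), pearson_r = c(r13, r23)),
            outputs$correlations, row.names = FALSE)
  headline$r_d1_d3 <- r13
  headline$r_d2_d3 <- r23
  message(sprintf("[mechanism] correlations: r(d1,d3) = %.3f, r(d2,d3) = %.3f",
                  r13, r23))

  kde13 <- kde2d_density(series$d1, series$d3)
  kde23 <- kde2d_density(series$d2, series$d3)
  outputs$kde_d1_d3 <- file.path(outdir, "kde_d1_d3.tsv")
  write_density2d(kde13, outputs$kde_d1_d3)
  outputs$kde_d1_d3_png <- file.path(outdir, "kde_d1_d3.png")
  plot_density2d(kde13, outputs$kde_d1_d3_png,
                 xlab = "d1 (nm)", ylab = "d3 (nm)")
  outputs$kde_d2_d3 <- file.path(outdir, "kde_d2_d3.tsv")
  write_density2d(kde23, outputs$kde_d2_d3)
  outputs$kde_d2_d3_png <- file.path(outdir, "kde_d2_d3.png")
  plot_density2d(kde23, outputs$kde_d2_d3_png,
                 xlab = "d2 (nm)", ylab = "d3 (nm)")

  report <- list(
    analysis = "mechanism",
    provenance = list(config_hash = hash, seed = config$seed %||% 1L,
                      package_version =
                        as.character(utils::packageVersion("allostat")),
                      n_frames_total = n_frames(ensemble),
                      n_frames_used = n_frames(bound),
                      filter_threshold_nm = thr),
    outputs = outputs,
    headline = headline
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}

# kcat fits for every dataset of a well table (single- or multi-timepoint)
.panel_kcat <- function(wells, counts_per_pmol, volume_ul) {
  fits <- list()
  for (ds in unique(wells$dataset)) {
    w <- wells[wells$dataset == ds, ]
    bg <- w$cpm[w$role == "no_enzyme_background"]
    if (length(bg) == 0L) {
      stop("validation error: dataset '", ds,
           "' lacks no_enzyme_background wells")
    }
    s <- w[w$role == "sample", ]
    product <- cpm_to_product(pmax(s$cpm - mean(bg), 0),
                              counts_per_pmol, volume_ul)
    fits[[ds]] <- fit_kcat(
      product, s$time, enzyme_nM = s$enzyme_conc[1],
      substrate = if ("substrate" %in% names(s)) s$substrate[1]
                  else NA_character_,
      complex_id = if ("complex_id" %in% names(s)) s$complex_id[1]
                   else NA_character_,
      compound_id = if ("compound_id" %in% names(s)) s$compound_id[1]
                    else NA_character_
    )
  }
  fits
}

#' Run the enzymology analysis end to end
#'
#' Stages: simulate (or read) an activity panel of endpoint timecourses,
#' fit kcat per (complex, compound, substrate) dataset, compute fold
#' changes against the vehicle control, fit the activation dose-response
#' per configured scenario, and fit the FP titration. Writes a
#' panel-shaped kcat CSV, fold-change/dose-response/FP CSVs and
#' `report.json` under `config$outdir`.
#'
#' @param config list with keys `outdir`, `seed`, optional `activity_csv`
#'   (well-level CPM table; simulated from the reference turnover panel
#'   when absent), `noise_cv`, `counts_per_pmol`, `volume_ul`, and
#'   optional scenario blocks `dose_response` and `fp` (argument lists for
#'   [assay_scenario()], or `NULL` to skip).
#' @return The run report (list), invisibly written as JSON.
#' @export
run_enzymology <- function(config) {
  outdir <- config$outdir %||% stop("config needs an outdir")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  counts_per_pmol <- config$counts_per_pmol %||% 500
  volume_ul <- config$volume_ul %||% 10
  hash <- .config_hash(config)
  outputs <- list()
  headline <- list()

  wells <- if (!is.null(config$activity_csv)) {
    read.csv(config$activity_csv)
  } else {
    simulate_activity_panel(noise_cv = config$noise_cv %||% 0.05,
                            seed = seed)
  }
  fits <- .panel_kcat(wells, counts_per_pmol, volume_ul)
  kcat_df <- do.call(rbind, lapply(names(fits), function(ds) {
    f <- fits[[ds]]
    data.frame(dataset = ds, substrate = f$substrate,
               complex_id = f$complex_id, compound_id = f$compound_id,
               kcat_per_h = f$kcat, sd = f$sd)
  }))
  kcat_df$condition <- paste(kcat_df$substrate, kcat_df$complex_id, sep = "_")
  outputs$kcat_table <- file.path(outdir, "kcat_table.csv")
  write.csv(kcat_df, outputs$kcat_table, row.names = FALSE)

  folds <- NULL
  if (all(c("compound_id", "complex_id", "substrate") %in% names(kcat_df))) {
    rows <- list()
    for (cond in unique(kcat_df$condition)) {
      sub <- kcat_df[kcat_df$condition == cond, ]
      ctrl_id <- sub$dataset[sub$compound_id == "DMSO"]
      if (length(ctrl_id) != 1L) next
      for (ds in sub$dataset) {
        fc <- fold_change(fits[[ds]], fits[[ctrl_id]])
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, compound_id = fits[[ds]]$compound_id,
          fold = fc$ratio, sd = fc$sd)
      }
    }
    folds <- do.call(rbind, rows)
    outputs$fold_changes <- file.path(outdir, "fold_changes.csv")
    write.csv(folds, outputs$fold_changes, row.names = FALSE)
    act <- folds[folds$compound_id %in% c("1", "2") &
                   folds$condition == "peptide_I363M", "fold"]
    if (length(act) > 0) headline$mutant_peptide_fold_activation <- mean(act)
  }
  message(sprintf("[enzymology] kcat fitted for %d datasets", length(fits)))

  if (!identical(config$dose_response, FALSE)) {
    dr_args <- config$dose_response %||% list()
    dr_sc <- do.call(assay_scenario,
                     c(list(seed = seed,
                            noise_cv = dr_args$noise_cv %||% 0.03),
                       dr_args[setdiff(names(dr_args), "noise_cv")]))
    dr_wells <- if (!is.null(config$dose_response_csv)) {
      read.csv(config$dose_response_csv)
    } else {
      simulate_assay(dr_sc, "dose_response")
    }
    dr_norm <- normalize_activity(dr_wells)
    s <- dr_norm[dr_norm$role == "sample", ]
    dr_fit <- fit_dose_response(s$compound_conc, s$percent_activity)
    outputs$dose_response <- file.path(outdir, "dose_response.csv")
    write.csv(data.frame(ec50_uM = dr_fit$ec50, se_ec50 = dr_fit$se_ec50,
                         hill = dr_fit$hill, top = dr_fit$top,
                         bottom = dr_fit$bottom,
                         direction = dr_fit$direction),
              outputs$dose_response, row.names = FALSE)
    headline$ec50_uM <- dr_fit$ec50
    message(sprintf("[enzymology] EC50 = %.2f uM (%s)", dr_fit$ec50,
                    dr_fit$direction))
  } else {
    message("[enzymology] dose-response skipped (not configured)")
  }

  if (!identical(config$fp, FALSE)) {
    fp_args <- config$fp %||% list()
    fp_sc <- do.call(assay_scenario,
                     c(list(seed = seed,
                            noise_cv = fp_args$noise_cv %||% 0.02),
                       fp_args[setdiff(names(fp_args), "noise_cv")]))
    fp_wells <- if (!is.null(config$fp_csv)) {
      read.csv(config$fp_csv)
    } else {
      simulate_assay(fp_sc, "fp_titration")
    }
    fp_fit <- fit_fp_binding(fp_wells$protein_conc, fp_wells$fp,
                             tracer_nM = fp_wells$tracer_conc[1])
    outputs$fp_fit <- file.path(outdir, "fp_fit.csv")
    write.csv(data.frame(kd_nM = fp_fit$kd, se_kd = fp_fit$se_kd,
                         fp_min = fp_fit$fp_min, fp_max = fp_fit$fp_max,
                         tracer_nM = fp_fit$tracer_nM),
              outputs$fp_fit, row.names = FALSE)
    headline$kd_nM <- fp_fit$kd
    message(sprintf("[enzymology] Kd = %.0f nM", fp_fit$kd))
  } else {
    message("[enzymology] FP titration skipped (not configured)")
  }

  report <- list(
    analysis = "enzymology",
    provenance = list(config_hash = hash, seed = seed,
                      package_version =
                        as.character(utils::packageVersion("allostat"))),
    outputs = outputs,
    headline = headline
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}
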