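#' Full-study configuration
#'
#' Defaults reproduce the study's design dimensions: 3 modalities x 2 phantom
#' sizes x 2 insert series (6 concentrations each) x 6 VMI energies x
#' 4 slices x 5 repeats. The VMI energy sweep runs on the fast statistical
#' tier (declared bias/noise model); the physics tier (full polyenergetic
#' simulation and reconstruction) runs at 70 keV, the energy at which the
#' three modalities are compared head to head.
#'
#' @param modalities,sizes,series Study dimensions.
#' @param vmi_energies Statistical-tier VMI sweep (keV).
#' @param physics Logical: run the physics tier (default TRUE).
#' @param physics_energies VMI energies for the physics tier (default 70).
#' @param n_slices,n_repeats Sample layout (defaults 4, 5).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param fluence_per_ray Photons per ray for the physics tier.
#' @param n_views,n_det,n_pix,pixel_mm,bin_width Physics-tier geometry.
#' @param table_concentrations Concentrations highlighted by
#'   [render_tables()] (calcium 120, iodine 5 mg/mL).
#' @return A `study_config` list.
#' @export
study_config <- function(modalities = c("PCCT", "DECT", "SECT"),
                         sizes = c("small", "large"),
                         series = c("iodine", "calcium"),
                         vmi_energies = c(40, 60, 70, 90, 110, 130),
                         physics = TRUE, physics_energies = 70,
                         n_slices = 4, n_repeats = 5, n_boot = 1000,
                         fluence_per_ray = 1e7,
                         n_views = 720, n_det = 367, n_pix = 256,
                         pixel_mm = 360 / 256, bin_width = 2,
                         table_concentrations = c(calcium = 120, iodine = 5)) {
  cfg <- list(modalities = modalities, sizes = sizes, series = series,
              vmi_energies = vmi_energies, physics = physics,
              physics_energies = physics_energies, n_slices = n_slices,
              n_repeats = n_repeats, n_boot = n_boot,
              fluence_per_ray = fluence_per_ray, n_views = n_views,
              n_det = n_det, n_pix = n_pix, pixel_mm = pixel_mm,
              bin_width = bin_width,
              table_concentrations = table_concentrations)
  if (!all(cfg$sizes %in% c("small", "large")) || length(cfg$sizes) == 0) {
    stop("config$sizes: must be among small, large", call. = FALSE)
  }
  structure(cfg, class = "study_config")
}

metric_row <- function(tier, series, modality, size, material, concentration,
                       vmi_energy, res, n) {
  data.frame(tier = tier, series = series, modality = modality, size = size,
             material = material, concentration = concentration,
             vmi_energy = vmi_energy, metric = res$kind,
             estimate = res$estimate, ci_low = res$ci_low,
             ci_high = res$ci_high, n = n, seed = res$seed,
             stringsAsFactors = FALSE)
}

# metrics for one configuration: named list size -> named list insert -> set
config_metrics <- function(tier, series_name, modality, energy_label,
                           sets_by_size, theory_by_insert, n_boot,
                           master_seed, background_insert = NULL) {
  rows <- list()
  conc <- attr(insert_series(series_name), "concentrations")
  insert_ids <- names(sets_by_size[[1]])
  for (ins in insert_ids) {
    cc <- conc[match(ins, insert_ids)]
    mseed <- child_seed(master_seed, "metrics", tier, series_name, modality,
                        energy_label, ins)
    for (size in names(sets_by_size)) {
      set <- sets_by_size[[size]][[ins]]
      n <- nrow(set$samples)
      if (modality != "SECT" && !is.null(theory_by_insert)) {
        acc <- accuracy_pct(set, theory_by_insert[[ins]], n_boot, seed = mseed)
        rows[[length(rows) + 1]] <- metric_row(tier, series_name, modality,
                                               size, ins, cc, energy_label,
                                               acc, n)
      }
      cov <- precision_cov(set, n_boot, seed = mseed)
      rows[[length(rows) + 1]] <- metric_row(tier, series_name, modality,
                                             size, ins, cc, energy_label,
                                             cov, n)
      if (!is.null(background_insert) && ins == background_insert) {
        bg <- background_sd(set, n_boot, seed = mseed)
        rows[[length(rows) + 1]] <- metric_row(tier, series_name, modality,
                                               size, ins, cc, energy_label,
                                               bg, n)
      }
    }
    if (all(c("large", "small") %in% names(sets_by_size))) {
      sdp <- size_dependence_pct(sets_by_size$large[[ins]],
                                 sets_by_size$small[[ins]], n_boot,
                                 seed = mseed)
      rows[[length(rows) + 1]] <- metric_row(tier, series_name, modality,
                                             "both", ins, cc, energy_label,
                                             sdp, nrow(sets_by_size$large[[ins]]$samples))
    }
  }
  do.call(rbind, rows)
}

#' Run the full evaluation study
#'
#' Executes the statistical-tier VMI energy sweep and (optionally) the
#' physics tier at 70 keV, extracts ROI samples, computes all metrics with
#' percentile-bootstrap CIs, and renders the summary tables. All randomness
#' derives from the master seed, so rerunning with the same seed reproduces
#' every output byte for byte.
#'
#' @param config A [study_config()].
#' @param master_seed Integer master seed.
#' @param out_dir Optional output directory; when given, writes
#'   `metrics.csv`, per-configuration sample CSVs, `tables.md`, and
#'   `manifest.json`.
#' @param write_images Also write the physics-tier image stacks (NIfTI +
#'   sidecar) under `out_dir/images`.
#' @return List with `metrics` (tidy data.frame), `tables` (character),
#'   `manifest` (list), and `samples` (nested list of `roi_sample_set`s).
#' @export
run_study <- function(config = study_config(), master_seed = 1,
                      out_dir = NULL, write_images = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  all_rows <- list()
  all_samples <- list()
  # effective energy label for SECT (its spectrum mean energy, ~70 keV)
  sect_energy <- if ("SECT" %in% config$modalities) {
    spectrum_mean_energy(acquisition_model("SECT")$spectra[[1]])
  } else NA_real_

  ## ---- statistical tier: VMI energy sweep -------------------------------
  for (series_name in config$series) {
    mats <- insert_series(series_name)
    conc <- attr(mats, "concentrations")
    bg_ins <- if (series_name == "iodine") names(mats)[1] else NULL
    for (mod in config$modalities) {
      energies <- if (mod == "SECT") sect_energy else config$vmi_energies
      for (E in energies) {
        sets_by_size <- lapply(setNames(config$sizes, config$sizes),
                               function(size) {
          sets <- lapply(seq_along(mats), function(i) {
            bm <- default_bias_model(mats[[i]], mod, size, E)
            statistical_roi_generator(
              lac_value(mats[[i]], E), bm$bias_pct, bm$noise_sd,
              config$n_slices, config$n_repeats,
              seed = child_seed(master_seed, "stat", series_name, mod, size,
                                round(E, 3), names(mats)[i]),
              insert_id = names(mats)[i])
          })
          setNames(sets, names(mats))
        })
        theory <- lapply(mats, lac_value, energy = E)
        elab <- if (mod == "SECT") NA_real_ else E
        all_rows[[length(all_rows) + 1]] <- config_metrics(
          "statistical", series_name, mod,
          if (is.na(elab)) "native" else elab, sets_by_size,
          if (mod == "SECT") NULL else theory, config$n_boot, master_seed,
          bg_ins)
        all_samples[[paste("stat", series_name, mod,
                           if (is.na(elab)) "native" else elab,
                           sep = "/")]] <- sets_by_size
      }
    }
  }

  ## ---- physics tier at the comparison energy ----------------------------
  stacks <- NULL
  if (isTRUE(config$physics)) {
    sim_cfg <- simulate_config(
      modalities = config$modalities, sizes = config$sizes,
      series = config$series, vmi_energies = config$physics_energies,
      n_slices = config$n_slices, n_repeats = config$n_repeats,
      fluence_per_ray = config$fluence_per_ray, n_views = config$n_views,
      n_det = config$n_det, n_pix = config$n_pix, pixel_mm = config$pixel_mm,
      bin_width = config$bin_width)
    stacks <- simulate_study(sim_cfg, master_seed)
    grouped <- sample_study_rois(stacks)
    for (series_name in config$series) {
      mats <- insert_series(series_name)
      bg_ins <- if (series_name == "iodine") names(mats)[1] else NULL
      for (mod in config$modalities) {
        energies <- if (mod == "SECT") "native" else
          as.character(config$physics_energies)
        for (elab in energies) {
          keys <- paste(series_name, mod, config$sizes, elab, sep = "/")
          if (!all(keys %in% names(grouped))) next
          sets_by_size <- setNames(lapply(keys, function(k) grouped[[k]]),
                                   config$sizes)
          E <- if (elab == "native") sect_energy else as.numeric(elab)
          theory <- lapply(mats, lac_value, energy = E)
          all_rows[[length(all_rows) + 1]] <- config_metrics(
            "physics", series_name, mod, elab, sets_by_size,
            if (mod == "SECT") NULL else theory, config$n_boot, master_seed,
            bg_ins)
          all_samples[[paste("phys", series_name, mod, elab,
                             sep = "/")]] <- sets_by_size
        }
      }
    }
  }

  metrics <- do.call(rbind, all_rows)
  rownames(metrics) <- NULL
  tables <- render_tables(metrics, config$table_concentrations)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ctqa")),
    master_seed = master_seed,
    config_digest = ctqa_digest(unclass(config)),
    metrics_digest = ctqa_digest(metrics),
    n_metric_rows = nrow(metrics))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    writeLines(tables, file.path(out_dir, "tables.md"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    samp_rows <- do.call(rbind, lapply(names(all_samples), function(key) {
      do.call(rbind, lapply(names(all_samples[[key]]), function(size) {
        do.call(rbind, lapply(all_samples[[key]][[size]], function(s) {
          cbind(config = key, size = size, insert = s$insert_id, s$samples)
        }))
      }))
    }))
    write.csv(samp_rows, file.path(out_dir, "samples.csv"), row.names = FALSE)
    if (write_images && !is.null(stacks)) {
      write_image_stacks(stacks, file.path(out_dir, "images"))
    }
  }
  message(sprintf("run_study: %d metric rows in %.1f s", nrow(metrics),
                  proc.time()[["elapsed"]] - t0))
  list(metrics = metrics, tables = tables, manifest = manifest,
       samples = all_samples)
}

fmt_cell <- function(df, metric, digits = 2) {
  if (nrow(df) == 0) return("-")
  sprintf(paste0("%.", digits, "f [%.", digits, "f, %.", digits, "f]"),
          df$estimate[1], df$ci_low[1], df$ci_high[1])
}

#' Render summary tables from a tidy metrics table
#'
#' Produces three markdown blocks -- accuracy, precision (COV), and size
#' dependence -- for the highlighted concentrations at the 70 keV comparison
#' point, one column per modality, with bracketed 95% CIs. The SECT accuracy
#' cell is always a dash: without an object-independent beam model, SECT has
#' no unique theoretical LAC, so its accuracy cannot be determined.
#'
#' @param metrics Tidy metrics data.frame from [run_study()].
#' @param table_concentrations Named vector, highlighted concentration per
#'   series.
#' @return Character vector of markdown lines.
#' @export
render_tables <- function(metrics,
                          table_concentrations = c(calcium = 120, iodine = 5)) {
  lines <- character(0)
  mods <- intersect(c("PCCT", "DECT", "SECT"), unique(metrics$modality))
  if (nrow(metrics) == 0 || length(mods) == 0) {
    return(c("## Summary", "", "(no metrics available)"))
  }
  tier <- if ("physics" %in% metrics$tier) "physics" else "statistical"
  pick <- function(mod, metric, series, size) {
    cc <- table_concentrations[[series]]
    e_ok <- if (mod == "SECT") TRUE else metrics$vmi_energy == "70"
    metrics[metrics$tier == tier & metrics$modality == mod &
            metrics$metric == metric & metrics$series == series &
            metrics$size == size & metrics$concentration == cc & e_ok, ,
            drop = FALSE]
  }
  blocks <- list(
    c("accuracy_pct", "Accuracy of LAC (%)"),
    c("cov", "Precision of LAC (COV)"),
    c("size_dependence_pct", "Size dependence of LAC (%)"))
  for (b in blocks) {
    metric <- b[1]; title <- b[2]
    lines <- c(lines, paste0("## ", title), "",
               paste0("| series | size | ", paste(mods, collapse = " | "),
                      " |"),
               paste0("|---|---|", paste(rep("---|", length(mods)),
                                         collapse = "")))
    for (series in intersect(c("calcium", "iodine"),
                             unique(metrics$series))) {
      sizes <- if (metric == "size_dependence_pct") "both" else
        intersect(c("small", "large"), unique(metrics$size))
      for (size in sizes) {
        cells <- vapply(mods, function(mod) {
          if (metric == "accuracy_pct" && mod == "SECT") return("-")
          d <- pick(mod, metric, series, size)
          fmt_cell(d, metric, digits = if (metric == "cov") 4 else 2)
        }, character(1))
        lines <- c(lines, paste0("| ", series, " (",
                                 table_concentrations[[series]], " mg/mL) | ",
                                 size, " | ", paste(cells, collapse = " | "),
                                 " |"))
      }
    }
    lines <- c(lines, "")
  }
  miss <- setdiff(vapply(blocks, `[`, character(1), 1),
                  unique(metrics$metric))
  if (length(miss) > 0) {
    warning("metrics missing from input: ", paste(miss, collapse = ", "))
  }
  lines
}

#' Analyze user-supplied image stacks
#'
#' Loads a directory of NIfTI + JSON sidecar stacks, places ROIs from a
#' centers file (or from the phantom layout carried in the sidecars),
#' extracts per-insert sample sets per configuration, and computes precision
#' and (given theoretical LACs) accuracy metrics.
#'
#' @param images_dir Directory of image stacks.
#' @param centers Optional path to a centers CSV ([read_centers_csv()]).
#' @param lac_water_ref Optional water LAC override (cm^-1) for the HU
#'   conversion; default uses each stack's sidecar value.
#' @param theory Optional named vector of theoretical LACs (cm^-1) keyed by
#'   insert id, enabling accuracy metrics.
#' @param n_boot,seed Bootstrap settings.
#' @return List with `samples` (per configuration) and `metrics` (tidy
#'   data.frame).
#' @export
analyze_images <- function(images_dir, centers = NULL, lac_water_ref = NULL,
                           theory = NULL, n_boot = 1000, seed = 1) {
  stacks <- load_image_stacks(images_dir)
  specs <- if (!is.null(centers)) read_centers_csv(centers) else NULL
  keys <- vapply(stacks, function(s) {
    paste(s$series, s$modality, s$size_label,
          ifelse(is.na(s$vmi_energy), "native", s$vmi_energy), sep = "/")
  }, character(1))
  samples <- lapply(split(seq_along(stacks), keys), function(idx) {
    sample_rois(stacks[idx], specs = specs, lac_water_ref = lac_water_ref)
  })
  rows <- list()
  for (key in names(samples)) {
    for (ins in names(samples[[key]])) {
      set <- samples[[key]][[ins]]
      cov <- precision_cov(set, n_boot, seed = seed)
      rows[[length(rows) + 1]] <- data.frame(
        config = key, insert = ins, metric = "cov", estimate = cov$estimate,
        ci_low = cov$ci_low, ci_high = cov$ci_high,
        n = nrow(set$samples), stringsAsFactors = FALSE)
      if (!is.null(theory) && ins %in% names(theory)) {
        acc <- accuracy_pct(set, theory[[ins]], n_boot, seed = seed)
        rows[[length(rows) + 1]] <- data.frame(
          config = key, insert = ins, metric = "accuracy_pct",
          estimate = acc$estimate, ci_low = acc$ci_low,
          ci_high = acc$ci_high, n = nrow(set$samples),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(samples = samples,
       metrics = if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Save / load a study configuration as YAML
#'
#' `save_study_config()` writes the configuration; `load_study_config()`
#' reads it back, validates it through [study_config()], and returns an
#' identical object (`load(save(cfg)) == cfg`).
#'
#' @param config A [study_config()].
#' @param path YAML file path.
#' @return `load_study_config()` returns a `study_config`.
#' @export
save_study_config <- function(config, path) {
  raw <- unclass(config)
  raw$table_concentrations <- as.list(raw$table_concentrations)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname save_study_config
#' @export
load_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tc <- unlist(raw$table_concentrations)
  raw$table_concentrations <- tc
  do.call(study_config, raw)
}
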