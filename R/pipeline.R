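#' Configuration of a full composition-analysis run
#'
#' Bundles everything one reproducible run needs: per-day inputs (either
#' ground-truth area percentages from which seeded phantoms are generated,
#' or paths to real stained images), segmentation thresholds, gel volumes
#' for the scaling factor, the fixed cell share, the significance level,
#' the master seed and an optional output directory. A persisted config
#' re-runs to identical outputs.
#'
#' @param area_truth data frame with columns `day`, `mineral_x`, `matrix_y`
#'   (area percentages): the per-day ground truth used to generate phantom
#'   sections. Ignored when `images` is given.
#' @param images optional named list (names = days); each element a list
#'   with character vectors `von_kossa` and `he` of image paths. When
#'   present the pipeline segments these instead of phantoms.
#' @param width,height,nucleus_count,nucleus_radius,noise_sd phantom
#'   geometry and noise (see [phantom_spec()]); used in phantom mode.
#' @param images_per_day phantom sections generated per day and stain
#'   (default 4); their area fractions are averaged per day.
#' @param initial_volume,final_volume gel volumes in mm^3 feeding
#'   [compute_f()].
#' @param thresholds an [rgb_thresholds] bundle.
#' @param cell_z fixed cell share in percent (default 1.5).
#' @param alpha significance level for contraction comparisons.
#' @param seed master seed; all pipeline randomness derives from it.
#' @param contraction optional list with [contraction_spec] elements
#'   `with_cells` and `without_cells` (and optionally `days`): enables the
#'   gel-contraction analytics section.
#' @param vesicles optional list of [vesicle_phantom_spec] objects (named
#'   by day): enables the vesicle morphometry section.
#' @param output_dir optional directory for CSV/JSON outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(area_truth = NULL, images = NULL,
                       width = 256, height = 256, nucleus_count = 5,
                       nucleus_radius = 6, noise_sd = 2, images_per_day = 4,
                       initial_volume = 64, final_volume = 1,
                       thresholds = rgb_thresholds(), cell_z = 1.5,
                       alpha = 0.01, seed = 1, contraction = NULL,
                       vesicles = NULL, output_dir = NULL) {
  stop_unless(!is.null(area_truth) || !is.null(images),
              "provide 'area_truth' (phantom mode) or 'images'")
  if (!is.null(area_truth)) {
    stop_unless(is.data.frame(area_truth) &&
                  all(c("day", "mineral_x", "matrix_y") %in% names(area_truth)),
                "'area_truth' needs columns day, mineral_x, matrix_y")
    stop_unless(all(area_truth$mineral_x >= 0 & area_truth$mineral_x <= 100) &&
                  all(area_truth$matrix_y >= 0 & area_truth$matrix_y <= 100),
                "area percentages must lie in [0, 100]")
  }
  if (!is.null(images)) {
    stop_unless(is.list(images) && !is.null(names(images)),
                "'images' must be a named list keyed by day")
    for (el in images)
      stop_unless(is.list(el) && all(c("von_kossa", "he") %in% names(el)),
                  "each 'images' entry needs 'von_kossa' and 'he' paths")
  }
  stop_unless(inherits(thresholds, "rgb_thresholds"),
              "'thresholds' must come from rgb_thresholds()")
  stop_unless(is_count(images_per_day) && images_per_day >= 1,
              "'images_per_day' must be a positive integer")
  if (!is.null(contraction))
    stop_unless(inherits(contraction$with_cells, "contraction_spec") &&
                  inherits(contraction$without_cells, "contraction_spec"),
                "'contraction' needs contraction_spec elements with_cells and without_cells")
  if (!is.null(vesicles))
    stop_unless(all(vapply(vesicles, inherits, logical(1),
                           "vesicle_phantom_spec")),
                "'vesicles' must be a list of vesicle_phantom_spec objects")
  structure(list(area_truth = area_truth, images = images, width = width,
                 height = height, nucleus_count = nucleus_count,
                 nucleus_radius = nucleus_radius, noise_sd = noise_sd,
                 images_per_day = as.integer(images_per_day),
                 initial_volume = initial_volume,
                 final_volume = final_volume, thresholds = thresholds,
                 cell_z = cell_z, alpha = alpha, seed = as.integer(seed),
                 contraction = contraction, vesicles = vesicles,
                 output_dir = output_dir),
            class = "run_config")
}

#' Read / write a run configuration (JSON or YAML)
#'
#' Configs are serialised with field names mirroring [run_config()];
#' the format is chosen by file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param config a [run_config].
#' @param path file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a [run_config].
#' @export
write_run_config <- function(config, path) {
  stop_unless(inherits(config, "run_config"), "'config' must be a run_config")
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  if (!is.null(x$contraction))
    x$contraction <- lapply(x$contraction, unclass)
  if (!is.null(x$vesicles)) x$vesicles <- lapply(x$vesicles, unclass)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$area_truth)) x$area_truth <- as.data.frame(x$area_truth)
  thr <- do.call(rgb_thresholds, as.list(x$thresholds))
  contraction <- NULL
  if (!is.null(x$contraction)) {
    contraction <- list(
      with_cells = do.call(contraction_spec, as.list(x$contraction$with_cells)),
      without_cells = do.call(contraction_spec,
                              as.list(x$contraction$without_cells)))
    if (!is.null(x$contraction$days)) contraction$days <- x$contraction$days
  }
  vesicles <- NULL
  if (!is.null(x$vesicles))
    vesicles <- lapply(x$vesicles, function(v)
      do.call(vesicle_phantom_spec, as.list(v)))
  run_config(area_truth = x$area_truth, images = x$images, width = x$width,
             height = x$height, nucleus_count = x$nucleus_count,
             nucleus_radius = x$nucleus_radius, noise_sd = x$noise_sd,
             images_per_day = x$images_per_day,
             initial_volume = x$initial_volume,
             final_volume = x$final_volume, thresholds = thr,
             cell_z = x$cell_z, alpha = x$alpha, seed = x$seed,
             contraction = contraction, vesicles = vesicles,
             output_dir = x$output_dir)
}

segment_day_images <- function(vk_images, he_images, thresholds) {
  vk <- vapply(vk_images, function(img)
    area_fraction(segment_mineral(img, thresholds)), numeric(1))
  he <- vapply(he_images, function(img)
    area_fraction(segment_matrix(img, thresholds)), numeric(1))
  list(mineral = vk, matrix = he)
}

#' Run the full composition-analysis pipeline
#'
#' Executes generate (or load) -> segment -> average -> compose in order:
#' segments every von Kossa and HE section per day, averages the per-image
#' area fractions within each day, computes the contraction-normalised
#' factor f from the gel volumes and converts the per-day areas into the
#' four-component volume composition. Optional sections add gel-contraction
#' analytics and vesicle morphometry. All randomness derives from the
#' config seed; re-running a persisted config reproduces outputs byte for
#' byte.
#'
#' @param config a [run_config].
#' @return An object of class `run_report`: list with `area_fractions`
#'   (per image), `per_day` (day means), `composition` (a
#'   [composition_trajectory]), optional `contraction` and `vesicles`
#'   sections, `warnings` and `fingerprint`. When `config$output_dir` is
#'   set, CSV tables and a JSON report are written there.
#' @examples
#' cfg <- run_config(area_truth = data.frame(day = 42, mineral_x = 30,
#'                                           matrix_y = 40),
#'                   width = 96, height = 96, images_per_day = 1,
#'                   initial_volume = 43, final_volume = 1)
#' rep <- run_pipeline(cfg)
#' rep$composition
#' @export
run_pipeline <- function(config) {
  stop_unless(inherits(config, "run_config"), "'config' must be a run_config")
  warns <- character(0)
  note <- function(w) warns <<- c(warns, w)

  if (!is.null(config$images)) {
    days <- as.numeric(names(config$images))
    per_image <- do.call(rbind, lapply(seq_along(days), function(i) {
      el <- config$images[[i]]
      vk <- lapply(el$von_kossa, read_stained_image, stain = "VON_KOSSA")
      he <- lapply(el$he, read_stained_image, stain = "HE")
      fr <- segment_day_images(vk, he, config$thresholds)
      rbind(data.frame(day = days[i], stain = "VON_KOSSA",
                       image = seq_along(fr$mineral), fraction = fr$mineral),
            data.frame(day = days[i], stain = "HE",
                       image = seq_along(fr$matrix), fraction = fr$matrix))
    }))
  } else {
    truth <- config$area_truth[order(config$area_truth$day), , drop = FALSE]
    days <- truth$day
    seeds <- matrix(derive_seeds(config$seed,
                                 2L * nrow(truth) * config$images_per_day),
                    nrow = nrow(truth))
    per_image <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      vk <- lapply(seq_len(config$images_per_day), function(j)
        generate_stain_phantom(phantom_spec(
          config$width, config$height,
          mineral_fraction = truth$mineral_x[i] / 100,
          nucleus_count = config$nucleus_count,
          nucleus_radius = config$nucleus_radius,
          noise_sd = config$noise_sd, seed = seeds[i, j],
          stain = "VON_KOSSA"))$image)
      he <- lapply(seq_len(config$images_per_day), function(j)
        generate_stain_phantom(phantom_spec(
          config$width, config$height,
          matrix_fraction = truth$matrix_y[i] / 100,
          nucleus_count = config$nucleus_count,
          nucleus_radius = config$nucleus_radius,
          noise_sd = config$noise_sd,
          seed = seeds[i, config$images_per_day + j],
          stain = "HE"))$image)
      fr <- segment_day_images(vk, he, config$thresholds)
      rbind(data.frame(day = days[i], stain = "VON_KOSSA",
                       image = seq_along(fr$mineral), fraction = fr$mineral),
            data.frame(day = days[i], stain = "HE",
                       image = seq_along(fr$matrix), fraction = fr$matrix))
    }))
  }

  vk_mean <- tapply(per_image$fraction[per_image$stain == "VON_KOSSA"],
                    per_image$day[per_image$stain == "VON_KOSSA"], mean)
  he_mean <- tapply(per_image$fraction[per_image$stain == "HE"],
                    per_image$day[per_image$stain == "HE"], mean)
  per_day <- data.frame(day = as.numeric(names(vk_mean)),
                        mineral_x = as.numeric(vk_mean),
                        matrix_y = as.numeric(he_mean))

  composition <- composition_trajectory(per_day, config$initial_volume,
                                        config$final_volume,
                                        cell_z = config$cell_z)
  # self-validation: closure must hold before anything is written
  closure <- rowSums(composition[, c("mineral", "matrix", "cell", "fibrin")])
  stop_unless(all(abs(closure - 100) < 1e-9),
              "internal error: composition closure violated")

  contraction <- NULL
  if (!is.null(config$contraction)) {
    cdays <- config$contraction$days
    if (is.null(cdays)) cdays <- seq(0, 42, by = 3)
    ser <- withCallingHandlers(
      generate_contraction_series(config$contraction$with_cells,
                                  config$contraction$without_cells,
                                  days = cdays),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    last_day <- max(cdays)
    comparison <- compare_conditions(ser[[1]], ser[[2]], alpha = config$alpha)
    contraction <- list(
      series = rbind(ser[[1]], ser[[2]]),
      terminal_contraction = c(
        with_cells = length_contraction(ser[[1]], last_day),
        without_cells = length_contraction(ser[[2]], last_day)),
      comparison = comparison,
      plateau_day = recover_plateau_day(config$contraction$with_cells,
                                        days = cdays, alpha = config$alpha))
  }

  vesicles <- NULL
  if (!is.null(config$vesicles)) {
    vesicles <- do.call(rbind, lapply(seq_along(config$vesicles), function(i) {
      ph <- generate_vesicle_phantom(config$vesicles[[i]])
      st <- vesicle_stats(ph$cell_mask, ph$vesicle_mask)
      nm <- names(config$vesicles)[i]
      data.frame(id = if (is.null(nm) || nm == "") as.character(i) else nm,
                 area_ratio_pct = st$area_ratio,
                 mean_size = ifelse(st$mean_defined, st$mean_size, NA),
                 count = st$count)
    }))
  }

  report <- structure(list(
    area_fractions = per_image, per_day = per_day,
    composition = composition, contraction = contraction,
    vesicles = vesicles, warnings = warns,
    fingerprint = list(package = "osteogel",
                       version = as.character(utils::packageVersion("osteogel")),
                       seed = config$seed)),
    class = "run_report")

  if (!is.null(config$output_dir)) write_run_report(report, config)
  report
}

write_run_report <- function(report, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  utils::write.csv(report$area_fractions, out("area_fractions.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$composition), out("composition.csv"),
                   row.names = FALSE)
  if (!is.null(report$contraction)) {
    utils::write.csv(report$contraction$series, out("contraction_series.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(report$contraction$comparison),
                     out("contraction_comparison.csv"), row.names = FALSE)
  }
  if (!is.null(report$vesicles))
    utils::write.csv(report$vesicles, out("vesicles.csv"), row.names = FALSE)
  json <- list(fingerprint = report$fingerprint,
               per_day = report$per_day,
               composition = as.data.frame(report$composition),
               warnings = report$warnings)
  if (!is.null(report$contraction))
    json$contraction <- list(
      terminal_contraction = as.list(report$contraction$terminal_contraction),
      plateau_day = report$contraction$plateau_day)
  jsonlite::write_json(json, out("report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", pretty = TRUE)
  invisible(config$output_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  %d day(s), %d segmented section(s)\n",
              nrow(x$per_day), nrow(x$area_fractions)))
  cat("  composition (volume %):\n")
  df <- as.data.frame(x$composition)
  for (i in seq_len(nrow(df)))
    cat(sprintf("    day %-3g mineral %5.1f  matrix %5.1f  cell %4.1f  fibrin %5.1f\n",
                df$day[i], df$mineral[i], df$matrix[i], df$cell[i],
                df$fibrin[i]))
  if (!is.null(x$contraction)) {
    tc <- x$contraction$terminal_contraction
    cat(sprintf("  contraction: %.1f%% (cells) vs %.1f%% (no cells); plateau day %s\n",
                tc[1], tc[2], format(x$contraction$plateau_day)))
  }
  if (!is.null(x$vesicles))
    cat(sprintf("  vesicles: %d phantom(s) analysed\n", nrow(x$vesicles)))
  if (length(x$warnings))
    cat(sprintf("  %d warning(s)\n", length(x$warnings)))
  invisible(x)
}
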