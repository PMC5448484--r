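#' Specification of a stained-section phantom
#'
#' Describes a synthetic stained section with known ground truth: image
#' size, requested mineral and matrix area fractions, nucleus geometry,
#' additive channel noise and a seed. The generator realises the requested
#' fractions to within one pixel of quantization and records exact truth
#' masks, so segmentation can be validated pixel-for-pixel.
#'
#' @param width,height raster size in pixels (positive integers).
#' @param mineral_fraction,matrix_fraction requested area fractions in
#'   \[0, 1\]; their sum must not exceed 1.
#' @param nucleus_count number of non-overlapping circular nuclei.
#' @param nucleus_radius nucleus radius in pixels.
#' @param noise_sd standard deviation of independent per-channel Gaussian
#'   noise (0--255 intensity units), applied after class colours are laid
#'   down, then clipped to \[0, 255\] and rounded.
#' @param seed integer seed; identical specs produce bit-identical phantoms.
#' @param stain `"HE"` or `"VON_KOSSA"`; selects the class palette so that
#'   ground-truth pixels satisfy the corresponding segmentation rule exactly
#'   when `noise_sd = 0` and background pixels satisfy none of the rules.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(width, height, mineral_fraction = 0,
                         matrix_fraction = 0, nucleus_count = 0,
                         nucleus_radius = 6, noise_sd = 0, seed = 1,
                         stain = c("VON_KOSSA", "HE")) {
  stain <- match.arg(stain)
  stop_unless(is_count(width) && width > 0 && is_count(height) && height > 0,
              "'width' and 'height' must be positive integers")
  stop_unless(is_number(mineral_fraction) && mineral_fraction >= 0 &&
                mineral_fraction <= 1, "'mineral_fraction' must be in [0, 1]")
  stop_unless(is_number(matrix_fraction) && matrix_fraction >= 0 &&
                matrix_fraction <= 1, "'matrix_fraction' must be in [0, 1]")
  stop_unless(mineral_fraction + matrix_fraction <= 1,
              "mineral_fraction + matrix_fraction must not exceed 1")
  stop_unless(is_count(nucleus_count), "'nucleus_count' must be a nonnegative integer")
  stop_unless(is_number(nucleus_radius) && nucleus_radius > 0,
              "'nucleus_radius' must be positive")
  stop_unless(is_number(noise_sd) && noise_sd >= 0, "'noise_sd' must be >= 0")
  stop_unless(is_count(abs(seed)), "'seed' must be an integer")
  structure(list(width = as.integer(width), height = as.integer(height),
                 mineral_fraction = mineral_fraction,
                 matrix_fraction = matrix_fraction,
                 nucleus_count = as.integer(nucleus_count),
                 nucleus_radius = nucleus_radius, noise_sd = noise_sd,
                 seed = as.integer(seed), stain = stain),
            class = "phantom_spec")
}

# Class palettes (R, G, B on 0-255). Chosen so that, without noise, each
# truth class satisfies exactly its own segmentation rule and the fibrin
# background satisfies none:
#   mineral  B/G < 0.85 and R/G > 1.02 (von Kossa brown)
#   matrix   210 < R < 225 on HE (eosin pink), R/G slightly > 1 elsewhere
#   nucleus  B/G > 1.05 (hematoxylin blue-purple / unstained nuclear zone)
#   background: von Kossa near-neutral gray (R/G <= 1, B/G >= 0.85);
#               HE pale pink with R >= 235, outside the eosin band.
phantom_palette <- function(stain) {
  if (stain == "VON_KOSSA") {
    list(background = c(200, 202, 200),
         matrix     = c(165, 150, 150),   # darker stained cell plasma
         mineral    = c(150, 120,  80),
         nucleus    = c(110, 100, 160))
  } else {
    list(background = c(240, 230, 232),
         matrix     = c(217, 170, 175),
         mineral    = c(150, 120,  80),
         nucleus    = c( 90,  80, 140))
  }
}

#' Generate a stained-section phantom with known ground truth
#'
#' Builds a synthetic section emulating the morphology seen around
#' mineralizing cells in fibrin gel: circular nuclei, an annular matrix
#' (stained plasma) halo around each nucleus, and mineral deposits radiating
#' outward from the cells, on a pale fibrin background. Pixels are assigned
#' to matrix and mineral in order of distance from the nearest nucleus
#' centre, so requested area fractions are met exactly up to rounding to a
#' whole pixel count. Per-channel Gaussian noise is added last.
#'
#' @param spec a [phantom_spec].
#' @return An object of class `stain_phantom`: a list with elements
#'   `image` ([stained_image]), `truth_mineral`, `truth_matrix`,
#'   `truth_nuclei` (each a [component_mask] of the image's dimensions) and
#'   `spec`.
#' @examples
#' ph <- generate_stain_phantom(phantom_spec(128, 128, mineral_fraction = 0.25,
#'                                           nucleus_count = 3, seed = 42))
#' area_fraction(ph$truth_mineral)
#' @export
generate_stain_phantom <- function(spec) {
  stop_unless(inherits(spec, "phantom_spec"), "'spec' must be a phantom_spec")
  h <- spec$height; w <- spec$width; npx <- h * w
  r <- spec$nucleus_radius
  pal <- phantom_palette(spec$stain)

  with_seed(spec$seed, {
    centers <- matrix(numeric(0), 0, 2)
    if (spec$nucleus_count > 0) {
      stop_unless(h >= 2 * r + 2 && w >= 2 * r + 2,
                  "raster too small for the requested nucleus radius")
      rows <- seq(ceiling(r + 1), floor(h - r))
      cols <- seq(ceiling(r + 1), floor(w - r))
      attempts <- 0L; max_attempts <- 200L * spec$nucleus_count
      while (nrow(centers) < spec$nucleus_count && attempts < max_attempts) {
        attempts <- attempts + 1L
        cand <- c(rows[sample.int(length(rows), 1L)],
                  cols[sample.int(length(cols), 1L)])
        if (nrow(centers) == 0L ||
            all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >
                (2 * r)^2))
          centers <- rbind(centers, cand)
      }
      if (nrow(centers) < spec$nucleus_count)
        stop(sprintf(paste0("could not place %d non-overlapping nuclei of ",
                            "radius %g in a %d x %d raster after %d attempts"),
                     spec$nucleus_count, r, h, w, max_attempts), call. = FALSE)
    }

    rr <- matrix(rep(seq_len(h), w), h)
    cc <- matrix(rep(seq_len(w), each = h), h)
    ref <- if (nrow(centers) > 0) centers else
      matrix(c((h + 1) / 2, (w + 1) / 2), 1)
    d2 <- matrix(Inf, h, w)
    for (i in seq_len(nrow(ref)))
      d2 <- pmin(d2, (rr - ref[i, 1])^2 + (cc - ref[i, 2])^2)

    nuclei <- if (nrow(centers) > 0) d2 <= r^2 else
      matrix(FALSE, h, w)

    n_mat <- round(spec$matrix_fraction * npx)
    n_min <- round(spec$mineral_fraction * npx)
    avail <- npx - sum(nuclei)
    if (n_mat + n_min > avail)
      stop(sprintf(paste0("requested fractions need %d pixels but only %d ",
                          "are free of nuclei"), n_mat + n_min, avail),
           call. = FALSE)

    ord <- order(as.vector(d2), seq_len(npx))       # stable, deterministic
    ord <- ord[!nuclei[ord]]
    mat_mask <- min_mask <- matrix(FALSE, h, w)
    if (n_mat > 0) mat_mask[ord[seq_len(n_mat)]] <- TRUE
    if (n_min > 0) min_mask[ord[n_mat + seq_len(n_min)]] <- TRUE

    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- matrix(pal$background[ch], h, w)
      plane[mat_mask] <- pal$matrix[ch]
      plane[min_mask] <- pal$mineral[ch]
      plane[nuclei]   <- pal$nucleus[ch]
      img[, , ch] <- plane
    }
    if (spec$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
      img <- pmin(pmax(img, 0), 255)
    }
    img <- round(img)

    structure(list(
      image = stained_image(img, stain = spec$stain),
      truth_mineral = component_mask(min_mask, "MINERAL", spec$stain),
      truth_matrix = component_mask(mat_mask, "MATRIX", spec$stain),
      truth_nuclei = component_mask(nuclei, "NUCLEUS", spec$stain),
      spec = spec), class = "stain_phantom")
  })
}

#' @export
print.stain_phantom <- function(x, ...) {
  cat(sprintf(paste0("<stain_phantom> %s %d x %d px; truth fractions: ",
                     "mineral %.2f%%, matrix %.2f%%, nuclei %.2f%%\n"),
              x$spec$stain, x$spec$height, x$spec$width,
              area_fraction(x$truth_mineral), area_fraction(x$truth_matrix),
              area_fraction(x$truth_nuclei)))
  invisible(x)
}

#' Specification of a synthetic gel-contraction experiment
#'
#' Describes one culture condition's long-axis length trajectory: a decay
#' from `initial_length` to `plateau_length` that reaches the plateau (to
#' within 1 percent of the initial gap) at `plateau_day`, measured in
#' `n_replicates` gels with additive Gaussian measurement error.
#'
#' @param initial_length initial long-axis length in mm (the casting mold
#'   is 10 mm long).
#' @param plateau_length asymptotic length in mm; must not exceed
#'   `initial_length`. Cell-laden gels contract to about 0.9--1 mm, cell-free
#'   gels only slightly.
#' @param plateau_day day at which the plateau is effectively reached
#'   (default 23).
#' @param n_replicates gels measured per day (default 4, quadruplicate).
#' @param measurement_sd standard deviation of the length measurement in mm
#'   (default 0.025, i.e. 25 micrometres for calibrated optical images).
#' @param seed integer seed.
#' @return An object of class `contraction_spec`.
#' @export
contraction_spec <- function(initial_length = 10, plateau_length,
                             plateau_day = 23, n_replicates = 4,
                             measurement_sd = 0.025, seed = 1) {
  stop_unless(is_number(initial_length) && initial_length > 0,
              "'initial_length' must be positive")
  stop_unless(is_number(plateau_length) && plateau_length > 0 &&
                plateau_length <= initial_length,
              "'plateau_length' must be in (0, initial_length]")
  stop_unless(is_number(plateau_day) && plateau_day > 0,
              "'plateau_day' must be positive")
  stop_unless(is_count(n_replicates) && n_replicates >= 1,
              "'n_replicates' must be a positive integer")
  stop_unless(is_number(measurement_sd) && measurement_sd >= 0,
              "'measurement_sd' must be >= 0")
  structure(list(initial_length = initial_length,
                 plateau_length = plateau_length,
                 plateau_day = plateau_day,
                 n_replicates = as.integer(n_replicates),
                 measurement_sd = measurement_sd,
                 seed = as.integer(seed)),
            class = "contraction_spec")
}

# Expected length on day d: plateau + gap * exp(-k d), with k fixed so the
# remaining gap is 1% of the initial gap at plateau_day.
contraction_mean_length <- function(spec, days) {
  gap <- spec$initial_length - spec$plateau_length
  if (gap == 0) return(rep(spec$initial_length, length(days)))
  k <- log(100) / spec$plateau_day
  spec$plateau_length + gap * exp(-k * days)
}

#' Generate synthetic gel-size time series for two culture conditions
#'
#' Produces replicate long-axis length measurements for a cell-laden and a
#' cell-free condition (or any two conditions) following a seeded
#' exponential decay to plateau with Gaussian measurement noise.
#'
#' @param spec_with_cells,spec_without_cells [contraction_spec] objects for
#'   the two conditions.
#' @param days measurement days (default every 3 days over 0--42).
#' @param labels condition labels attached to the two series.
#' @return A list of two [gel_size_series] objects, named by `labels`.
#' @examples
#' s <- generate_contraction_series(
#'   contraction_spec(10, 1, seed = 1),
#'   contraction_spec(10, 9.3, seed = 2))
#' length_contraction(s[[1]], day = 42)
#' @export
generate_contraction_series <- function(spec_with_cells, spec_without_cells,
                                        days = seq(0, 42, by = 3),
                                        labels = c("cells", "no cells")) {
  stop_unless(length(labels) == 2L, "'labels' must have two entries")
  out <- list(generate_gel_series(spec_with_cells, days, labels[1]),
              generate_gel_series(spec_without_cells, days, labels[2]))
  names(out) <- labels
  out
}

#' Generate one synthetic gel-size series
#'
#' @param spec a [contraction_spec].
#' @param days measurement days.
#' @param condition label for the series.
#' @return A [gel_size_series].
#' @export
generate_gel_series <- function(spec, days = seq(0, 42, by = 3),
                                condition = "gel") {
  stop_unless(inherits(spec, "contraction_spec"),
              "'spec' must be a contraction_spec")
  stop_unless(is.numeric(days) && length(days) >= 1 && !is.unsorted(days,
              strictly = TRUE), "'days' must be strictly increasing")
  mu <- contraction_mean_length(spec, days)
  with_seed(spec$seed, {
    n <- spec$n_replicates
    len <- rep(mu, each = n) +
      stats::rnorm(n * length(days), 0, spec$measurement_sd)
    gel_size_series(day = rep(days, each = n),
                    length_mm = len,
                    replicate = rep(seq_len(n), length(days)),
                    condition = condition)
  })
}

#' Specification of a mineralized-vesicle phantom
#'
#' Describes a synthetic cell-surface image: one circular cell region of
#' approximately `cell_area` pixels containing `vesicle_count` circular,
#' mutually non-adjacent mineralized vesicles with Gaussian-distributed
#' radii, strictly inside the cell.
#'
#' @param cell_area target cell area in pixels.
#' @param vesicle_count number of vesicles (>= 0).
#' @param vesicle_radius_mean,vesicle_radius_sd mean and sd of vesicle
#'   radius in pixels (radii are truncated below at 1).
#' @param seed integer seed.
#' @return An object of class `vesicle_phantom_spec`.
#' @export
vesicle_phantom_spec <- function(cell_area, vesicle_count,
                                 vesicle_radius_mean = 3,
                                 vesicle_radius_sd = 0, seed = 1) {
  stop_unless(is_number(cell_area) && cell_area > 0,
              "'cell_area' must be positive")
  stop_unless(is_count(vesicle_count), "'vesicle_count' must be >= 0")
  stop_unless(is_number(vesicle_radius_mean) && vesicle_radius_mean > 0,
              "'vesicle_radius_mean' must be positive")
  stop_unless(is_number(vesicle_radius_sd) && vesicle_radius_sd >= 0,
              "'vesicle_radius_sd' must be >= 0")
  structure(list(cell_area = cell_area,
                 vesicle_count = as.integer(vesicle_count),
                 vesicle_radius_mean = vesicle_radius_mean,
                 vesicle_radius_sd = vesicle_radius_sd,
                 seed = as.integer(seed)),
            class = "vesicle_phantom_spec")
}

#' Generate a vesicle phantom with known per-vesicle areas
#'
#' Places non-overlapping (and non-8-adjacent, so labelling recovers them
#' individually) circular vesicles strictly inside a circular cell mask.
#' Recorded truth sizes are the exact pixel counts of the placed disks.
#'
#' @param spec a [vesicle_phantom_spec].
#' @return An object of class `vesicle_phantom`: list with `cell_mask`,
#'   `vesicle_mask` (both [component_mask]), and `truth_sizes` (integer
#'   vector of per-vesicle pixel areas, in placement order).
#' @export
generate_vesicle_phantom <- function(spec) {
  stop_unless(inherits(spec, "vesicle_phantom_spec"),
              "'spec' must be a vesicle_phantom_spec")
  r_cell <- sqrt(spec$cell_area / pi)
  side <- 2L * ceiling(r_cell) + 5L
  ctr <- (side + 1) / 2
  rr <- matrix(rep(seq_len(side), side), side)
  cc <- matrix(rep(seq_len(side), each = side), side)
  d2c <- (rr - ctr)^2 + (cc - ctr)^2
  cell <- d2c <= r_cell^2

  ves <- matrix(FALSE, side, side)
  sizes <- integer(0)
  with_seed(spec$seed, {
    for (i in seq_len(spec$vesicle_count)) {
      placed <- FALSE
      for (attempt in seq_len(400L)) {
        rad <- max(1, stats::rnorm(1, spec$vesicle_radius_mean,
                                   spec$vesicle_radius_sd))
        if (rad + 1 >= r_cell) next
        # centre so the whole disk is strictly inside the cell
        ok_centres <- which(d2c <= (r_cell - rad - 1)^2 & cell)
        if (!length(ok_centres)) next
        pick <- ok_centres[sample.int(length(ok_centres), 1L)]
        pr <- rr[pick]; pc <- cc[pick]
        d2v <- (rr - pr)^2 + (cc - pc)^2
        disk <- d2v <= rad^2
        # keep a 1-px moat so distinct vesicles never touch, even diagonally
        if (any(ves[d2v <= (rad + 1.5)^2])) next
        ves[disk] <- TRUE
        sizes <- c(sizes, sum(disk))
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(paste0("could not place vesicle %d of %d (radius ~%g) ",
                            "inside the cell; reduce count or radius"),
                     i, spec$vesicle_count, spec$vesicle_radius_mean),
             call. = FALSE)
    }
  })
  structure(list(cell_mask = component_mask(cell, "GENERIC"),
                 vesicle_mask = component_mask(ves, "GENERIC"),
                 truth_sizes = sizes, spec = spec),
            class = "vesicle_phantom")
}
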