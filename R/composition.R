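#' Contraction-normalised scaling factor f
#'
#' The composition model scales stained-section area percentages into
#' construct volume percentages with a single factor
#' `f = (initial gel volume - gel volume at day 42) / 42`,
#' anchored on the day-42 endpoint of the contraction experiment.
#'
#' @param initial_volume initial gel volume (mm^3), > 0.
#' @param final_volume gel volume at day 42 (mm^3), > 0.
#' @param period normalisation period in days (default 42).
#' @return The scalar factor `f`. An expanding gel (negative `f`) is an
#'   error; a non-contracting gel returns `f = 0` with a warning, and is
#'   rejected downstream by [estimate_composition()].
#' @examples
#' compute_f(43, 1)   # 1
#' compute_f(64, 1)   # 1.5
#' @export
compute_f <- function(initial_volume, final_volume, period = 42) {
  stop_unless(is_number(initial_volume) && initial_volume > 0,
              "'initial_volume' must be positive")
  stop_unless(is_number(final_volume) && final_volume > 0,
              "'final_volume' must be positive")
  stop_unless(is_number(period) && period > 0, "'period' must be positive")
  if (initial_volume < final_volume)
    stop("gel expanded (final volume exceeds initial volume): f would be negative",
         call. = FALSE)
  f <- (initial_volume - final_volume) / period
  if (f == 0)
    warning("gel did not contract: f = 0 cannot normalise compositions",
            call. = FALSE)
  f
}

#' Volume of a cylindrical gel
#'
#' The gel is cast in a cylindrical silicone mold (10 mm long, 6 mm in
#' diameter), so its initial volume is that of a cylinder.
#'
#' @param length cylinder length (mm).
#' @param diameter cylinder diameter (mm).
#' @return Volume in mm^3 (`pi * (d/2)^2 * length`).
#' @examples
#' cylinder_volume(10, 6)  # 90 * pi
#' @export
cylinder_volume <- function(length, diameter) {
  stop_unless(is_number(length) && length > 0, "'length' must be positive")
  stop_unless(is_number(diameter) && diameter > 0, "'diameter' must be positive")
  pi * (diameter / 2)^2 * length
}

#' Volume of a spheroidal gel
#'
#' Contracted cell-laden gels become spheroidal; the volume is computed as
#' a prolate spheroid from the measured long and short axes
#' (`pi/6 * long * short^2`).
#'
#' @param long_axis,short_axis full axis lengths (mm).
#' @return Volume in mm^3. Equal axes give the sphere volume.
#' @examples
#' spheroid_volume(0.9, 0.9)  # (4/3) * pi * 0.45^3
#' @export
spheroid_volume <- function(long_axis, short_axis) {
  stop_unless(is_number(long_axis) && long_axis > 0, "'long_axis' must be positive")
  stop_unless(is_number(short_axis) && short_axis > 0,
              "'short_axis' must be positive")
  stop_unless(short_axis <= long_axis,
              "'short_axis' must not exceed 'long_axis'")
  (pi / 6) * long_axis * short_axis^2
}

#' Estimate the four-component volume composition at one timepoint
#'
#' Converts measured area percentages into volume percentages:
#' `Vx = X / f` (mineral), `Vy = Y / f` (matrix), `Vz = Z / f` (cell, with
#' the cell share fixed at 1.5 percent), and the residual fibrin gel as
#' `100 - Vx - Vy - Vz`. Components are kept on the percent scale
#' throughout so every accepted estimate closes to 100 exactly.
#'
#' @param mineral_x mineral area percentage X from von Kossa segmentation.
#' @param matrix_y matrix area percentage Y from HE segmentation.
#' @param f scaling factor from [compute_f()]; must be positive.
#' @param day optional culture day attached to the estimate.
#' @param cell_z fixed cell share in percent (default 1.5, from prior
#'   observations that cell number saturates within days of seeding and is
#'   then maintained). Overriding it is allowed but reported.
#' @return An object of class `composition_estimate`: list with `Vx`, `Vy`,
#'   `Vz`, `fibrin` (percent, summing to 100) and `day`.
#' @examples
#' estimate_composition(46.5, 57, f = 1.5, day = 42)
#' @export
estimate_composition <- function(mineral_x, matrix_y, f, day = NA,
                                 cell_z = 1.5) {
  stop_unless(is_number(mineral_x) && mineral_x >= 0 && mineral_x <= 100,
              "'mineral_x' must be a percentage in [0, 100]")
  stop_unless(is_number(matrix_y) && matrix_y >= 0 && matrix_y <= 100,
              "'matrix_y' must be a percentage in [0, 100]")
  stop_unless(is_number(f), "'f' must be a number")
  if (f <= 0)
    stop("scaling factor f must be positive (gel must have contracted)",
         call. = FALSE)
  stop_unless(is_number(cell_z) && cell_z > 0, "'cell_z' must be positive")
  if (!identical(cell_z, 1.5))
    message(sprintf("cell share overridden: Z = %g%% (default 1.5%%)", cell_z))
  vx <- mineral_x / f
  vy <- matrix_y / f
  vz <- cell_z / f
  total <- vx + vy + vz
  if (total > 100)
    stop(sprintf(paste0("infeasible composition: Vx + Vy + Vz = %.4f%% ",
                        "exceeds 100%% (X = %g, Y = %g, f = %g)"),
                 total, mineral_x, matrix_y, f), call. = FALSE)
  structure(list(Vx = vx, Vy = vy, Vz = vz, fibrin = 100 - total,
                 day = day, f = f),
            class = "composition_estimate")
}

#' @export
print.composition_estimate <- function(x, digits = 2, ...) {
  hdr <- if (is.na(x$day)) "<composition_estimate>" else
    sprintf("<composition_estimate> day %s", format(x$day))
  cat(hdr, "\n")
  cat(sprintf("  mineral %.*f%%  matrix %.*f%%  cell %.*f%%  fibrin %.*f%%  (f = %g)\n",
              digits, x$Vx, digits, x$Vy, digits, x$Vz, digits, x$fibrin, x$f))
  invisible(x)
}

#' @export
as.data.frame.composition_estimate <- function(x, ...) {
  data.frame(day = x$day, mineral = x$Vx, matrix = x$Vy, cell = x$Vz,
             fibrin = x$fibrin)
}

#' Composition trajectory over culture days
#'
#' Applies [estimate_composition()] to per-day area measurements using one
#' shared scaling factor computed from the initial and day-42 gel volumes.
#' Anchoring `f` on day 42 for all timepoints is the literal reading of the
#' normalisation definition; a per-day factor
#' `f_d = (initial volume - volume at day d) / d` is available behind
#' `per_day_f = TRUE`, in which case `areas` must carry a `volume` column.
#'
#' @param areas data frame with columns `day`, `mineral_x`, `matrix_y`
#'   (area percentages), optionally `volume` (mm^3, used only with
#'   `per_day_f = TRUE`).
#' @param initial_volume,final_volume gel volumes (mm^3) feeding
#'   [compute_f()].
#' @param cell_z fixed cell share in percent.
#' @param per_day_f use a per-day scaling factor instead of the shared
#'   day-42-anchored one (off by default).
#' @return An object of class `composition_trajectory`: a data frame with
#'   columns `day`, `mineral`, `matrix`, `cell`, `fibrin` (volume percent),
#'   ordered by day, with the factor(s) in attribute `f`.
#' @examples
#' areas <- data.frame(day = c(28, 35, 42),
#'                     mineral_x = c(0, 15, 46.5),
#'                     matrix_y = c(9, 37.5, 57))
#' composition_trajectory(areas, initial_volume = 64, final_volume = 1)
#' @export
composition_trajectory <- function(areas, initial_volume, final_volume,
                                   cell_z = 1.5, per_day_f = FALSE) {
  stop_unless(is.data.frame(areas) && nrow(areas) >= 1,
              "'areas' must be a data frame with at least one timepoint")
  stop_unless(all(c("day", "mineral_x", "matrix_y") %in% names(areas)),
              "'areas' needs columns day, mineral_x, matrix_y")
  areas <- areas[order(areas$day), , drop = FALSE]
  if (per_day_f) {
    stop_unless("volume" %in% names(areas),
                "per-day f needs a 'volume' column in 'areas'")
    stop_unless(all(areas$day > 0), "per-day f needs strictly positive days")
    fs <- vapply(seq_len(nrow(areas)), function(i)
      compute_f(initial_volume, areas$volume[i], period = areas$day[i]),
      numeric(1))
  } else {
    fs <- rep(compute_f(initial_volume, final_volume), nrow(areas))
  }
  est <- lapply(seq_len(nrow(areas)), function(i)
    estimate_composition(areas$mineral_x[i], areas$matrix_y[i], fs[i],
                         day = areas$day[i], cell_z = cell_z))
  out <- do.call(rbind, lapply(est, as.data.frame))
  rownames(out) <- NULL
  structure(out, f = fs, class = c("composition_trajectory", "data.frame"))
}

#' @export
plot.composition_trajectory <- function(x, ...) {
  comp <- t(as.matrix(x[, c("mineral", "matrix", "cell", "fibrin")]))
  cols <- c("saddlebrown", "palevioletred2", "slateblue3", "wheat")
  graphics::barplot(comp, names.arg = x$day, col = cols, border = NA,
                    xlab = "culture day", ylab = "volume composition (%)",
                    ...)
  graphics::legend("topright", rev(rownames(comp)), fill = rev(cols),
                   bg = "white", cex = 0.8)
  invisible(x)
}
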