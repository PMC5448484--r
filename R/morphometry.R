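#' Label connected vesicle regions in a binary mask
#'
#' Connected-component labelling of a binary mask under 8-connectivity
#' (diagonal neighbours connect; 4-connectivity available). Components
#' smaller than `min_size` are discarded and their count reported.
#' Labels are assigned in raster (column-major) order of each component's
#' first pixel, so labelling is deterministic.
#'
#' @param mask a [component_mask] or logical matrix.
#' @param min_size minimum component area in pixels (default 1, no
#'   filtering).
#' @param connectivity 8 (default) or 4.
#' @return An object of class `vesicle_labels`: list with `labels`
#'   (integer matrix, 0 = background), `sizes` (integer vector of component
#'   areas, index = label), `n` (number of components) and `discarded`
#'   (components removed by `min_size`).
#' @examples
#' m <- matrix(FALSE, 5, 5); m[1:2, 1:2] <- TRUE; m[4:5, 4:5] <- TRUE
#' label_vesicles(m)$sizes
#' @export
label_vesicles <- function(mask, min_size = 1, connectivity = 8) {
  m <- as_mask_matrix(mask)
  stop_unless(is_number(min_size) && min_size >= 1, "'min_size' must be >= 1")
  stop_unless(connectivity %in% c(4, 8), "'connectivity' must be 4 or 8")
  h <- nrow(m); w <- ncol(m)
  labels <- matrix(0L, h, w)
  idx <- which(m)
  if (!length(idx))
    return(structure(list(labels = labels, sizes = integer(0), n = 0L,
                          discarded = 0L), class = "vesicle_labels"))

  vid <- match(seq_len(h * w), idx)           # pixel -> vertex id
  ri <- (idx - 1L) %% h + 1L                  # row of each foreground pixel
  ci <- (idx - 1L) %/% h + 1L                 # column
  # column-major neighbour offsets: down, right (+ diagonals for 8-conn)
  offs <- list(c(1L, 1L, 0L), c(h, 0L, 1L))
  if (connectivity == 8)
    offs <- c(offs, list(c(h + 1L, 1L, 1L), c(h - 1L, -1L, 1L)))
  ea <- eb <- integer(0)
  for (o in offs) {
    keep <- ri + o[2] >= 1L & ri + o[2] <= h & ci + o[3] <= w
    nb <- idx[keep] + o[1]
    src <- idx[keep]
    hit <- !is.na(vid[nb])
    ea <- c(ea, vid[src[hit]])
    eb <- c(eb, vid[nb[hit]])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(ea))
    g <- igraph::add_edges(g, rbind(ea, eb))
  memb <- igraph::components(g)$membership
  # renumber so labels follow raster order of first appearance
  first <- match(unique(memb), memb)
  relab <- integer(max(memb))
  relab[memb[sort(first)]] <- seq_along(first)
  lab <- relab[memb]
  sizes <- tabulate(lab)
  discarded <- 0L
  if (min_size > 1) {
    small <- which(sizes < min_size)
    if (length(small)) {
      discarded <- length(small)
      lab[lab %in% small] <- 0L
      keepl <- sort(unique(lab[lab > 0L]))
      lab[lab > 0L] <- match(lab[lab > 0L], keepl)
      sizes <- tabulate(lab[lab > 0L])
    }
  }
  labels[idx] <- lab
  structure(list(labels = labels, sizes = as.integer(sizes),
                 n = length(sizes), discarded = discarded),
            class = "vesicle_labels")
}

#' @export
print.vesicle_labels <- function(x, ...) {
  cat(sprintf("<vesicle_labels> %d region(s)", x$n))
  if (x$n > 0)
    cat(sprintf(", areas %s px", paste(x$sizes, collapse = ", ")))
  if (x$discarded > 0)
    cat(sprintf(" (%d below min_size discarded)", x$discarded))
  cat("\n")
  invisible(x)
}

#' Per-cell mineralized-vesicle statistics
#'
#' Computes, for one segmented cell, the area ratio occupied by mineralized
#' vesicles (`100 * |vesicles within cell| / |cell|`) and the mean vesicle
#' size from connected-component labelling. Vesicle pixels outside the cell
#' mask are clipped to it (the statistic is defined on the single cell);
#' the clipped fraction is reported as a warning when nonzero.
#'
#' @param cell_mask logical matrix or [component_mask] of the cell region;
#'   must be non-empty.
#' @param vesicle_mask logical matrix or [component_mask] of vesicle pixels,
#'   same dimensions.
#' @param pixel_size optional physical pixel edge length; when given, sizes
#'   are also reported in squared physical units.
#' @param min_size,connectivity passed to [label_vesicles()].
#' @return An object of class `vesicle_stats`: list with `area_ratio`
#'   (percent), `count`, `sizes` (per-vesicle pixel areas), `mean_size`
#'   (`NA` with `mean_defined = FALSE` when there are no vesicles),
#'   `mean_size_physical` (when `pixel_size` given) and `clipped_fraction`.
#' @examples
#' cell <- matrix(TRUE, 20, 20)
#' ves <- matrix(FALSE, 20, 20); ves[3:6, 3:6] <- TRUE
#' vesicle_stats(cell, ves)
#' @export
vesicle_stats <- function(cell_mask, vesicle_mask, pixel_size = NULL,
                          min_size = 1, connectivity = 8) {
  cm <- as_mask_matrix(cell_mask)
  vm <- as_mask_matrix(vesicle_mask)
  stop_unless(all(dim(cm) == dim(vm)),
              "cell and vesicle masks must have the same dimensions")
  cell_area <- sum(cm)
  stop_unless(cell_area > 0, "empty cell mask: vesicle statistics undefined")
  n_out <- sum(vm & !cm)
  clipped <- if (sum(vm) > 0) n_out / sum(vm) else 0
  if (n_out > 0)
    warning(sprintf("%.1f%% of vesicle pixels fall outside the cell: clipped",
                    100 * clipped), call. = FALSE)
  vin <- vm & cm
  lab <- label_vesicles(vin, min_size = min_size, connectivity = connectivity)
  sizes <- lab$sizes
  defined <- lab$n > 0
  mean_px <- if (defined) mean(sizes) else NA_real_
  out <- list(area_ratio = 100 * sum(vin) / cell_area,
              count = lab$n,
              sizes = sizes,
              mean_size = mean_px,
              mean_defined = defined,
              clipped_fraction = clipped,
              pixel_size = pixel_size)
  if (!is.null(pixel_size)) {
    stop_unless(is_number(pixel_size) && pixel_size > 0,
                "'pixel_size' must be positive")
    out$mean_size_physical <- mean_px * pixel_size^2
  }
  structure(out, class = "vesicle_stats")
}

#' @export
print.vesicle_stats <- function(x, ...) {
  cat(sprintf("<vesicle_stats> %d vesicle(s), area ratio %.2f%%", x$count,
              x$area_ratio))
  if (x$mean_defined) {
    cat(sprintf(", mean size %.1f px", x$mean_size))
    if (!is.null(x$pixel_size))
      cat(sprintf(" (%.3g physical units^2)", x$mean_size_physical))
  } else {
    cat(", mean size undefined (no vesicles)")
  }
  cat("\n")
  invisible(x)
}
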