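#' Gel-size time series for one culture condition
#'
#' Long-axis length measurements of replicate gels over culture days.
#'
#' @param day numeric vector of day indices (one entry per measurement).
#' @param length_mm long-axis lengths in mm, all positive.
#' @param replicate optional replicate identifiers; defaults to numbering
#'   measurements within each day.
#' @param condition label for the culture condition (e.g. a cell density
#'   or `"no cells"`).
#' @return An object of class `gel_size_series`: a data frame with columns
#'   `day`, `replicate`, `length_mm`, `condition`, sorted by day.
#' @examples
#' s <- gel_size_series(day = rep(c(0, 7), each = 2),
#'                      length_mm = c(10, 10.1, 5.2, 5.0))
#' length_contraction(s, day = 7)
#' @export
gel_size_series <- function(day, length_mm, replicate = NULL,
                            condition = "gel") {
  stop_unless(is.numeric(day) && length(day) >= 1, "'day' must be numeric")
  stop_unless(is.numeric(length_mm) && length(length_mm) == length(day),
              "'length_mm' must match 'day' in length")
  stop_unless(all(is.finite(length_mm)) && all(length_mm > 0),
              "lengths must be positive")
  if (is.null(replicate)) {
    replicate <- stats::ave(day, day, FUN = seq_along)
  }
  stop_unless(length(replicate) == length(day),
              "'replicate' must match 'day' in length")
  df <- data.frame(day = day, replicate = replicate, length_mm = length_mm,
                   condition = condition)
  df <- df[order(df$day, df$replicate), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("gel_size_series", "data.frame"))
}

#' @export
print.gel_size_series <- function(x, ...) {
  days <- unique(x$day)
  cat(sprintf("<gel_size_series> '%s': %d day(s), %d measurement(s)\n",
              x$condition[1], length(days), nrow(x)))
  m <- tapply(x$length_mm, x$day, mean)
  cat("  mean length (mm):",
      paste(sprintf("d%g=%.2f", as.numeric(names(m)), m), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
plot.gel_size_series <- function(x, ...) {
  m <- tapply(x$length_mm, x$day, mean)
  d <- as.numeric(names(m))
  graphics::plot(x$day, x$length_mm, pch = 1, col = "gray50",
                 xlab = "culture day", ylab = "long-axis length (mm)",
                 main = x$condition[1], ...)
  graphics::lines(d, m, type = "b", pch = 16)
  invisible(x)
}

series_lengths <- function(series, day) {
  series$length_mm[series$day == day]
}

#' Length contraction of a gel at a given day
#'
#' Percent reduction of the mean long-axis length relative to the first
#' measured day: `100 * (mean initial - mean at day) / mean initial`.
#' Scale-free: rescaling all lengths leaves it unchanged.
#'
#' @param series a [gel_size_series].
#' @param day a day present in the series.
#' @return Contraction percentage.
#' @examples
#' s <- gel_size_series(day = c(0, 23), length_mm = c(10, 1))
#' length_contraction(s, 23)  # 90
#' @export
length_contraction <- function(series, day) {
  stop_unless(inherits(series, "gel_size_series"),
              "'series' must be a gel_size_series")
  stop_unless(day %in% series$day,
              sprintf("day %s not present in series", format(day)))
  d0 <- min(series$day)
  init <- mean(series_lengths(series, d0))
  100 * (init - mean(series_lengths(series, day))) / init
}

# Two-sample p-value robust to zero-variance groups (t.test() errors on
# essentially-constant data): equal constant groups are maximally
# non-significant, distinct constant groups maximally significant.
two_sample_p <- function(x, y, var_equal = TRUE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Per-day comparison of two gel-size series
#'
#' Two-sample Student's t test (pooled variance) of the replicate lengths
#' of two conditions on every shared day, flagged for significance at
#' `alpha` (default 0.01, i.e. a 99 percent confidence level). Days with
#' fewer than two replicates in either condition are skipped with a
#' warning. No multiple-testing correction is applied across days: each
#' day is reported on its own, as in the per-day significance stars of the
#' original contraction figures.
#'
#' @param a,b [gel_size_series] objects for the two conditions.
#' @param alpha significance level (default 0.01).
#' @param var_equal pooled-variance Student test when `TRUE` (default);
#'   `FALSE` gives the Welch variant.
#' @return A data frame with columns `day`, `p_value`, `significant`
#'   (classed `condition_comparison`); zero rows if no shared day is
#'   testable.
#' @export
compare_conditions <- function(a, b, alpha = 0.01, var_equal = TRUE) {
  stop_unless(inherits(a, "gel_size_series") &&
                inherits(b, "gel_size_series"),
              "'a' and 'b' must be gel_size_series")
  stop_unless(is_number(alpha) && alpha > 0 && alpha < 1,
              "'alpha' must be in (0, 1)")
  shared <- sort(intersect(unique(a$day), unique(b$day)))
  days <- p <- numeric(0)
  skipped <- numeric(0)
  for (d in shared) {
    x <- series_lengths(a, d); y <- series_lengths(b, d)
    if (length(x) < 2 || length(y) < 2) {
      skipped <- c(skipped, d)
      next
    }
    days <- c(days, d)
    p <- c(p, two_sample_p(x, y, var_equal))
  }
  if (length(skipped))
    warning(sprintf("day(s) %s skipped: fewer than 2 replicates per condition",
                    paste(skipped, collapse = ", ")), call. = FALSE)
  structure(data.frame(day = days, p_value = p, significant = p < alpha),
            alpha = alpha,
            conditions = c(a$condition[1], b$condition[1]),
            class = c("condition_comparison", "data.frame"))
}

#' Detect the contraction plateau of a gel-size series
#'
#' Operationalises "no significant size difference in further culture" as:
#' compare replicate lengths of every pair of consecutive measured days
#' with a Student's t test; the plateau day is the day following the last
#' significant pair. A series with no significant pair plateaus at its
#' first day; a series whose final pair is still significant has not
#' plateaued within the observation window and yields `NA`.
#'
#' @param series a [gel_size_series] with at least two days.
#' @param alpha significance level (default 0.01).
#' @param var_equal pooled-variance Student test when `TRUE` (default).
#' @return The plateau day, or `NA` if the series is still contracting at
#'   its end or no day has the two replicates the test needs.
#' @export
detect_plateau <- function(series, alpha = 0.01, var_equal = TRUE) {
  stop_unless(inherits(series, "gel_size_series"),
              "'series' must be a gel_size_series")
  days <- sort(unique(series$day))
  stop_unless(length(days) >= 2, "need at least two measured days")
  reps <- lapply(days, function(d) series_lengths(series, d))
  if (any(lengths(reps) < 2)) {
    warning("fewer than 2 replicates on some day(s): plateau undetermined",
            call. = FALSE)
    return(NA_real_)
  }
  sig <- vapply(seq_len(length(days) - 1), function(j)
    two_sample_p(reps[[j]], reps[[j + 1]], var_equal) < alpha, logical(1))
  if (!any(sig)) return(days[1])
  last <- max(which(sig))
  if (last == length(days) - 1) return(NA_real_)
  days[last + 1]
}

#' Median recovered plateau day over replicated synthetic experiments
#'
#' A single noisy series gives a noisy plateau estimate; the stable summary
#' is the median of [detect_plateau()] over independently seeded replicate
#' experiments generated from the same [contraction_spec].
#'
#' @param spec a [contraction_spec]; its seed seeds the whole ensemble.
#' @param days measurement days passed to [generate_gel_series()].
#' @param n_series number of replicate experiments (default 15).
#' @param alpha significance level for [detect_plateau()].
#' @return Median plateau day (`NA` values, i.e. series still contracting,
#'   enter the median as `Inf` and a result of `Inf` means most series never
#'   plateaued).
#' @export
recover_plateau_day <- function(spec, days = seq(0, 42, by = 3),
                                n_series = 15, alpha = 0.01) {
  stop_unless(inherits(spec, "contraction_spec"),
              "'spec' must be a contraction_spec")
  seeds <- derive_seeds(spec$seed, n_series)
  est <- vapply(seeds, function(s) {
    sp <- spec
    sp$seed <- s
    d <- detect_plateau(generate_gel_series(sp, days), alpha = alpha)
    if (is.na(d)) Inf else d
  }, numeric(1))
  stats::median(est)
}
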