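test_that("labelling handles trivial masks", {
  expect_equal(label_vesicles(matrix(FALSE, 5, 5))$n, 0)
  m <- matrix(FALSE, 7, 7)
  m[1:2, 1:2] <- TRUE
  m[5:6, 5:6] <- TRUE
  lab <- label_vesicles(m)
  expect_equal(lab$n, 2)
  expect_equal(lab$sizes, c(4L, 4L))
  expect_equal(sum(lab$labels > 0), 8)
  # diagonal touch merges under 8-connectivity, splits under 4
  d <- matrix(FALSE, 4, 4); d[1, 1] <- d[2, 2] <- TRUE
  expect_equal(label_vesicles(d, connectivity = 8)$n, 1)
  expect_equal(label_vesicles(d, connectivity = 4)$n, 2)
  # min_size filtering discards and reports
  m2 <- m; m2[7, 1] <- TRUE; m2[1, 7] <- TRUE  # two isolated pixels
  lab2 <- label_vesicles(m2, min_size = 2)
  expect_equal(lab2$discarded, 2)
  expect_equal(lab2$n, 2)
})

test_that("labelling equals a flood-fill oracle on random masks", {
  for (seed in 1:100) {
    set.seed(seed)
    m <- matrix(runif(32 * 32) < 0.35, 32, 32)
    expect_identical(label_vesicles(m)$labels, flood_fill_label(m, 8))
    if (seed <= 20)
      expect_identical(label_vesicles(m, connectivity = 4)$labels,
                       flood_fill_label(m, 4))
  }
})

test_that("vesicle statistics follow their definitions", {
  cell <- matrix(FALSE, 40, 40); cell[4:37, 4:37] <- TRUE  # |cell| known
  ves <- matrix(FALSE, 40, 40); ves[10:19, 10:19] <- TRUE  # one 100 px vesicle
  cell_area <- sum(cell)
  st <- vesicle_stats(cell, ves)
  expect_equal(st$area_ratio, 100 * 100 / cell_area)
  expect_equal(st$count, 1)
  expect_equal(st$mean_size, 100)
  expect_true(st$mean_defined)
  # physical units
  stp <- vesicle_stats(cell, ves, pixel_size = 0.5)
  expect_equal(stp$mean_size_physical, 100 * 0.25)
  # no vesicles: ratio 0, undefined mean flagged explicitly
  st0 <- vesicle_stats(cell, matrix(FALSE, 40, 40))
  expect_equal(st0$area_ratio, 0)
  expect_false(st0$mean_defined)
  expect_true(is.na(st0$mean_size))
  # vesicle pixels outside the cell are clipped with a warning
  out <- ves; out[1:2, 1:2] <- TRUE
  expect_warning(stc <- vesicle_stats(cell, out), "clipped")
  expect_equal(stc$area_ratio, st$area_ratio)
  expect_gt(stc$clipped_fraction, 0)
  # empty cell is rejected
  expect_error(vesicle_stats(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)),
               "empty cell")
})

test_that("phantom truth sizes are reproduced exactly", {
  vp <- generate_vesicle_phantom(vesicle_phantom_spec(6000, 5, 5, 1.5,
                                                      seed = 12))
  st <- vesicle_stats(vp$cell_mask, vp$vesicle_mask)
  expect_equal(sort(st$sizes), sort(vp$truth_sizes))
  expect_equal(st$mean_size, mean(vp$truth_sizes))
  expect_equal(st$area_ratio,
               100 * sum(vp$truth_sizes) / sum(vp$cell_mask))
})

test_that("area ratio is invariant under translation and 90-degree rotation", {
  vp <- generate_vesicle_phantom(vesicle_phantom_spec(3000, 4, 4, 0.5,
                                                      seed = 9))
  cell <- as_logical_matrix(vp$cell_mask)
  ves <- as_logical_matrix(vp$vesicle_mask)
  base <- vesicle_stats(cell, ves)
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  r <- vesicle_stats(rot90(cell), rot90(ves))
  expect_equal(r$area_ratio, base$area_ratio)
  expect_equal(sort(r$sizes), sort(base$sizes))
  shift <- function(m) {
    out <- matrix(FALSE, nrow(m) + 3, ncol(m) + 5)
    out[4:(nrow(m) + 3), 6:(ncol(m) + 5)] <- m
    out
  }
  s <- vesicle_stats(shift(cell), shift(ves))
  expect_equal(s$area_ratio, base$area_ratio)
})

test_that("labelled sizes sum to the in-cell vesicle area", {
  set.seed(17)
  for (i in 1:10) {
    cell <- matrix(runif(40 * 40) < 0.9, 40, 40)
    if (!any(cell)) next
    ves <- matrix(runif(40 * 40) < 0.2, 40, 40)
    st <- suppressWarnings(vesicle_stats(cell, ves))
    expect_equal(sum(st$sizes), sum(ves & cell))
  }
})

test_that("richer vesicle phantoms give larger morphometry statistics", {
  # emulates the culture-period series: more and larger vesicles per cell
  specs <- list(vesicle_phantom_spec(8000, 4, 2.5, 0.3, seed = 41),
                vesicle_phantom_spec(8000, 9, 3.5, 0.3, seed = 42),
                vesicle_phantom_spec(8000, 15, 4.5, 0.3, seed = 43))
  st <- lapply(specs, function(s) {
    vp <- generate_vesicle_phantom(s)
    vesicle_stats(vp$cell_mask, vp$vesicle_mask)
  })
  ratios <- vapply(st, `[[`, numeric(1), "area_ratio")
  means <- vapply(st, `[[`, numeric(1), "mean_size")
  expect_true(all(diff(ratios) > 0))
  expect_true(all(diff(means) > 0))
})
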