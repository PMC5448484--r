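test_that("empty phantom is pure background with empty truth masks", {
  for (stain in c("VON_KOSSA", "HE")) {
    ph <- generate_stain_phantom(phantom_spec(32, 32, seed = 1, stain = stain))
    expect_equal(sum(ph$truth_mineral), 0)
    expect_equal(sum(ph$truth_matrix), 0)
    expect_equal(sum(ph$truth_nuclei), 0)
    # a single background colour across the raster
    expect_equal(length(unique(as.vector(ph$image$pixels[, , 1]))), 1L)
    expect_equal(length(unique(as.vector(ph$image$pixels[, , 3]))), 1L)
  }
})

test_that("requested fractions are realized to within pixel quantization", {
  cases <- expand.grid(mf = c(0, 0.1, 0.25, 0.465), yf = c(0, 0.2, 0.4),
                       n = c(0, 4))
  for (i in seq_len(nrow(cases))) {
    ph <- generate_stain_phantom(phantom_spec(
      256, 256, mineral_fraction = cases$mf[i],
      matrix_fraction = cases$yf[i], nucleus_count = cases$n[i],
      seed = 100 + i))
    expect_lt(abs(area_fraction(ph$truth_mineral) - 100 * cases$mf[i]), 0.5)
    expect_lt(abs(area_fraction(ph$truth_matrix) - 100 * cases$yf[i]), 0.5)
    expect_equal(dim(ph$truth_mineral), dim(ph$image))
  }
})

test_that("identical specs produce bit-identical phantoms and leave RNG alone", {
  spec <- phantom_spec(64, 64, mineral_fraction = 0.3, matrix_fraction = 0.1,
                       nucleus_count = 3, noise_sd = 4, seed = 77)
  set.seed(999)
  before <- .Random.seed
  a <- generate_stain_phantom(spec)
  expect_identical(.Random.seed, before)  # caller RNG state untouched
  b <- generate_stain_phantom(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(unclass(a$truth_nuclei), unclass(b$truth_nuclei))
  # a different seed moves the nuclei
  spec2 <- phantom_spec(64, 64, mineral_fraction = 0.3,
                        matrix_fraction = 0.1, nucleus_count = 3,
                        noise_sd = 4, seed = 78)
  expect_false(identical(generate_stain_phantom(spec2)$image$pixels,
                         a$image$pixels))
})

test_that("noise-free phantoms are recovered exactly by their own stain rules", {
  vk <- generate_stain_phantom(phantom_spec(128, 128, mineral_fraction = 0.25,
                                            matrix_fraction = 0.15,
                                            nucleus_count = 4, seed = 5))
  expect_identical(as_logical_matrix(segment_mineral(vk$image)),
                   as_logical_matrix(vk$truth_mineral))
  expect_identical(as_logical_matrix(segment_nuclei(vk$image)),
                   as_logical_matrix(vk$truth_nuclei))
  he <- generate_stain_phantom(phantom_spec(128, 128, matrix_fraction = 0.4,
                                            nucleus_count = 4, seed = 6,
                                            stain = "HE"))
  expect_identical(as_logical_matrix(segment_matrix(he$image)),
                   as_logical_matrix(he$truth_matrix))
  expect_identical(as_logical_matrix(segment_nuclei(he$image)),
                   as_logical_matrix(he$truth_nuclei))
})

test_that("infeasible phantom specs fail informatively", {
  expect_error(phantom_spec(64, 64, mineral_fraction = 0.7,
                            matrix_fraction = 0.5),
               "must not exceed 1")
  expect_error(phantom_spec(0, 64), "positive integers")
  expect_error(phantom_spec(64, 64, noise_sd = -1), "noise_sd")
  # too many nuclei to place without overlap
  expect_error(generate_stain_phantom(
    phantom_spec(40, 40, nucleus_count = 30, nucleus_radius = 6, seed = 1)),
    "non-overlapping nuclei")
  # fractions feasible alone but not once nuclei claim pixels
  expect_error(generate_stain_phantom(
    phantom_spec(64, 64, mineral_fraction = 0.6, matrix_fraction = 0.4,
                 nucleus_count = 2, seed = 1)),
    "free of nuclei")
})

test_that("contraction generator matches its spec arithmetic", {
  # no contraction, no noise: constant series
  s0 <- generate_gel_series(contraction_spec(10, 10, measurement_sd = 0,
                                             seed = 1))
  expect_true(all(s0$length_mm == 10))
  expect_equal(length_contraction(s0, max(s0$day)), 0)
  # noise-free decays hit the stated terminal contraction
  s90 <- generate_gel_series(contraction_spec(10, 1, measurement_sd = 0,
                                              seed = 1))
  expect_equal(length_contraction(s90, 42), 90, tolerance = 1e-3)
  s7 <- generate_gel_series(contraction_spec(10, 9.3, measurement_sd = 0,
                                             seed = 1))
  expect_equal(length_contraction(s7, 42), 7, tolerance = 1e-3)
  # expected lengths are monotone non-increasing
  m <- tapply(s90$length_mm, s90$day, mean)
  expect_true(all(diff(m) <= 0))
  # paired generator returns labelled series, deterministically
  pair <- generate_contraction_series(contraction_spec(10, 1, seed = 2),
                                      contraction_spec(10, 9.3, seed = 3))
  expect_named(pair, c("cells", "no cells"))
  pair2 <- generate_contraction_series(contraction_spec(10, 1, seed = 2),
                                       contraction_spec(10, 9.3, seed = 3))
  expect_identical(pair[[1]]$length_mm, pair2[[1]]$length_mm)
})

test_that("vesicle phantoms record exact truth sizes", {
  # zero vesicles
  vp0 <- generate_vesicle_phantom(vesicle_phantom_spec(1000, 0, seed = 1))
  expect_equal(sum(vp0$vesicle_mask), 0)
  expect_length(vp0$truth_sizes, 0)
  # truth sizes equal labelled-region areas exactly, vesicles inside cell
  vp <- generate_vesicle_phantom(vesicle_phantom_spec(4000, 6, 4, 1,
                                                      seed = 21))
  expect_true(all(vp$vesicle_mask[!vp$cell_mask] == FALSE))
  lab <- label_vesicles(vp$vesicle_mask)
  expect_equal(lab$n, 6)
  expect_equal(sort(lab$sizes), sort(vp$truth_sizes))
  # determinism
  vp2 <- generate_vesicle_phantom(vesicle_phantom_spec(4000, 6, 4, 1,
                                                       seed = 21))
  expect_identical(unclass(vp$vesicle_mask), unclass(vp2$vesicle_mask))
  # infeasible placement fails informatively
  expect_error(generate_vesicle_phantom(
    vesicle_phantom_spec(200, 50, 4, 0, seed = 1)), "could not place")
})
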