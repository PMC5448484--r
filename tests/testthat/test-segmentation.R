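test_that("mineral rule applies the ratio thresholds strictly", {
  expect_true(segment_mineral(one_pixel_image(120, 100, 80))[1, 1])
  expect_false(segment_mineral(one_pixel_image(200, 200, 200))[1, 1])
  # boundary: R/G exactly 1.02 or B/G exactly 0.85 must NOT classify
  expect_false(segment_mineral(one_pixel_image(102, 100, 80))[1, 1])
  expect_false(segment_mineral(one_pixel_image(120, 100, 85))[1, 1])
  # G = 0: undefined ratios, conservatively non-mineral, counted
  img <- stained_image(array(c(120, 120, 0, 100, 60, 60),
                             dim = c(2, 1, 3)), "VON_KOSSA")
  m <- suppressMessages(segment_mineral(img))
  expect_false(m[1, 1])  # the G = 0 pixel
  expect_true(m[2, 1])   # R/G = 1.2, B/G = 0.6
  expect_equal(attr(m, "g_zero_pixels"), 1L)
  expect_message(segment_mineral(img), "G = 0")
  # wrong stain tag is rejected
  expect_error(segment_mineral(one_pixel_image(120, 100, 80, stain = "HE")),
               "VON_KOSSA")
})

test_that("matrix rule uses the open red-intensity interval", {
  expect_true(segment_matrix(one_pixel_image(215, 100, 100, "HE"))[1, 1])
  expect_false(segment_matrix(one_pixel_image(210, 100, 100, "HE"))[1, 1])
  expect_false(segment_matrix(one_pixel_image(225, 100, 100, "HE"))[1, 1])
  expect_true(segment_matrix(one_pixel_image(224, 100, 100, "HE"))[1, 1])
  expect_error(segment_matrix(one_pixel_image(215, 100, 100, "VON_KOSSA")),
               "HE")
})

test_that("nucleus rule responds to elevated blue/green on either stain", {
  thr <- rgb_thresholds(nucleus_bg_min = 1.05)
  expect_true(segment_nuclei(one_pixel_image(100, 100, 150), thr)[1, 1])
  expect_false(segment_nuclei(one_pixel_image(128, 128, 128), thr)[1, 1])
  expect_true(segment_nuclei(one_pixel_image(100, 100, 150, "HE"), thr)[1, 1])
  # configurable threshold is honoured
  expect_false(segment_nuclei(one_pixel_image(100, 100, 150),
                              rgb_thresholds(nucleus_bg_min = 1.6))[1, 1])
})

test_that("line profiles report per-position ratios left to right", {
  px <- array(c(110, 100, 90,   # R values of the three columns
                100, 100, 100,  # G
                90, 100, 130),  # B
              dim = c(1, 3, 3))
  lp <- extract_line_profile(stained_image(px, "VON_KOSSA"), row = 1)
  expect_equal(lp$rg_ratio, c(1.1, 1.0, 0.9))
  expect_equal(lp$bg_ratio, c(0.9, 1.0, 1.3))
  expect_equal(lp$position, 1:3)
  gray <- stained_image(array(128, dim = c(4, 5, 3)), "HE")
  lpg <- extract_line_profile(gray, 2)
  expect_true(all(lpg$rg_ratio == 1) && all(lpg$bg_ratio == 1))
  expect_error(extract_line_profile(gray, 9), "row")
  expect_error(extract_line_profile(gray, 0), "row")
})

test_that("a line through a phantom cell shows the published signature", {
  # nucleus at centre flanked by mineral: B/G peaks over the nucleus span,
  # R/G exceeds 1.02 over the mineral spans
  ph <- generate_stain_phantom(phantom_spec(65, 65, mineral_fraction = 0.5,
                                            nucleus_count = 1,
                                            nucleus_radius = 8, seed = 42))
  centre_row <- which(rowSums(ph$truth_nuclei) == max(rowSums(ph$truth_nuclei)))[1]
  lp <- extract_line_profile(ph$image, centre_row)
  nuc_cols <- which(ph$truth_nuclei[centre_row, ])
  min_cols <- which(ph$truth_mineral[centre_row, ])
  expect_true(all(lp$bg_ratio[nuc_cols] > 1.05))
  expect_true(all(lp$rg_ratio[min_cols] > 1.02))
  expect_true(all(lp$bg_ratio[min_cols] < 0.85))
})

test_that("area_fraction handles full, empty and ROI-restricted masks", {
  m <- matrix(TRUE, 4, 4)
  expect_equal(area_fraction(m), 100)
  expect_equal(area_fraction(matrix(FALSE, 4, 4)), 0)
  half <- matrix(c(TRUE, FALSE), 4, 4)
  expect_equal(area_fraction(half), 50)
  roi <- matrix(FALSE, 4, 4); roi[1:2, ] <- TRUE
  expect_equal(area_fraction(m, roi), 100)
  expect_error(area_fraction(m, matrix(FALSE, 4, 4)), "empty")
  expect_error(area_fraction(m, matrix(TRUE, 2, 2)), "dimensions")
})

test_that("vectorized rules equal a per-pixel loop on random rasters", {
  thr <- rgb_thresholds()
  for (seed in 1:100) {
    set.seed(seed)
    img <- random_image(32, 32)
    expect_identical(as_logical_matrix(suppressMessages(segment_mineral(img, thr))),
                     naive_classify(img, "mineral", thr))
    expect_identical(as_logical_matrix(suppressMessages(segment_nuclei(img, thr))),
                     naive_classify(img, "nucleus", thr))
    img_he <- stained_image(img$pixels, "HE")
    expect_identical(as_logical_matrix(segment_matrix(img_he, thr)),
                     naive_classify(img_he, "matrix", thr))
  }
})

test_that("raising thresholds shrinks masks monotonically", {
  set.seed(8)
  img <- random_image(64, 64)
  base <- sum(suppressMessages(segment_mineral(img)))
  stricter <- sum(suppressMessages(
    segment_mineral(img, rgb_thresholds(mineral_rg_min = 1.2))))
  expect_lte(stricter, base)
  img_he <- stained_image(img$pixels, "HE")
  narrow <- sum(segment_matrix(img_he, rgb_thresholds(matrix_red_low = 215,
                                                      matrix_red_high = 220)))
  wide <- sum(segment_matrix(img_he, rgb_thresholds(matrix_red_low = 205,
                                                    matrix_red_high = 230)))
  expect_lte(narrow, sum(segment_matrix(img_he)))
  expect_gte(wide, sum(segment_matrix(img_he)))
})

test_that("noisy phantoms recover area fractions within 3 percentage points", {
  for (seed in 1:5) {
    vk <- generate_stain_phantom(phantom_spec(256, 256,
                                              mineral_fraction = 0.25,
                                              matrix_fraction = 0.1,
                                              nucleus_count = 5,
                                              noise_sd = 5, seed = seed))
    got <- area_fraction(segment_mineral(vk$image))
    expect_lt(abs(got - area_fraction(vk$truth_mineral)), 3)
    he <- generate_stain_phantom(phantom_spec(256, 256,
                                              matrix_fraction = 0.15,
                                              nucleus_count = 5,
                                              noise_sd = 5, seed = seed,
                                              stain = "HE"))
    got <- area_fraction(segment_matrix(he$image))
    expect_lt(abs(got - area_fraction(he$truth_matrix)), 3)
  }
})

test_that("phantom nuclei are recovered with high overlap", {
  ph <- generate_stain_phantom(phantom_spec(128, 128, nucleus_count = 6,
                                            nucleus_radius = 7, seed = 3))
  rec <- segment_nuclei(ph$image)
  jac <- sum(rec & ph$truth_nuclei) / sum(rec | ph$truth_nuclei)
  expect_gte(jac, 0.95)
})
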