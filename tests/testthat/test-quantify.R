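test_that("zone intensity matches the brute-force pixel oracle exactly", {
  set.seed(42)
  img <- disc_image(a = 300, bg = 100)
  img$pixels <- img$pixels + matrix(rnorm(length(img$pixels), 0, 10),
                                    nrow(img$pixels))
  for (centre in list(c(50, 50), c(48.6, 51.2), c(50.5, 49.5))) {
    f <- fit_at(centre[1], centre[2])
    m <- zone_intensity(img, f)
    o <- brute_zone_stats(img$pixels, centre[1], centre[2], 25)
    # identical pixel classification; means agree to summation-order epsilon
    expect_equal(m$mean_in, o$mean_in, tolerance = 1e-12)
    expect_equal(m$mean_bg, o$mean_bg, tolerance = 1e-12)
    expect_equal(m$corrected, o$corrected, tolerance = 1e-9)
  }
})

test_that("corrected intensity: identity, disc recovery, shift invariance", {
  flat <- sheet_image(matrix(77, 101, 101), 100)
  expect_equal(zone_intensity(flat, fit_at(50, 50))$corrected, 0)

  img <- disc_image(a = 300, bg = 100)
  m <- zone_intensity(img, fit_at(50, 50))
  expect_equal(m$mean_bg, 100)
  expect_equal(m$corrected, 300, tolerance = 0.01)  # partial boundary pixels

  shifted <- img; shifted$pixels <- img$pixels + 5000
  m2 <- zone_intensity(shifted, fit_at(50, 50))
  expect_equal(m2$corrected, m$corrected)
})

test_that("background ring outside the image and failed fits are errors", {
  img <- disc_image()
  expect_error(zone_intensity(img, fit_at(10, 50)), "exits the image")
  expect_error(zone_intensity(img, fit_at(50, 50), bg_factor = 3),
               "exits the image")
  bad <- fit_at(50, 50); bad$provenance <- "failed"
  expect_error(zone_intensity(img, bad), "failed fit")
})

test_that("exact linear calibration inverts exactly", {
  curve <- fit_calibration(data.frame(cells = c(0, 1e4, 1e5),
                                      corrected = c(0, 10, 100)),
                           form = "linear")
  expect_equal(as.numeric(cells_from_intensity(curve, 10)), 1e4)
  expect_equal(as.numeric(cells_from_intensity(curve, 100)), 1e5)
  expect_equal(as.numeric(cells_from_intensity(curve, 0)), 0)
})

test_that("hyperbolic parameters are recovered from forward-model data", {
  set.seed(5)
  cal <- cal_model("hyperbola", I_max = 40000, K = 1e5)
  cells <- rep(round(4000 * (50 / 1)^((0:7) / 7)), each = 8)  # 8 levels
  corrected <- cal$forward(cells) + rnorm(length(cells), 0, 150)
  curve <- fit_calibration(cells = cells, corrected = corrected)
  co <- curve$coefficients
  expect_lt(abs(co[["I_max"]] - 40000) / 40000, 0.05)
  expect_lt(abs(co[["K"]] - 1e5) / 1e5, 0.05)
  # inverse-consistency: forward then inverse within 1%
  for (c0 in c(12000, 50000, 120000)) {
    back <- as.numeric(cells_from_intensity(curve, predict_intensity(curve, c0)))
    expect_lt(abs(back - c0) / c0, 0.01)
  }
})

test_that("calibration rejects degenerate input and flags non-monotone data", {
  expect_error(fit_calibration(data.frame(cells = c(0, 1e4),
                                          corrected = c(0, 10))),
               "at least 3 distinct")
  expect_error(fit_calibration(data.frame(cells = rep(c(0, 1e4), 5),
                                          corrected = rnorm(10))),
               "at least 3 distinct")
  down <- fit_calibration(data.frame(cells = c(0, 1e4, 1e5),
                                     corrected = c(100, 50, 0)),
                          form = "linear")
  expect_true(down$monotone_warning)
})

test_that("intensity above the fitted range is converted but flagged", {
  curve <- fit_calibration(data.frame(cells = c(0, 1e4, 1e5),
                                      corrected = c(0, 10, 100)),
                           form = "linear")
  est <- cells_from_intensity(curve, c(50, 110))
  expect_equal(attr(est, "extrapolated"), c(FALSE, TRUE))
  expect_equal(as.numeric(est)[2], 1.1e5)
  # negative corrected intensities floor at zero cells
  est2 <- cells_from_intensity(curve, -40)
  expect_equal(as.numeric(est2), 0)
})

test_that("seeded cells from volume and density", {
  expect_identical(seeded_cells(4, 3e7), 120000)
  expect_identical(seeded_cells(4, 3e6), 12000)
  expect_identical(seeded_cells(0, 3e7), 0)
  expect_error(seeded_cells(-1, 10), "non-negative")
})
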