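test_that("ring count follows ceil(outer_factor * R): 3.0 mm at 100 um -> 33", {
  img <- disc_image(w = 151, h = 151, cx = 75, cy = 75, R = 30)
  pr <- half_radial_profile(img, fit_at(75, 75, R = 30))
  expect_equal(pr$n_rings, 33L)
  expect_length(pr$left, 33L)
  expect_length(pr$right, 33L)
})

test_that("half-ring means match the brute-force polar-binning oracle", {
  set.seed(9)
  img <- disc_image()
  img$pixels <- img$pixels + matrix(rnorm(length(img$pixels), 0, 20),
                                    nrow(img$pixels))
  for (ang in c(0, pi / 5)) {
    pr <- half_radial_profile(img, fit_at(50.3, 49.7), axis_angle = ang)
    o <- brute_half_radial(img$pixels, 50.3, 49.7, pr$n_rings, ang)
    # identical binning; means agree to summation-order epsilon
    expect_identical(pr$n_left, o$n_left)
    expect_identical(pr$n_right, o$n_right)
    expect_equal(pr$left, o$left, tolerance = 1e-12)
    expect_equal(pr$right, o$right, tolerance = 1e-12)
  }
})

test_that("bins partition the disc and conserve the plain mean", {
  set.seed(10)
  img <- disc_image()
  img$pixels <- img$pixels + matrix(rnorm(length(img$pixels), 0, 20),
                                    nrow(img$pixels))
  pr <- half_radial_profile(img, fit_at(50, 50))
  n <- pr$n_left + pr$n_right
  # every pixel with d <= n_rings is in exactly one (ring, half) bin
  d <- sqrt(outer((0:100 - 50)^2, (0:100 - 50)^2, "+"))
  expect_equal(sum(n), sum(d <= pr$n_rings))
  binned_mean <- sum(pr$left * pr$n_left + pr$right * pr$n_right) / sum(n)
  expect_equal(binned_mean, mean(img$pixels[d <= pr$n_rings]))
})

test_that("rotationally symmetric zones give equal half-profiles", {
  # half-pixel margin puts the centre between pixel columns, so no pixel
  # sits exactly on the dividing axis
  sim <- generate_sheet(clean_params(n_rows = 1, n_cols = 1,
                                     rim_fraction = 0.15, margin_um = 4550),
                        5000)
  f <- fit_at(sim$truth$x_px[1], sim$truth$y_px[1])
  pr <- half_radial_profile(sim$image, f)
  expect_equal(pr$left, pr$right)
  expect_equal(profile_asymmetry(pr), 0)
})

test_that("mirroring about the axis swaps left and right exactly", {
  set.seed(12)
  px <- matrix(rnorm(101 * 102, 500, 50), 101, 102)
  img <- sheet_image(px, 100)
  # vertical axis at x = 50.5 (between pixel columns, so no on-axis pixels)
  mir <- sheet_image(px[, ncol(px):1], 100)
  a <- half_radial_profile(img, fit_at(50.5, 50))
  b <- half_radial_profile(mir, fit_at(50.5, 50))
  expect_equal(a$left, b$right)
  expect_equal(a$right, b$left)
})

test_that("a half-bright zone separates into its two half profiles", {
  img <- disc_image(a = 0, bg = 100)       # flat background
  px <- img$pixels
  for (y in 0:100) for (x in 0:100)
    if (x < 50.5 && sqrt((x - 50.5)^2 + (y - 50)^2) <= 25)
      px[y + 1, x + 1] <- 400
  img <- sheet_image(px, 100)
  pr <- half_radial_profile(img, fit_at(50.5, 50))
  inside <- 1:24
  expect_true(all(abs(pr$left[inside] - 400) < 1e-9))
  expect_true(all(abs(pr$right[inside] - 100) < 1e-9))
  expect_gt(profile_asymmetry(pr), 0.9)
})

test_that("heat maps assemble to the printed replicate-by-ring shapes", {
  make_prof <- function(layer, row, col, n_rings = 38) {
    structure(list(layer = layer, channel = "GFP", row = row, col = col,
                   axis_angle = 0, n_rings = n_rings,
                   left = rep(row + 1, n_rings), right = rep(col + 1, n_rings),
                   n_left = rep(3, n_rings), n_right = rep(3, n_rings)),
              class = "radial_profile")
  }
  g8 <- grid_spec(8, 6)
  pm <- default_plate_map(g8)
  # 8 replicates x 1 experiment at 38 rings -> 8 x 76
  p1 <- lapply(0:7, function(r) make_prof("L1", r, 0))
  hm1 <- assemble_heatmap(p1, pm)
  expect_equal(dim(hm1), c(8L, 76L))
  # 8 replicates x 6 experiments -> 8 x 456
  p6 <- unlist(lapply(0:5, function(cc)
    lapply(0:7, function(r) make_prof("L1", r, cc))), recursive = FALSE)
  hm6 <- assemble_heatmap(p6, pm)
  expect_equal(dim(hm6), c(8L, 456L))
  # row layout: [rev(left), right] puts the zone centre mid-row
  expect_equal(unname(hm1[3, c(1, 38, 39, 76)]), c(3, 3, 1, 1))
  # layers stack vertically, L1 on top
  p2 <- c(p1, lapply(0:7, function(r) make_prof("L2", r, 0)))
  hm2 <- assemble_heatmap(p2, pm, layer_order = c("L1", "L2"))
  expect_equal(dim(hm2), c(16L, 76L))
  expect_equal(attr(hm2, "row_info")$layer[1], "L1")
  # mixed ring counts and empty input are errors
  expect_error(assemble_heatmap(c(p1, list(make_prof("L1", 0, 1, 33))), pm),
               "mixed n_rings")
  expect_error(assemble_heatmap(list(), pm), "no profiles")
})

test_that("rendering writes a PNG with separators and a CSV round-trip", {
  make_prof <- function(layer, row, col) {
    structure(list(layer = layer, channel = "GFP", row = row, col = col,
                   axis_angle = 0, n_rings = 38,
                   left = stats::runif(38), right = stats::runif(38),
                   n_left = rep(3, 38), n_right = rep(3, 38)),
              class = "radial_profile")
  }
  set.seed(3)
  pm <- default_plate_map(grid_spec(8, 6))
  profs <- unlist(lapply(0:5, function(cc) unlist(lapply(c("L1", "L2"),
    function(l) lapply(0:7, function(r) make_prof(l, r, cc))),
    recursive = FALSE)), recursive = FALSE)
  hm <- assemble_heatmap(profs, pm, layer_order = c("L1", "L2"))
  path <- withr::local_tempfile(fileext = ".png")
  out <- render_heatmap(hm, path)
  rendered <- png::readPNG(path)
  # 6 experiment blocks of 76 + 5 black separator columns;
  # 2 layer bands of 8 + 1 white separator row
  expect_equal(dim(rendered)[1:2], c(16L + 1L, 456L + 5L))
  expect_length(out$col_separators, 5L)
  expect_length(out$row_separators, 1L)
  # white layer-separator rows overwrite the black experiment-separator
  # columns at their crossings
  expect_true(all(rendered[-(out$row_separators + 1), out$col_separators + 1] == 0))
  expect_true(all(rendered[out$row_separators + 1, ] == 1))
  back <- as.matrix(utils::read.csv(out$csv))
  expect_equal(unname(back), matrix(as.numeric(unclass(hm)), nrow(hm)),
               tolerance = 1e-12)

  # all-zero matrices render without exceptions
  hm0 <- hm; hm0[] <- 0
  expect_silent(render_heatmap(hm0, withr::local_tempfile(fileext = ".png")))
})
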