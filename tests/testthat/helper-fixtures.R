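# Shared fixture builders and independent brute-force oracles.
# The oracles deliberately use plain per-pixel loops and never call the
# package's binning code, so they stay an independent route to the same
# quantities.

# small clean sheet: no warp, no noise, proportional fluorescence
clean_params <- function(n_rows = 2, n_cols = 3, rim_fraction = 0,
                         noise_sd = 0, warp = 0, seed = 1, ...) {
  sheet_sim_params(n_rows = n_rows, n_cols = n_cols, pitch_um = 9000,
                   zone_radius_um = 2500, pixel_um = 100,
                   rim_fraction = rim_fraction, warp_amplitude_px = warp,
                   noise_sd = noise_sd,
                   cal = cal_model("linear", gain = 0.2), seed = seed, ...)
}

# the acceptance-study conditions: default generator (hyperbolic
# fluorescence, 15% cell-free rim), warped and noisy 96-zone sheet
study_params <- function(seed, warp = 3, noise_frac = 0.05) {
  p0 <- sheet_sim_params()
  signal_range <- (p0$paper_bg + p0$cal$forward(120000)) - p0$paper_bg
  sheet_sim_params(warp_amplitude_px = warp, warp_scale_px = 200,
                   noise_sd = noise_frac * signal_range, seed = seed)
}

# paint a flat disc of value `bg + a` (radius R) on constant background `bg`
disc_image <- function(w = 101, h = 101, cx = 50, cy = 50, R = 25,
                       a = 300, bg = 100, pixel_um = 100) {
  px <- matrix(bg, h, w)
  for (y in 0:(h - 1)) for (x in 0:(w - 1))
    if (sqrt((x - cx)^2 + (y - cy)^2) <= R) px[y + 1, x + 1] <- bg + a
  sheet_image(px, pixel_um)
}

fit_at <- function(x, y, R = 25, row = 0, col = 0)
  list(row = row, col = col, x = x, y = y, radius_px = R, provenance = "auto")

# oracle: per-pixel classification into disc / background circumference
brute_zone_stats <- function(pixels, cx, cy, R, bg_factor = 1.2) {
  rb <- round(bg_factor * R)
  s_in <- 0; n_in <- 0; s_bg <- 0; n_bg <- 0
  for (y in 0:(nrow(pixels) - 1)) for (x in 0:(ncol(pixels) - 1)) {
    d <- sqrt((x - cx)^2 + (y - cy)^2)
    if (d <= R) { s_in <- s_in + pixels[y + 1, x + 1]; n_in <- n_in + 1 }
    if (round(d) == rb) { s_bg <- s_bg + pixels[y + 1, x + 1]; n_bg <- n_bg + 1 }
  }
  list(mean_in = s_in / n_in, mean_bg = s_bg / n_bg,
       corrected = s_in / n_in - s_bg / n_bg)
}

# oracle: per-pixel polar binning into (ring, half) bins
brute_half_radial <- function(pixels, cx, cy, n_rings, axis_angle = 0) {
  sum_l <- numeric(n_rings); n_l <- numeric(n_rings)
  sum_r <- numeric(n_rings); n_r <- numeric(n_rings)
  for (y in 0:(nrow(pixels) - 1)) for (x in 0:(ncol(pixels) - 1)) {
    dx <- x - cx; dy <- y - cy
    d <- sqrt(dx^2 + dy^2)
    if (d > n_rings) next
    r <- max(ceiling(d), 1)
    u <- dx * cos(axis_angle) + dy * sin(axis_angle)
    if (u <= 0) { sum_l[r] <- sum_l[r] + pixels[y + 1, x + 1]; n_l[r] <- n_l[r] + 1 }
    else { sum_r[r] <- sum_r[r] + pixels[y + 1, x + 1]; n_r[r] <- n_r[r] + 1 }
  }
  list(left = ifelse(n_l > 0, sum_l / n_l, NA_real_),
       right = ifelse(n_r > 0, sum_r / n_r, NA_real_),
       n_left = n_l, n_right = n_r)
}

# detection score on one simulated study sheet: fraction of zones auto-fit
# with centre error at most tol_R * R
detection_score <- function(sim, grid, tol_R = 0.2) {
  fits <- detect_zones(sim$image, grid)
  m <- merge(fits, sim$truth, by = c("row", "col"))
  R <- grid$zone_radius_um / sim$image$pixel_um
  err <- sqrt((m$x - m$x_px)^2 + (m$y - m$y_px)^2)
  mean(m$provenance == "auto" & err <= tol_R * R)
}
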