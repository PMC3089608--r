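#' Forward fluorescence model
#'
#' Maps a number of cells in a zone to the fluorescence signal it adds on top
#' of the paper background. The default is a saturating hyperbola
#' `I = I_max * c / (c + K)`, the standard behaviour of integrated
#' fluorescence at high label density; a proportional (`linear`) model with
#' slope `gain` is available for exact arithmetic checks.
#'
#' @param form `"hyperbola"` or `"linear"`.
#' @param I_max,K hyperbola parameters: saturation intensity and the cell
#'   count at half-saturation.
#' @param gain slope of the linear model (intensity per cell).
#' @return An object of class `cal_model` with a `$forward(cells)` function.
#' @export
cal_model <- function(form = c("hyperbola", "linear"), I_max = 40000,
                      K = 1e5, gain = 0.2) {
  form <- match.arg(form)
  forward <- switch(form,
    hyperbola = function(cells) I_max * cells / (cells + K),
    linear = function(cells) gain * cells)
  structure(list(form = form, I_max = I_max, K = K, gain = gain,
                 forward = forward), class = "cal_model")
}

#' Simulation parameters for a synthetic sheet scan
#'
#' Defines the geometry, optics and distortions of a simulated gel-scanner
#' image of one wax-patterned paper layer. Defaults mirror the standard
#' 96-zone array (8 x 12 zones, 9 mm pitch, 5 mm zone diameter) scanned at
#' 100 um resolution, with a 15% cell-free rim at the zone perimeter, the
#' midpoint of the 10-20% observed in real spotted layers.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param pitch_um,zone_radius_um,pixel_um geometry in micrometres.
#' @param paper_bg,wax_bg autofluorescence levels of bare paper inside a zone
#'   and of wax-impregnated paper between zones (16-bit intensity units).
#'   They must differ: the wax/paper contrast at the zone border is what zone
#'   detection keys on.
#' @param rim_fraction fraction of the zone radius left cell-free at the
#'   perimeter, in `[0, 1)`; capillary wicking of the gel outpaces cell
#'   transport, so the cell-laden disc is smaller than the wax-defined zone.
#' @param warp_amplitude_px maximum displacement of the smooth non-rigid
#'   deformation (wet paper compresses, bends or buckles on the scanner bed).
#' @param warp_scale_px smoothness (length scale) of the deformation field.
#' @param expansion optional global anisotropic scaling `c(sx, sy)` emulating
#'   wet-paper expansion; default `c(1, 1)` (off).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param cal forward fluorescence model, a [cal_model].
#' @param margin_um blank border around the zone grid.
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return An object of class `sheet_sim_params`.
#' @export
sheet_sim_params <- function(n_rows = 8L, n_cols = 12L, pitch_um = 9000,
                             zone_radius_um = 2500, pixel_um = 100,
                             paper_bg = 2000, wax_bg = 5000,
                             rim_fraction = 0.15, warp_amplitude_px = 0,
                             warp_scale_px = 200, expansion = c(1, 1),
                             noise_sd = 0, cal = cal_model(),
                             margin_um = pitch_um / 2, seed = NULL) {
  if (pitch_um <= 2 * zone_radius_um)
    stop("pitch_um must exceed 2 * zone_radius_um (zones must not overlap)")
  if (wax_bg == paper_bg)
    stop("wax_bg must differ from paper_bg: zone detection relies on the ",
         "wax/paper autofluorescence contrast")
  if (rim_fraction < 0 || rim_fraction >= 1)
    stop("rim_fraction must lie in [0, 1)")
  if (noise_sd < 0 || warp_amplitude_px < 0 || warp_scale_px <= 0)
    stop("noise_sd and warp_amplitude_px must be >= 0, warp_scale_px > 0")
  stopifnot(inherits(cal, "cal_model"))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pitch_um = pitch_um, zone_radius_um = zone_radius_um,
                 pixel_um = pixel_um, paper_bg = paper_bg, wax_bg = wax_bg,
                 rim_fraction = rim_fraction,
                 warp_amplitude_px = warp_amplitude_px,
                 warp_scale_px = warp_scale_px,
                 expansion = as.numeric(expansion), noise_sd = noise_sd,
                 cal = cal, margin_um = margin_um, seed = seed),
            class = "sheet_sim_params")
}

# Smooth random displacement field: a sum of `n_bumps` Gaussian radial-basis
# bumps of length scale `scale`, rescaled so the maximum displacement
# magnitude over the field equals `amplitude`. Returns a function
# (x, y) -> list(dx, dy).
make_warp_field <- function(width, height, amplitude, scale, n_bumps = 6L) {
  if (amplitude <= 0) {
    f <- function(x, y) list(dx = rep(0, length(x)), dy = rep(0, length(x)))
    return(f)
  }
  cx <- stats::runif(n_bumps, 0, width - 1)
  cy <- stats::runif(n_bumps, 0, height - 1)
  ax <- stats::rnorm(n_bumps)
  ay <- stats::rnorm(n_bumps)
  raw <- function(x, y) {
    dx <- numeric(length(x)); dy <- numeric(length(x))
    for (i in seq_len(n_bumps)) {
      w <- exp(-((x - cx[i])^2 + (y - cy[i])^2) / (2 * scale^2))
      dx <- dx + ax[i] * w
      dy <- dy + ay[i] * w
    }
    list(dx = dx, dy = dy)
  }
  # normalize on a coarse lattice (the field is smooth at scale `scale`)
  gx <- seq(0, width - 1, length.out = 40)
  gy <- seq(0, height - 1, length.out = 40)
  gg <- expand.grid(x = gx, y = gy)
  d0 <- raw(gg$x, gg$y)
  m <- max(sqrt(d0$dx^2 + d0$dy^2))
  k <- if (m > 0) amplitude / m else 0
  function(x, y) {
    d <- raw(x, y)
    list(dx = k * d$dx, dy = k * d$dy)
  }
}

#' Generate a synthetic sheet scan with ground truth
#'
#' Renders the forward model of a gel-scanner image of one multi-zone paper
#' layer: for each zone, a cell-laden disc of radius
#' `(1 - rim_fraction) * R` whose intensity is `paper_bg` plus the forward
#' fluorescence model of its cell count, surrounded by a bare-paper annulus
#' out to the wax-defined radius `R`, embedded in wax background. The whole
#' field is then displaced by a smooth random non-rigid warp and i.i.d.
#' Gaussian noise is added last.
#'
#' @param params a [sheet_sim_params].
#' @param zone_values cells per zone: either a single number recycled over
#'   the grid, an `n_rows x n_cols` matrix, or a data frame with columns
#'   `row`, `col` (0-based) and `cells`; unlisted positions hold 0 cells.
#' @param channel,layer_id metadata for the generated [sheet_image].
#' @return A list of class `sheet_sim` with elements `image` (the noisy
#'   [sheet_image]), `truth` (data frame `row`, `col`, `x_px`, `y_px`,
#'   `cells` with post-warp zone centres) and `true_image` (the noiseless
#'   intensity raster).
#' @export
generate_sheet <- function(params, zone_values = 0, channel = "GFP",
                           layer_id = "L1") {
  stopifnot(inherits(params, "sheet_sim_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)

  cells <- zone_value_matrix(zone_values, p$n_rows, p$n_cols)
  px <- p$pixel_um
  pitch <- p$pitch_um / px
  R <- p$zone_radius_um / px
  margin <- p$margin_um / px
  width <- ceiling(2 * margin + (p$n_cols - 1) * pitch) + 1L
  height <- ceiling(2 * margin + (p$n_rows - 1) * pitch) + 1L

  warp <- make_warp_field(width, height, p$warp_amplitude_px, p$warp_scale_px)

  # analytic (pre-warp) centres, in scene coordinates
  grid0 <- expand.grid(col = seq_len(p$n_cols) - 1L, row = seq_len(p$n_rows) - 1L)
  cx0 <- margin + grid0$col * pitch
  cy0 <- margin + grid0$row * pitch

  # pixel lattice; rendered value at pixel q is the scene evaluated at the
  # source point q - D(q), optionally de-scaled by the global expansion
  xs <- rep(0:(width - 1L), each = height)
  ys <- rep(0:(height - 1L), times = width)
  d <- warp(xs, ys)
  ex <- p$expansion[1]; ey <- p$expansion[2]
  sx <- (xs - d$dx) / ex
  sy <- (ys - d$dy) / ey

  ci <- pmin(pmax(round((sx - margin) / pitch), 0), p$n_cols - 1L)
  ri <- pmin(pmax(round((sy - margin) / pitch), 0), p$n_rows - 1L)
  dz <- sqrt((sx - (margin + ci * pitch))^2 + (sy - (margin + ri * pitch))^2)
  nc <- cells[cbind(ri + 1L, ci + 1L)]
  sig <- p$cal$forward(nc)
  val <- ifelse(dz <= (1 - p$rim_fraction) * R, p$paper_bg + sig,
                ifelse(dz <= R, p$paper_bg, p$wax_bg))
  true_img <- matrix(val, nrow = height, ncol = width)

  # post-warp centres: solve q = c * expansion + D(q) by fixed-point iteration
  qx <- cx0 * ex; qy <- cy0 * ey
  for (i in 1:25) {
    dd <- warp(qx, qy)
    qx <- cx0 * ex + dd$dx
    qy <- cy0 * ey + dd$dy
  }
  truth <- data.frame(row = grid0$row, col = grid0$col,
                      x_px = qx, y_px = qy,
                      cells = cells[cbind(grid0$row + 1L, grid0$col + 1L)])

  dmin <- if (length(qx) > 1L) min(stats::dist(cbind(qx, qy))) else Inf
  if (dmin < 2 * R)
    stop("geometry error: warped zones overlap (minimum centre distance ",
         sprintf("%.1f", dmin), " px < 2R = ", sprintf("%.1f", 2 * R), " px)")

  noisy <- true_img
  if (p$noise_sd > 0)
    noisy <- noisy + matrix(stats::rnorm(length(noisy), 0, p$noise_sd),
                            nrow = height)
  structure(list(image = sheet_image(noisy, px, channel, layer_id),
                 truth = truth, true_image = true_img, params = p),
            class = "sheet_sim")
}

zone_value_matrix <- function(zone_values, n_rows, n_cols) {
  if (is.data.frame(zone_values)) {
    m <- matrix(0, n_rows, n_cols)
    if (any(zone_values$row < 0 | zone_values$row >= n_rows |
            zone_values$col < 0 | zone_values$col >= n_cols))
      stop("zone_values positions outside the grid")
    m[cbind(zone_values$row + 1L, zone_values$col + 1L)] <- zone_values$cells
    m
  } else if (is.matrix(zone_values)) {
    if (!all(dim(zone_values) == c(n_rows, n_cols)))
      stop("zone_values matrix must be n_rows x n_cols")
    zone_values
  } else {
    matrix(rep_len(as.numeric(zone_values), n_rows * n_cols), n_rows, n_cols)
  }
}

#' Write the ground-truth sidecar of a simulation
#'
#' @param sim a `sheet_sim` from [generate_sheet()].
#' @param path output CSV path (columns `row`, `col`, `x_px`, `y_px`, `cells`).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  stopifnot(inherits(sim, "sheet_sim"))
  utils::write.csv(sim$truth, path, row.names = FALSE)
  invisible(path)
}
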