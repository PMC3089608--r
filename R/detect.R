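#' Locate every zone on a possibly warped sheet image
#'
#' Wet paper compresses, bends or buckles on the scanner bed, so the zone
#' array cannot be mapped by a rigid grid or corrected by a Euclidean
#' transform. Instead the region of interest is partitioned into an
#' `n_rows x n_cols` grid of cells and the zone border is re-found inside
#' each cell independently: gradient-magnitude (Sobel) edges are extracted
#' with a per-cell Otsu threshold (applied on the log of the gradient
#' magnitude, so a faint wax border survives next to a bright cell-disc
#' edge), and a circle of the known wax-defined
#' radius `R` is fitted to them by searching over centre positions for the
#' one whose circumference has maximal edge support (a single-radius circular
#' Hough accumulation). Edge contrast exists because wax-impregnated and bare
#' paper differ in autofluorescence.
#'
#' Positions where no acceptable circle is found (`fit_quality` below
#' `min_quality`) are returned with `provenance = "failed"`, never silently
#' guessed; they can be corrected with [override_zone()].
#'
#' @param image a [sheet_image].
#' @param grid a [grid_spec]; its `zone_radius_um` fixes the fitted radius
#'   and its `roi` (if set) the region holding the grid.
#' @param prior_fits optional result of a previous call; fits with
#'   `provenance = "manual"` are preserved unless `clear_manual = TRUE`.
#' @param min_quality fits with edge support below this fraction are flagged
#'   `failed` (default 0.3).
#' @param blur_sigma Gaussian pre-smoothing of the image before edge
#'   detection, in pixels.
#' @param clear_manual discard previously applied manual overrides.
#' @return A data frame of class `zone_fits` with one row per grid position:
#'   `layer`, `row`, `col`, `x`, `y` (0-based pixel centre), `radius_px`,
#'   `quality` (fraction of the fitted circumference supported by edge
#'   pixels), `provenance` (`auto`, `manual` or `failed`).
#' @export
detect_zones <- function(image, grid, prior_fits = NULL, min_quality = 0.3,
                         blur_sigma = 1, clear_manual = FALSE) {
  stopifnot(inherits(image, "sheet_image"), inherits(grid, "grid_spec"))
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  R <- grid$zone_radius_um / image$pixel_um

  roi <- grid$roi %||% c(0, 0, w - 1, h - 1)
  x0 <- roi[1]; y0 <- roi[2]; x1 <- roi[3]; y1 <- roi[4]
  if (x0 < 0 || y0 < 0 || x1 > w - 1 || y1 > h - 1)
    stop("ROI exceeds the image bounds")
  cw <- (x1 - x0 + 1) / grid$n_cols
  ch <- (y1 - y0 + 1) / grid$n_rows
  if (cw < 2 * R || ch < 2 * R)
    stop("geometry error: ROI too small to hold ", grid$n_rows, " x ",
         grid$n_cols, " cells of diameter 2R = ", round(2 * R, 1), " px")

  sm <- if (blur_sigma > 0) EBImage::gblur(px, sigma = blur_sigma) else px
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::filter2(sm, kx, boundary = "replicate")
  gy <- EBImage::filter2(sm, t(kx), boundary = "replicate")
  gmag <- sqrt(gx^2 + gy^2)

  # per-cell Otsu threshold on gradient magnitude -> binary edge map
  edges <- matrix(0, h, w)
  cell_bounds <- function(i, n, lo, hi) {
    a <- floor(lo + (i - 1) * (hi - lo + 1) / n)
    b <- if (i == n) floor(hi) else floor(lo + i * (hi - lo + 1) / n) - 1
    c(a, b)
  }
  for (r in seq_len(grid$n_rows)) {
    yb <- cell_bounds(r, grid$n_rows, y0, y1)
    for (cc in seq_len(grid$n_cols)) {
      xb <- cell_bounds(cc, grid$n_cols, x0, x1)
      tile <- gmag[(yb[1] + 1):(yb[2] + 1), (xb[1] + 1):(xb[2] + 1)]
      mx <- max(tile)
      # a tile without real contrast has no edges (the floor absorbs the
      # numerical noise of the FFT-based filtering)
      if (mx <= 1e-6 * max(abs(px))) next
      # Otsu on log-magnitude: gradient strengths span orders of magnitude
      # when a bright cell disc and a faint wax border coexist in one cell;
      # the log scale separates all edges from the noise floor rather than
      # strong edges from weak ones.
      th <- expm1(EBImage::otsu(log1p(tile), range = c(0, log1p(mx))))
      edges[(yb[1] + 1):(yb[2] + 1), (xb[1] + 1):(xb[2] + 1)] <-
        (tile > th) * 1
    }
  }

  # single-radius Hough: edge support of a circle of radius R at each centre
  kr <- ceiling(R) + 1L
  off <- -kr:kr
  dk <- sqrt(outer(off^2, off^2, "+"))
  kern <- (abs(dk - R) <= 0.5) * 1
  acc <- EBImage::filter2(edges, kern / sum(kern), boundary = 0)

  fits <- vector("list", grid$n_rows * grid$n_cols)
  k <- 1L
  for (r in seq_len(grid$n_rows)) {
    yb <- cell_bounds(r, grid$n_rows, y0, y1)
    for (cc in seq_len(grid$n_cols)) {
      xb <- cell_bounds(cc, grid$n_cols, x0, x1)
      win <- acc[(yb[1] + 1):(yb[2] + 1), (xb[1] + 1):(xb[2] + 1)]
      q <- max(win)
      idx <- which(win >= q - 1e-9, arr.ind = TRUE)
      # ties broken toward the grid-cell centre
      cxc <- (xb[1] + xb[2]) / 2; cyc <- (yb[1] + yb[2]) / 2
      d2 <- (idx[, 2] - 1 + xb[1] - cxc)^2 + (idx[, 1] - 1 + yb[1] - cyc)^2
      best <- idx[which.min(d2), , drop = TRUE]
      # sub-pixel refinement: support-weighted centroid of the accumulator
      # plateau in a +/-2 px neighbourhood (a perfect circle yields a flat
      # plateau between lattice positions)
      bx <- best[2] - 1 + xb[1]; by <- best[1] - 1 + yb[1]
      if (q > 0) {
        # sub-pixel refinement: support-weighted centroid of the whole
        # near-maximal accumulator plateau around the chosen position (a
        # perfect circle yields a flat plateau between lattice positions)
        pl <- which(win >= 0.98 * q, arr.ind = TRUE)
        near <- abs(pl[, 1] - best[1]) <= 4 & abs(pl[, 2] - best[2]) <= 4
        pl <- pl[near, , drop = FALSE]
        wgt <- win[pl]
        bx <- sum((pl[, 2] - 1 + xb[1]) * wgt) / sum(wgt)
        by <- sum((pl[, 1] - 1 + yb[1]) * wgt) / sum(wgt)
      }
      fits[[k]] <- data.frame(
        layer = image$layer_id, row = r - 1L, col = cc - 1L,
        x = bx, y = by,
        radius_px = R, quality = q,
        provenance = if (q >= min_quality) "auto" else "failed")
      k <- k + 1L
    }
  }
  out <- do.call(rbind, fits)
  rownames(out) <- NULL

  if (!is.null(prior_fits) && !clear_manual) {
    man <- prior_fits[prior_fits$provenance == "manual", , drop = FALSE]
    for (i in seq_len(nrow(man))) {
      j <- which(out$row == man$row[i] & out$col == man$col[i])
      out[j, c("x", "y", "radius_px", "quality", "provenance")] <-
        man[i, c("x", "y", "radius_px", "quality", "provenance")]
    }
  }
  structure(out, class = c("zone_fits", "data.frame"),
            image_dim = c(h, w), pixel_um = image$pixel_um,
            grid_radius_px = R)
}

#' Manually override the fit of one zone
#'
#' Mirrors the interactive correction step of the original workflow: zones
#' whose border was not detected accurately are replaced by a user-supplied
#' centre, with the radius reset to the nominal grid radius.
#'
#' @param fits a `zone_fits` data frame from [detect_zones()].
#' @param row,col 0-based grid position to override.
#' @param center_px numeric `c(x, y)` centre in 0-based pixel coordinates.
#' @return The updated `zone_fits`; the overridden row has
#'   `provenance = "manual"`.
#' @export
override_zone <- function(fits, row, col, center_px) {
  stopifnot(inherits(fits, "zone_fits"))
  j <- which(fits$row == row & fits$col == col)
  if (length(j) != 1L)
    stop("position (", row, ", ", col, ") is not in the grid")
  d <- attr(fits, "image_dim")
  if (center_px[1] < 0 || center_px[1] > d[2] - 1 ||
      center_px[2] < 0 || center_px[2] > d[1] - 1)
    stop("centre (", center_px[1], ", ", center_px[2],
         ") lies outside the image")
  fits$x[j] <- center_px[1]
  fits$y[j] <- center_px[2]
  fits$radius_px[j] <- attr(fits, "grid_radius_px")
  fits$quality[j] <- NA_real_
  fits$provenance[j] <- "manual"
  fits
}
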