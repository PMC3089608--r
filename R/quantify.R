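#' Background-corrected mean intensity of one zone
#'
#' Measures the mean grey-scale intensity inside the fitted zone circle and
#' subtracts the local background estimated on a thin circumference at
#' `bg_factor * R`, which crosses wax-patterned paper holding no cells. A
#' pixel belongs to the disc if its centre lies within `R` of the fitted
#' centre; the background ring is the set of pixels whose centre distance
#' rounds to `round(bg_factor * R)` (a one-pixel circumference, not an
#' annulus). The corrected intensity may be negative (background
#' over-subtraction) and is deliberately not clipped.
#'
#' @param image a [sheet_image].
#' @param fit a single zone fit: one row of a `zone_fits` data frame (or any
#'   list with `row`, `col`, `x`, `y`, `radius_px`, `provenance`).
#' @param bg_factor radial factor of the background circumference
#'   (default 1.2).
#' @return A one-row data frame of class `zone_measurement`: `layer`, `row`,
#'   `col`, `channel`, `mean_in`, `mean_bg`, `corrected`, `cells_est`
#'   (`NA` until a calibration is applied).
#' @export
zone_intensity <- function(image, fit, bg_factor = 1.2) {
  stopifnot(inherits(image, "sheet_image"))
  if (!is.null(fit$provenance) && fit$provenance == "failed")
    stop("zone (", fit$row, ", ", fit$col,
         ") has a failed fit; override it before quantification")
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  cx <- fit$x; cy <- fit$y; R <- fit$radius_px
  rb <- round(bg_factor * R)
  if (cx - rb < -0.5 || cx + rb > w - 0.5 || cy - rb < -0.5 || cy + rb > h - 0.5)
    stop("background ring of zone (", fit$row, ", ", fit$col,
         ") at ", bg_factor, " * R exits the image bounds")

  xlo <- max(0L, floor(cx - rb)); xhi <- min(w - 1L, ceiling(cx + rb))
  ylo <- max(0L, floor(cy - rb)); yhi <- min(h - 1L, ceiling(cy + rb))
  sub <- px[(ylo + 1):(yhi + 1), (xlo + 1):(xhi + 1), drop = FALSE]
  dx <- (xlo:xhi) - cx
  dy <- (ylo:yhi) - cy
  dmat <- sqrt(outer(dy^2, dx^2, "+"))
  mean_in <- mean(sub[dmat <= R])
  mean_bg <- mean(sub[round(dmat) == rb])
  data.frame(layer = image$layer_id, row = fit$row, col = fit$col,
             channel = image$channel, mean_in = mean_in, mean_bg = mean_bg,
             corrected = mean_in - mean_bg, cells_est = NA_real_)
}

#' Measure all zones of a sheet
#'
#' Applies [zone_intensity()] to every usable fit; failed fits are returned
#' with `NA` measurements so that no zone is silently dropped.
#'
#' @param image a [sheet_image].
#' @param fits a `zone_fits` data frame from [detect_zones()].
#' @param bg_factor background circumference factor (default 1.2).
#' @param curve optional [fit_calibration()] curve; when given, `cells_est`
#'   is filled via [cells_from_intensity()].
#' @return A data frame with one `zone_measurement` row per grid position.
#' @export
measure_zones <- function(image, fits, bg_factor = 1.2, curve = NULL) {
  rows <- lapply(seq_len(nrow(fits)), function(i) {
    f <- fits[i, ]
    if (f$provenance == "failed")
      return(data.frame(layer = image$layer_id, row = f$row, col = f$col,
                        channel = image$channel, mean_in = NA_real_,
                        mean_bg = NA_real_, corrected = NA_real_,
                        cells_est = NA_real_))
    zone_intensity(image, f, bg_factor)
  })
  out <- do.call(rbind, rows)
  if (!is.null(curve)) {
    est <- cells_from_intensity(curve, out$corrected)
    out$cells_est <- as.numeric(est)
  }
  out
}

#' Fit a calibration curve converting intensity to cell number
#'
#' Fits the relation between the number of cells seeded in a zone and its
#' background-corrected fluorescence intensity. The default form is a
#' saturating hyperbola with an additive offset,
#' `I = b + I_max * c / (c + K)`, matching the saturation behaviour of
#' integrated fluorescence; the offset absorbs any residual mismatch between
#' the in-zone and wax-ring backgrounds. A `linear` form `I = b + a * c`
#' (ordinary least squares) is available for proportional regimes.
#'
#' @param points data frame with columns `cells` and `corrected` (one point
#'   per calibration zone), or a pair of vectors via `cells =`/`corrected =`.
#' @param form `"hyperbola"` (default) or `"linear"`.
#' @param cells,corrected alternative vector interface.
#' @return An object of class `calibration_curve`: fitted coefficients, the
#'   valid cell/intensity ranges, residuals, and a monotonicity warning flag.
#' @export
fit_calibration <- function(points = NULL, form = c("hyperbola", "linear"),
                            cells = NULL, corrected = NULL) {
  form <- match.arg(form)
  if (!is.null(points)) {
    cells <- points$cells
    corrected <- points$corrected
  }
  ok <- is.finite(cells) & is.finite(corrected)
  cells <- cells[ok]; corrected <- corrected[ok]
  if (length(unique(cells)) < 3L)
    stop("calibration needs at least 3 distinct cell counts")

  # flag (do not fail on) non-monotone mean intensities beyond tolerance
  mu <- tapply(corrected, cells, mean)
  mu <- mu[order(as.numeric(names(mu)))]
  tol <- 0.02 * diff(range(corrected))
  monotone_warning <- any(diff(mu) < -tol)

  if (form == "linear") {
    fit <- stats::lm(corrected ~ cells)
    coefs <- c(b = unname(stats::coef(fit)[1]), a = unname(stats::coef(fit)[2]))
    if (coefs["a"] <= 0) monotone_warning <- TRUE
    fitted <- unname(stats::fitted(fit))
  } else {
    b0 <- min(corrected)
    i0 <- max(corrected) - b0
    k0 <- stats::median(cells[cells > 0])
    fit <- minpack.lm::nlsLM(
      corrected ~ b + I_max * cells / (cells + K),
      start = list(b = b0, I_max = 2 * i0, K = k0),
      lower = c(b = -Inf, I_max = 1e-9, K = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    coefs <- stats::coef(fit)
    fitted <- as.numeric(stats::fitted(fit))
  }
  structure(list(form = form, coefficients = coefs,
                 cells_range = range(cells),
                 intensity_range = range(fitted),
                 residuals = corrected - fitted,
                 monotone_warning = monotone_warning,
                 n_points = length(cells)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> form=%s; %s; fitted on %d points, cells in [%g, %g]%s\n",
              x$form,
              paste(sprintf("%s=%.4g", names(x$coefficients), x$coefficients),
                    collapse = ", "),
              x$n_points, x$cells_range[1], x$cells_range[2],
              if (x$monotone_warning) "; WARNING: non-monotone data" else ""))
  invisible(x)
}

#' Evaluate a calibration curve forward (cells -> intensity)
#'
#' @param curve a `calibration_curve`.
#' @param cells cell counts.
#' @return Predicted corrected intensities.
#' @export
predict_intensity <- function(curve, cells) {
  co <- curve$coefficients
  if (curve$form == "linear") co["b"] + co["a"] * cells
  else co["b"] + co["I_max"] * cells / (cells + co["K"])
}

#' Convert corrected intensity to an estimated cell number
#'
#' Inverse evaluation of the calibration curve. Corrected intensities at or
#' below the curve's zero-cell intensity map to 0 cells; estimates are never
#' negative. Intensities above the fitted range are still converted but
#' flagged as extrapolations (attribute `extrapolated`); for the hyperbolic
#' form, intensities at or beyond the saturation asymptote have no finite
#' inverse and return `NA` with the flag set.
#'
#' @param curve a `calibration_curve`.
#' @param corrected background-corrected intensities (vectorised).
#' @return Numeric vector of estimated cell counts with a logical attribute
#'   `extrapolated` marking values outside the fitted intensity range.
#' @export
cells_from_intensity <- function(curve, corrected) {
  stopifnot(inherits(curve, "calibration_curve"))
  co <- curve$coefficients
  upper <- max(curve$intensity_range)
  extrapolated <- corrected > upper
  if (curve$form == "linear") {
    est <- (corrected - co["b"]) / co["a"]
  } else {
    s <- corrected - co["b"]
    est <- ifelse(s >= co["I_max"], NA_real_, co["K"] * s / (co["I_max"] - s))
    extrapolated <- extrapolated | (!is.na(corrected) & s >= co["I_max"])
  }
  est <- ifelse(!is.na(corrected) & corrected <= 0, 0, est)
  est <- pmax(est, 0)
  names(est) <- NULL
  attr(est, "extrapolated") <- unname(extrapolated)
  est
}

#' Cells seeded in a zone from spotted volume and suspension density
#'
#' @param volume_uL spotted volume in microlitres.
#' @param density_cells_per_mL suspension density in cells per millilitre.
#' @return Cell count, rounded to the nearest integer (vectorised).
#' @examples
#' seeded_cells(4, 3e7)  # 120000, the high-density "H" zone
#' seeded_cells(4, 3e6)  # 12000, the low-density "L" zone
#' @export
seeded_cells <- function(volume_uL, density_cells_per_mL) {
  if (any(volume_uL < 0) || any(density_cells_per_mL < 0))
    stop("volume and density must be non-negative")
  round(volume_uL * 1e-3 * density_cells_per_mL)
}
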