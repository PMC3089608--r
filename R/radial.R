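#' Half-radial intensity profile of one zone
#'
#' Defines a polar coordinate system in the zone (`r = 0` at the fitted
#' centre, the `phi = 0` axis at `axis_angle`) and averages pixel intensities
#' over concentric one-pixel-wide rings, separately for the two halves of
#' each ring on either side of the axis. The two half-profiles make the
#' central symmetry of a cylindrical 3D culture checkable: for a symmetric
#' zone they coincide; a left/right difference reveals asymmetry.
#'
#' Ring `r` holds the pixels whose centre distance `d` satisfies
#' `r - 1 < d <= r` (the centre pixel, `d = 0`, is assigned to ring 1), for
#' `r = 1, ..., n_rings` with `n_rings = ceiling(outer_factor * R)`; the
#' outer rings beyond `R` sample background fluorescence. With `axis_angle =
#' 0` the axis is vertical and splits the zone into left and right halves;
#' pixels exactly on the axis are assigned to the left half.
#'
#' @param image a [sheet_image].
#' @param fit one zone fit (row of a `zone_fits`).
#' @param outer_factor outermost ring radius as a multiple of the fitted
#'   radius (default 1.1: the outer ~10% of the profile is background).
#' @param axis_angle orientation of the dividing axis in radians
#'   (default 0 = vertical).
#' @return An object of class `radial_profile`: zone identity, `n_rings`,
#'   numeric vectors `left` and `right` (mean intensity per half-ring) and
#'   `n_left`, `n_right` (pixel counts per half-ring).
#' @export
half_radial_profile <- function(image, fit, outer_factor = 1.1,
                                axis_angle = 0) {
  stopifnot(inherits(image, "sheet_image"))
  if (!is.null(fit$provenance) && fit$provenance == "failed")
    stop("zone (", fit$row, ", ", fit$col, ") has a failed fit")
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  cx <- fit$x; cy <- fit$y
  n_rings <- as.integer(ceiling(outer_factor * fit$radius_px))
  if (cx - n_rings < -0.5 || cx + n_rings > w - 0.5 ||
      cy - n_rings < -0.5 || cy + n_rings > h - 0.5)
    stop("outer ring of zone (", fit$row, ", ", fit$col,
         ") exits the image bounds")

  xlo <- max(0, floor(cx - n_rings)); xhi <- min(w - 1, ceiling(cx + n_rings))
  ylo <- max(0, floor(cy - n_rings)); yhi <- min(h - 1, ceiling(cy + n_rings))
  sub <- px[(ylo + 1):(yhi + 1), (xlo + 1):(xhi + 1), drop = FALSE]
  dx <- matrix(rep((xlo:xhi) - cx, each = nrow(sub)), nrow = nrow(sub))
  dy <- matrix(rep((ylo:yhi) - cy, times = ncol(sub)), nrow = nrow(sub))
  d <- sqrt(dx^2 + dy^2)

  ring <- pmax(ceiling(d), 1)          # half-open rings (r-1, r]; d = 0 -> 1
  keep <- d <= n_rings
  # signed coordinate perpendicular to the axis; u <= 0 (incl. on-axis) = left
  u <- dx * cos(axis_angle) + dy * sin(axis_angle)
  side <- ifelse(u <= 0, 1L, 2L)

  idx <- factor(ring[keep], levels = seq_len(n_rings))
  sd1 <- side[keep] == 1L
  sum_l <- tapply(sub[keep][sd1], idx[sd1], sum)
  n_l <- tapply(rep(1, sum(sd1)), idx[sd1], sum)
  sum_r <- tapply(sub[keep][!sd1], idx[!sd1], sum)
  n_r <- tapply(rep(1, sum(!sd1)), idx[!sd1], sum)
  tidy <- function(v) { v[is.na(v)] <- 0; as.numeric(v) }
  n_l <- tidy(n_l); n_r <- tidy(n_r)
  left <- ifelse(n_l > 0, tidy(sum_l) / n_l, NA_real_)
  right <- ifelse(n_r > 0, tidy(sum_r) / n_r, NA_real_)

  structure(list(layer = image$layer_id, channel = image$channel,
                 row = fit$row, col = fit$col, axis_angle = axis_angle,
                 n_rings = n_rings, left = left, right = right,
                 n_left = n_l, n_right = n_r),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %s zone (%d, %d): %d rings, left/right mean %g / %g\n",
              x$layer, x$row, x$col, x$n_rings,
              mean(x$left, na.rm = TRUE), mean(x$right, na.rm = TRUE)))
  invisible(x)
}

#' Left/right asymmetry statistic of a radial profile
#'
#' Maximum over rings of `|left - right|`, normalised by the profile's
#' dynamic range; near-zero for a centrally symmetric zone.
#'
#' @param profile a `radial_profile`.
#' @return A single number in `[0, Inf)` (0 when the profile is flat).
#' @export
profile_asymmetry <- function(profile) {
  rng <- diff(range(c(profile$left, profile$right), na.rm = TRUE))
  if (rng == 0) return(0)
  max(abs(profile$left - profile$right), na.rm = TRUE) / rng
}

#' Assemble half-radial profiles into a replicate/experiment/layer heat map
#'
#' Each zone contributes one row of `2 * n_rings` values ordered
#' `[rev(left), right]` so the zone centre sits mid-row. Replicates of one
#' experiment are stacked vertically; experiments are concatenated
#' horizontally as column blocks; in multi-layer views the per-layer blocks
#' are stacked vertically with L1 on top.
#'
#' @param profiles list of `radial_profile` objects (all with equal
#'   `n_rings`).
#' @param map plate-map data frame (`row`, `col`, `experiment`, `replicate`).
#' @param layer_order character vector of layer ids, top first; default the
#'   order of appearance.
#' @return An object of class `zone_heatmap`: the numeric matrix plus
#'   attributes `experiments`, `layers`, `n_rings`, `row_info` (data frame
#'   of layer/replicate per matrix row) and `col_blocks` (start column of
#'   each experiment block).
#' @export
assemble_heatmap <- function(profiles, map, layer_order = NULL) {
  if (length(profiles) == 0L) stop("no profiles to assemble")
  nr <- vapply(profiles, function(p) p$n_rings, numeric(1))
  if (length(unique(nr)) != 1L)
    stop("profiles have mixed n_rings: ", paste(unique(nr), collapse = ", "))
  n_rings <- nr[1]

  meta <- do.call(rbind, lapply(profiles, function(p)
    data.frame(layer = p$layer, row = p$row, col = p$col)))
  key <- merge(meta, map[, c("row", "col", "experiment", "replicate")],
               by = c("row", "col"), sort = FALSE)
  if (nrow(key) != length(profiles))
    stop("some profiles have no plate-map entry")
  # merge() may reorder; realign to the profile list
  ord <- match(paste(meta$layer, meta$row, meta$col),
               paste(key$layer, key$row, key$col))
  key <- key[ord, ]

  layers <- layer_order %||% unique(key$layer)
  experiments <- unique(key$experiment[order(key$col)])
  replicates <- unique(key$replicate[order(key$row)])

  rows_info <- expand.grid(replicate = replicates, layer = layers,
                           stringsAsFactors = FALSE)[, c("layer", "replicate")]
  rows_info <- rows_info[order(match(rows_info$layer, layers)), ]
  m <- matrix(NA_real_, nrow = nrow(rows_info),
              ncol = 2 * n_rings * length(experiments))
  col_blocks <- (seq_along(experiments) - 1L) * 2L * n_rings + 1L

  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    ri <- which(rows_info$layer == key$layer[i] &
                rows_info$replicate == key$replicate[i])
    ei <- match(key$experiment[i], experiments)
    if (length(ri) != 1L || is.na(ei)) next
    m[ri, col_blocks[ei]:(col_blocks[ei] + 2L * n_rings - 1L)] <-
      c(rev(p$left), p$right)
  }
  rownames(m) <- paste(rows_info$layer, rows_info$replicate, sep = ":")
  structure(m, class = c("zone_heatmap", "matrix"),
            experiments = experiments, layers = layers, n_rings = n_rings,
            row_info = rows_info, col_blocks = col_blocks)
}

#' Render a heat map to PNG and CSV
#'
#' Writes a grayscale PNG (dark = high intensity, matching the printed
#' convention that black is proportional to fluorescence) with 1-pixel black
#' separator columns between experiment blocks and 1-pixel white separator
#' rows between layer bands, plus the raw matrix as CSV.
#'
#' @param hm a `zone_heatmap`.
#' @param path output PNG path; the CSV is written next to it (`.csv`).
#' @param invert render high intensity as dark (default `TRUE`).
#' @return Invisibly, a list with `png`, `csv`, and the 0-based pixel offsets
#'   of the inserted `col_separators` and `row_separators`.
#' @export
render_heatmap <- function(hm, path, invert = TRUE) {
  stopifnot(inherits(hm, "zone_heatmap"))
  m <- unclass(hm)
  attributes(m) <- list(dim = dim(hm))
  if (length(m) == 0L) stop("empty heat map")
  rng <- range(m, na.rm = TRUE)
  norm <- if (diff(rng) == 0) matrix(0.5, nrow(m), ncol(m)) else
    (m - rng[1]) / diff(rng)
  norm[is.na(norm)] <- 0
  if (invert) norm <- 1 - norm

  n_rings <- attr(hm, "n_rings")
  experiments <- attr(hm, "experiments")
  layers <- attr(hm, "layers")
  row_info <- attr(hm, "row_info")

  # black column between consecutive experiment blocks
  ncolb <- 2L * n_rings
  col_sep <- integer(0)
  pieces <- list()
  for (e in seq_along(experiments)) {
    pieces[[length(pieces) + 1L]] <- norm[, ((e - 1L) * ncolb + 1L):(e * ncolb),
                                          drop = FALSE]
    if (e < length(experiments)) {
      col_sep <- c(col_sep, ncol(do.call(cbind, pieces)))
      pieces[[length(pieces) + 1L]] <- matrix(0, nrow(norm), 1L)
    }
  }
  canvas <- do.call(cbind, pieces)

  # white row between consecutive layer bands
  row_sep <- integer(0)
  if (length(layers) > 1L) {
    bands <- list()
    for (l in seq_along(layers)) {
      sel <- which(row_info$layer == layers[l])
      bands[[length(bands) + 1L]] <- canvas[sel, , drop = FALSE]
      if (l < length(layers)) {
        row_sep <- c(row_sep, sum(vapply(bands, nrow, integer(1))))
        bands[[length(bands) + 1L]] <- matrix(1, 1L, ncol(canvas))
      }
    }
    canvas <- do.call(rbind, bands)
  }

  png::writePNG(canvas, path)
  csv <- sub("\\.png$", ".csv", path, ignore.case = TRUE)
  if (identical(csv, path)) csv <- paste0(path, ".csv")
  utils::write.csv(m, csv, row.names = FALSE)
  invisible(list(png = path, csv = csv,
                 col_separators = col_sep, row_separators = row_sep))
}

#' Long-format table of radial profiles
#'
#' @param profiles list of `radial_profile` objects.
#' @return Data frame: `layer`, `channel`, `row`, `col`, `ring`, `left`,
#'   `right`, `n_left`, `n_right`.
#' @export
profiles_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p)
    data.frame(layer = p$layer, channel = p$channel, row = p$row, col = p$col,
               ring = seq_len(p$n_rings), left = p$left, right = p$right,
               n_left = p$n_left, n_right = p$n_right)))
}
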