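#' Build the long-format results table
#'
#' Combines zone-mean measurements and (optionally) half-radial profiles into
#' one long table: each zone contributes a `"zone-mean"` row and, when a
#' profile is given, one row per ring. Ring rows carry the per-half means in
#' `intensity_left`/`intensity_right` and their pixel-weighted full-ring mean
#' in `raw_intensity`.
#'
#' @param measurements data frame of zone measurements
#'   (from [measure_zones()]).
#' @param map plate map supplying `experiment`/`replicate` labels.
#' @param profiles optional list of `radial_profile` objects.
#' @return Data frame with columns `layer`, `experiment`, `replicate`, `row`,
#'   `col`, `ring`, `channel`, `raw_intensity`, `background`, `corrected`,
#'   `cells_est`, `intensity_left`, `intensity_right`.
#' @export
results_table <- function(measurements, map, profiles = NULL) {
  mm <- merge(measurements, map[, c("row", "col", "experiment", "replicate")],
              by = c("row", "col"), sort = FALSE)
  base <- data.frame(layer = mm$layer, experiment = mm$experiment,
                     replicate = mm$replicate, row = mm$row, col = mm$col,
                     ring = "zone-mean", channel = mm$channel,
                     raw_intensity = mm$mean_in, background = mm$mean_bg,
                     corrected = mm$corrected, cells_est = mm$cells_est,
                     intensity_left = NA_real_, intensity_right = NA_real_)
  if (is.null(profiles)) return(base)
  ring_rows <- lapply(profiles, function(p) {
    i <- which(mm$row == p$row & mm$col == p$col & mm$layer == p$layer)[1]
    full <- ifelse(p$n_left + p$n_right > 0,
                   (ifelse(p$n_left > 0, p$left * p$n_left, 0) +
                    ifelse(p$n_right > 0, p$right * p$n_right, 0)) /
                     (p$n_left + p$n_right), NA_real_)
    data.frame(layer = p$layer,
               experiment = if (length(i)) mm$experiment[i] else NA,
               replicate = if (length(i)) mm$replicate[i] else NA,
               row = p$row, col = p$col,
               ring = as.character(seq_len(p$n_rings)), channel = p$channel,
               raw_intensity = full,
               background = if (length(i)) mm$mean_bg[i] else NA_real_,
               corrected = full - (if (length(i)) mm$mean_bg[i] else NA_real_),
               cells_est = NA_real_,
               intensity_left = p$left, intensity_right = p$right)
  })
  rbind(base, do.call(rbind, ring_rows))
}

#' Export a results table to tabulated text
#'
#' @param results a data frame (typically from [results_table()]); may be
#'   empty, which yields a header-only file.
#' @param path output file path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_results <- function(results, path, format = c("csv", "tsv")) {
  supported <- c("csv", "tsv")
  if (length(format) == 1L && !format %in% supported)
    stop("unknown format '", format, "'; supported formats: ",
         paste(supported, collapse = ", "))
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(results, path, sep = sep, row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Re-import an exported results table
#'
#' @param path file written by [export_results()].
#' @param format `"csv"` or `"tsv"`.
#' @return The results data frame.
#' @export
import_results <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = NA)
}
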