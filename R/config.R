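#' Zone-array grid geometry
#'
#' Describes a rectangular array of circular culture zones bounded by printed
#' wax barriers. Defaults follow the standard 96-zone layout: 9 mm pitch and
#' 5 mm zone diameter.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param pitch_um centre-to-centre zone spacing in micrometres; must exceed
#'   the zone diameter so that zones do not overlap.
#' @param zone_radius_um radius of the wax-defined zone in micrometres.
#' @param roi optional region of interest holding the grid, as
#'   `c(x0, y0, x1, y1)` in 0-based pixel coordinates (top-left and
#'   bottom-right corners, inclusive). When `NULL` the whole image is used.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows = 8L, n_cols = 12L, pitch_um = 9000,
                      zone_radius_um = 2500, roi = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("n_rows and n_cols must be >= 1")
  if (pitch_um <= 2 * zone_radius_um)
    stop("pitch_um must exceed 2 * zone_radius_um (zones must not overlap)")
  if (!is.null(roi)) {
    if (length(roi) != 4L || roi[3] <= roi[1] || roi[4] <= roi[2])
      stop("roi must be c(x0, y0, x1, y1) with x1 > x0 and y1 > y0")
    roi <- as.numeric(roi)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 pitch_um = as.numeric(pitch_um),
                 zone_radius_um = as.numeric(zone_radius_um), roi = roi),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d zones, pitch %g um, zone radius %g um\n",
              x$n_rows, x$n_cols, x$pitch_um, x$zone_radius_um))
  invisible(x)
}

#' Plate map: experimental identity of every zone
#'
#' Maps each `(row, col)` grid position to an experiment, replicate and
#' condition label. The default layout follows the convention that zones
#' within the same column are replicates of one experiment: experiment ids are
#' derived from columns and replicate ids from rows.
#'
#' @param grid a [grid_spec].
#' @param experiment,replicate,condition,fluorophore optional vectors (or
#'   matrices in grid shape, row-major) overriding the default labels; each is
#'   recycled across the `n_rows * n_cols` positions in row-major order.
#' @return A data frame with columns `row`, `col` (0-based), `experiment`,
#'   `replicate`, `condition`, `fluorophore`.
#' @export
default_plate_map <- function(grid, experiment = NULL, replicate = NULL,
                              condition = "H", fluorophore = "GFP") {
  pos <- expand.grid(col = seq_len(grid$n_cols) - 1L,
                     row = seq_len(grid$n_rows) - 1L)
  pm <- data.frame(row = pos$row, col = pos$col)
  pm$experiment <- if (is.null(experiment)) sprintf("e%d", pm$col + 1L) else
    rep_len(as.character(experiment), nrow(pm))
  pm$replicate <- if (is.null(replicate)) sprintf("r%d", pm$row + 1L) else
    rep_len(as.character(replicate), nrow(pm))
  pm$condition <- rep_len(as.character(condition), nrow(pm))
  pm$fluorophore <- rep_len(as.character(fluorophore), nrow(pm))
  validate_plate_map(pm, grid)
}

validate_plate_map <- function(pm, grid = NULL) {
  need <- c("row", "col", "experiment", "replicate", "condition", "fluorophore")
  miss <- setdiff(need, names(pm))
  if (length(miss)) stop("plate map is missing columns: ",
                         paste(miss, collapse = ", "))
  key <- paste(pm$row, pm$col)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("plate map positions mapped more than once: (row col) ",
         paste(dups, collapse = "; "))
  }
  if (!is.null(grid)) {
    bad <- pm$row < 0 | pm$row >= grid$n_rows | pm$col < 0 | pm$col >= grid$n_cols
    if (any(bad)) stop("plate map positions outside the grid: (row col) ",
                       paste(unique(key[bad]), collapse = "; "))
  }
  pm[order(pm$row, pm$col), , drop = FALSE]
}

#' Stack design: ordered layer composition of one 3D culture
#'
#' A stack is a vertical assembly of paper layers; L1 faces the oxygenated
#' culture medium and the last layer the impermeable backing. Each layer
#' contributes one 200-um-thick slab of cell-laden gel per zone.
#'
#' @param stack_id identifier of the stack.
#' @param layers character vector of ordered layer ids, L1 first.
#' @param seeding data frame with one row per layer: `layer_id`, `condition`,
#'   `cells` (seeded cells in this stack's zone on that layer), `fluorophore`.
#'   May be empty for an empty design.
#' @param layer_thickness_um thickness of one layer (default 200).
#' @return An object of class `stack_design`.
#' @export
stack_design <- function(stack_id, layers = character(), seeding = NULL,
                         layer_thickness_um = 200) {
  layers <- as.character(layers)
  if (is.null(seeding))
    seeding <- data.frame(layer_id = character(), condition = character(),
                          cells = numeric(), fluorophore = character())
  if (nrow(seeding) && !all(seeding$layer_id %in% layers))
    stop("seeding refers to layer ids not in the layer list")
  if (nrow(seeding) && any(seeding$cells < 0)) stop("seeded cells must be >= 0")
  structure(list(stack_id = as.character(stack_id), layers = layers,
                 seeding = seeding,
                 layer_thickness_um = as.numeric(layer_thickness_um)),
            class = "stack_design")
}

#' Load a pipeline configuration file
#'
#' Reads a YAML (or JSON) configuration describing the grid geometry, the
#' plate map and any stack designs, applying the standard-array defaults where
#' fields are omitted: 9 mm pitch, 5 mm zone diameter, background ring factor
#' 1.2, ring width 1 pixel.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A list with elements `grid` ([grid_spec]), `plate_map` (data
#'   frame), `stacks` (list of [stack_design]), `quantify` (list with
#'   `bg_factor`, `ring_width_px`, `outer_factor`), and `raw` (the parsed
#'   file contents).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  g <- cfg$grid %||% list()
  zone_radius_um <- if (!is.null(g$zone_diameter_um)) g$zone_diameter_um / 2
    else g$zone_radius_um %||% 2500
  grid <- grid_spec(n_rows = g$rows %||% 8L, n_cols = g$cols %||% 12L,
                    pitch_um = g$pitch_um %||% 9000,
                    zone_radius_um = zone_radius_um,
                    roi = if (!is.null(g$roi)) unlist(g$roi))
  pixel_um <- g$pixel_um %||% 100

  pm <- if (is.null(cfg$plate_map)) {
    default_plate_map(grid)
  } else {
    tab <- as.data.frame(do.call(rbind, lapply(cfg$plate_map, function(z) {
      z <- lapply(z, function(v) if (is.null(v)) NA else v)
      data.frame(row = as.integer(z$row), col = as.integer(z$col),
                 experiment = as.character(z$experiment %||% sprintf("e%d", as.integer(z$col) + 1L)),
                 replicate = as.character(z$replicate %||% sprintf("r%d", as.integer(z$row) + 1L)),
                 condition = as.character(z$condition %||% "H"),
                 fluorophore = as.character(z$fluorophore %||% "GFP"))
    })))
    validate_plate_map(tab, grid)
  }

  stacks <- lapply(cfg$stacks %||% list(), function(s) {
    seeding <- if (is.null(s$seeding)) NULL else
      as.data.frame(do.call(rbind, lapply(s$seeding, function(z)
        data.frame(layer_id = as.character(z$layer), condition = as.character(z$condition %||% "H"),
                   cells = as.numeric(z$cells), fluorophore = as.character(z$fluorophore %||% "GFP")))))
    stack_design(s$stack_id %||% "s1", layers = unlist(s$layers),
                 seeding = seeding,
                 layer_thickness_um = s$layer_thickness_um %||% 200)
  })

  q <- cfg$quantify %||% list()
  list(grid = grid, pixel_um = pixel_um, plate_map = pm, stacks = stacks,
       quantify = list(bg_factor = q$bg_factor %||% 1.2,
                       ring_width_px = q$ring_width_px %||% 1,
                       outer_factor = q$outer_factor %||% 1.1),
       raw = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
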