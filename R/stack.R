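#' Total seeded cells and thickness of a stack
#'
#' @param design a [stack_design].
#' @return List with `cells` (sum of seeded cells over layers) and
#'   `thickness_um` (`n_layers * layer_thickness_um`). An all-H eight-layer
#'   stack of 120,000-cell zones totals 960,000 cells over 1600 um.
#' @export
stack_total <- function(design) {
  stopifnot(inherits(design, "stack_design"))
  list(cells = sum(design$seeding$cells),
       thickness_um = length(design$layers) * design$layer_thickness_um)
}

#' Enumerate the distinct stacks formed by aligned sheets
#'
#' Stacking a set of sheets aligns same-position zones into one 3D culture
#' per (experiment geometry, replicate) pair: six geometries with eight
#' replicates each yield 48 stacks. Every pair must be present on every
#' layer; a replicate present on some layers but not others is an assembly
#' error, not a smaller stack.
#'
#' @param layer_maps named list of plate-map data frames, one per layer
#'   (each with columns `experiment`, `replicate`).
#' @return Data frame of distinct stacks: `stack_id`, `experiment`,
#'   `replicate`; its row count is the number of stacks.
#' @export
enumerate_stacks <- function(layer_maps) {
  if (length(layer_maps) == 0L) stop("no layer maps given")
  keys <- lapply(layer_maps, function(pm)
    unique(paste(pm$experiment, pm$replicate, sep = "\r")))
  all_keys <- unique(unlist(keys))
  present <- vapply(keys, function(k) all(all_keys %in% k), logical(1))
  if (!all(present)) {
    missing_on <- names(layer_maps)[!present] %||% which(!present)
    stop("zones missing on some layers: every (experiment, replicate) pair ",
         "must appear on every layer (incomplete: ",
         paste(missing_on, collapse = ", "), ")")
  }
  parts <- do.call(rbind, strsplit(sort(all_keys), "\r", fixed = TRUE))
  data.frame(stack_id = paste(parts[, 1], parts[, 2], sep = ":"),
             experiment = parts[, 1], replicate = parts[, 2])
}

#' Per-layer growth table of a stack experiment
#'
#' Compares calibrated cell-count estimates with the day-0 seeding, layer by
#' layer, across replicates.
#'
#' @param result data frame with columns `layer_id`, `replicate`,
#'   `cells_est` (one row per layer per replicate).
#' @param design a [stack_design] supplying seeded cells per layer.
#' @return Data frame per layer: `layer_id`, `n`, `mean_est`, `sd_est`
#'   (`NA` with a single replicate), `seeded`, `ratio` (mean_est / seeded;
#'   `NA` for unseeded layers).
#' @export
growth_table <- function(result, design) {
  stopifnot(inherits(design, "stack_design"))
  seeded <- stats::setNames(design$seeding$cells, design$seeding$layer_id)
  layers <- design$layers
  out <- lapply(layers, function(l) {
    v <- result$cells_est[result$layer_id == l]
    s <- unname(seeded[l])
    if (is.na(s) && !(l %in% names(seeded))) s <- 0
    data.frame(layer_id = l, n = length(v),
               mean_est = if (length(v)) mean(v) else NA_real_,
               sd_est = if (length(v) >= 2L) stats::sd(v) else NA_real_,
               seeded = s,
               ratio = if (length(v) && s > 0) mean(v) / s else NA_real_)
  })
  do.call(rbind, out)
}

#' Two-sample comparison of replicate values between conditions
#'
#' Welch's two-sided t-test by default (pooled-variance optional), used e.g.
#' to compare per-layer cell numbers with and without Mitomycin C. Degenerate
#' zero-variance inputs follow the natural limits: equal constant groups give
#' statistic 0 and p = 1; unequal constant groups give an infinite statistic
#' (signed as mean(a) - mean(b)) and p = 0.
#'
#' @param a,b numeric vectors of replicate values (each of length >= 2).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return List of class `condition_test`: `statistic`, `p_value`, `df`,
#'   `mean_a`, `mean_b`, `method`.
#' @export
compare_conditions <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    d <- mean(a) - mean(b)
    res <- list(statistic = if (d == 0) 0 else sign(d) * Inf,
                p_value = if (d == 0) 1 else 0,
                df = length(a) + length(b) - 2,
                mean_a = mean(a), mean_b = mean(b),
                method = "t-test (degenerate zero-variance limit)")
    return(structure(res, class = "condition_test"))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  structure(list(statistic = unname(tt$statistic),
                 p_value = tt$p.value, df = unname(tt$parameter),
                 mean_a = mean(a), mean_b = mean(b),
                 method = tt$method),
            class = "condition_test")
}

#' @export
print.condition_test <- function(x, ...) {
  cat(sprintf("<condition_test> %s: t = %.3g, df = %.3g, p = %.3g (means %.4g vs %.4g)\n",
              x$method, x$statistic, x$df, x$p_value, x$mean_a, x$mean_b))
  invisible(x)
}

#' Fraction of labelled cells that migrated to a receiver layer
#'
#' For migration from a sender layer into an adjacent receiver layer the
#' fraction is `receiver / (receiver + sender)`, computed on the
#' background-corrected fluorescence of the label (e.g.
#' `GFP(L1) / (GFP(L1) + GFP(L2))` for migration from L2 up into L1). The
#' statistic is scale-invariant, so intensities and calibrated cell counts
#' give the same fraction when the calibration is proportional.
#'
#' @param sender,receiver non-negative signals in the same units
#'   (vectorised).
#' @return Fractions in `[0, 1]`; a pair with both signals zero yields `NA`
#'   with a warning.
#' @export
migration_fraction <- function(sender, receiver) {
  if (any(sender < 0, na.rm = TRUE) || any(receiver < 0, na.rm = TRUE))
    stop("signals must be non-negative")
  tot <- sender + receiver
  if (any(tot == 0, na.rm = TRUE))
    warning("sender and receiver both zero: fraction undefined (NA)")
  ifelse(tot == 0, NA_real_, receiver / tot)
}

#' Directionality of migration per sender layer
#'
#' For senders with migration measured both towards the medium-facing side
#' ("up") and away from it ("down"), compares the paired up/down fractions
#' across replicates: ratio of means and a paired two-sided t-test. Senders
#' with only one direction (e.g. the outermost layers) cannot be paired and
#' are reported separately with `NA` statistics.
#'
#' @param results data frame with columns `sender`, `direction` (`"up"` or
#'   `"down"`), `replicate`, `fraction`.
#' @return Data frame per sender: `sender`, `n_pairs`, `mean_up`,
#'   `mean_down`, `ratio` (up / down), `statistic`, `p_value`, `paired`.
#' @export
directionality <- function(results) {
  need <- c("sender", "direction", "replicate", "fraction")
  if (!all(need %in% names(results)))
    stop("results must have columns ", paste(need, collapse = ", "))
  out <- lapply(unique(results$sender), function(s) {
    d <- results[results$sender == s, ]
    up <- d[d$direction == "up", c("replicate", "fraction")]
    dn <- d[d$direction == "down", c("replicate", "fraction")]
    pair <- merge(up, dn, by = "replicate", suffixes = c("_up", "_down"))
    if (nrow(up) == 0L || nrow(dn) == 0L || nrow(pair) == 0L) {
      warning("sender ", s, " has unmatched up/down measurements; ",
              "reported without pairing")
      return(data.frame(sender = s, n_pairs = 0L,
                        mean_up = if (nrow(up)) mean(up$fraction) else NA_real_,
                        mean_down = if (nrow(dn)) mean(dn$fraction) else NA_real_,
                        ratio = NA_real_, statistic = NA_real_,
                        p_value = NA_real_, paired = FALSE))
    }
    dif <- pair$fraction_up - pair$fraction_down
    if (nrow(pair) < 2L) {
      st <- if (dif[1] == 0) 0 else NA_real_
      pv <- if (dif[1] == 0) 1 else NA_real_
    } else if (stats::var(dif) == 0) {
      # degenerate constant-difference limit of the paired t-test
      st <- if (mean(dif) == 0) 0 else sign(mean(dif)) * Inf
      pv <- if (mean(dif) == 0) 1 else 0
    } else {
      tt <- stats::t.test(pair$fraction_up, pair$fraction_down, paired = TRUE)
      st <- unname(tt$statistic); pv <- tt$p.value
    }
    mu <- mean(pair$fraction_up); md <- mean(pair$fraction_down)
    data.frame(sender = s, n_pairs = nrow(pair), mean_up = mu, mean_down = md,
               ratio = if (md > 0) mu / md else NA_real_,
               statistic = st, p_value = pv, paired = TRUE)
  })
  do.call(rbind, out)
}
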