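# Unit localization along probe penetrations and tonotopic gradient
# regressions.

#' Project along-shank unit positions to vertical depth
#'
#' Given each penetration's insertion angle relative to the brain surface,
#' converts a unit's distance from the probe tip into a vertical depth
#' component (`depth = dist * sin(angle)`).
#'
#' @param geometry data.frame with `penetration_id`, `angle_deg` (one row
#'   per penetration).
#' @param units data.frame with `unit_id`, `penetration_id`,
#'   `dist_from_tip_um`.
#' @return `units` with added `vertical_um = dist_from_tip_um *
#'   sin(angle)`.
#' @export
locate_units <- function(geometry, units) {
  m <- match(units$penetration_id, geometry$penetration_id)
  if (anyNA(m)) {
    missing <- unique(units$penetration_id[is.na(m)])
    stop("no geometry for penetration(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ang <- geometry$angle_deg[m]
  units$vertical_um <- units$dist_from_tip_um * sin(ang * pi / 180)
  units
}

#' Tonotopic gradient regression for one penetration
#'
#' Least-squares regression of `log2(CF)` on distance from the probe tip
#' (mm). The slope's significance comes from the regression F test; the
#' penetration is classified `negative-significant`, `positive-significant`
#' or `non-significant` at `alpha`.
#'
#' @param cf_hz Characteristic frequencies of the penetration's units.
#' @param dist_um Distances from the probe tip (micrometers).
#' @param alpha Significance level (default 0.05).
#' @return List with `slope` (log2-CF per mm), `intercept`, `p_value`,
#'   `classification`, `n`, `degenerate` (all CFs identical).
#' @export
tonotopy_regression <- function(cf_hz, dist_um, alpha = 0.05) {
  ok <- is.finite(cf_hz) & is.finite(dist_um)
  cf_hz <- cf_hz[ok]; dist_um <- dist_um[ok]
  if (length(cf_hz) < 3)
    stop("need >= 3 CF-bearing units in the penetration", call. = FALSE)
  if (var(cf_hz) == 0 || var(dist_um) == 0) {
    return(list(slope = 0, intercept = log2(cf_hz[1]), p_value = NA_real_,
                classification = "non-significant", n = length(cf_hz),
                degenerate = TRUE))
  }
  d_mm <- dist_um / 1000
  fit <- lm(log2(cf_hz) ~ d_mm)
  sm <- suppressWarnings(summary(fit))
  p <- unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                 lower.tail = FALSE))
  slope <- unname(coef(fit)[2])
  cls <- if (is.na(p) || p >= alpha) "non-significant"
  else if (slope < 0) "negative-significant" else "positive-significant"
  list(slope = slope, intercept = unname(coef(fit)[1]), p_value = p,
       classification = cls, n = length(cf_hz), degenerate = FALSE)
}

#' Aggregate tonotopy fits across penetrations
#'
#' @param fits data.frame with one row per penetration: `slope`,
#'   `classification`.
#' @return List with `counts` (table of classifications), `mean_slope`,
#'   `t_test` (one-sample t test of the slopes against zero).
#' @export
aggregate_tonotopy <- function(fits) {
  counts <- table(factor(fits$classification,
                         levels = c("negative-significant",
                                    "positive-significant",
                                    "non-significant")))
  sl <- fits$slope[is.finite(fits$slope)]
  tt <- if (length(sl) >= 3 && sd(sl) > 0) t.test(sl) else NULL
  list(counts = counts, mean_slope = mean(sl),
       t_p_value = if (is.null(tt)) NA_real_ else tt$p.value)
}

#' Per-penetration tonotopy analysis for a recorded population
#'
#' Joins the tuning table with the unit geometry and regresses log2(CF) on
#' distance from tip within each penetration with at least `min_units`
#' CF-bearing units.
#'
#' @param tuning Tuning table (one kind) with `unit_id`, `cf_hz`.
#' @param units Unit table with `unit_id`, `penetration_id`,
#'   `dist_from_tip_um`.
#' @param min_units Minimum CF-bearing units per penetration (default 3).
#' @param alpha Significance level.
#' @return data.frame, one row per analyzed penetration.
#' @export
tonotopy_by_penetration <- function(tuning, units, min_units = 3,
                                    alpha = 0.05) {
  df <- merge(tuning[!is.na(tuning$cf_hz), c("unit_id", "cf_hz")],
              units[, c("unit_id", "penetration_id", "dist_from_tip_um")],
              by = "unit_id")
  rows <- list()
  for (p in sort(unique(df$penetration_id))) {
    sub <- df[df$penetration_id == p, ]
    if (nrow(sub) < min_units) next
    r <- tonotopy_regression(sub$cf_hz, sub$dist_from_tip_um, alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      penetration_id = p, slope = r$slope, p_value = r$p_value,
      classification = r$classification, n_units = r$n,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
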