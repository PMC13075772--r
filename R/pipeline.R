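# End-to-end reference experiment: synthesize -> score -> fit ->
# discriminate -> decode -> report.

#' Reference configuration bundle
#'
#' Collects the reference calibration in one place: the
#' behavioral generator (thresholds 31.5/28 dB for PT/NBN, plateau
#' d' ~ 3.3), the unit generator (median C50s ~57.7/55.5 dB, NBN C50 offset
#' -2.2 dB, latencies 23/26 ms) and the stimulus grid.
#'
#' @param n_units,n_pops,pop_size,tune_budget Scale knobs for the neural
#'   arm (defaults match the reference protocol; tests use smaller values).
#' @return List with `grid`, `behavior`, `units`, `decoding`.
#' @export
reference_config <- function(n_units = 150, n_pops = 10, pop_size = 50,
                             tune_budget = 20) {
  list(grid = build_stimulus_grid(),
       behavior = behavior_config(),
       units = unit_config(n_units = n_units),
       decoding = list(n_pops = n_pops, size = pop_size,
                       window = c(0, 50), tune_budget = tune_budget))
}

#' Run the reference experiment end to end on synthetic data
#'
#' Executes both arms on generated data: behavioral sessions are scored
#' with the signal-detection pipeline (rates, d-prime, thresholds, strategy
#' regression); the synthetic unit population is run through
#' responsiveness detection, log-normal rate-level fitting with CF/C50
#' extraction, temporal dynamics, CF-versus-adjacent discriminability and
#' (optionally) pseudopopulation frequency decoding with a shuffled-label
#' baseline. Returns summary tables plus a run manifest. All stages derive
#' their seeds deterministically from `seed`.
#'
#' @param config A [reference_config()] bundle.
#' @param seed Integer master seed.
#' @param run_decoding,run_dprime Stage switches (both default TRUE).
#' @return List of class `reference_run` with elements `behavior`
#'   (`group`, `thresholds`, `strategy`), `neural` (`tuning`, `fits`,
#'   `paired_c50`, `temporal`, `dprime`, `decoding`), and `manifest`.
#' @export
run_reference_experiment <- function(config = reference_config(),
                                     seed = 1L, run_decoding = TRUE,
                                     run_dprime = TRUE) {
  grid <- config$grid

  # --- behavioral arm ---
  beh <- generate_behavior_sessions(config$behavior, child_seed(seed, 1))
  out <- classify_trials(beh$trials, seed = child_seed(seed, 2))
  summ <- sdt_summary(out)
  agg <- sdt_group_summary(summ)
  thr <- behavioral_thresholds(agg$animal)
  lowest <- min(config$behavior$amplitudes)
  an_low <- agg$animal[agg$animal$spl_db == lowest, ]
  strat <- lapply(split(an_low, an_low$kind), function(d)
    strategy_regression(d$MSR, d$FAR))

  # --- neural arm ---
  pop <- generate_unit_population(config$units, grid, child_seed(seed, 3))
  tun <- analyze_tuning(pop$spikes, grid, seed = child_seed(seed, 4))
  paired <- paired_c50_differences(tun$tuning)
  temp <- temporal_dynamics(pop$spikes, grid, tun$tuning)
  dp <- NULL
  if (run_dprime) {
    dvl <- dprime_vs_level(pop$spikes, grid, tun$tuning)
    dp <- list(by_unit = dvl, curve = dprime_curve(dvl))
  }
  dec <- NULL
  if (run_decoding) {
    dcfg <- config$decoding
    res <- list()
    for (k in grid$kinds) {
      pool <- tun$tuning$unit_id[tun$tuning$kind == k &
                                   tun$tuning$responsive]
      pops <- build_pseudopopulations(pop$spikes, grid, pool, kinds = k,
                                      size = dcfg$size,
                                      n_pops = dcfg$n_pops,
                                      window = dcfg$window,
                                      seed = child_seed(seed, 5))
      acc <- vapply(seq_along(pops), function(i)
        decode_frequency(pops[[i]], k, tune_budget = dcfg$tune_budget,
                         seed = child_seed(seed, 50 + i))$accuracy, 0)
      sh <- vapply(seq_along(pops), function(i)
        decode_frequency(pops[[i]], k, shuffle = TRUE,
                         tune_budget = dcfg$tune_budget,
                         seed = child_seed(seed, 70 + i))$accuracy, 0)
      res[[k]] <- list(accuracy = acc, shuffled = sh)
    }
    dec <- res
  }
  manifest <- list(
    seed = seed, timestamp = NA_character_,  # keep manifests reproducible
    n_behavior_trials = nrow(beh$trials),
    n_units = config$units$n_units,
    n_responsive = sum(tun$tuning$responsive) / length(grid$kinds),
    stages = c("behavior", "sdt", "units", "tuning", "temporal",
               if (run_dprime) "dprime", if (run_decoding) "decoding"))
  structure(list(
    behavior = list(group = agg$group, animal = agg$animal,
                    thresholds = thr, strategy = strat),
    neural = list(tuning = tun$tuning, fits = tun$fits, paired_c50 = paired,
                  temporal = temp, dprime = dp, decoding = dec),
    manifest = manifest), class = "reference_run")
}

#' Paired PT-minus-NBN C50 differences at matched CF
#'
#' Restricts the tuning table to units with a defined CF for both kinds and
#' identical CF across kinds (the consistent-CF subset), and returns the
#' per-unit PT minus NBN C50 difference at that CF.
#'
#' @param tuning Tuning table from [analyze_tuning()].
#' @return data.frame with `unit_id`, `cf_hz`, `c50_pt`, `c50_nbn`,
#'   `difference`; attribute `median_difference`.
#' @export
paired_c50_differences <- function(tuning) {
  pt <- tuning[tuning$kind == "PT" & !is.na(tuning$cf_hz), ]
  nbn <- tuning[tuning$kind == "NBN" & !is.na(tuning$cf_hz), ]
  m <- merge(pt[, c("unit_id", "cf_hz", "c50_at_cf")],
             nbn[, c("unit_id", "cf_hz", "c50_at_cf")],
             by = "unit_id", suffixes = c("_pt", "_nbn"))
  m <- m[m$cf_hz_pt == m$cf_hz_nbn, ]
  out <- data.frame(unit_id = m$unit_id, cf_hz = m$cf_hz_pt,
                    c50_pt = m$c50_at_cf_pt, c50_nbn = m$c50_at_cf_nbn,
                    difference = m$c50_at_cf_pt - m$c50_at_cf_nbn,
                    stringsAsFactors = FALSE)
  attr(out, "median_difference") <- median(out$difference)
  out
}

#' @export
print.reference_run <- function(x, ...) {
  thr <- x$behavior$thresholds
  cat("Reference synthetic experiment\n")
  cat("  behavioral thresholds (dB):",
      paste(sprintf("%s=%g", thr$kind, thr$threshold_db), collapse = ", "),
      "\n")
  if (!is.null(attr(thr, "difference")))
    cat("  PT - NBN threshold difference:", attr(thr, "difference"),
        "dB\n")
  cat("  consistent-CF units:", nrow(x$neural$paired_c50),
      "| median paired C50 difference (PT - NBN):",
      round(attr(x$neural$paired_c50, "median_difference"), 2), "dB\n")
  if (!is.null(x$neural$decoding)) {
    for (k in names(x$neural$decoding)) {
      d <- x$neural$decoding[[k]]
      cat(sprintf("  decoding (%s): accuracy %.3f, shuffled %.3f\n", k,
                  mean(d$accuracy), mean(d$shuffled)))
    }
  }
  invisible(x)
}

#' One replicate of the behavioral threshold-difference recovery
#'
#' Generates the full behavioral design (by default 8 animals x 10
#' sessions under the reference configuration), scores it with the
#' signal-detection pipeline and returns the recovered PT-minus-NBN
#' detection threshold difference.
#'
#' @param config A [behavior_config()].
#' @param seed Integer seed.
#' @param alpha Threshold-test significance level.
#' @return List with `difference` (dB), `thresholds` (per-kind table).
#' @export
recover_threshold_difference <- function(config = behavior_config(),
                                         seed = 1L, alpha = 0.05) {
  beh <- generate_behavior_sessions(config, child_seed(seed, 1))
  out <- classify_trials(beh$trials, seed = child_seed(seed, 2))
  agg <- sdt_group_summary(sdt_summary(out))
  thr <- behavioral_thresholds(agg$animal, alpha = alpha)
  list(difference = attr(thr, "difference"), thresholds = thr)
}

#' One replicate of the paired C50-offset recovery
#'
#' Generates `n_units` synthetic units with matched characteristic
#' frequencies (the generator assigns the same CF to both kinds by design),
#' keeps those detected as responsive to both stimulus kinds, fits the
#' log-normal rate-level function for each kind at each unit's assigned CF,
#' and returns the per-unit paired PT-minus-NBN C50 differences for units
#' where both fits converge with `R^2 > 0.7` and a defined C50.
#'
#' This recovery exercises the fitting pipeline at a known test frequency;
#' it deliberately does not re-estimate the CF (see
#' [paired_c50_differences()] for the full CF-selection route).
#'
#' @param config A [unit_config()].
#' @param grid Stimulus grid.
#' @param seed Integer seed.
#' @param r2_min Fit-quality floor.
#' @return Numeric vector of paired differences (dB), one per usable unit.
#' @export
recover_c50_offset <- function(config = unit_config(n_units = 200),
                               grid = build_stimulus_grid(), seed = 1L,
                               r2_min = 0.7) {
  pop <- generate_unit_population(config, grid, child_seed(seed, 1))
  counts <- spike_count_table(pop$spikes, grid)
  dual <- intersect(responsive_pool(pop$spikes, grid, "PT"),
                    responsive_pool(pop$spikes, grid, "NBN"))
  diffs <- rep(NA_real_, nrow(pop$units))
  for (i in seq_len(nrow(pop$units))) {
    u <- pop$units$unit_id[i]
    if (!u %in% dual) next
    j <- match(pop$units$cf_hz[i], grid$frequencies)
    c50 <- vapply(c("PT", "NBN"), function(k) {
      fra <- compute_fra(counts, grid, u, k)
      f <- fit_rate_level(grid$spls, fra$norm[j, ],
                          seed = child_seed(seed, 10 + i))
      s <- derive_sensitivity(f)
      if (isTRUE(f$r_squared > r2_min) && isTRUE(s$defined)) s$c50
      else NA_real_
    }, 0)
    diffs[i] <- c50[["PT"]] - c50[["NBN"]]
  }
  diffs[is.finite(diffs)]
}

#' Shuffled-label decoding accuracies on reference pseudopopulations
#'
#' Generates a reference unit population, detects the responsive pool per
#' stimulus kind, builds pseudopopulations of `size` units and runs the
#' frequency decoder with permuted labels, returning the held-out accuracy
#' of every population (chance is 1/11 for the default grid).
#'
#' @param config A [unit_config()].
#' @param grid Stimulus grid.
#' @param kinds Kinds to include.
#' @param n_pops Populations per kind.
#' @param size Units per population.
#' @param window Spike-count window (ms).
#' @param seed Integer seed.
#' @return Numeric vector of accuracies (length `n_pops * length(kinds)`).
#' @export
shuffled_decoding_accuracy <- function(config = unit_config(n_units = 120),
                                       grid = build_stimulus_grid(),
                                       kinds = c("PT", "NBN"), n_pops = 10,
                                       size = 50, window = c(0, 50),
                                       seed = 1L) {
  pop <- generate_unit_population(config, grid, child_seed(seed, 1))
  acc <- numeric(0)
  for (k in kinds) {
    pool <- responsive_pool(pop$spikes, grid, k)
    pops <- build_pseudopopulations(pop$spikes, grid, pool, kinds = k,
                                    size = size, n_pops = n_pops,
                                    window = window,
                                    seed = child_seed(seed, 2))
    acc <- c(acc, vapply(seq_along(pops), function(i)
      decode_frequency(pops[[i]], k, shuffle = TRUE,
                       seed = child_seed(seed, 100 + i))$accuracy, 0))
  }
  acc
}
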