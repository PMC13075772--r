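# Frequency response areas, responsiveness detection, log-normal rate-level
# fitting, C50 / half-width / CF extraction and tuning bandwidth.

#' Spike counts per condition and trial over a time window
#'
#' Tabulates spikes falling in `window` (ms relative to stimulus onset) for
#' every unit x kind x frequency x SPL x trial cell of the grid, filling
#' explicit zeros for trials without spikes.
#'
#' @param spikes Long spike table (see [generate_unit_population()]).
#' @param grid The stimulus grid (supplies the full condition lattice and
#'   trial count).
#' @param window Length-2 window in ms.
#' @param kinds Kinds to include (default: the grid's kinds).
#' @return data.frame with columns unit_id, kind, freq_hz, spl_db, trial, n.
#' @export
spike_count_table <- function(spikes, grid, window = c(5, 95),
                              kinds = grid$kinds) {
  dt <- data.table::as.data.table(spikes)
  dt <- dt[kind %in% kinds & spike_ms >= window[1] & spike_ms < window[2]]
  cnt <- dt[, .(n = .N), by = .(unit_id, kind, freq_hz, spl_db, trial)]
  units <- unique(spikes$unit_id)
  lattice <- data.table::CJ(unit_id = units, kind = kinds,
                            freq_hz = grid$frequencies, spl_db = grid$spls,
                            trial = seq_len(grid$n_trials))
  out <- merge(lattice, cnt,
               by = c("unit_id", "kind", "freq_hz", "spl_db", "trial"),
               all.x = TRUE)
  out[is.na(n), n := 0L]
  as.data.frame(out)
}

#' Frequency response area of one unit
#'
#' Trial-averaged firing rate (spikes in the response window divided by the
#' window duration) for every frequency x SPL condition, with a normalized
#' copy scaled by the matrix maximum.
#'
#' @param counts Count table from [spike_count_table()] (any number of
#'   units; filtered internally).
#' @param grid Stimulus grid.
#' @param unit One unit id.
#' @param kind `"PT"` or `"NBN"`.
#' @param window The window (ms) the counts were taken in (sets the rate
#'   denominator).
#' @return Object of class `fra`: list with `rates` (frequency x SPL
#'   matrix, sp/s), `norm` (rates / max), `max_rate`, `degenerate` flag
#'   (all-zero matrix), `trial_counts` (long data.frame), `unit_id`, `kind`.
#' @export
compute_fra <- function(counts, grid, unit, kind = c("PT", "NBN"),
                        window = c(5, 95)) {
  kind <- match.arg(kind)
  .u <- unit; .k <- kind
  dt <- data.table::as.data.table(counts)
  dt <- dt[unit_id == .u & kind == .k]
  if (nrow(dt) == 0) stop("no trials for this unit/kind", call. = FALSE)
  have <- unique(dt[, .(freq_hz, spl_db)])
  need <- data.table::CJ(freq_hz = grid$frequencies, spl_db = grid$spls)
  miss <- need[!have, on = c("freq_hz", "spl_db")]
  if (nrow(miss) > 0)
    stop("missing conditions: ",
         paste(sprintf("%g Hz/%g dB", miss$freq_hz, miss$spl_db),
               collapse = ", "), call. = FALSE)
  dur_s <- diff(window) / 1000
  avg <- dt[, .(rate = mean(n) / dur_s), by = .(freq_hz, spl_db)]
  m <- matrix(0, length(grid$frequencies), length(grid$spls),
              dimnames = list(grid$frequencies, grid$spls))
  m[cbind(match(avg$freq_hz, grid$frequencies),
          match(avg$spl_db, grid$spls))] <- avg$rate
  mx <- max(m)
  structure(list(
    rates = m, norm = if (mx > 0) m / mx else m, max_rate = mx,
    degenerate = mx <= 0,
    trial_counts = as.data.frame(dt[, .(freq_hz, spl_db, trial, n)]),
    unit_id = unit, kind = kind, window = window), class = "fra")
}

#' Detect auditory-responsive units
#'
#' Two-way ANOVA (frequency x amplitude) on the per-trial response-window
#' spike counts, followed by per-frequency one-way amplitude ANOVAs with
#' Bonferroni correction across the frequency bands. A unit is responsive
#' when at least one frequency shows a corrected amplitude effect at
#' `alpha`.
#'
#' @param fra An [compute_fra()] object.
#' @param alpha Corrected significance level (default 0.01).
#' @return List with `responsive`, `p_per_freq` (Bonferroni-corrected,
#'   named by frequency), `p_two_way` (amplitude main effect), and
#'   `degenerate` (zero variance everywhere).
#' @export
detect_responsive <- function(fra, alpha = 0.01) {
  tc <- fra$trial_counts
  if (var(tc$n) == 0) {
    p <- setNames(rep(NA_real_, length(unique(tc$freq_hz))),
                  sort(unique(tc$freq_hz)))
    return(list(responsive = FALSE, p_per_freq = p, p_two_way = NA_real_,
                degenerate = TRUE))
  }
  f <- factor(tc$freq_hz)
  a <- factor(tc$spl_db)
  tw <- anova(aov(tc$n ~ f * a))
  p_amp <- tw["a", "Pr(>F)"]
  freqs <- levels(f)
  p_raw <- vapply(freqs, function(fq) {
    sel <- tc$freq_hz == as.numeric(fq)
    y <- tc$n[sel]
    g <- factor(tc$spl_db[sel])
    if (var(y) == 0) return(1)
    oneway.test(y ~ g, var.equal = TRUE)$p.value
  }, 0)
  p_adj <- pmin(p_raw * length(freqs), 1)
  names(p_adj) <- freqs
  list(responsive = any(p_adj < alpha, na.rm = TRUE), p_per_freq = p_adj,
       p_two_way = p_amp, degenerate = FALSE)
}

#' Fit the log-normal rate-level function at one frequency
#'
#' Bounded nonlinear least squares of [ln_rate_level()] to (unit-normalized)
#' trial-averaged rates against SPL, with all parameters strictly positive
#' and upper bounds `[150, 20, 10, 0.4]` for `(E, mu, sigma, B)`.
#' Initialization is multi-start: structured data-driven starts (a ladder
#' of dispersions with the log-center solved from the data's half-range
#' crossing) plus seeded random starts over the bounded box; the best
#' coefficient of determination wins, ties broken by the smaller `E`.
#'
#' @param spl SPL values (dB).
#' @param rate Normalized trial-averaged rates (same length).
#' @param n_starts Number of multi-start draws.
#' @param upper Upper bounds for `(E, mu, sigma, B)`.
#' @param seed Seed for the start draws.
#' @return Object of class `rate_level_fit`: list with `E`, `mu`, `sigma`,
#'   `B`, `r_squared`, `converged`, `spl`, `rate`.
#' @export
fit_rate_level <- function(spl, rate, n_starts = 8,
                           upper = c(150, 20, 10, 0.4), seed = 1L) {
  if (length(spl) < 4) stop("need >= 4 SPL points", call. = FALSE)
  lower <- c(1e-6, 1e-6, 1e-6, 1e-6)
  dat <- data.frame(x = spl, y = rate)
  sst <- sum((rate - mean(rate))^2)
  # structured data-driven starts: a ladder of dispersions, mu solved so the
  # starting curve's C50 matches the data's half-range crossing, E scaled to
  # the data maximum; plus seeded random starts over the bounded box
  b0 <- min(max(min(rate), 1e-3), upper[4] - 1e-3)
  rng <- max(rate) - b0
  xs <- sort(spl)
  ro <- rate[order(spl)]
  cross <- which(ro >= b0 + 0.5 * rng)[1]
  c50_guess <- if (is.na(cross) || rng <= 0) median(spl) else xs[cross]
  structured <- list()
  for (s0 in c(0.15, 0.22, 0.3, 0.4, 0.6)) {
    mu0 <- tryCatch(ln_mu_for_c50(c50_guess, s0), error = function(e) NA)
    if (!is.finite(mu0)) next
    # scale E so the curve's global peak matches the data range
    e0 <- max(rng, 0.05) * s0 * sqrt(2 * pi) * exp(mu0 - s0^2 / 2)
    structured[[length(structured) + 1L]] <-
      list(E = min(e0, upper[1] * 0.99), mu = min(mu0, upper[2] * 0.99),
           sigma = s0, B = b0)
  }
  rand <- local_seed_eval(seed, lhs::randomLHS(max(n_starts - 5, 3), 4))
  random_starts <- lapply(seq_len(nrow(rand)), function(i) {
    s <- rand[i, ]
    list(E = 0.5 + s[1] * 120,
         mu = log(min(spl)) + s[2] * (log(max(spl)) + 1 - log(min(spl))),
         sigma = 0.1 + s[3] * 2.4,
         B = 1e-3 + s[4] * (upper[4] - 2e-3))
  })
  start_list <- c(structured, random_starts)
  best <- NULL
  for (st in start_list) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ ln_rate_level(x, E, mu, sigma, B), data = dat, start = st,
        lower = lower, upper = c(upper[1], upper[2], upper[3], upper[4]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    r2 <- if (sst > 0) 1 - sum(residuals(fit)^2) / sst else NA_real_
    cand <- c(as.list(coef(fit)), list(r2 = r2))
    if (is.null(best) || isTRUE(cand$r2 > best$r2 + 1e-12) ||
        (isTRUE(abs(cand$r2 - best$r2) <= 1e-12) &&
         isTRUE(cand$E < best$E))) best <- cand
  }
  if (is.null(best)) {
    return(structure(list(E = NA_real_, mu = NA_real_, sigma = NA_real_,
                          B = NA_real_, r_squared = NA_real_,
                          converged = FALSE, spl = spl, rate = rate),
                     class = "rate_level_fit"))
  }
  structure(list(E = best$E, mu = best$mu, sigma = best$sigma, B = best$B,
                 r_squared = best$r2, converged = TRUE, spl = spl,
                 rate = rate), class = "rate_level_fit")
}

#' @export
predict.rate_level_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$spl else newdata
  ln_rate_level(x, object$E, object$mu, object$sigma, object$B)
}

#' Derive C50, half-width and monotonicity from a rate-level fit
#'
#' C50 is located by root-finding on the fitted curve over the evaluation
#' domain as the SPL where the curve first reaches 50% of its
#' baseline-to-maximum range. The half-width is the SPL extent where the
#' curve exceeds half its maximum; when the curve is still above half-max at
#' the domain's upper edge the half-width is infinite and the unit is
#' monotonic at that frequency (O-shaped otherwise). The domain extends
#' beyond the tested SPL range on purpose, so monotonic and O-shaped
#' profiles can be told apart.
#'
#' @param fit A [fit_rate_level()] object.
#' @param domain Evaluation interval in dB (default 0-100).
#' @return List with `c50`, `hw`, `monotonic`, `rmax` (fitted maximum over
#'   the domain), `peak_spl`, `defined` (FALSE when the fit failed or the
#'   curve never reaches half-range).
#' @export
derive_sensitivity <- function(fit, domain = c(0, 100)) {
  if (!isTRUE(fit$converged))
    return(list(c50 = NA_real_, hw = NA_real_, monotonic = NA,
                rmax = NA_real_, peak_spl = NA_real_, defined = FALSE))
  lm_ <- ln_curve_landmarks(fit$E, fit$mu, fit$sigma, fit$B, domain)
  list(c50 = lm_$c50, hw = lm_$hw, monotonic = lm_$monotonic,
       rmax = lm_$rmax, peak_spl = lm_$peak_spl,
       defined = is.finite(lm_$c50))
}

#' Selection criteria and characteristic frequency for one unit
#'
#' Applies the four per-frequency criteria: (1) fit `R^2 > 0.7`; (2) fitted
#' maximum at least 50% of the unit-wide maximum response; (3) frequency
#' selectivity: fewer than `max_side_bands` contiguous neighboring bands on
#' each side whose response at the candidate's best SPL exceeds half the
#' candidate's response there (an SPL-domain alternative, `hw <
#' hw_max_db`, is available via `width_mode = "spl"`); (4) Bonferroni-
#' corrected amplitude-effect p below `alpha`. An automated atypical-fit
#' filter excludes frequencies whose fitted maximum exceeds the observed
#' maximum by more than 50% or whose C50 lies outside the tested SPL range
#' by more than 10 dB. The characteristic frequency (CF) is the
#' criterion-passing frequency with the lowest C50.
#'
#' @param fits data.frame with one row per frequency: `freq_hz`,
#'   `r_squared`, `rmax`, `c50`, `hw`, `monotonic`, `peak_spl`, `defined`.
#' @param p_per_freq Named corrected p-values from [detect_responsive()].
#' @param fra The unit's [compute_fra()] object (normalized responses are
#'   used for the selectivity criterion).
#' @param r2_min,rmax_frac,alpha Criterion thresholds.
#' @param width_mode `"frequency"` (default) or `"spl"`.
#' @param max_side_bands,hw_max_db Width-criterion parameters.
#' @param spl_margin_db Atypical-filter C50 margin outside the tested range.
#' @return List with `tuning` (one-row data.frame: unit_id, kind, cf_hz,
#'   c50_at_cf, o_shaped, n_passing) and `fits` (the input with criterion
#'   flag columns added).
#' @export
select_characteristic_frequency <- function(fits, p_per_freq, fra,
                                            r2_min = 0.7, rmax_frac = 0.5,
                                            alpha = 0.01,
                                            width_mode = c("frequency",
                                                           "spl"),
                                            max_side_bands = 2,
                                            hw_max_db = 40,
                                            spl_margin_db = 10) {
  width_mode <- match.arg(width_mode)
  freqs <- as.numeric(rownames(fra$norm))
  spls <- as.numeric(colnames(fra$norm))
  fits <- fits[order(fits$freq_hz), , drop = FALSE]
  unit_max <- max(fra$norm)  # 1 unless degenerate
  p <- p_per_freq[as.character(fits$freq_hz)]
  crit_r2 <- !is.na(fits$r_squared) & fits$r_squared > r2_min
  crit_rmax <- !is.na(fits$rmax) & fits$rmax >= rmax_frac * unit_max
  crit_p <- !is.na(p) & p < alpha
  atypical <- (!is.na(fits$rmax) & fits$rmax > 1.5 * unit_max) |
    (!is.na(fits$c50) & (fits$c50 < min(spls) - spl_margin_db |
                           fits$c50 > max(spls) + spl_margin_db))
  crit_width <- logical(nrow(fits))
  for (i in seq_len(nrow(fits))) {
    if (!isTRUE(fits$defined[i])) { crit_width[i] <- FALSE; next }
    if (width_mode == "spl") {
      crit_width[i] <- is.finite(fits$hw[i]) && fits$hw[i] < hw_max_db ||
        !is.finite(fits$hw[i]) && hw_max_db == Inf
      if (!is.finite(fits$hw[i])) crit_width[i] <- FALSE
      next
    }
    # frequency-selectivity reading: at this frequency's best tested SPL,
    # count contiguous neighbor bands whose observed normalized response
    # exceeds half of this frequency's response there
    j <- which.min(abs(spls - fits$peak_spl[i]))
    col <- fra$norm[, j]
    thr <- 0.5 * col[i]
    if (thr <= 0) { crit_width[i] <- FALSE; next }
    n_left <- 0
    k <- i - 1
    while (k >= 1 && col[k] > thr) { n_left <- n_left + 1; k <- k - 1 }
    n_right <- 0
    k <- i + 1
    while (k <= length(col) && col[k] > thr) {
      n_right <- n_right + 1; k <- k + 1
    }
    crit_width[i] <- n_left < max_side_bands && n_right < max_side_bands
  }
  pass <- crit_r2 & crit_rmax & crit_p & crit_width & !atypical &
    fits$defined
  fits$crit_r2 <- crit_r2; fits$crit_rmax <- crit_rmax
  fits$crit_p <- crit_p; fits$crit_width <- crit_width
  fits$atypical <- atypical; fits$passing <- pass
  if (!any(pass)) {
    tuning <- data.frame(unit_id = fra$unit_id, kind = fra$kind,
                         cf_hz = NA_real_, c50_at_cf = NA_real_,
                         o_shaped = NA, n_passing = 0L,
                         stringsAsFactors = FALSE)
  } else {
    i_cf <- which(pass)[which.min(fits$c50[pass])]
    tuning <- data.frame(unit_id = fra$unit_id, kind = fra$kind,
                         cf_hz = fits$freq_hz[i_cf],
                         c50_at_cf = fits$c50[i_cf],
                         o_shaped = !fits$monotonic[i_cf],
                         n_passing = sum(pass), stringsAsFactors = FALSE)
  }
  list(tuning = tuning, fits = fits)
}

#' Frequency tuning bandwidth in bands
#'
#' Mode `"above_C50_10dB"` counts the criterion-passing frequency bands,
#' contiguous around the CF, whose C50 is below the CF's C50 + 10 dB. Mode
#' `"fixed_amplitude"` counts, at one SPL, the bands whose observed
#' normalized response exceeds half the maximum response at that SPL.
#'
#' @param tuning One-row tuning data.frame from
#'   [select_characteristic_frequency()].
#' @param fits The per-frequency fit table with criterion flags.
#' @param fra The unit's FRA (needed for `"fixed_amplitude"`).
#' @param mode Bandwidth mode.
#' @param spl_db SPL for `"fixed_amplitude"` mode.
#' @param margin_db Margin above the CF's C50 (default 10 dB).
#' @return Integer band count (NA when the CF is undefined).
#' @export
tuning_bandwidth <- function(tuning, fits, fra = NULL,
                             mode = c("above_C50_10dB", "fixed_amplitude"),
                             spl_db = NULL, margin_db = 10) {
  mode <- match.arg(mode)
  if (mode == "fixed_amplitude") {
    stopifnot(!is.null(fra), !is.null(spl_db))
    spls <- as.numeric(colnames(fra$norm))
    j <- which.min(abs(spls - spl_db))
    col <- fra$norm[, j]
    if (max(col) <= 0) return(NA_integer_)
    return(sum(col > 0.5 * max(col)))
  }
  if (is.na(tuning$cf_hz)) return(NA_integer_)
  fits <- fits[order(fits$freq_hz), , drop = FALSE]
  i_cf <- match(tuning$cf_hz, fits$freq_hz)
  cutoff <- tuning$c50_at_cf + margin_db
  ok <- fits$passing & !is.na(fits$c50) & fits$c50 < cutoff
  n <- 1L
  k <- i_cf - 1L
  while (k >= 1 && ok[k]) { n <- n + 1L; k <- k - 1L }
  k <- i_cf + 1L
  while (k <= nrow(fits) && ok[k]) { n <- n + 1L; k <- k + 1L }
  n
}

#' Full tuning analysis for a population of units
#'
#' Runs, per unit and stimulus kind: FRA construction, responsiveness
#' detection, per-frequency log-normal fits, sensitivity extraction, the
#' selection criteria and CF assignment, and the 10-dB-above-C50 bandwidth.
#'
#' @param spikes Long spike table.
#' @param grid Stimulus grid.
#' @param kinds Kinds to analyze.
#' @param window Response window (ms).
#' @param domain C50 evaluation domain (dB).
#' @param seed Seed for fit multi-starts.
#' @param ... Passed to [select_characteristic_frequency()].
#' @return List with `tuning` (one row per unit x kind), `fits` (one row per
#'   unit x kind x frequency), and `fra` (named list of FRA objects).
#' @export
analyze_tuning <- function(spikes, grid, kinds = grid$kinds,
                           window = c(5, 95), domain = c(0, 100),
                           seed = 1L, ...) {
  counts <- spike_count_table(spikes, grid, window, kinds)
  units <- unique(spikes$unit_id)
  tun_rows <- list(); fit_rows <- list(); fras <- list()
  for (u in units) {
    for (k in kinds) {
      fra <- compute_fra(counts, grid, u, k, window)
      fras[[paste(u, k, sep = ".")]] <- fra
      resp <- detect_responsive(fra)
      freqs <- grid$frequencies
      per_freq <- lapply(seq_along(freqs), function(i) {
        rate <- fra$norm[i, ]
        fit <- fit_rate_level(grid$spls, rate,
                              seed = child_seed(seed, i))
        sens <- derive_sensitivity(fit, domain)
        data.frame(unit_id = u, kind = k, freq_hz = freqs[i],
                   E = fit$E, mu = fit$mu, sigma = fit$sigma, B = fit$B,
                   r_squared = fit$r_squared, rmax = sens$rmax,
                   c50 = sens$c50, hw = sens$hw,
                   monotonic = sens$monotonic, peak_spl = sens$peak_spl,
                   defined = sens$defined, stringsAsFactors = FALSE)
      })
      fits <- do.call(rbind, per_freq)
      sel <- select_characteristic_frequency(fits, resp$p_per_freq, fra,
                                             ...)
      tun <- sel$tuning
      tun$responsive <- resp$responsive
      tun$bandwidth_10db <- tuning_bandwidth(tun, sel$fits)
      tun_rows[[length(tun_rows) + 1L]] <- tun
      fit_rows[[length(fit_rows) + 1L]] <- sel$fits
    }
  }
  list(tuning = do.call(rbind, tun_rows),
       fits = do.call(rbind, fit_rows), fra = fras)
}

#' Responsive-unit pool without rate-level fitting
#'
#' Runs only the responsiveness detection (two-way ANOVA plus Bonferroni-
#' corrected per-frequency amplitude tests) for every unit, skipping the
#' log-normal fits. Intended for decoding workflows, which need the
#' responsive pool but not the tuning parameters.
#'
#' @param spikes Long spike table.
#' @param grid Stimulus grid.
#' @param kind Stimulus kind.
#' @param alpha Corrected significance level.
#' @param window Response window (ms).
#' @return Character vector of responsive unit ids.
#' @export
responsive_pool <- function(spikes, grid, kind, alpha = 0.01,
                            window = c(5, 95)) {
  counts <- spike_count_table(spikes, grid, window, kind)
  dt <- data.table::as.data.table(counts)
  units <- unique(dt$unit_id)
  ok <- vapply(units, function(u) {
    .u <- u
    tc <- as.data.frame(dt[unit_id == .u, .(freq_hz, spl_db, trial, n)])
    fra <- list(trial_counts = tc)
    detect_responsive(fra, alpha)$responsive
  }, logical(1))
  units[ok]
}
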