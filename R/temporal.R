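# PSTH peak latency / peak rate and ISI-decay time constants.

#' Best stimulus condition for a unit
#'
#' The SPL (at the unit's CF) eliciting the highest trial-averaged response
#' in the analysis window.
#'
#' @param counts Count table from [spike_count_table()].
#' @param unit Unit id.
#' @param kind Stimulus kind.
#' @param cf_hz The unit's characteristic frequency.
#' @return List with `freq_hz`, `spl_db`, `mean_count`.
#' @export
best_condition <- function(counts, unit, kind, cf_hz) {
  .u <- unit; .k <- kind
  dt <- data.table::as.data.table(counts)
  dt <- dt[unit_id == .u & kind == .k & freq_hz == cf_hz]
  if (nrow(dt) == 0) stop("no trials at the CF", call. = FALSE)
  avg <- dt[, .(m = mean(n)), by = spl_db]
  i <- which.max(avg$m)
  list(freq_hz = cf_hz, spl_db = avg$spl_db[i], mean_count = avg$m[i])
}

#' Peristimulus time histogram with peak latency
#'
#' Trial-averaged firing rate in fixed bins over a stimulus-locked span.
#' The peak rate is the maximum bin rate; latency is reported at the peak
#' bin's center, with ties broken by the earliest bin.
#'
#' @param spikes Long spike table.
#' @param unit,kind,freq_hz,spl_db Condition selector.
#' @param bin_ms Bin width (default 5 ms).
#' @param span_ms Analysis span relative to onset.
#' @param n_trials Trials per condition (rate denominator).
#' @return Object of class `psth`: list with `time_ms` (bin centers),
#'   `rate` (sp/s), `peak_rate`, `latency_ms`, `no_spikes` flag.
#' @export
compute_psth <- function(spikes, unit, kind, freq_hz, spl_db, bin_ms = 5,
                         span_ms = c(0, 150), n_trials = 15) {
  .u <- unit; .k <- kind; .f <- freq_hz; .s <- spl_db
  dt <- data.table::as.data.table(spikes)
  sel <- dt[unit_id == .u & kind == .k & freq_hz == .f & spl_db == .s]
  breaks <- seq(span_ms[1], span_ms[2], by = bin_ms)
  centers <- head(breaks, -1) + bin_ms / 2
  t <- sel$spike_ms[sel$spike_ms >= span_ms[1] & sel$spike_ms < span_ms[2]]
  if (length(t) == 0) {
    return(structure(list(time_ms = centers,
                          rate = rep(0, length(centers)),
                          peak_rate = NA_real_, latency_ms = NA_real_,
                          no_spikes = TRUE, unit_id = unit, kind = kind),
                     class = "psth"))
  }
  h <- tabulate(findInterval(t, breaks, rightmost.closed = FALSE),
                nbins = length(centers))
  rate <- h / n_trials / (bin_ms / 1000)
  i <- which.max(rate)  # which.max takes the earliest maximum
  structure(list(time_ms = centers, rate = rate, peak_rate = rate[i],
                 latency_ms = centers[i], no_spikes = FALSE,
                 unit_id = unit, kind = kind), class = "psth")
}

#' Fit a single-exponential decay to the ISI distribution
#'
#' Within-trial intervals between consecutive spikes shorter than 30 ms are
#' pooled across the trials of one condition, binned at 1 ms over 0-30 ms
#' and normalized to a probability mass per bin. The density is fit with
#' `A * exp(-t / tau) + C` (`t`, `tau` in seconds) by bounded nonlinear
#' least squares with initial values `[1, 1, 1]`, lower bounds `[0, 0, 0]`
#' and upper bounds `[Inf, 1, Inf]`. Fits are conventionally kept when
#' `R^2 > 0.7`.
#'
#' @param spikes Long spike table.
#' @param unit,kind,freq_hz,spl_db Condition selector.
#' @param max_isi_ms ISI ceiling (default 30 ms).
#' @param bin_ms Histogram bin (default 1 ms).
#' @param min_isi Minimum pooled ISI count required to attempt a fit.
#' @return Object of class `isi_fit`: list with `A`, `tau_s`, `C`,
#'   `r_squared`, `n_isi`, `density`, `t_s` (bin centers, s), `ok`
#'   (fit attempted and converged), `degenerate` (single-bin histogram).
#' @export
fit_isi_decay <- function(spikes, unit, kind, freq_hz, spl_db,
                          max_isi_ms = 30, bin_ms = 1, min_isi = 30) {
  .u <- unit; .k <- kind; .f <- freq_hz; .s <- spl_db
  dt <- data.table::as.data.table(spikes)
  sel <- dt[unit_id == .u & kind == .k & freq_hz == .f & spl_db == .s]
  data.table::setorder(sel, trial, spike_ms)
  isi <- sel[, .(d = diff(spike_ms)), by = trial]$d
  isi <- isi[isi > 0 & isi < max_isi_ms]
  out <- list(A = NA_real_, tau_s = NA_real_, C = NA_real_,
              r_squared = NA_real_, n_isi = length(isi), density = NULL,
              t_s = NULL, ok = FALSE, degenerate = FALSE)
  if (length(isi) < min_isi) return(structure(out, class = "isi_fit"))
  breaks <- seq(0, max_isi_ms, by = bin_ms)
  h <- tabulate(findInterval(isi, breaks, rightmost.closed = FALSE),
                nbins = length(breaks) - 1)
  if (sum(h > 0) < 2) {
    out$degenerate <- TRUE
    return(structure(out, class = "isi_fit"))
  }
  dens <- h / sum(h)  # probability mass per 1 ms bin
  t_s <- (head(breaks, -1) + bin_ms / 2) / 1000
  dat <- data.frame(t = t_s, y = dens)
  sst <- sum((dens - mean(dens))^2)
  one_fit <- function(st) tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t / tau) + C, data = dat, start = st,
                      lower = c(0, 0, 0), upper = c(Inf, 1, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  # canonical init [1, 1, 1]; a data-scaled fallback start guards against
  # the flat local optimum when the histogram scale is far from unity
  fits <- list(one_fit(list(A = 1, tau = 1, C = 1)),
               one_fit(list(A = max(dens), tau = 0.01,
                            C = max(min(dens), 1e-6))))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) return(structure(out, class = "isi_fit"))
  r2s <- vapply(fits, function(f)
    if (sst > 0) 1 - sum(residuals(f)^2) / sst else NA_real_, 0)
  fit <- fits[[which.max(r2s)]]
  out$A <- coef(fit)[["A"]]; out$tau_s <- coef(fit)[["tau"]]
  out$C <- coef(fit)[["C"]]
  out$r_squared <- max(r2s)
  out$density <- dens; out$t_s <- t_s; out$ok <- TRUE
  structure(out, class = "isi_fit")
}

#' Temporal dynamics at the best stimulus for a set of units
#'
#' Convenience wrapper: for each tuned unit x kind, finds the best stimulus
#' (highest mean response at the CF), computes PSTH peak latency / peak rate
#' and the ISI-decay time constant there.
#'
#' @param spikes Long spike table.
#' @param grid Stimulus grid.
#' @param tuning Tuning table from [analyze_tuning()] (rows with defined
#'   CF are used).
#' @param window Response window for best-condition selection (ms).
#' @param r2_min Keep threshold for ISI fits.
#' @return data.frame with one row per unit x kind: best condition, latency,
#'   peak rate, tau (s) and ISI-fit quality.
#' @export
temporal_dynamics <- function(spikes, grid, tuning, window = c(5, 95),
                              r2_min = 0.7) {
  counts <- spike_count_table(spikes, grid, window)
  rows <- list()
  tun <- tuning[!is.na(tuning$cf_hz), , drop = FALSE]
  for (i in seq_len(nrow(tun))) {
    u <- tun$unit_id[i]; k <- tun$kind[i]; cf <- tun$cf_hz[i]
    bc <- best_condition(counts, u, k, cf)
    ps <- compute_psth(spikes, u, k, cf, bc$spl_db,
                       n_trials = grid$n_trials)
    isi <- fit_isi_decay(spikes, u, k, cf, bc$spl_db)
    rows[[i]] <- data.frame(
      unit_id = u, kind = k, cf_hz = cf, best_spl_db = bc$spl_db,
      latency_ms = ps$latency_ms, peak_rate = ps$peak_rate,
      tau_s = isi$tau_s, isi_r_squared = isi$r_squared,
      n_isi = isi$n_isi,
      tau_kept = isTRUE(isi$ok) && isTRUE(isi$r_squared > r2_min),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
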