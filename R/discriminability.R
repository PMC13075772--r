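# Trial-wise two-alternative frequency discriminability: Pc and d-prime
# between the CF and adjacent frequency bands, as a function of SPL
# relative to C50.

#' Convert a probability correct to d-prime
#'
#' `d' = sqrt(2) * qnorm(Pc)`, the two-alternative forced-choice relation.
#'
#' @param pc Probability correct in (0, 1).
#' @return d-prime.
#' @export
pc_to_dprime <- function(pc) sqrt(2) * qnorm(pc)

#' Probability correct from trial-wise decision-variable counts
#'
#' `Pc = (n_pos + 0.5 * (1 + n_zero)) / (n_total + 1)`: trials where the
#' decision variable is exactly zero carry no information and receive half
#' credit, and the +1 smoothing keeps Pc strictly inside (0, 1).
#'
#' @param n_pos Trials with `D > 0`.
#' @param n_zero Trials with `D = 0`.
#' @param n_total All trials.
#' @return Pc.
#' @export
pc_statistic <- function(n_pos, n_zero, n_total) {
  (n_pos + 0.5 * (1 + n_zero)) / (n_total + 1)
}

#' Single-unit CF-versus-adjacent discriminability at one SPL
#'
#' Models the unit as the observer in a two-alternative task: per trial,
#' the evoked-minus-baseline count at the CF is compared with the
#' evoked-minus-baseline count at an adjacent frequency band
#' (`D = dCF - dAdj`; trials paired by acquisition index). Evoked counts
#' are taken 5-55 ms post onset and baseline counts in the final 50 ms
#' before onset. `Pc` is computed by [pc_statistic()] and converted by
#' [pc_to_dprime()]; with both neighbors available d-prime is averaged over
#' the left and right comparisons, at a grid border only the available side
#' is used.
#'
#' @param spikes Long spike table.
#' @param grid Stimulus grid.
#' @param unit Unit id.
#' @param kind Stimulus kind.
#' @param cf_hz The unit's CF (a grid frequency).
#' @param spl_db Tested SPL (must be on the grid).
#' @param evoked_window,baseline_window Count windows (ms re onset).
#' @param pairing `"index"` (default) pairs trial k at the CF with trial k
#'   at the adjacent band; `"permute"` averages Pc over `n_perm` seeded
#'   shuffles of the adjacent trials.
#' @param n_perm,seed Permutation-mode parameters.
#' @return One-row data.frame: unit_id, kind, spl_db, n_pos, n_zero, n_tot
#'   (summed over the sides used), pc (mean over sides), dprime (mean over
#'   sides), n_sides.
#' @export
trial_discriminability <- function(spikes, grid, unit, kind, cf_hz, spl_db,
                                   evoked_window = c(5, 55),
                                   baseline_window = c(-50, 0),
                                   pairing = c("index", "permute"),
                                   n_perm = 100, seed = 1L) {
  pairing <- match.arg(pairing)
  if (!spl_db %in% grid$spls) stop("SPL not on the grid", call. = FALSE)
  i_cf <- match(cf_hz, grid$frequencies)
  if (is.na(i_cf)) stop("CF not on the grid", call. = FALSE)
  adj <- c(i_cf - 1L, i_cf + 1L)
  adj <- adj[adj >= 1 & adj <= length(grid$frequencies)]
  .u <- unit; .k <- kind; .s <- spl_db
  dt <- data.table::as.data.table(spikes)
  dt <- dt[unit_id == .u & kind == .k & spl_db == .s]
  count_in <- function(freq, win) {
    .f <- freq
    sel <- dt[freq_hz == .f & spike_ms >= win[1] & spike_ms < win[2],
              .(n = .N), by = trial]
    v <- integer(grid$n_trials)
    v[sel$trial] <- sel$n
    v
  }
  d_cf <- count_in(cf_hz, evoked_window) - count_in(cf_hz, baseline_window)
  per_side <- lapply(adj, function(j) {
    f_adj <- grid$frequencies[j]
    d_adj <- count_in(f_adj, evoked_window) -
      count_in(f_adj, baseline_window)
    one <- function(d_adj_perm) {
      D <- d_cf - d_adj_perm
      c(n_pos = sum(D > 0), n_zero = sum(D == 0), n_tot = length(D))
    }
    if (pairing == "index") {
      cnt <- one(d_adj)
    } else {
      cnt <- local_seed_eval(seed, {
        reps <- replicate(n_perm, one(sample(d_adj)))
        rowMeans(reps)
      })
    }
    pc <- pc_statistic(cnt[["n_pos"]], cnt[["n_zero"]], cnt[["n_tot"]])
    c(cnt, pc = pc, dprime = pc_to_dprime(pc))
  })
  m <- do.call(rbind, per_side)
  data.frame(unit_id = unit, kind = kind, spl_db = spl_db,
             n_pos = sum(m[, "n_pos"]), n_zero = sum(m[, "n_zero"]),
             n_tot = sum(m[, "n_tot"]), pc = mean(m[, "pc"]),
             dprime = mean(m[, "dprime"]), n_sides = nrow(m),
             stringsAsFactors = FALSE)
}

#' d-prime versus level relative to C50 for tuned units
#'
#' Computes [trial_discriminability()] at every tested SPL for each tuned
#' unit and re-indexes the SPL axis by the offset from the unit's C50,
#' snapped to the 5 dB stimulus grid (ties toward the lower SPL).
#'
#' @param spikes Long spike table.
#' @param grid Stimulus grid.
#' @param tuning Tuning table with `cf_hz` and `c50_at_cf` per unit x kind.
#' @param ... Passed to [trial_discriminability()].
#' @return data.frame with one row per unit x kind x SPL: the
#'   discriminability fields plus `offset_db`.
#' @export
dprime_vs_level <- function(spikes, grid, tuning, ...) {
  tun <- tuning[!is.na(tuning$cf_hz) & !is.na(tuning$c50_at_cf), ,
                drop = FALSE]
  step <- min(diff(sort(grid$spls)))
  rows <- list()
  for (i in seq_len(nrow(tun))) {
    u <- tun$unit_id[i]; k <- tun$kind[i]
    # snap C50 to the SPL grid step; ties toward the lower SPL
    c50s <- step * ceiling(tun$c50_at_cf[i] / step - 0.5)
    for (s in grid$spls) {
      r <- trial_discriminability(spikes, grid, u, k, tun$cf_hz[i], s, ...)
      r$c50_snapped_db <- c50s
      r$offset_db <- s - c50s
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}

#' Population mean d-prime by C50 offset
#'
#' @param dvl Output of [dprime_vs_level()].
#' @return data.frame per kind x offset: mean d-prime, SEM and unit count.
#' @export
dprime_curve <- function(dvl) {
  dt <- data.table::as.data.table(dvl)
  out <- dt[, .(mean_dprime = mean(dprime), sem = sd(dprime) / sqrt(.N),
                n_units = .N), by = .(kind, offset_db)]
  data.table::setorder(out, kind, offset_db)
  as.data.frame(out)
}
utils::globalVariables(c("dprime", "offset_db"))
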