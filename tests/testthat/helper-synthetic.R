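# Shared fixtures, built once per session and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

ref_grid <- function() memo("grid", build_stimulus_grid())

# small reference population shared by FRA / temporal / discriminability
# tests (30 units keeps the per-file cost low)
small_pop <- function() memo("small_pop", {
  generate_unit_population(unit_config(n_units = 30), ref_grid(),
                           seed = 4021)
})

small_tuning <- function() memo("small_tuning", {
  suppressWarnings(analyze_tuning(small_pop()$spikes, ref_grid(),
                                  seed = 77))
})

# hand-built spike table: one unit, deterministic spike times per trial
synth_spikes <- function(times_by_cond, n_trials = 15) {
  rows <- list()
  for (i in seq_along(times_by_cond)) {
    cond <- times_by_cond[[i]]
    for (tr in seq_len(n_trials)) {
      tt <- cond$times
      if (length(tt) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = cond$unit %||% "u1", penetration_id = 1L,
        dist_from_tip_um = 0, trial = tr, kind = cond$kind,
        freq_hz = cond$freq, spl_db = cond$spl, spike_ms = tt,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
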