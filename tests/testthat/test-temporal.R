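# PSTH latency and ISI-decay estimation.

test_that("PSTH latency reports the peak bin center, earliest on ties", {
  sp <- synth_spikes(list(list(kind = "PT", freq = 560, spl = 40,
                               times = 12)))
  ps <- compute_psth(sp, "u1", "PT", 560, 40)
  expect_equal(ps$latency_ms, 12.5)
  expect_equal(ps$peak_rate, 15 / 15 / 0.005)
  # exact tie between two bins -> earliest wins
  sp2 <- synth_spikes(list(list(kind = "PT", freq = 560, spl = 40,
                                times = c(12, 22))))
  ps2 <- compute_psth(sp2, "u1", "PT", 560, 40)
  expect_equal(ps2$latency_ms, 12.5)
  # no spikes -> flagged
  sp3 <- synth_spikes(list(list(kind = "PT", freq = 560, spl = 40,
                                times = -50)))
  ps3 <- compute_psth(sp3, "u1", "PT", 560, 40)
  expect_true(ps3$no_spikes)
  expect_true(is.na(ps3$latency_ms))
})

test_that("homogeneous Poisson ISI decay recovers tau = 1/rate", {
  set.seed(4)
  sp <- do.call(rbind, lapply(1:700, function(tr) {
    n <- rpois(1, 100 * 0.35)
    if (n == 0) return(NULL)
    data.frame(unit_id = "h1", penetration_id = 1L, dist_from_tip_um = 0,
               trial = tr, kind = "PT", freq_hz = 560, spl_db = 40,
               spike_ms = sort(runif(n, -100, 250)))
  }))
  f <- fit_isi_decay(sp, "h1", "PT", 560, 40)
  expect_true(f$ok)
  expect_gt(f$r_squared, 0.95)
  expect_equal(f$tau_s, 0.010, tolerance = 0.15)  # ISI density ~ e^(-100 t)
})

test_that("ISI fitting guards: too few ISIs, metronome, tau bound", {
  sp <- synth_spikes(list(list(kind = "PT", freq = 560, spl = 40,
                               times = c(10, 20))), n_trials = 5)
  f <- fit_isi_decay(sp, "u1", "PT", 560, 40)  # 5 ISIs < floor
  expect_false(f$ok)
  expect_equal(f$n_isi, 5)
  # metronomic spiking: all ISIs identical -> single occupied bin
  spm <- synth_spikes(list(list(kind = "PT", freq = 560, spl = 40,
                                times = seq(0, 95, by = 5))), n_trials = 15)
  fm <- fit_isi_decay(spm, "u1", "PT", 560, 40)
  expect_true(fm$degenerate)
  expect_false(fm$ok)
  # tau never exceeds the 1 s bound: near-uniform ISIs push tau upward
  set.seed(9)
  spu <- do.call(rbind, lapply(1:40, function(tr)
    data.frame(unit_id = "u1", penetration_id = 1L, dist_from_tip_um = 0,
               trial = tr, kind = "PT", freq_hz = 560, spl_db = 40,
               spike_ms = cumsum(runif(10, 5, 29)))))
  fu <- fit_isi_decay(spu, "u1", "PT", 560, 40)
  if (fu$ok) expect_lte(fu$tau_s, 1)
})

test_that("latency estimates are invariant to spike-count scaling", {
  # doubling the trial count leaves the expected PSTH shape unchanged
  times <- list(list(kind = "PT", freq = 560, spl = 40,
                     times = c(12, 18, 30)))
  sp1 <- synth_spikes(times, n_trials = 15)
  sp2 <- synth_spikes(times, n_trials = 30)
  p1 <- compute_psth(sp1, "u1", "PT", 560, 40, n_trials = 15)
  p2 <- compute_psth(sp2, "u1", "PT", 560, 40, n_trials = 30)
  expect_equal(p1$latency_ms, p2$latency_ms)
  expect_equal(p1$rate, p2$rate)
})

test_that("fitted ISI tau tracks the generating decay constant", {
  # controlled high-rate population: evoked magnitude fixed so the ISI
  # scale is driven by the decay constant alone
  grid <- ref_grid()
  cfg <- unit_config(n_units = 25, evoked_meanlog = log(150),
                     evoked_sdlog = 0, baseline_meanlog = log(5),
                     baseline_sdlog = 0, tau_pt_sdlog = 0.5)
  pop <- generate_unit_population(cfg, grid, seed = 61)
  gt <- pop$ground_truth
  rows <- list()
  for (i in seq_len(nrow(pop$units))) {
    u <- pop$units$unit_id[i]
    g <- gt[gt$unit_id == u & gt$kind == "PT", ]
    f <- fit_isi_decay(pop$spikes, u, "PT", g$cf_hz, 75)
    if (isTRUE(f$ok) && isTRUE(f$r_squared > 0.7))
      rows[[length(rows) + 1L]] <- c(fit = f$tau_s, true = g$tau_ms)
  }
  m <- do.call(rbind, rows)
  expect_gte(nrow(m), 12)
  expect_gt(cor(m[, "fit"], m[, "true"], method = "spearman"), 0.6)
})

test_that("reference offsets: PT precedes NBN in latency and decay", {
  grid <- ref_grid()
  # latency: measured on the shared small population
  td <- memo("small_temporal", {
    temporal_dynamics(small_pop()$spikes, grid, small_tuning()$tuning)
  })
  m <- merge(td[td$kind == "PT", ], td[td$kind == "NBN", ], by = "unit_id")
  m <- m[is.finite(m$latency_ms.x) & is.finite(m$latency_ms.y), ]
  expect_gte(nrow(m), 8)
  d <- m$latency_ms.y - m$latency_ms.x  # NBN minus PT
  expect_gte(median(d), 0)
  expect_gt(mean(d > 0), mean(d < 0))
  # decay: high-rate controlled population, paired sign test
  cfg <- unit_config(n_units = 30, evoked_meanlog = log(150),
                     evoked_sdlog = 0, baseline_meanlog = log(5),
                     baseline_sdlog = 0)
  pop <- generate_unit_population(cfg, grid, seed = 62)
  gt <- pop$ground_truth
  tau <- sapply(seq_len(nrow(pop$units)), function(i) {
    u <- pop$units$unit_id[i]
    cf <- pop$units$cf_hz[i]
    vapply(c("PT", "NBN"), function(k) {
      f <- fit_isi_decay(pop$spikes, u, k, cf, 75)
      if (isTRUE(f$ok) && isTRUE(f$r_squared > 0.7)) f$tau_s else NA_real_
    }, 0)
  })
  ok <- is.finite(tau["PT", ]) & is.finite(tau["NBN", ])
  expect_gte(sum(ok), 10)
  n_pos <- sum(tau["NBN", ok] > tau["PT", ok])
  p <- binom.test(n_pos, sum(ok), alternative = "greater")$p.value
  expect_lt(p, 0.05)
})
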