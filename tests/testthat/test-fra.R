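# FRA construction, responsiveness ANOVA, log-normal fitting, C50/HW
# extraction, CF selection, bandwidth.

test_that("FRA rates follow count/window arithmetic", {
  grid <- ref_grid()
  # 9 spikes in the window on every trial of one condition -> 100 sp/s
  conds <- list(list(kind = "PT", freq = 560, spl = 40,
                     times = seq(10, 90, by = 10)))
  sp <- synth_spikes(conds)
  counts <- spike_count_table(sp, grid, kinds = "PT")
  fra <- compute_fra(counts, grid, "u1", "PT")
  expect_equal(fra$rates["560", "40"], 9 / 0.09)
  expect_equal(fra$max_rate, 100)
  expect_equal(max(fra$norm), 1)
  expect_false(fra$degenerate)
  # all-zero matrix flagged degenerate
  sp0 <- synth_spikes(list(list(kind = "PT", freq = 560, spl = 40,
                                times = -99)))  # outside window
  fra0 <- compute_fra(spike_count_table(sp0, grid, kinds = "PT"), grid,
                      "u1", "PT")
  expect_true(fra0$degenerate)
  expect_true(all(fra0$rates == 0))
})

test_that("missing conditions are reported as an error", {
  grid <- ref_grid()
  sub <- build_stimulus_grid()
  sub$frequencies <- sub$frequencies[1:3]  # lattice built from fewer conds
  sp <- synth_spikes(list(list(kind = "PT", freq = 560, spl = 40,
                               times = 10)))
  counts <- spike_count_table(sp, sub, kinds = "PT")
  counts <- counts[counts$freq_hz != 800, ]
  expect_error(compute_fra(counts, sub, "u1", "PT"), "missing conditions")
})

test_that("responsiveness: constant counts are never responsive", {
  grid <- ref_grid()
  tc <- expand.grid(freq_hz = grid$frequencies, spl_db = grid$spls,
                    trial = 1:15)
  tc$n <- 3L
  res <- detect_responsive(list(trial_counts = tc))
  expect_false(res$responsive)
  expect_true(res$degenerate)
})

test_that("responsiveness: type-I rate on null units is at most nominal", {
  grid <- ref_grid()
  tc0 <- expand.grid(freq_hz = grid$frequencies, spl_db = grid$spls,
                     trial = 1:15)
  n_sim <- 400
  set.seed(808)
  hits <- 0
  for (i in seq_len(n_sim)) {
    tc <- tc0
    tc$n <- rpois(nrow(tc), 2)
    hits <- hits + detect_responsive(list(trial_counts = tc))$responsive
  }
  # alpha = 0.01 after Bonferroni; allow binomial slack above the nominal
  # 1% (99th percentile of Binomial(400, 0.01) is 9)
  expect_lte(hits, 10)
})

test_that("responsiveness: strongly driven units are detected", {
  grid <- ref_grid()
  cfg <- unit_config(n_units = 1, evoked_meanlog = log(40),
                     evoked_sdlog = 0, baseline_meanlog = log(2),
                     baseline_sdlog = 0)
  hits <- 0
  for (s in 1:15) {
    pop <- generate_unit_population(cfg, grid, seed = 5000 + s)
    counts <- spike_count_table(pop$spikes, grid)
    fra <- compute_fra(counts, grid, pop$units$unit_id[1], "PT")
    hits <- hits + detect_responsive(fra)$responsive
  }
  expect_gte(hits, 14)
  # and a unit with zero evoked gain is (almost) never responsive
  cfg0 <- unit_config(n_units = 1, evoked_meanlog = -Inf, evoked_sdlog = 0)
  pop0 <- generate_unit_population(cfg0, grid, seed = 1)
  counts0 <- spike_count_table(pop0$spikes, grid)
  fra0 <- compute_fra(counts0, grid, pop0$units$unit_id[1], "PT")
  expect_false(detect_responsive(fra0)$responsive)
})

test_that("noiseless log-normal curves are recovered exactly", {
  x <- ref_grid()$spls
  y <- ln_rate_level(x, 50, 4, 0.5, 0.05)
  f <- fit_rate_level(x, y)
  expect_equal(f$E, 50, tolerance = 1e-4)
  expect_equal(f$mu, 4, tolerance = 1e-5)
  expect_equal(f$sigma, 0.5, tolerance = 1e-4)
  expect_equal(f$B, 0.05, tolerance = 1e-5)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  # the fitted curve's peak sits at exp(mu - sigma^2) ~ 42.52 dB (mode of
  # the scaled log-normal, by calculus)
  s <- derive_sensitivity(f)
  expect_equal(s$peak_spl, exp(4 - 0.25), tolerance = 0.2)
  expect_error(fit_rate_level(c(40, 50, 60), c(0, 1, 1)), ">= 4 SPL")
})

test_that("flat data yield an uninformative fit, not a spurious C50", {
  x <- ref_grid()$spls
  f <- fit_rate_level(x, rep(0.2, 8))
  expect_false(isTRUE(f$r_squared > 0.1))
})

test_that("C50 matches an independent bisection oracle to 0.01 dB", {
  pars <- list(c(50, 4, 0.5, 0.05), c(80, 4.6, 0.35, 0.02),
               c(20, 4.2, 0.2, 0.1))
  for (p in pars) {
    f <- structure(list(E = p[1], mu = p[2], sigma = p[3], B = p[4],
                        converged = TRUE), class = "rate_level_fit")
    s <- derive_sensitivity(f, domain = c(0, 100))
    # oracle: dense scan for the maximum, then bisection on the rising limb
    g <- function(x) ln_rate_level(x, p[1], p[2], p[3], p[4])
    xs <- seq(0.1, 100, by = 1e-3)
    vmax <- max(g(xs))
    target <- p[4] + 0.5 * (vmax - p[4])
    lo <- 0.1; hi <- xs[which.max(g(xs))]
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (g(mid) < target) lo <- mid else hi <- mid
    }
    expect_equal(s$c50, (lo + hi) / 2, tolerance = 0.01)
  }
})

test_that("C50 is invariant under positive affine response maps", {
  x <- ref_grid()$spls
  set.seed(21)
  base <- ln_rate_level(x, 60, 4.5, 0.35, 0.05) + rnorm(8, 0, 0.02)
  f1 <- fit_rate_level(x, base, seed = 3)
  s1 <- derive_sensitivity(f1)
  f2 <- fit_rate_level(x, 0.5 * base + 0.02, seed = 3)
  s2 <- derive_sensitivity(f2)
  expect_equal(s1$c50, s2$c50, tolerance = 0.2)
})

test_that("O-shape agrees with the curve's derivative at the domain edge", {
  # narrow sigma: rises then falls inside the domain -> finite half-width
  for (p in list(c(30, 4.2, 0.2, 0.02), c(120, 5, 0.45, 0.02))) {
    f <- structure(list(E = p[1], mu = p[2], sigma = p[3], B = p[4],
                        converged = TRUE), class = "rate_level_fit")
    s <- derive_sensitivity(f, domain = c(0, 100))
    h <- 1e-4
    deriv <- (ln_rate_level(100, p[1], p[2], p[3], p[4]) -
                ln_rate_level(100 - h, p[1], p[2], p[3], p[4])) / h
    if (s$monotonic) {
      expect_true(deriv > 0 || s$rmax > 0.5 *
                    ln_rate_level(100, p[1], p[2], p[3], p[4]))
      expect_true(is.infinite(s$hw))
    } else {
      expect_lt(deriv, 0)
      expect_true(is.finite(s$hw))
    }
  }
})

test_that("CF selection applies the criterion logic", {
  grid <- ref_grid()
  fra <- list(norm = matrix(0.9, 11, 8,
                            dimnames = list(grid$frequencies, grid$spls)),
              unit_id = "u1", kind = "PT")
  # selectivity matrix: make the candidate's column peaked around itself
  fra$norm[, ] <- 0.1
  fra$norm[8, ] <- 1    # 6300 Hz strong
  fra$norm[9, ] <- 0.9  # 9000 Hz strong
  base_fit <- data.frame(
    freq_hz = grid$frequencies, E = 50, mu = 4.5, sigma = 0.4, B = 0.05,
    r_squared = 0.2, rmax = 0.2, c50 = NA_real_, hw = Inf,
    monotonic = TRUE, peak_spl = 75, defined = FALSE)
  fits <- base_fit
  fits[fits$freq_hz == 6300, c("r_squared", "rmax", "c50", "defined")] <-
    list(0.9, 1.0, 50, TRUE)
  fits[fits$freq_hz == 9000, c("r_squared", "rmax", "c50", "defined")] <-
    list(0.9, 0.9, 55, TRUE)
  p <- setNames(rep(1, 11), grid$frequencies)
  p[c("6300", "9000")] <- 0.001
  sel <- select_characteristic_frequency(fits, p, fra)
  expect_equal(sel$tuning$cf_hz, 6300)  # argmin C50 among passing
  expect_equal(sel$tuning$c50_at_cf, 50)
  # best-C50 frequency failing R^2 falls through to the next passing one
  fits2 <- fits
  fits2[fits2$freq_hz == 6300, "r_squared"] <- 0.5
  sel2 <- select_characteristic_frequency(fits2, p, fra)
  expect_equal(sel2$tuning$cf_hz, 9000)
  # no passing frequency -> excluded
  sel3 <- select_characteristic_frequency(base_fit, p, fra)
  expect_true(is.na(sel3$tuning$cf_hz))
  expect_identical(sel3$tuning$n_passing, 0L)
  # atypical-fit filter: fitted max far above the data excludes the band
  fits4 <- fits
  fits4[fits4$freq_hz == 6300, "rmax"] <- 2.0
  sel4 <- select_characteristic_frequency(fits4, p, fra)
  expect_equal(sel4$tuning$cf_hz, 9000)
})

test_that("bandwidth counts bands below C50 + 10 dB around the CF", {
  grid <- ref_grid()
  fits <- data.frame(freq_hz = grid$frequencies, c50 = NA_real_,
                     passing = FALSE)
  # CF at 4500 with C50 50; neighbors 55, 58, 65
  fits$c50[fits$freq_hz == 4500] <- 50
  fits$c50[fits$freq_hz == 3150] <- 55
  fits$c50[fits$freq_hz == 6300] <- 58
  fits$c50[fits$freq_hz == 9000] <- 65
  fits$passing <- !is.na(fits$c50)
  tuning <- data.frame(unit_id = "u1", kind = "PT", cf_hz = 4500,
                       c50_at_cf = 50)
  expect_equal(tuning_bandwidth(tuning, fits), 3)  # 55 and 58 < 60; 65 not
  # single passing frequency -> bandwidth 1
  fits1 <- fits
  fits1$passing <- fits1$freq_hz == 4500
  expect_equal(tuning_bandwidth(tuning, fits1), 1)
  # undefined CF
  expect_true(is.na(tuning_bandwidth(
    data.frame(unit_id = "u1", kind = "PT", cf_hz = NA_real_,
               c50_at_cf = NA_real_), fits)))
})

test_that("Poisson units at known rates reproduce their FRA within error", {
  grid <- ref_grid()
  pop <- small_pop()
  gt <- pop$ground_truth
  counts <- spike_count_table(pop$spikes, grid)
  u <- pop$units$unit_id[1]
  fra <- compute_fra(counts, grid, u, "PT")
  # the strongest condition's rate should be within sampling error of
  # baseline + evoked (binomial/Poisson error at 15 trials)
  g <- gt[gt$unit_id == u & gt$kind == "PT", ]
  top <- max(fra$rates)
  expected_max <- g$baseline_rate + g$evoked_rate
  se <- sqrt(expected_max / (15 * 0.09))
  expect_lt(abs(top - expected_max), 5 * se + 0.15 * expected_max)
})
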