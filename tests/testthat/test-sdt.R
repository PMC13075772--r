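# Signal-detection scoring: trial labels, rates, d-prime, strategy
# regression.

mk_trials <- function(onset, release) {
  data.frame(trial_id = seq_along(onset), animal = 1L, session = 1L,
             press_ms = 0, onset_ms = onset, kind = "PT", spl_db = 53,
             release_ms = release, stringsAsFactors = FALSE)
}

test_that("trial labels follow the window rules", {
  out <- classify_trials(mk_trials(
    onset = c(1500, 1500, 1500, 1500),
    release = c(1800, 2300, NA, 800)), seed = 1)
  expect_equal(as.character(out$label), c("H", "M", "M", "AB"))

  # long-onset trial: the label must be consistent with the drawn virtual
  # window, and the window must close before the true onset
  long <- mk_trials(onset = rep(3000, 200),
                    release = c(rep(1800, 100), rep(NA, 100)))
  outl <- classify_trials(long, seed = 7)
  expect_true(all(outl$virtual_onset_ms + 700 <= outl$onset_ms + 1e-9))
  rel <- long$release_ms
  expected <- ifelse(is.na(rel), "CR",
              ifelse(rel <= outl$virtual_onset_ms, "AB",
              ifelse(rel <= outl$virtual_onset_ms + 700, "FA", "CR")))
  expect_equal(as.character(outl$label), expected)
  expect_true(all(c("FA", "AB") %in% outl$label))  # 1800 straddles windows
})

test_that("every trial gets exactly one label (partition property)", {
  beh <- generate_behavior_sessions(behavior_config(
    n_animals = 3, n_sessions = 2, trials_per_session = 300), seed = 11)
  out <- classify_trials(beh$trials, seed = 12)
  expect_identical(sum(table(out$label)), nrow(beh$trials))
  expect_false(anyNA(out$label))
})

test_that("scoring rejects malformed inputs", {
  expect_error(classify_trials(mk_trials(500, NA)), "onset outside")
  expect_error(classify_trials(mk_trials(1500, -10)), "release at or before")
})

test_that("d-prime and performance match the defining formulas", {
  # symmetric rates: d' = 0 for any common value
  for (p in c(0.2, 0.5, 0.8)) {
    expect_equal(qnorm(p) - qnorm(p), 0)
  }
  # HR 0.9, FAR 0.1: two evaluations of the inverse normal CDF
  counts <- data.frame(label = factor(
    c(rep("H", 9), "M", "FA", rep("CR", 9)),
    levels = c("H", "M", "FA", "CR", "AB")))
  s <- sdt_summary(counts, by = character(0))
  expect_equal(s$HR, 0.9)
  expect_equal(s$FAR, 0.1)
  expect_equal(s$d_prime, qnorm(0.9) - qnorm(0.1), tolerance = 1e-12)
  expect_equal(s$d_prime, 2.563103, tolerance = 1e-6)
  # performance on the printed formula: HT=40, CR=40, FA=10, MS=10 -> 0.8
  counts2 <- data.frame(label = factor(
    c(rep("H", 40), rep("CR", 40), rep("FA", 10), rep("M", 10)),
    levels = c("H", "M", "FA", "CR", "AB")))
  s2 <- sdt_summary(counts2, by = character(0))
  expect_equal(s2$performance, 0.8)
})

test_that("edge rates are corrected and d-prime stays finite", {
  counts <- data.frame(label = factor(
    c(rep("H", 10), rep("CR", 9), "FA"),
    levels = c("H", "M", "FA", "CR", "AB")))
  s <- sdt_summary(counts, by = character(0))
  expect_true(is.finite(s$d_prime))
  expect_equal(s$d_prime, qnorm(10.5 / 11) - qnorm(1.5 / 11),
               tolerance = 1e-12)
  s_raw <- sdt_summary(counts, by = character(0), correction = "none")
  expect_true(is.infinite(s_raw$d_prime))
})

test_that("d-prime is monotone in HR and antitone in FAR", {
  hr <- seq(0.05, 0.95, by = 0.05)
  d_hr <- qnorm(hr) - qnorm(0.1)
  expect_true(all(diff(d_hr) > 0))
  far <- seq(0.05, 0.95, by = 0.05)
  d_far <- qnorm(0.9) - qnorm(far)
  expect_true(all(diff(d_far) < 0))
})

test_that("strategy regression recovers exact fits and flags degeneracy", {
  msr <- c(0.1, 0.3, 0.5, 0.7)
  far <- 0.6 - 0.5 * msr
  r <- strategy_regression(msr, far)
  expect_equal(r$slope, -0.5, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  expect_lt(r$p_value, 0.05)
  rd <- strategy_regression(rep(0.4, 5), runif(5))
  expect_true(rd$degenerate)
  expect_error(strategy_regression(c(0.1, 0.2), c(0.3, 0.2)), "3 animals")
})

test_that("synthetic animals along the strategy axis anticorrelate MSR/FAR", {
  cfg <- behavior_config()  # reference: 8 animals, strategy axis on
  beh <- generate_behavior_sessions(cfg, seed = 2024)
  out <- classify_trials(beh$trials, seed = 2025)
  agg <- sdt_group_summary(sdt_summary(out))
  low <- agg$animal[agg$animal$spl_db == 28, ]
  for (k in c("PT", "NBN")) {
    d <- low[low$kind == k, ]
    r <- strategy_regression(d$MSR, d$FAR)
    expect_lt(r$slope, 0)
    expect_lt(r$p_value, 0.05)
  }
})
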