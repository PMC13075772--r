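# Pseudopopulation assembly and ECOC SVM frequency decoding.

mk_pop <- function(X_by_kind, freq, spl = rep(60, length(freq))) {
  list(population_id = 1L, unit_ids = colnames(X_by_kind[[1]]),
       X = X_by_kind, freq = freq, spl = spl, window = c(0, 50))
}

# 11 classes, one indicator unit per class plus noise units
separable_pop <- function(seed = 1, noise_sd = 0.05, n_rep = 12) {
  set.seed(seed)
  freqs <- nominal_center_frequencies()
  y <- rep(freqs, each = n_rep)
  X <- matrix(rnorm(length(y) * 22, 0, noise_sd), length(y), 22)
  for (j in seq_along(freqs)) X[y == freqs[j], j] <- X[y == freqs[j], j] + 5
  colnames(X) <- sprintf("u%02d", 1:22)
  mk_pop(list(PT = X), y)
}

test_that("pseudopopulation sampling: replacement, size, determinism", {
  grid <- ref_grid()
  pop <- small_pop()
  pool <- pop$units$unit_id[1:5]
  pp <- build_pseudopopulations(pop$spikes, grid, pool, kinds = "PT",
                                size = 50, n_pops = 3, seed = 11)
  expect_length(pp, 3)
  expect_length(pp[[1]]$unit_ids, 50)
  expect_true(any(duplicated(pp[[1]]$unit_ids)))  # 5-unit pool forces it
  expect_true(all(pp[[1]]$unit_ids %in% pool))
  expect_equal(dim(pp[[1]]$X$PT), c(11 * 8 * 15, 50))
  pp2 <- build_pseudopopulations(pop$spikes, grid, pool, kinds = "PT",
                                 size = 50, n_pops = 3, seed = 11)
  expect_identical(pp[[1]]$unit_ids, pp2[[1]]$unit_ids)
  expect_identical(pp[[1]]$X, pp2[[1]]$X)
  expect_error(build_pseudopopulations(pop$spikes, grid, character(0)),
               "empty")
})

test_that("a separable population is decoded nearly perfectly", {
  r <- decode_frequency(separable_pop(), "PT", tune_budget = 5, seed = 3)
  expect_gte(r$accuracy, 0.95)
  expect_equal(sort(unique(r$per_freq$freq_hz)),
               sort(nominal_center_frequencies()))
})

test_that("shuffled labels decode at chance", {
  r <- decode_frequency(separable_pop(n_rep = 15), "PT", shuffle = TRUE,
                        seed = 8)
  # binomial 99% CI around 1/11 for the held-out trial count
  n <- r$n_test
  ci <- qbinom(c(0.005, 0.995), n, 1 / 11) / n
  expect_gte(r$accuracy, ci[1])
  expect_lte(r$accuracy, ci[2])
  expect_true(r$shuffled)
})

test_that("two response-identical classes confuse only each other", {
  set.seed(5)
  freqs <- nominal_center_frequencies()
  y <- rep(freqs, each = 24)
  X <- matrix(rnorm(length(y) * 22, 0, 0.05), length(y), 22)
  for (j in seq_along(freqs)) X[y == freqs[j], j] <- X[y == freqs[j], j] + 5
  # make class 2 respond like class 1 (same tuning, independent noise)
  n2 <- sum(y == freqs[2])
  X[y == freqs[2], ] <- matrix(rnorm(n2 * 22, 0, 0.05), n2, 22)
  X[y == freqs[2], 1] <- X[y == freqs[2], 1] + 5
  colnames(X) <- sprintf("u%02d", 1:22)
  r <- decode_frequency(mk_pop(list(PT = X), y), "PT", tune_budget = 5,
                        seed = 4)
  twin <- r$per_freq$accuracy[r$per_freq$freq_hz %in% freqs[1:2]]
  others <- r$per_freq$accuracy[!r$per_freq$freq_hz %in% freqs[1:2]]
  expect_lt(mean(twin), 0.85)     # ~50% pairwise confusion
  expect_gte(mean(twin), 0.15)
  expect_gte(mean(others), 0.9)   # unaffected classes stay separable
})

test_that("accuracy is invariant to unit order and common positive scaling", {
  pop <- separable_pop(seed = 2)
  r0 <- decode_frequency(pop, "PT", tune_budget = 3, seed = 6)
  perm <- sample(ncol(pop$X$PT))
  popp <- pop; popp$X$PT <- pop$X$PT[, perm]
  rp <- decode_frequency(popp, "PT", tune_budget = 3, seed = 6)
  expect_equal(r0$accuracy, rp$accuracy)
  pops <- pop; pops$X$PT <- pop$X$PT * 3.7
  rs <- decode_frequency(pops, "PT", tune_budget = 3, seed = 6)
  expect_equal(r0$accuracy, rs$accuracy)
})

test_that("cross-condition generalization mirrors tuning correspondence", {
  set.seed(12)
  freqs <- nominal_center_frequencies()
  y <- rep(freqs, each = 12)
  mk <- function() {
    X <- matrix(rnorm(length(y) * 22, 0, 0.3), length(y), 22)
    colnames(X) <- sprintf("u%02d", 1:22)
    X
  }
  shared <- mk()
  for (j in seq_along(freqs))
    shared[y == freqs[j], j] <- shared[y == freqs[j], j] + 4
  # identical response structure across kinds: cross ~ within
  same <- mk_pop(list(PT = shared, NBN = shared + matrix(
    rnorm(length(shared), 0, 0.3), nrow(shared))), y)
  r_same <- cross_condition_decode(same, "PT", "NBN", tune_budget = 3,
                                   seed = 9)
  expect_gt(r_same$within_accuracy, 0.9)
  expect_gt(r_same$accuracy, 0.8 * r_same$within_accuracy)
  # independent random tuning per kind: cross falls to chance, within high
  other <- mk()
  perm_classes <- c(6:11, 1:5)  # remap which unit codes which class
  for (j in seq_along(freqs))
    other[y == freqs[j], perm_classes[j]] <-
      other[y == freqs[j], perm_classes[j]] + 4
  indep <- mk_pop(list(PT = shared, NBN = other), y)
  r_ind <- cross_condition_decode(indep, "PT", "NBN", tune_budget = 3,
                                  seed = 10)
  expect_gt(r_ind$within_accuracy, 0.9)
  expect_lt(r_ind$accuracy, 0.3)
})
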