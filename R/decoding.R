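# Pseudopopulation assembly and 11-class frequency decoding with linear
# support-vector classifiers: one-vs-one error-correcting output codes with
# hinge-loss-weighted decoding, shuffled-label baselines and cross-condition
# generalization.

# --- ECOC linear SVM core -------------------------------------------------

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}
standardize_apply <- function(X, st) sweep(sweep(X, 2, st$mu), 2, st$sd, "/")

#' Train a one-vs-one ECOC linear SVM
#'
#' Trains all pairwise linear-kernel support-vector machines (via
#' \pkg{e1071}) on standardized features. Prediction picks the class with
#' the smallest average binary hinge loss over its pairwise learners
#' (loss-weighted decoding).
#'
#' @param X Numeric trials x units matrix.
#' @param y Class labels (coerced to factor).
#' @param cost Box constraint of the linear SVM.
#' @return Object of class `ecoc_svm`.
#' @export
ecoc_svm_fit <- function(X, y, cost = 1) {
  y <- factor(y)
  st <- standardize_fit(X)
  Xs <- standardize_apply(X, st)
  model <- e1071::svm(Xs, y, kernel = "linear", cost = cost,
                      scale = FALSE, type = "C-classification")
  structure(list(model = model, standardize = st, levels = levels(y),
                 cost = cost), class = "ecoc_svm")
}

#' @export
predict.ecoc_svm <- function(object, newdata, ...) {
  Xs <- standardize_apply(newdata, object$standardize)
  pr <- predict(object$model, Xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lev <- object$levels
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  loss <- matrix(0, nrow(dv), length(lev), dimnames = list(NULL, lev))
  n_learn <- setNames(numeric(length(lev)), lev)
  for (j in seq_along(pairs)) {
    a <- pairs[[j]][1]; b <- pairs[[j]][2]
    f <- dv[, j]
    loss[, a] <- loss[, a] + pmax(0, 1 - f)   # m = +1 for first class
    loss[, b] <- loss[, b] + pmax(0, 1 + f)   # m = -1 for second class
    n_learn[a] <- n_learn[a] + 1
    n_learn[b] <- n_learn[b] + 1
  }
  loss <- sweep(loss, 2, pmax(n_learn, 1), "/")
  factor(lev[apply(loss, 1, which.min)], levels = lev)
}

# stratified index split: fraction `frac` of each stratum into the first set
stratified_split <- function(strata, frac) {
  train <- logical(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_tr <- round(length(idx) * frac)
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

#' Tune the SVM box constraint with a seeded budgeted search
#'
#' Evaluates a log-spaced grid of candidate costs on a stratified
#' inner train/validation split and returns the cost with the best
#' validation accuracy (ties toward the smaller cost).
#'
#' @param X,y Training data.
#' @param budget Number of candidate costs evaluated.
#' @param range Log10 range of the cost grid.
#' @param frac Inner training fraction.
#' @param seed Seed for the inner split.
#' @return The selected cost (scalar).
#' @export
tune_svm_cost <- function(X, y, budget = 20, range = c(-3, 2),
                          frac = 0.75, seed = 1L) {
  y <- factor(y)
  costs <- 10^seq(range[1], range[2], length.out = budget)
  local_seed_eval(seed, {
    tr <- stratified_split(y, frac)
    acc <- vapply(costs, function(cc) {
      m <- ecoc_svm_fit(X[tr, , drop = FALSE], y[tr], cost = cc)
      mean(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
    }, 0)
    costs[which.max(acc)]  # which.max picks the first (smallest) on ties
  })
}

# --- pseudopopulations ----------------------------------------------------

# trials x units count matrix for one kind; rows ordered freq, spl, trial
decoding_matrix <- function(counts, grid, kind) {
  .k <- kind
  dt <- data.table::as.data.table(counts)
  dt <- dt[kind == .k]
  wide <- data.table::dcast(dt, freq_hz + spl_db + trial ~ unit_id,
                            value.var = "n")
  data.table::setorder(wide, freq_hz, spl_db, trial)
  meta <- wide[, .(freq_hz, spl_db, trial)]
  X <- as.matrix(wide[, -(1:3)])
  list(X = X, freq = meta$freq_hz, spl = meta$spl_db, trial = meta$trial)
}

#' Assemble pseudopopulations for decoding
#'
#' Samples `size` units uniformly with replacement from the responsive pool
#' (no constraint on CF or C50) and collects their per-trial spike counts in
#' the decoding window, treating trial index k of a condition as one
#' pseudotrial across units. Labels are the stimulus frequency (irrespective
#' of SPL); the SPL is carried along for per-amplitude breakdowns.
#'
#' @param spikes Long spike table.
#' @param grid Stimulus grid.
#' @param pool Character vector of responsive unit ids to sample from.
#' @param kinds Kinds for which response matrices are built (all from the
#'   same sampled units, enabling cross-condition decoding).
#' @param size Units per population (default 50).
#' @param n_pops Number of populations (default 10).
#' @param window Spike-count window (ms re onset, default 0-50).
#' @param seed Integer seed.
#' @return List of `n_pops` pseudopopulations; each has `unit_ids`, `X`
#'   (named list of trials x size matrices per kind), `freq`, `spl`,
#'   `window`.
#' @export
build_pseudopopulations <- function(spikes, grid, pool,
                                    kinds = grid$kinds, size = 50,
                                    n_pops = 10, window = c(0, 50),
                                    seed = 1L) {
  if (length(pool) == 0) stop("empty responsive pool", call. = FALSE)
  counts <- spike_count_table(spikes, grid, window, kinds)
  counts <- counts[counts$unit_id %in% pool, , drop = FALSE]
  mats <- lapply(kinds, function(k) decoding_matrix(counts, grid, k))
  names(mats) <- kinds
  local_seed_eval(seed, {
    lapply(seq_len(n_pops), function(p) {
      ids <- sample(pool, size, replace = TRUE)
      X <- lapply(mats, function(m) {
        out <- m$X[, ids, drop = FALSE]
        colnames(out) <- sprintf("%s.%d", ids, seq_along(ids))
        out
      })
      list(population_id = p, unit_ids = ids, X = X,
           freq = mats[[1]]$freq, spl = mats[[1]]$spl, window = window)
    })
  })
}

#' Decode stimulus frequency from one pseudopopulation
#'
#' Splits trials stratified by frequency (and amplitude where counts
#' permit) into a training fraction and a held-out test set, tunes the SVM
#' cost on the training data, trains the one-vs-one ECOC classifier and
#' reports held-out accuracy overall, per frequency, and per
#' frequency x amplitude. With `shuffle = TRUE` the frequency labels are
#' permuted across trials before splitting, yielding the chance baseline.
#'
#' @param pop One pseudopopulation from [build_pseudopopulations()].
#' @param kind Which kind's response matrix to use.
#' @param split Training fraction (default 2/3).
#' @param shuffle Permute labels first.
#' @param tune_budget Cost-search budget (see [tune_svm_cost()]).
#' @param cost Fixed box constraint; `NULL` (default) tunes it on the
#'   training data. Label-shuffled baselines use a fixed cost of 1 unless
#'   one is supplied: chance-level accuracy does not depend on the
#'   regularizer, while tuning against random labels is very slow.
#' @param seed Integer seed (split, shuffle, tuning).
#' @return List of class `decoding_result`: `accuracy`, `per_freq`,
#'   `per_freq_amp` (data.frames), `n_test`, `cost`, `shuffled`, `kind`.
#' @export
decode_frequency <- function(pop, kind, split = 2 / 3, shuffle = FALSE,
                             tune_budget = 20, cost = NULL, seed = 1L) {
  X <- pop$X[[kind]]
  y <- factor(pop$freq)
  amp <- pop$spl
  local_seed_eval(seed, {
    if (shuffle) y <- y[sample(length(y))]
    strata <- interaction(y, amp, drop = TRUE)
    if (min(table(strata)) < 3) strata <- y
    tr <- stratified_split(strata, split)
    if (length(unique(y[tr])) < length(levels(y)))
      stop("a class is missing from the training split", call. = FALSE)
    if (is.null(cost))
      cost <- if (shuffle) 1 else
        tune_svm_cost(X[tr, , drop = FALSE], y[tr], budget = tune_budget,
                      seed = sample.int(2^31 - 1, 1))
    model <- ecoc_svm_fit(X[tr, , drop = FALSE], y[tr], cost = cost)
    pred <- predict(model, X[!tr, , drop = FALSE])
    truth <- y[!tr]
    ok <- pred == truth
    per_freq <- aggregate(ok, list(freq_hz = as.numeric(as.character(truth))),
                          mean)
    names(per_freq)[2] <- "accuracy"
    pfa <- aggregate(ok, list(freq_hz = as.numeric(as.character(truth)),
                              spl_db = amp[!tr]), mean)
    names(pfa)[3] <- "accuracy"
    structure(list(accuracy = mean(ok), per_freq = per_freq,
                   per_freq_amp = pfa, n_test = sum(!tr), cost = cost,
                   shuffled = shuffle, kind = kind,
                   population_id = pop$population_id),
              class = "decoding_result")
  })
}

#' Cross-condition decoding (train on one kind, test on the other)
#'
#' Tunes and trains the ECOC classifier on all trials of the training
#' condition, reports the within-condition accuracy from stratified k-fold
#' cross-validation on the training data, and the cross-condition accuracy
#' from applying the trained model to all trials of the test condition.
#' Intended for pseudopopulations built from units responsive to both
#' kinds.
#'
#' @param pop Pseudopopulation with response matrices for both kinds.
#' @param train_kind,test_kind Stimulus kinds.
#' @param folds Cross-validation folds (default 5).
#' @param tune_budget,seed As in [decode_frequency()].
#' @return List of class `decoding_result` with `within_accuracy`
#'   (cross-validated), `accuracy` (cross-condition), `per_freq`,
#'   `train_kind`, `test_kind`, `cost`.
#' @export
cross_condition_decode <- function(pop, train_kind, test_kind, folds = 5,
                                   tune_budget = 20, seed = 1L) {
  Xtr <- pop$X[[train_kind]]
  Xte <- pop$X[[test_kind]]
  y <- factor(pop$freq)
  local_seed_eval(seed, {
    cost <- tune_svm_cost(Xtr, y, budget = tune_budget,
                          seed = sample.int(2^31 - 1, 1))
    # stratified k-fold CV on the training condition
    fold <- integer(length(y))
    for (s in levels(y)) {
      idx <- sample(which(y == s))
      fold[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
    cv_ok <- logical(length(y))
    for (f in seq_len(folds)) {
      m <- ecoc_svm_fit(Xtr[fold != f, , drop = FALSE], y[fold != f],
                        cost = cost)
      cv_ok[fold == f] <- predict(m, Xtr[fold == f, , drop = FALSE]) ==
        y[fold == f]
    }
    model <- ecoc_svm_fit(Xtr, y, cost = cost)
    pred <- predict(model, Xte)
    ok <- pred == y
    per_freq <- aggregate(ok, list(freq_hz = as.numeric(as.character(y))),
                          mean)
    names(per_freq)[2] <- "accuracy"
    structure(list(accuracy = mean(ok), within_accuracy = mean(cv_ok),
                   per_freq = per_freq, cost = cost,
                   train_kind = train_kind, test_kind = test_kind,
                   population_id = pop$population_id),
              class = "decoding_result")
  })
}

#' @importFrom stats aggregate residuals
NULL
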