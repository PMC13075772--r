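# Signal-detection scoring of lever-release trials: H/M/FA/CR/AB labels,
# per-cell rates, performance and d-prime, and the strategy regression.

#' Classify behavioral trials into signal-detection components
#'
#' Each trial is segmented by its target onset time. Short-onset trials
#' (onset in `[1000, 2250]` ms) are scored against the true target: a release
#' within `(onset, onset + 700]` ms is a hit (H), anything later (or no
#' release) a miss (M). Long-onset trials (onset in `(2250, 3500]` ms) are
#' scored against a virtual onset drawn per trial (seeded) uniformly over
#' the hit-window onset range `[1000, 2250]` ms, truncated so that the
#' virtual window closes before the true target onset: a release inside the
#' virtual window is a false alarm (FA), none is a correct rejection (CR).
#' Any release occurring before the trial's scoring window is an abort (AB)
#' and is excluded from rate computations. Because no target has occurred by
#' the end of the false-alarm window, the false-alarm rate is independent of
#' target amplitude by construction, while from the animal's point of view
#' the hit and false-alarm windows remain indistinguishable.
#'
#' @param trials Behavior trial table (see [generate_behavior_sessions()]).
#' @param seed Integer seed for the virtual-onset draws.
#' @param segment_split_ms Boundary between short- and long-onset segments.
#' @param response_window_ms Response window duration (ms).
#' @param onset_range_ms Admissible onset range; onsets outside error out.
#' @return The trial table with added columns `label` (factor H/M/FA/CR/AB),
#'   `virtual_onset_ms` (NA for short-onset trials), `scoring_start_ms`,
#'   `scoring_end_ms`.
#' @export
classify_trials <- function(trials, seed = NULL, segment_split_ms = 2250,
                            response_window_ms = 700,
                            onset_range_ms = c(1000, 3500)) {
  stopifnot(all(c("onset_ms", "release_ms") %in% names(trials)))
  if (any(trials$onset_ms < onset_range_ms[1] |
          trials$onset_ms > onset_range_ms[2]))
    stop("target onset outside the admissible range", call. = FALSE)
  if (any(!is.na(trials$release_ms) &
          trials$release_ms <= trials$press_ms %||% 0))
    stop("release at or before lever press", call. = FALSE)
  n <- nrow(trials)
  short <- trials$onset_ms <= segment_split_ms
  # virtual window must close before the true onset so that FAR cannot
  # depend on target amplitude
  virt_hi <- pmax(pmin(segment_split_ms,
                       trials$onset_ms - response_window_ms),
                  onset_range_ms[1])
  virt <- local_seed_eval(seed, runif(n, onset_range_ms[1], virt_hi))
  virt[short] <- NA_real_
  start <- ifelse(short, trials$onset_ms, virt)
  end <- start + response_window_ms
  rel <- trials$release_ms
  label <- character(n)
  ab <- !is.na(rel) & rel <= start
  inwin <- !is.na(rel) & rel > start & rel <= end
  label[short & ab] <- "AB"
  label[short & inwin] <- "H"
  label[short & !ab & !inwin] <- "M"
  label[!short & ab] <- "AB"
  label[!short & inwin] <- "FA"
  label[!short & !ab & !inwin] <- "CR"
  out <- trials
  out$label <- factor(label, levels = c("H", "M", "FA", "CR", "AB"))
  out$virtual_onset_ms <- virt
  out$scoring_start_ms <- start
  out$scoring_end_ms <- end
  out
}

z_rate <- function(p) qnorm(p)

#' Summarize signal-detection outcomes into rates and d-prime
#'
#' Computes, per grouping cell (by default animal x session x kind x
#' amplitude), the H/M/FA/CR counts, hit rate `HR = H/(H+M)`, false-alarm
#' rate `FAR = FA/(FA+CR)`, miss rate, performance
#' `(H+CR)/(H+CR+FA+M)` and `d' = Z(HR) - Z(FAR)`. Aborts are excluded.
#' When HR or FAR is exactly 0 or 1 the log-linear correction adds 0.5 to
#' each of the four counts of that cell before computing both rates, so the
#' z-transform stays finite (switch off with `correction = "none"`, which
#' yields infinite d-prime at the edges). Cells with no scored target trials
#' or no scored no-target trials get `NA` rates and are flagged.
#'
#' @param outcomes Output of [classify_trials()].
#' @param by Character vector of grouping columns.
#' @param correction `"loglinear"` (default) or `"none"`.
#' @return data.frame with counts, rates, `performance`, `d_prime`, and a
#'   logical `incomplete` flag.
#' @export
#' @examples
#' # HR 0.9 vs FAR 0.1 gives d' = qnorm(.9) - qnorm(.1) ~= 2.563
sdt_summary <- function(outcomes,
                        by = c("animal", "session", "kind", "spl_db"),
                        correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  dt <- data.table::as.data.table(outcomes)
  by <- intersect(by, names(dt))
  cnt <- dt[, .(
    H = sum(label == "H"), M = sum(label == "M"),
    FA = sum(label == "FA"), CR = sum(label == "CR"),
    AB = sum(label == "AB")), by = by]
  cnt[, `:=`(
    HR = H / (H + M), FAR = FA / (FA + CR), MSR = M / (H + M),
    performance = (H + CR) / (H + CR + FA + M))]
  h <- cnt$H; m <- cnt$M; fa <- cnt$FA; cr <- cnt$CR
  hr_c <- cnt$HR; far_c <- cnt$FAR
  if (correction == "loglinear") {
    edge <- (!is.na(hr_c) & (hr_c == 0 | hr_c == 1)) |
      (!is.na(far_c) & (far_c == 0 | far_c == 1))
    edge[is.na(edge)] <- FALSE
    hr_c[edge] <- (h[edge] + 0.5) / (h[edge] + m[edge] + 1)
    far_c[edge] <- (fa[edge] + 0.5) / (fa[edge] + cr[edge] + 1)
  }
  cnt[, d_prime := z_rate(hr_c) - z_rate(far_c)]
  cnt[, incomplete := is.na(HR) | is.na(FAR)]
  as.data.frame(cnt)
}

#' Aggregate session-level SDT summaries to animal and group level
#'
#' Rates and d-prime are first averaged across sessions within each animal,
#' then across animals, matching the study's aggregation order.
#'
#' @param summary Output of [sdt_summary()] with `animal` and `session`
#'   columns.
#' @return List with `animal` (per animal x kind x amplitude means) and
#'   `group` (per kind x amplitude mean, sd and n across animals).
#' @export
sdt_group_summary <- function(summary) {
  dt <- data.table::as.data.table(summary)
  vars <- intersect(c("HR", "FAR", "MSR", "performance", "d_prime"),
                    names(dt))
  an <- dt[, lapply(.SD, mean, na.rm = TRUE),
           by = c("animal", "kind", "spl_db"), .SDcols = vars]
  gr <- an[, c(lapply(.SD, mean, na.rm = TRUE),
               list(d_prime_sd = sd(d_prime, na.rm = TRUE),
                    n_animals = sum(!is.na(d_prime)))),
           by = c("kind", "spl_db"), .SDcols = vars]
  list(animal = as.data.frame(an), group = as.data.frame(gr))
}

#' Detection threshold per stimulus kind from group d-prime
#'
#' The threshold for a kind is the lowest tested amplitude at which the
#' group d-prime differs from zero by a one-sample t-test across animals
#' (two-sided, at `alpha`). Animal-level d-prime values (session means) are
#' the test's observations.
#'
#' @param animal_summary The `animal` element of [sdt_group_summary()].
#' @param alpha Significance level.
#' @return data.frame per kind with `threshold_db` (NA when no amplitude is
#'   significant) plus a `difference` attribute `PT - NBN` when both exist.
#' @export
behavioral_thresholds <- function(animal_summary, alpha = 0.05) {
  dt <- data.table::as.data.table(animal_summary)
  res <- dt[, {
    spls <- sort(unique(spl_db))
    thr <- NA_real_
    for (a in spls) {
      x <- d_prime[spl_db == a]
      x <- x[is.finite(x)]
      if (length(x) >= 3 && sd(x) > 0) {
        if (t.test(x)$p.value < alpha) { thr <- a; break }
      }
    }
    list(threshold_db = thr)
  }, by = "kind"]
  out <- as.data.frame(res)
  if (all(c("PT", "NBN") %in% out$kind)) {
    attr(out, "difference") <- out$threshold_db[out$kind == "PT"] -
      out$threshold_db[out$kind == "NBN"]
  }
  out
}
utils::globalVariables(c("H", "M", "FA", "CR", "AB", "HR", "FAR", "MSR",
                         "d_prime", "incomplete", "performance"))

#' Miss-rate versus false-alarm-rate strategy regression
#'
#' Ordinary least-squares fit of per-animal FAR on MSR (both at the lowest
#' tested amplitude), quantifying the response-strategy axis: animals
#' trading misses against false alarms produce a negative slope. Significance
#' comes from the regression F test.
#'
#' @param msr,far Per-animal miss rates and false-alarm rates.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`, and `degenerate` (TRUE when `msr` has zero variance, in which case
#'   the fit is undefined and the other fields are NA).
#' @export
strategy_regression <- function(msr, far) {
  ok <- is.finite(msr) & is.finite(far)
  msr <- msr[ok]; far <- far[ok]
  if (length(msr) < 3)
    stop("need at least 3 animals for the strategy regression",
         call. = FALSE)
  if (var(msr) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, p_value = NA_real_,
                n = length(msr), degenerate = TRUE))
  }
  fit <- lm(far ~ msr)
  sm <- suppressWarnings(summary(fit))
  if (!is.finite(sm$r.squared)) {
    return(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                r_squared = NA_real_, p_value = NA_real_, n = length(msr),
                degenerate = TRUE))
  }
  pval <- if (sm$r.squared == 1) 0 else
    unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared, p_value = pval, n = length(msr),
       degenerate = FALSE)
}

#' @importFrom stats pf
NULL
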