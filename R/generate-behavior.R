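# Synthetic go/no-go lever-release sessions with ground-truth bookkeeping.

#' Reference configuration for the behavioral session generator
#'
#' Defaults encode the reference study conditions: 8 animals x 10 sessions,
#' 8 target amplitudes (28-53 dB SPL), PT and NBN targets interleaved, target
#' onset uniform in 1,000-3,500 ms after lever press, a 700 ms response
#' window, and a cumulative-Gaussian psychometric detection function whose
#' NBN midpoint sits one behavioral amplitude step (3.5 dB) below the PT
#' midpoint. Spontaneous (false-alarm) releases follow a constant hazard that
#' is independent of target amplitude by construction; an abort hazard
#' operates before the scoring epoch. A per-animal strategy axis trades miss
#' rate against false-alarm rate (liberal animals release more readily and
#' detect at slightly lower amplitudes).
#'
#' @param n_animals,n_sessions,trials_per_session Design sizes.
#' @param amplitudes Target amplitudes (dB SPL).
#' @param kinds Stimulus kinds presented (interleaved with equal probability).
#' @param onset_range_ms Target onset window after lever press (ms).
#' @param response_window_ms Release window after target onset scored as a
#'   response to the target (ms).
#' @param psychometric Named list per kind with `midpoint` (dB), `width`
#'   (dB, cumulative-Gaussian SD), `asymptote` (max detection probability),
#'   `lapse` (probability a detected target is not acted upon).
#' @param fa_hazard_per_s Spontaneous release hazard (1/s) from 1,000 ms on.
#' @param abort_hazard_per_s Release hazard (1/s) before 1,000 ms.
#' @param strategy_scale Strength of the per-animal strategy axis: animal
#'   `i` has score `s_i` evenly spaced in `[-1, 1]`; its hazard is scaled by
#'   `exp(strategy_scale * s_i)` and its psychometric midpoints shifted by
#'   `-strategy_shift_db * s_i`.
#' @param strategy_shift_db Midpoint shift per unit strategy score (dB).
#' @param rt_meanlog,rt_sdlog Log-normal reaction-time parameters (ms).
#' @param step_ms Discrete hazard step (ms).
#' @return A list of class `behavior_config`.
#' @export
behavior_config <- function(n_animals = 8, n_sessions = 10,
                            trials_per_session = 500,
                            amplitudes = c(28, 31.5, 35, 38.5, 42.5, 46,
                                           49.5, 53),
                            kinds = c("PT", "NBN"),
                            onset_range_ms = c(1000, 3500),
                            response_window_ms = 700,
                            psychometric = list(
                              PT  = list(midpoint = 32.0, width = 1.5,
                                         asymptote = 0.99, lapse = 0),
                              NBN = list(midpoint = 28.5, width = 1.5,
                                         asymptote = 0.99, lapse = 0)),
                            fa_hazard_per_s = 0.08,
                            abort_hazard_per_s = 0.25,
                            strategy_scale = 1.2,
                            strategy_shift_db = 0.8,
                            rt_meanlog = log(280), rt_sdlog = 0.25,
                            step_ms = 10) {
  for (k in names(psychometric)) {
    p <- psychometric[[k]]
    stopifnot_scalar_prob(p$asymptote, paste0("asymptote[", k, "]"))
    stopifnot_scalar_prob(p$lapse, paste0("lapse[", k, "]"))
    if (p$midpoint < min(amplitudes) - 20 || p$midpoint > max(amplitudes) + 20)
      stop("psychometric midpoint far outside the amplitude range",
           call. = FALSE)
  }
  if (fa_hazard_per_s < 0 || abort_hazard_per_s < 0)
    stop("hazards must be non-negative", call. = FALSE)
  structure(as.list(environment()), class = "behavior_config")
}

#' Detection probability of the psychometric model
#'
#' @param amplitude_db Amplitudes (dB SPL).
#' @param psy One element of `behavior_config()$psychometric`.
#' @return Detection probabilities.
#' @export
psychometric_p <- function(amplitude_db, psy) {
  psy$asymptote * (1 - psy$lapse) *
    pnorm((amplitude_db - psy$midpoint) / psy$width)
}

#' Generate synthetic behavioral sessions
#'
#' Simulates lever-press trials: the animal may release spontaneously (abort
#' hazard before 1,000 ms, false-alarm hazard from 1,000 ms until the target
#' resolves, continuing through the response window when the target goes
#' undetected), or detect the target with probability given by the
#' psychometric function and release after a log-normal reaction time capped
#' at the response window. Hazards are discrete per-`step_ms` Bernoulli
#' steps. All times are in ms relative to the lever press.
#'
#' @param config A [behavior_config()].
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return List with `trials` (data.frame: trial_id, animal, session,
#'   press_ms, onset_ms, kind, spl_db, release_ms with `NA` for held trials)
#'   and `ground_truth` (data.frame with the latent detection indicator,
#'   detection probability and hazard release time per trial; never consumed
#'   by analysis functions).
#' @export
generate_behavior_sessions <- function(config = behavior_config(),
                                       seed = NULL) {
  cfg <- config
  local_seed_eval(seed, {
    n_tr <- cfg$n_animals * cfg$n_sessions * cfg$trials_per_session
    animal <- rep(seq_len(cfg$n_animals),
                  each = cfg$n_sessions * cfg$trials_per_session)
    session <- rep(rep(seq_len(cfg$n_sessions),
                       each = cfg$trials_per_session), cfg$n_animals)
    strategy <- if (cfg$n_animals == 1) 0 else
      seq(-1, 1, length.out = cfg$n_animals)
    s <- strategy[animal]
    kind <- sample(cfg$kinds, n_tr, replace = TRUE)
    spl <- sample(cfg$amplitudes, n_tr, replace = TRUE)
    onset <- runif(n_tr, cfg$onset_range_ms[1], cfg$onset_range_ms[2])

    step <- cfg$step_ms
    p_ab <- pmin(1, cfg$abort_hazard_per_s * exp(cfg$strategy_scale * s) *
                   step / 1000)
    p_fa <- pmin(1, cfg$fa_hazard_per_s * exp(cfg$strategy_scale * s) *
                   step / 1000)
    # first hazard event in [0, 1000): geometric number of steps
    t_ab <- ifelse(p_ab > 0, (rgeom(n_tr, pmax(p_ab, 1e-12)) + 1) * step,
                   Inf)
    t_ab[p_ab == 0] <- Inf
    t_ab[t_ab >= 1000] <- Inf
    # hazard event from 1000 ms on (runs until release or trial end)
    t_fa <- ifelse(p_fa > 0,
                   1000 + (rgeom(n_tr, pmax(p_fa, 1e-12)) + 1) * step, Inf)
    t_fa[p_fa == 0] <- Inf

    # detection
    midpt <- vapply(kind, function(k) cfg$psychometric[[k]]$midpoint, 0)
    p_det <- numeric(n_tr)
    for (k in cfg$kinds) {
      i <- kind == k
      psy <- cfg$psychometric[[k]]
      psy$midpoint <- psy$midpoint - cfg$strategy_shift_db * s[i]
      p_det[i] <- psychometric_p(spl[i], psy)
    }
    detected <- runif(n_tr) < p_det
    rt <- pmin(rlnorm(n_tr, cfg$rt_meanlog, cfg$rt_sdlog),
               cfg$response_window_ms - step)
    t_det <- ifelse(detected, onset + rt, Inf)

    # earliest event wins; spontaneous releases may precede detection
    release <- pmin(t_ab, t_fa, t_det)
    # spontaneous release cannot occur after detection-driven release; and
    # trials end at onset + response window if nothing happened by then the
    # animal holds (release NA)
    trial_end <- onset + cfg$response_window_ms
    release[release > trial_end] <- NA_real_

    press <- rep(0, n_tr)
    trials <- data.frame(
      trial_id = seq_len(n_tr), animal = animal, session = session,
      press_ms = press, onset_ms = onset, kind = kind, spl_db = spl,
      release_ms = release, stringsAsFactors = FALSE)
    gt <- data.frame(
      trial_id = seq_len(n_tr), p_detect = p_det, detected = detected,
      hazard_release_ms = pmin(t_ab, t_fa), strategy = s,
      stringsAsFactors = FALSE)
    list(trials = trials, ground_truth = gt)
  })
}
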