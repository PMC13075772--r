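# Stimulus condition grid, narrowband-noise band geometry, waveform
# synthesis, and the Fletcher critical-band utility.

#' Canonical half-octave center frequencies
#'
#' The nominal 11 half-octave-spaced center frequencies (Hz) used for both
#' pure-tone and narrowband-noise protocols. These are the conventional
#' rounded values; they are close to, but not exactly, successive multiples
#' of sqrt(2).
#'
#' @return Numeric vector of 11 frequencies in Hz.
#' @export
#' @examples
#' nominal_center_frequencies()
nominal_center_frequencies <- function() {
  c(560, 800, 1120, 1600, 2240, 3150, 4500, 6300, 9000, 12500, 18000)
}

#' Build the frequency x SPL stimulus condition grid
#'
#' Constructs the condition lattice for the recording protocol: half-octave
#' spaced center frequencies crossed with a linear ladder of sound pressure
#' levels, presented as both pure tones (PT) and narrowband noise (NBN).
#'
#' In the default (`exact = FALSE`) mode the canonical nominal frequency list
#' (see [nominal_center_frequencies()]) is filtered to `[low_hz, high_hz]`.
#' With `exact = TRUE` the centers are true `anchor * 2^(k/2)` multiples,
#' k = 0, 1, 2, ..., kept while inside the bounds.
#'
#' @param low_hz,high_hz Frequency bounds in Hz applied to the centers.
#' @param anchor_hz Anchor frequency for the exact half-octave ladder.
#' @param spl_min,spl_max,spl_step SPL ladder in dB SPL.
#' @param kinds Character vector of stimulus kinds, subset of `c("PT","NBN")`.
#' @param duration_ms Stimulus duration (ms).
#' @param ramp_ms Raised-cosine on/off ramp duration (ms).
#' @param iti_ms Length-2 inter-trial interval range (ms).
#' @param n_trials Repetitions per condition.
#' @param exact Use exact sqrt(2) spacing instead of the nominal list.
#' @return An object of class `stimulus_grid`: a list with elements
#'   `frequencies`, `spls`, `kinds`, `duration_ms`, `ramp_ms`, `iti_ms`,
#'   `n_trials`.
#' @export
#' @examples
#' g <- build_stimulus_grid()
#' length(g$frequencies)  # 11
#' length(g$spls)         # 8
build_stimulus_grid <- function(low_hz = 500, high_hz = 22000,
                                anchor_hz = 560,
                                spl_min = 40, spl_max = 75, spl_step = 5,
                                kinds = c("PT", "NBN"),
                                duration_ms = 100, ramp_ms = 10,
                                iti_ms = c(200, 300), n_trials = 15,
                                exact = FALSE) {
  if (low_hz >= anchor_hz || anchor_hz > high_hz)
    stop("need low_hz < anchor_hz <= high_hz", call. = FALSE)
  if (spl_step <= 0) stop("spl_step must be positive", call. = FALSE)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (duration_ms <= 2 * ramp_ms)
    stop("duration_ms must exceed 2 * ramp_ms", call. = FALSE)
  if (exact) {
    k <- 0:ceiling(2 * log2(high_hz / anchor_hz))
    freqs <- anchor_hz * 2^(k / 2)
    freqs <- freqs[freqs >= low_hz & freqs <= high_hz]
  } else {
    freqs <- nominal_center_frequencies()
    freqs <- freqs[freqs >= low_hz & freqs <= high_hz]
  }
  spls <- seq(spl_min, spl_max, by = spl_step)
  kinds <- match.arg(kinds, c("PT", "NBN"), several.ok = TRUE)
  structure(
    list(frequencies = freqs, spls = spls, kinds = kinds,
         duration_ms = duration_ms, ramp_ms = ramp_ms, iti_ms = iti_ms,
         n_trials = as.integer(n_trials)),
    class = "stimulus_grid")
}

#' @export
print.stimulus_grid <- function(x, ...) {
  cat("Stimulus grid:", length(x$frequencies), "frequencies x",
      length(x$spls), "SPLs x", paste(x$kinds, collapse = "/"), "\n")
  cat("  centers (Hz):", paste(x$frequencies, collapse = ", "), "\n")
  cat("  SPLs (dB):", paste(x$spls, collapse = ", "), "\n")
  cat(sprintf("  %d trials/condition, %g ms + %g ms ramps, ITI %g-%g ms\n",
              x$n_trials, x$duration_ms, x$ramp_ms, x$iti_ms[1], x$iti_ms[2]))
  invisible(x)
}

#' Narrowband-noise band edges for a grid center
#'
#' Grid bands get their edges at the geometric midpoints to the neighboring
#' centers so that adjacent bands tile the axis with no overlap and no gap;
#' the two outermost bands are closed by a quarter-octave extension. The
#' behavioral band centered at 8,500 Hz is a conventional override with fixed
#' 7,000-10,000 Hz edges (a half-octave-wide band that is not geometric
#' around its center).
#'
#' @param grid A `stimulus_grid`.
#' @param center_hz Band center frequency (Hz); must be a grid center or the
#'   behavioral override center.
#' @param overrides Named list mapping center (as character) to `c(low, high)`
#'   edges. Default carries the behavioral 8,500 Hz band.
#' @return List with `center_hz`, `low_hz`, `high_hz`, `filter_order`.
#' @export
#' @examples
#' g <- build_stimulus_grid()
#' nbn_band_edges(g, 8500)$low_hz   # 7000
#' nbn_band_edges(g, 560)$high_hz   # sqrt(560*800)
nbn_band_edges <- function(grid, center_hz,
                           overrides = list(`8500` = c(7000, 10000))) {
  key <- as.character(center_hz)
  if (!is.null(overrides[[key]])) {
    e <- overrides[[key]]
    return(list(center_hz = center_hz, low_hz = e[1], high_hz = e[2],
                filter_order = 2L))
  }
  fr <- grid$frequencies
  i <- match(center_hz, fr)
  if (is.na(i))
    stop(sprintf("center %g Hz is not on the grid and has no override",
                 center_hz), call. = FALSE)
  lo <- if (i == 1L) center_hz * 2^(-1 / 4) else sqrt(fr[i - 1L] * fr[i])
  hi <- if (i == length(fr)) center_hz * 2^(1 / 4) else sqrt(fr[i] * fr[i + 1L])
  list(center_hz = center_hz, low_hz = lo, high_hz = hi, filter_order = 2L)
}

#' Synthesize a pure-tone or narrowband-noise stimulus waveform
#'
#' PT is a sine at the center frequency; NBN is white noise passed through a
#' causal second-order Butterworth bandpass at the band edges. Both receive
#' raised-cosine on/off ramps and are RMS-scaled to the target SPL relative
#' to a configurable reference pressure (absolute calibration is out of
#' scope; only relative levels matter downstream).
#'
#' @param kind `"PT"` or `"NBN"`.
#' @param frequency_hz Tone frequency (PT) or band center (NBN, when `band`
#'   is derived from a grid elsewhere).
#' @param band For NBN, a list with `low_hz`/`high_hz` as returned by
#'   [nbn_band_edges()]. Ignored for PT.
#' @param duration_ms,ramp_ms Duration and ramp (ms).
#' @param fs Sampling rate (Hz); must exceed twice the highest frequency.
#' @param spl_db Target level, dB re `ref_pressure` RMS.
#' @param ref_pressure Reference pressure in the waveform's amplitude units.
#' @param seed Integer seed for the NBN noise draw.
#' @return Numeric waveform of length `round(duration_ms/1000 * fs)` with
#'   attributes `fs` and `spl_db`.
#' @export
synthesize_stimulus <- function(kind = c("PT", "NBN"), frequency_hz = NULL,
                                band = NULL, duration_ms = 100, ramp_ms = 10,
                                fs = 96000, spl_db = 60,
                                ref_pressure = 20e-6, seed = NULL) {
  kind <- match.arg(kind)
  if (duration_ms <= 0) stop("duration_ms must be positive", call. = FALSE)
  if (duration_ms <= 2 * ramp_ms)
    stop("duration_ms must exceed 2 * ramp_ms", call. = FALSE)
  n <- round(duration_ms / 1000 * fs)
  t <- seq_len(n) / fs
  if (kind == "PT") {
    if (is.null(frequency_hz)) stop("PT needs `frequency_hz`", call. = FALSE)
    if (fs <= 2 * frequency_hz) stop("Nyquist violation", call. = FALSE)
    x <- sin(2 * pi * frequency_hz * t)
  } else {
    if (is.null(band)) stop("NBN needs `band`", call. = FALSE)
    if (fs <= 2 * band$high_hz) stop("Nyquist violation", call. = FALSE)
    w <- local_seed_eval(seed, rnorm(n))
    bf <- signal::butter(2, c(band$low_hz, band$high_hz) / (fs / 2),
                         type = "pass")
    x <- as.numeric(signal::filter(bf, w))  # causal, forward only
  }
  # raised-cosine on/off ramps
  nr <- round(ramp_ms / 1000 * fs)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
  }
  target_rms <- ref_pressure * 10^(spl_db / 20)
  x <- x / sqrt(mean(x^2)) * target_rms
  attr(x, "fs") <- fs
  attr(x, "spl_db") <- spl_db
  x
}

#' Fletcher critical band from a critical ratio
#'
#' `CB = 10^(CR/10)`, the classical relation between the masking-based
#' critical ratio (dB) and the critical bandwidth (Hz).
#'
#' @param critical_ratio_db Critical ratio in dB.
#' @return Critical bandwidth in Hz.
#' @export
#' @examples
#' critical_band(35)  # ~3162 Hz, i.e. ~3.1-3.2 kHz
critical_band <- function(critical_ratio_db) {
  10^(critical_ratio_db / 10)
}
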