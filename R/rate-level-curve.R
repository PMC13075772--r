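# The log-normal rate-level curve shared by the fitting module and the
# synthetic generator's ground truth.

#' Log-normal rate-level function
#'
#' `f(x) = E / (x * sigma * sqrt(2*pi)) * exp(-(log(x) - mu)^2 / (2*sigma^2))
#'  + B`, with `x` the sound pressure level in dB and natural log. `E` scales
#' the response magnitude, `mu` is the log-domain center, `sigma` the
#' dispersion and `B` the baseline.
#'
#' @param x SPL in dB (positive).
#' @param E,mu,sigma,B Curve parameters (positive).
#' @return Curve values.
#' @export
ln_rate_level <- function(x, E, mu, sigma, B) {
  E / (x * sigma * sqrt(2 * pi)) *
    exp(-(log(x) - mu)^2 / (2 * sigma^2)) + B
}

# dense evaluation grid over the sensitivity evaluation domain
ln_domain_grid <- function(domain) {
  seq(max(domain[1], 0.1), domain[2], length.out = 600)
}

#' Landmarks of a log-normal rate-level curve over an evaluation domain
#'
#' Computes the fitted maximum, the C50 (SPL of the first upcrossing of 50%
#' of the baseline-to-maximum range), the half-width (SPL extent over which
#' the curve exceeds half its maximum) and the monotonicity flag (half-width
#' infinite because the curve has not fallen back below half-maximum by the
#' domain's upper edge). Crossings are located on a dense grid and refined
#' with [stats::uniroot()] to high precision.
#'
#' @param E,mu,sigma,B Curve parameters.
#' @param domain Length-2 evaluation interval in dB (default 0-100; the
#'   lower edge is clipped to 0.1 dB where the log is defined).
#' @return List `rmax`, `c50`, `hw`, `monotonic`, `peak_spl`. `c50` is `NA`
#'   when the curve never reaches half-range inside the domain.
#' @export
ln_curve_landmarks <- function(E, mu, sigma, B, domain = c(0, 100)) {
  xs <- ln_domain_grid(domain)
  v <- ln_rate_level(xs, E, mu, sigma, B)
  rmax <- max(v)
  peak_spl <- xs[which.max(v)]
  half_range <- B + 0.5 * (rmax - B)
  c50 <- NA_real_
  up <- which(v >= half_range)
  if (length(up) > 0 && rmax > B) {
    i <- up[1]
    if (i == 1L) c50 <- xs[1] else {
      c50 <- uniroot(function(x) ln_rate_level(x, E, mu, sigma, B) -
                       half_range, c(xs[i - 1L], xs[i]),
                     tol = 1e-6)$root
    }
  }
  half_max <- 0.5 * rmax
  above <- v > half_max
  if (!any(above)) {
    hw <- NA_real_; monotonic <- FALSE
  } else if (above[length(above)]) {
    hw <- Inf; monotonic <- TRUE
  } else {
    lo_i <- which(above)[1]
    hi_i <- max(which(above))
    lo <- if (lo_i == 1L) xs[1] else
      uniroot(function(x) ln_rate_level(x, E, mu, sigma, B) - half_max,
              c(xs[lo_i - 1L], xs[lo_i]), tol = 1e-6)$root
    hi <- uniroot(function(x) ln_rate_level(x, E, mu, sigma, B) - half_max,
                  c(xs[hi_i], xs[hi_i + 1L]), tol = 1e-6)$root
    hw <- hi - lo
    monotonic <- FALSE
  }
  list(rmax = rmax, c50 = c50, hw = hw, monotonic = monotonic,
       peak_spl = peak_spl)
}

# Solve mu so that the curve's C50 over `domain` equals `c50` (baseline-free
# shape; C50 does not depend on E or B). Used by the synthetic generator to
# parameterize units by their true C50.
ln_mu_for_c50 <- function(c50, sigma, domain = c(0, 100)) {
  f <- function(mu)
    ln_curve_landmarks(1, mu, sigma, 0, domain)$c50 - c50
  uniroot(f, c(log(c50) - 2, log(c50) + 2 + sigma^2), tol = 1e-5)$root
}
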