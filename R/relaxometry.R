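#' Steady-state direct water saturation signal
#'
#' Normalized water signal under continuous-wave off-resonance irradiation of
#' a single free-water pool:
#' \deqn{Z(\Delta\omega) = \frac{R_1 (R_2^2 + \Delta\omega^2)}
#'       {R_1 (R_2^2 + \Delta\omega^2) + \omega_1^2 R_2}}
#' with R1 = 1/T1,obs, R2 = 1/T2,obs and omega1 = gamma B1.  This is the
#' direct-saturation (DE) reference model used for WASSR-based T2 mapping.
#'
#' @param offset_ppm saturation offset(s), ppm
#' @param b1_ut saturation amplitude, µT
#' @param t1_ms observed T1, ms
#' @param t2_ms observed T2, ms
#' @param f0_mhz proton frequency, MHz
#' @return normalized signal Z in (0, 1]
#' @export
eq1_signal <- function(offset_ppm, b1_ut, t1_ms, t2_ms,
                       f0_mhz = DEFAULT_F0_MHZ) {
  stopifnot(t1_ms > 0, t2_ms > 0, b1_ut >= 0)
  r1 <- 1000 / t1_ms
  r2 <- 1000 / t2_ms
  dw <- ppm_to_radsec(offset_ppm, f0_mhz)
  w1 <- b1_to_omega1(b1_ut)
  num <- r1 * (r2^2 + dw^2)
  num / (num + w1^2 * r2)
}

#' Magnitude inversion-recovery signal with finite-TR correction
#'
#' \deqn{S(TI) = S_0 |1 - 2 e^{-TI/T_1} + e^{-TR/T_1}|}
#' assuming ideal inversion and a 90-degree readout that saturates the
#' longitudinal magnetization each repetition.
#'
#' @param ti_ms inversion time(s), ms
#' @param t1_ms longitudinal relaxation time, ms
#' @param s0 equilibrium signal
#' @param tr_ms repetition time, ms
#' @return signal magnitude(s)
#' @export
ir_signal <- function(ti_ms, t1_ms, s0 = 1, tr_ms = 10000) {
  stopifnot(t1_ms > 0, all(ti_ms > 0), tr_ms > 0)
  s0 * abs(1 - 2 * exp(-ti_ms / t1_ms) + exp(-tr_ms / t1_ms))
}

#' Fit T1 from an inversion-recovery series
#'
#' Polarity-restored nonlinear least squares of \code{\link{ir_signal}}:
#' magnitude data lose the sign of the pre-null points, so every
#' physically possible sign pattern (the first j samples negative, by
#' ascending TI) is tried against the signed recovery model; for each
#' candidate T1 the scale s0 is profiled out analytically and the smooth
#' 1-D profile is minimized over log T1.  The lowest-residual pattern
#' wins, which is exact even when the null point falls on a sample.
#'
#' @param signals measured magnitudes, one per TI
#' @param ti_ms inversion times, ms
#' @param tr_ms repetition time, ms
#' @param t1_range admissible T1 range (ms); fits outside are invalid
#' @return list with \code{t1_ms}, \code{s0}, \code{rss}, \code{valid}
#' @export
fit_t1 <- function(signals, ti_ms, tr_ms = 10000, t1_range = c(10, 10000)) {
  stopifnot(length(signals) == length(ti_ms), length(ti_ms) >= 3)
  ord <- order(ti_ms)
  ti <- ti_ms[ord]; sig <- signals[ord]
  lo <- log(t1_range[1]); hi <- log(t1_range[2])
  grid <- seq(lo, hi, length.out = 60)
  span <- grid[2] - grid[1]
  best <- list(rss = Inf, t1 = NA_real_, s0 = NA_real_)
  for (j in 0:length(ti)) {
    d <- sig
    if (j > 0) d[seq_len(j)] <- -d[seq_len(j)]
    rss_of <- function(logt1) {
      t1 <- exp(logt1)
      m <- 1 - 2 * exp(-ti / t1) + exp(-tr_ms / t1)
      s0 <- sum(d * m) / sum(m^2)
      if (!is.finite(s0) || s0 < 0) return(sum(d^2))
      sum((d - s0 * m)^2)
    }
    g0 <- grid[which.min(vapply(grid, rss_of, numeric(1)))]
    opt <- stats::optimize(rss_of, interval = c(g0 - 1.5 * span,
                                                g0 + 1.5 * span),
                           tol = 1e-12)
    if (opt$objective < best$rss) {
      t1 <- exp(opt$minimum)
      m <- 1 - 2 * exp(-ti / t1) + exp(-tr_ms / t1)
      best <- list(rss = opt$objective, t1 = t1,
                   s0 = sum(d * m) / sum(m^2))
    }
  }
  valid <- is.finite(best$t1) && best$t1 > t1_range[1] * 1.001 &&
    best$t1 < t1_range[2] * 0.999 && best$s0 > 0
  list(t1_ms = best$t1, s0 = best$s0, rss = best$rss, valid = valid)
}

#' Fit observed T2 from a WASSR Z-spectrum given T1
#'
#' One-parameter least squares of \code{\link{eq1_signal}} over the
#' B0-corrected WASSR window (all points with |offset| <= \code{window_ppm}).
#'
#' @param z normalized WASSR signals
#' @param offset_ppm offsets, ppm (same length as \code{z})
#' @param t1_ms observed T1 for this voxel, ms
#' @param b1_ut WASSR saturation amplitude, µT
#' @param window_ppm fit window half-width, ppm (about the centre)
#' @param center_ppm known B0 shift of the spectrum, ppm: the model is
#'   evaluated at offset - center, which corrects B0 without
#'   re-interpolating the narrow direct-saturation dip
#' @param t2_range admissible T2 range (ms)
#' @param f0_mhz proton frequency, MHz
#' @return list with \code{t2_ms}, \code{rss}, \code{valid}
#' @export
fit_t2_wassr <- function(z, offset_ppm, t1_ms, b1_ut = 0.1, window_ppm = 1,
                         center_ppm = 0, t2_range = c(1, 1000),
                         f0_mhz = DEFAULT_F0_MHZ) {
  keep <- is.finite(z) & abs(offset_ppm - center_ppm) <= window_ppm
  stopifnot(sum(keep) >= 3)
  zz <- z[keep]
  off <- offset_ppm[keep] - center_ppm
  rss_of <- function(logt2) {
    sum((zz - eq1_signal(off, b1_ut, t1_ms, exp(logt2), f0_mhz))^2)
  }
  opt <- stats::optimize(rss_of, interval = log(t2_range), tol = 1e-12)
  t2 <- exp(opt$minimum)
  valid <- t2 > t2_range[1] * 1.001 && t2 < t2_range[2] * 0.999
  list(t2_ms = t2, rss = opt$objective, valid = valid)
}
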