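#' Super-Lorentzian lineshape of the semisolid pool
#'
#' Orientation integral over dipolar-broadened Gaussians,
#' \deqn{g(\Delta) = \sqrt{2/\pi} \int_0^1
#'   \frac{T_{2,MT}}{|3u^2-1|}
#'   \exp\!\left(-2\left[\frac{2\pi \Delta f_0 T_{2,MT}}{3u^2-1}\right]^2\right) du}
#' with the offset in ppm, f0 in MHz and T2,MT in seconds inside the
#' integral.  Evaluated by adaptive quadrature split at the stationary
#' orientation u = 1/sqrt(3).  The lineshape integrates to 1 over angular
#' frequency.  The divergence at zero offset is handled by constant
#' extrapolation: |offset| below \code{cutoff_ppm} is evaluated at
#' \code{cutoff_ppm}.
#'
#' @param offset_ppm offset(s) from water, ppm
#' @param t2_mt_us semisolid T2, µs
#' @param f0_mhz proton frequency, MHz
#' @param cutoff_ppm on-resonance cutoff, ppm
#' @return lineshape value(s), seconds
#' @export
superlorentzian_g <- function(offset_ppm, t2_mt_us, f0_mhz = DEFAULT_F0_MHZ,
                              cutoff_ppm = 1) {
  stopifnot(t2_mt_us > 0)
  t2 <- t2_mt_us * 1e-6
  u0 <- 1 / sqrt(3)
  one <- function(ppm) {
    d_hz <- ppm_to_hz(max(abs(ppm), cutoff_ppm), f0_mhz)
    f <- function(u) {
      s <- 3 * u^2 - 1
      arg <- ifelse(s == 0, Inf, (2 * pi * d_hz * t2 / s)^2)
      ifelse(s == 0, 0, t2 / abs(s) * exp(-2 * arg))
    }
    quad <- function(lo, hi) {
      q <- stats::integrate(f, lo, hi, rel.tol = 1e-9, abs.tol = 1e-18,
                            subdivisions = 1000L, stop.on.error = FALSE)
      if (!q$message %in% c("OK", "roundoff error is detected in the extrapolation table"))
        stop("super-Lorentzian quadrature failed: ", q$message)
      q$value
    }
    sqrt(2 / pi) * (quad(0, u0) + quad(u0, 1))
  }
  vapply(offset_ppm, one, numeric(1))
}

#' Two-pool MT model parameter set
#'
#' Container for the four free parameters of the two-pool
#' magnetization-transfer model: free-pool T2 (T2,F, ms), exchange rate from
#' the semisolid to the free pool (R_MT, Hz), relative semisolid pool size
#' (M0,MT), and semisolid T2 (T2,MT, µs).  R1,MT is conventionally fixed
#' (default 1 Hz).  The derived MT effect is the product R_MT * M0,MT.
#'
#' @param t2_f_ms free-pool T2, ms
#' @param r_mt_hz exchange rate MT -> free, Hz
#' @param m0_mt relative semisolid pool size (0..1)
#' @param t2_mt_us semisolid T2, µs
#' @param r1_mt_hz semisolid R1, Hz (fixed, not fitted)
#' @return object of class \code{mt_params}
#' @export
mt_params <- function(t2_f_ms, r_mt_hz, m0_mt, t2_mt_us, r1_mt_hz = 1) {
  stopifnot(t2_f_ms > 0, r_mt_hz > 0, m0_mt >= 0, m0_mt <= 1, t2_mt_us > 0,
            r1_mt_hz > 0)
  structure(list(t2_f_ms = t2_f_ms, r_mt_hz = r_mt_hz, m0_mt = m0_mt,
                 t2_mt_us = t2_mt_us, r1_mt_hz = r1_mt_hz,
                 mt_effect_hz = r_mt_hz * m0_mt),
            class = "mt_params")
}

#' @export
print.mt_params <- function(x, ...) {
  cat(sprintf(
    "Two-pool MT parameters: T2,F = %.3g ms, R_MT = %.3g Hz, M0,MT = %.4g,\n",
    x$t2_f_ms, x$r_mt_hz, x$m0_mt))
  cat(sprintf("  T2,MT = %.3g us, MT effect R_MT*M0,MT = %.3g Hz\n",
              x$t2_mt_us, x$mt_effect_hz))
  invisible(x)
}

#' Free-pool R1 constrained to the observed relaxation rate
#'
#' The mono-exponential recovery rate R1,obs of the coupled two-pool system
#' differs from the intrinsic free-pool R1,F.  Given measured T1,obs and the
#' exchange parameters, the intrinsic rate is
#' \deqn{R_{1,F} = R_{1,obs} - \frac{R_{MT} M_{0,MT} (R_{1,MT} - R_{1,obs})}
#'       {R_{1,MT} - R_{1,obs} + R_{MT}}}
#'
#' @param t1_obs_ms observed T1, ms
#' @param r_mt_hz exchange rate, Hz
#' @param m0_mt relative semisolid pool size
#' @param r1_mt_hz semisolid R1, Hz
#' @return R1,F in Hz
#' @export
constrain_r1f <- function(t1_obs_ms, r_mt_hz, m0_mt, r1_mt_hz = 1) {
  r1_obs <- 1000 / t1_obs_ms
  denom <- r1_mt_hz - r1_obs + r_mt_hz
  if (any(abs(denom) < 1e-12))
    stop("degenerate R1 constraint: R1,MT - R1,obs + R_MT = 0")
  r1_obs - r_mt_hz * m0_mt * (r1_mt_hz - r1_obs) / denom
}

#' Steady-state Z of the two-pool MT model
#'
#' Closed-form steady state of the coupled longitudinal equations with the
#' free-pool transverse components eliminated (exact at steady state):
#' R_rf,F = omega1^2 T2,F / (1 + (dw T2,F)^2) for the free pool and
#' R_rf,MT = pi omega1^2 g(offset) for the semisolid pool, with g the
#' super-Lorentzian lineshape.
#'
#' @param params \code{\link{mt_params}} object
#' @param t1_obs_ms observed T1, ms (sets R1,F via \code{\link{constrain_r1f}})
#' @param b1_ut saturation amplitude, µT
#' @param offset_ppm offset(s), ppm
#' @param f0_mhz proton frequency, MHz
#' @param lineshape optional precomputed g values (recycled against offsets)
#' @return Z value(s) in (0, 1]
#' @export
two_pool_z <- function(params, t1_obs_ms, b1_ut, offset_ppm,
                       f0_mhz = DEFAULT_F0_MHZ, lineshape = NULL) {
  r1f <- constrain_r1f(t1_obs_ms, params$r_mt_hz, params$m0_mt,
                       params$r1_mt_hz)
  if (r1f <= 0) stop("constrained R1,F is not positive")
  w1 <- b1_to_omega1(b1_ut)
  dw <- ppm_to_radsec(offset_ppm, f0_mhz)
  t2f <- params$t2_f_ms / 1000
  rrf_f <- w1^2 * t2f / (1 + (dw * t2f)^2)
  if (is.null(lineshape))
    lineshape <- superlorentzian_g(offset_ppm, params$t2_mt_us, f0_mhz)
  rrf_mt <- pi * w1^2 * lineshape
  rm <- params$r_mt_hz
  m0 <- params$m0_mt
  r1mt <- params$r1_mt_hz
  num <- r1f * r1mt + r1f * rrf_mt + r1f * rm + r1mt * rm * m0
  den <- (r1f + rrf_f + rm * m0) * (r1mt + rrf_mt + rm) - rm^2 * m0
  num / den
}

#' Fit the two-pool MT model to a set of Z-spectra
#'
#' Bounded trust-region nonlinear least squares (Levenberg-Marquardt with
#' box constraints) over the four free parameters {T2,F, R_MT, M0,MT,
#' T2,MT}, with R1,F constrained to the supplied T1,obs each iteration.
#' The conventional inputs are Z-spectra at B1 = 0.1, 3 and 6 µT; the
#' 0.1 µT spectrum informs direct saturation and enters only within
#' \code{de_window_ppm} of water, the high-B1 spectra over their full
#' grids.  Multiple jittered restarts guard against local minima; the
#' lowest-residual solution is kept.
#'
#' @param spectra list of spectra, each a list with elements \code{b1_ut},
#'   \code{offset_ppm}, \code{z}
#' @param t1_obs_ms observed T1, ms
#' @param f0_mhz proton frequency, MHz
#' @param de_window_ppm window applied to spectra with B1 < 0.3 µT
#' @param init initial values c(T2,F ms, R_MT Hz, M0,MT, T2,MT µs)
#' @param lower,upper box constraints in the same order
#' @param n_restarts additional jittered starts
#' @param seed seed for the restart jitter
#' @return list with \code{params} (an \code{\link{mt_params}}),
#'   \code{mt_effect_hz}, \code{residual_norm}, \code{converged},
#'   \code{at_boundary}
#' @export
fit_two_pool <- function(spectra, t1_obs_ms, f0_mhz = DEFAULT_F0_MHZ,
                         de_window_ppm = 1,
                         init = c(40, 20, 0.05, 8),
                         lower = c(5, 1, 0, 1),
                         upper = c(500, 100, 0.5, 30),
                         n_restarts = 3, seed = 0) {
  stopifnot(length(spectra) >= 1)
  off <- numeric(0); zz <- numeric(0); b1 <- numeric(0)
  for (sp in spectra) {
    keep <- is.finite(sp$z)
    if (sp$b1_ut < 0.3) keep <- keep & abs(sp$offset_ppm) <= de_window_ppm
    off <- c(off, sp$offset_ppm[keep])
    zz <- c(zz, sp$z[keep])
    b1 <- c(b1, rep(sp$b1_ut, sum(keep)))
  }
  if (length(zz) < 20) stop("need at least 20 Z-spectrum points to fit")
  resid_fn <- function(p) {
    pars <- mt_params(p[1], p[2], p[3], p[4])
    model <- numeric(length(zz))
    for (bb in unique(b1)) {
      i <- b1 == bb
      model[i] <- two_pool_z(pars, t1_obs_ms, bb, off[i], f0_mhz)
    }
    model - zz
  }
  run_one <- function(p0) {
    tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(p0, lower * 1.0001), upper * 0.9999),
                         lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
  }
  fits <- list(run_one(init))
  if (n_restarts > 0) {
    rng <- local({set.seed(seed); matrix(stats::runif(4 * n_restarts, 0.6, 1.6),
                                         ncol = 4)})
    for (k in seq_len(n_restarts)) fits <- c(fits, list(run_one(init * rng[k, ])))
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("two-pool fit failed on all starts")
  dev <- vapply(fits, stats::deviance, numeric(1))
  best <- fits[[which.min(dev)]]
  p <- stats::coef(best)
  at_bound <- any(p <= lower * 1.001 + 1e-12) || any(p >= upper * 0.999)
  pars <- mt_params(p[[1]], p[[2]], p[[3]], p[[4]])
  list(params = pars, mt_effect_hz = pars$mt_effect_hz,
       residual_norm = sqrt(stats::deviance(best)),
       converged = best$info %in% 1:4, at_boundary = at_bound)
}
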