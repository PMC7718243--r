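#' Time-domain Bloch-McConnell steady-state simulators
#'
#' Numerical reference simulators used to cross-check the closed-form
#' signal models.  The equations of motion are linear, so they are
#' propagated in time with the exact matrix-exponential propagator over
#' fixed steps until the state stops changing; the free-pool transverse
#' components are carried explicitly (they oscillate at the full offset
#' frequency), making this an independent route to the same steady state
#' as the algebraically reduced closed forms.
#'
#' @name bloch
NULL

# propagate dy/dt = A y + b from y0 until steady state, exact per step
propagate_to_steady <- function(a, b, y0, h = 0.5, tol = 1e-12,
                                max_steps = 4000L) {
  eh <- as.matrix(Matrix::expm(a * h))
  ch <- solve(a, eh %*% b - b)
  y <- y0
  for (k in seq_len(max_steps)) {
    ynew <- drop(eh %*% y + ch)
    if (max(abs(ynew - y)) < tol) return(ynew)
    y <- ynew
  }
  y
}

#' Single-pool Bloch steady-state Z under CW saturation
#'
#' Propagates (Mx, My, Mz) of a single water pool under continuous
#' irradiation at the given offset until steady state and returns Mz.
#'
#' @param b1_ut saturation amplitude, µT
#' @param offset_ppm offset, ppm
#' @param t1_ms,t2_ms relaxation times, ms
#' @param f0_mhz proton frequency, MHz
#' @return steady-state Z
#' @export
bloch_z <- function(b1_ut, offset_ppm, t1_ms, t2_ms,
                    f0_mhz = DEFAULT_F0_MHZ) {
  r1 <- 1000 / t1_ms; r2 <- 1000 / t2_ms
  w1 <- b1_to_omega1(b1_ut)
  dw <- ppm_to_radsec(offset_ppm, f0_mhz)
  a <- matrix(c(-r2,  dw,   0,
                -dw, -r2,  w1,
                  0, -w1, -r1), 3, 3, byrow = TRUE)
  b <- c(0, 0, r1)
  y <- propagate_to_steady(a, b, c(0, 0, 1))
  y[3]
}

#' Two-pool Bloch-McConnell steady-state Z under CW saturation
#'
#' Propagates the free pool (Mx, My, Mz) plus the semisolid longitudinal
#' magnetization, whose RF saturation enters as the rate
#' pi omega1^2 g(offset) with the super-Lorentzian lineshape, until steady
#' state.  Serves as the oracle for \code{\link{two_pool_z}}.
#'
#' @param params \code{\link{mt_params}}
#' @param t1_obs_ms observed T1, ms (converted to R1,F via
#'   \code{\link{constrain_r1f}})
#' @param b1_ut saturation amplitude, µT
#' @param offset_ppm offset, ppm
#' @param f0_mhz proton frequency, MHz
#' @return steady-state free-pool Z
#' @export
bloch_mcconnell_z <- function(params, t1_obs_ms, b1_ut, offset_ppm,
                              f0_mhz = DEFAULT_F0_MHZ) {
  r1f <- constrain_r1f(t1_obs_ms, params$r_mt_hz, params$m0_mt,
                       params$r1_mt_hz)
  r2f <- 1000 / params$t2_f_ms
  w1 <- b1_to_omega1(b1_ut)
  dw <- ppm_to_radsec(offset_ppm, f0_mhz)
  rm <- params$r_mt_hz; m0 <- params$m0_mt; r1mt <- params$r1_mt_hz
  kf <- rm * m0                    # free -> MT (detailed balance, M0,F = 1)
  rrf_mt <- pi * w1^2 * superlorentzian_g(offset_ppm, params$t2_mt_us, f0_mhz)
  # y = (MxF, MyF, MzF, MzMT)
  a <- matrix(c(-r2f,   dw,              0,                 0,
                 -dw, -r2f,             w1,                 0,
                   0,  -w1, -(r1f + kf),                   rm,
                   0,    0,          kf, -(r1mt + rrf_mt + rm)),
              4, 4, byrow = TRUE)
  b <- c(0, 0, r1f, r1mt * m0)
  y <- propagate_to_steady(a, b, c(0, 0, 1, m0))
  y[3]
}

#' Observed mono-exponential recovery rate of the two-pool system
#'
#' Smallest-magnitude eigenvalue of the longitudinal exchange matrix (no
#' RF), i.e. the apparent R1 that an inversion-recovery experiment sees.
#' Used to verify the R1,F constraint.
#'
#' @param r1f_hz intrinsic free-pool R1, Hz
#' @param params \code{\link{mt_params}}
#' @return observed R1, Hz
#' @export
observed_r1_two_pool <- function(r1f_hz, params) {
  rm <- params$r_mt_hz; m0 <- params$m0_mt; r1mt <- params$r1_mt_hz
  kf <- rm * m0
  a <- matrix(c(-(r1f_hz + kf), rm,
                kf, -(r1mt + rm)), 2, 2, byrow = TRUE)
  -max(Re(eigen(a, only.values = TRUE)$values))
}

#' Inversion-recovery signal by time-domain longitudinal relaxation
#'
#' Simulates the steady cycle of an inversion-recovery experiment (ideal
#' inversion, 90-degree readout that nulls Mz, free relaxation for the
#' rest of TR) by integrating dMz/dt = R1 (M0 - Mz) with an ODE solver,
#' cycling until the pre-inversion magnetization converges.  Oracle for
#' \code{\link{ir_signal}}.
#'
#' @param ti_ms inversion time, ms
#' @param t1_ms longitudinal relaxation time, ms
#' @param tr_ms repetition time, ms
#' @param s0 equilibrium signal
#' @return signal magnitude at the readout
#' @export
ir_signal_ode <- function(ti_ms, t1_ms, tr_ms = 10000, s0 = 1) {
  r1 <- 1 / t1_ms                 # per ms
  relax <- function(mz0, t) {
    f <- function(t, y, p) list(r1 * (s0 - y))
    out <- deSolve::lsoda(c(mz = mz0), c(0, t), f, NULL,
                          rtol = 1e-12, atol = 1e-14)
    unname(out[nrow(out), 2])
  }
  m_pre <- s0
  for (cycle in 1:50) {
    m_ti <- relax(-m_pre, ti_ms)            # inversion, recover to readout
    m_next <- relax(0, tr_ms - ti_ms)       # 90-degree readout nulls Mz
    if (abs(m_next - m_pre) < 1e-12) { m_pre <- m_next; break }
    m_pre <- m_next
  }
  abs(relax(-m_pre, ti_ms))
}
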