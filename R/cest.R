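#' Extrapolated semisolid MT reference (EMR)
#'
#' Evaluates the fitted two-pool model (direct saturation + MT, no CEST
#' pools) at a low B1 level; this is the CEST-free reference Z_EMR against
#' which the measured (label) Z-spectrum is compared.
#'
#' @param params fitted \code{\link{mt_params}}
#' @param t1_obs_ms observed T1, ms
#' @param b1_ut low saturation amplitude, µT
#' @param offset_ppm offsets, ppm
#' @param f0_mhz proton frequency, MHz
#' @return Z_EMR value(s)
#' @export
compute_emr <- function(params, t1_obs_ms, b1_ut, offset_ppm,
                        f0_mhz = DEFAULT_F0_MHZ) {
  two_pool_z(params, t1_obs_ms, b1_ut, offset_ppm, f0_mhz)
}

#' Inverse-difference CEST metric MTR_REX
#'
#' MTR_REX = 1/Z_lab - 1/Z_EMR.  The inverse difference removes the
#' multiplicative dilution of the CEST effect by direct saturation and MT.
#' Negative values are retained.
#'
#' @param z_lab measured normalized signal(s)
#' @param z_emr reference signal(s)
#' @return MTR_REX, dimensionless
#' @export
mtr_rex <- function(z_lab, z_emr) {
  if (any(z_lab <= 0, na.rm = TRUE) || any(z_emr <= 0, na.rm = TRUE))
    stop("Z values must be positive")
  1 / z_lab - 1 / z_emr
}

#' Apparent exchange-dependent relaxation AREX
#'
#' AREX = MTR_REX / T1 with T1 in seconds, compensating T1 differences
#' between tissues; units Hz.  The measured T1,obs is used by convention.
#'
#' @param mtr_rex MTR_REX value(s)
#' @param t1_ms T1 in ms
#' @return AREX in Hz
#' @export
arex <- function(mtr_rex, t1_ms) {
  stopifnot(all(t1_ms > 0, na.rm = TRUE))
  mtr_rex / (t1_ms / 1000)
}

#' Per-voxel MTR_REX and AREX maps at the CEST/rNOE offsets
#'
#' For each requested low-B1 level and offset, Z_lab is read from the
#' B0-corrected spectrum by linear interpolation and Z_EMR from the
#' two-pool model; MTR_REX and AREX are computed per voxel.
#'
#' @param preproc \code{\link{preprocess_study}} output
#' @param mt_fit either a single \code{\link{mt_params}} (applied to every
#'   voxel, e.g. an ROI fit) or a list of per-voxel maps as returned by
#'   \code{\link{fit_mt_map}}
#' @param t1_map matrix of T1,obs, ms
#' @param b1_ut low-B1 levels to evaluate, µT
#' @param offsets_ppm query offsets, ppm
#' @param mask logical matrix (default: preprocessing validity mask)
#' @param conventional if TRUE also return the conventional subtraction
#'   metric Z_EMR - Z_lab
#' @param f0_mhz proton frequency, MHz
#' @return list with arrays \code{mtr_rex} and \code{arex} (and optionally
#'   \code{subtraction}) of dim (rows, cols, offsets, B1 levels), with
#'   dimnames on the last two margins
#' @export
cest_maps <- function(preproc, mt_fit, t1_map, b1_ut = c(0.5, 2),
                      offsets_ppm = c(3.5, 2.0, -3.3),
                      mask = preproc$valid, conventional = FALSE,
                      f0_mhz = DEFAULT_F0_MHZ) {
  nr <- nrow(mask); nc <- ncol(mask)
  uniform <- inherits(mt_fit, "mt_params")
  dn <- list(NULL, NULL, as.character(offsets_ppm), as.character(b1_ut))
  shape <- c(nr, nc, length(offsets_ppm), length(b1_ut))
  out <- list(mtr_rex = array(NA_real_, shape, dn),
              arex = array(NA_real_, shape, dn))
  if (conventional) out$subtraction <- array(NA_real_, shape, dn)
  b1s <- vapply(preproc$zs, `[[`, numeric(1), "b1_ut")
  for (j in seq_along(b1_ut)) {
    nm <- names(preproc$zs)[which(abs(b1s - b1_ut[j]) < 1e-9)]
    if (!length(nm)) stop("no preprocessed stack at B1 = ", b1_ut[j])
    zset <- preproc$zs[[nm]]
    for (v in which(mask & is.finite(t1_map))) {
      row <- (v - 1) %% nr + 1; col <- (v - 1) %/% nr + 1
      zz <- zset$z[row, col, ]
      ok <- is.finite(zz)
      if (sum(ok) < 4) next
      z_lab <- stats::approx(zset$offset_ppm[ok], zz[ok],
                             xout = offsets_ppm, rule = 1)$y
      pars <- if (uniform) mt_fit else {
        if (!is.finite(mt_fit$t2_f_ms[row, col])) next
        mt_params(mt_fit$t2_f_ms[row, col], mt_fit$r_mt_hz[row, col],
                  mt_fit$m0_mt[row, col], mt_fit$t2_mt_us[row, col])
      }
      z_emr <- compute_emr(pars, t1_map[row, col], b1_ut[j], offsets_ppm,
                           f0_mhz)
      good <- is.finite(z_lab) & z_lab > 0
      mr <- rep(NA_real_, length(offsets_ppm))
      mr[good] <- 1 / z_lab[good] - 1 / z_emr[good]
      out$mtr_rex[row, col, , j] <- mr
      out$arex[row, col, , j] <- mr / (t1_map[row, col] / 1000)
      if (conventional)
        out$subtraction[row, col, , j] <- z_emr - z_lab
    }
  }
  out
}
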