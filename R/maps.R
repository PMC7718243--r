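#' Voxelwise T1 map from the inversion-recovery series
#'
#' @param study \code{\link{simulate_study}} output (uses \code{study$ir})
#' @param mask logical matrix of voxels to fit (default non-background)
#' @param tr_ms repetition time of the IR acquisition, ms
#' @return list with \code{t1_ms} and \code{s0} matrices and a logical
#'   \code{valid} matrix
#' @export
fit_t1_map <- function(study, mask = NULL, tr_ms = study$protocol$tr_ms) {
  if (is.null(mask)) mask <- study$label != 1L
  nr <- nrow(mask); nc <- ncol(mask)
  t1 <- matrix(NA_real_, nr, nc); s0 <- t1; valid <- matrix(FALSE, nr, nc)
  for (v in which(mask)) {
    row <- (v - 1) %% nr + 1; col <- (v - 1) %/% nr + 1
    f <- fit_t1(study$ir$frames[row, col, ], study$ir$ti_ms, tr_ms)
    t1[row, col] <- f$t1_ms; s0[row, col] <- f$s0
    valid[row, col] <- f$valid
  }
  list(t1_ms = t1, s0 = s0, valid = valid)
}

#' Voxelwise T2 map from the preprocessed WASSR stack and a T1 map
#'
#' @param preproc \code{\link{preprocess_study}} output
#' @param t1_map matrix of T1,obs (ms)
#' @param mask logical matrix (default: the preprocessing validity mask)
#' @return list with \code{t2_ms} and \code{valid} matrices
#' @export
fit_t2_map <- function(preproc, t1_map, mask = preproc$valid) {
  ws <- preproc$wassr_raw
  nr <- nrow(mask); nc <- ncol(mask)
  t2 <- matrix(NA_real_, nr, nc); valid <- matrix(FALSE, nr, nc)
  for (v in which(mask & is.finite(t1_map))) {
    row <- (v - 1) %% nr + 1; col <- (v - 1) %/% nr + 1
    sh <- preproc$b0_wassr[row, col]
    if (!is.finite(sh)) next
    f <- tryCatch(fit_t2_wassr(ws$z[row, col, ], ws$offset_ppm,
                               t1_map[row, col], b1_ut = ws$b1_ut,
                               center_ppm = sh),
                  error = function(e) NULL)
    if (!is.null(f)) {
      t2[row, col] <- f$t2_ms; valid[row, col] <- f$valid
    }
  }
  list(t2_ms = t2, valid = valid)
}

#' ROI-level two-pool MT fit
#'
#' Averages the preprocessed Z-spectra at the MT-informative B1 levels
#' over the ROI, then fits the two-pool model to the mean spectra with the
#' ROI-mean T1,obs — the default analysis mode for group statistics.
#'
#' @param preproc \code{\link{preprocess_study}} output
#' @param t1_map matrix of T1,obs, ms
#' @param mask logical ROI matrix
#' @param b1_levels B1 levels entering the fit, µT
#' @param ... passed to \code{\link{fit_two_pool}}
#' @return \code{\link{fit_two_pool}} result plus \code{t1_obs_ms}
#' @export
fit_mt_roi <- function(preproc, t1_map, mask, b1_levels = c(0.1, 3, 6),
                       ...) {
  mask <- mask & preproc$valid & is.finite(t1_map)
  if (!any(mask)) stop("empty ROI after validity masking")
  spectra <- list()
  for (nm in names(preproc$zs)) {
    zset <- preproc$zs[[nm]]
    if (!any(abs(zset$b1_ut - b1_levels) < 1e-9)) next
    nf <- dim(zset$z)[3]
    zm <- vapply(seq_len(nf), function(k) {
      zz <- zset$z[, , k][mask]
      mean(zz[is.finite(zz)])
    }, numeric(1))
    spectra[[nm]] <- list(b1_ut = zset$b1_ut, offset_ppm = zset$offset_ppm,
                          z = zm)
  }
  fit <- fit_two_pool(spectra, mean(t1_map[mask]), ...)
  fit$t1_obs_ms <- mean(t1_map[mask])
  fit
}

#' Voxelwise two-pool MT fit
#'
#' Per-voxel variant of \code{\link{fit_mt_roi}}; considerably slower and
#' intended for parameter maps of small regions.
#'
#' @inheritParams fit_mt_roi
#' @return list of matrices: \code{t2_f_ms}, \code{mt_effect_hz},
#'   \code{t2_mt_us}, \code{r_mt_hz}, \code{m0_mt}, \code{valid}
#' @export
fit_mt_map <- function(preproc, t1_map, mask, b1_levels = c(0.1, 3, 6),
                       ...) {
  mask <- mask & preproc$valid & is.finite(t1_map)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- list(t2_f_ms = matrix(NA_real_, nr, nc))
  out$mt_effect_hz <- out$t2_f_ms; out$t2_mt_us <- out$t2_f_ms
  out$r_mt_hz <- out$t2_f_ms; out$m0_mt <- out$t2_f_ms
  out$valid <- matrix(FALSE, nr, nc)
  use <- vapply(preproc$zs, function(s)
    any(abs(s$b1_ut - b1_levels) < 1e-9), logical(1))
  for (v in which(mask)) {
    row <- (v - 1) %% nr + 1; col <- (v - 1) %/% nr + 1
    spectra <- lapply(preproc$zs[use], function(s)
      list(b1_ut = s$b1_ut, offset_ppm = s$offset_ppm,
           z = s$z[row, col, ]))
    fit <- tryCatch(fit_two_pool(spectra, t1_map[row, col], ...),
                    error = function(e) NULL)
    if (is.null(fit)) next
    out$t2_f_ms[row, col] <- fit$params$t2_f_ms
    out$mt_effect_hz[row, col] <- fit$mt_effect_hz
    out$t2_mt_us[row, col] <- fit$params$t2_mt_us
    out$r_mt_hz[row, col] <- fit$params$r_mt_hz
    out$m0_mt[row, col] <- fit$params$m0_mt
    out$valid[row, col] <- fit$converged && !fit$at_boundary
  }
  out
}
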