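#' Drift correction from interleaved reference scans
#'
#' Fits a straight line (least squares) through the reference-scan signals
#' versus acquisition index and divides every frame by the line's predicted
#' reference value at its own index; the result is the drift-corrected
#' normalized Z-spectrum.
#'
#' @param frames numeric vector (one voxel, acquisition order), matrix
#'   (voxels x frames) or 3-D array (rows x cols x frames)
#' @param table acquisition table with \code{acq_index} and
#'   \code{is_reference} (see \code{\link{acquisition_table}})
#' @return list with \code{z} (measurement frames only, normalized; same
#'   leading dimensions as the input), \code{offsets_kept} (indices into
#'   the measurement frames of \code{table}), \code{intercept},
#'   \code{slope} (per voxel), \code{valid} (per voxel; FALSE where the
#'   predicted reference is not positive)
#' @export
drift_correct <- function(frames, table) {
  dims <- NULL
  if (is.array(frames) && length(dim(frames)) == 3) {
    dims <- dim(frames)[1:2]
    frames <- matrix(frames, prod(dims), dim(frames)[3])
  } else if (is.vector(frames)) {
    frames <- matrix(frames, 1)
  }
  stopifnot(ncol(frames) == nrow(table))
  ref_i <- which(table$is_reference)
  if (length(ref_i) < 2) stop("need at least 2 reference frames")
  x <- table$acq_index[ref_i]
  xb <- mean(x); sxx <- sum((x - xb)^2)
  refs <- frames[, ref_i, drop = FALSE]
  slope <- as.vector(refs %*% (x - xb)) / sxx
  intercept <- rowMeans(refs) - slope * xb
  meas_i <- which(!table$is_reference)
  pred <- outer(slope, table$acq_index[meas_i]) + intercept
  valid <- apply(pred > 0, 1, all) & intercept > 0
  z <- frames[, meas_i, drop = FALSE] / pred
  z[!valid, ] <- NA_real_
  if (!is.null(dims)) {
    z <- array(z, c(dims, length(meas_i)))
    slope <- matrix(slope, dims[1], dims[2])
    intercept <- matrix(intercept, dims[1], dims[2])
    valid <- matrix(valid, dims[1], dims[2])
  }
  list(z = z, offsets_kept = meas_i, intercept = intercept, slope = slope,
       valid = valid)
}

# Lorentzian with amplitude a, FWHM w, centre c
lorentz <- function(offset, a, w, c) a * w^2 / (w^2 + 4 * (offset - c)^2)

#' B0 shift from a WASSR spectrum by single-Lorentzian fitting
#'
#' Nonlinear least squares of 1 - L(offset; amplitude, width, centre) to
#' the points with |offset| <= \code{window_ppm}; the fitted centre is the
#' per-voxel B0 shift.  Points with Z below \code{min_z} are excluded to
#' avoid fitting the noise-dominated bottom of the direct-saturation dip.
#'
#' @param z normalized WASSR signals
#' @param offset_ppm offsets, ppm
#' @param window_ppm fit window half-width, ppm
#' @param min_z lower Z cutoff for inclusion
#' @return list with \code{shift_ppm}, \code{width_ppm},
#'   \code{amplitude}, \code{valid}
#' @export
fit_b0_wassr <- function(z, offset_ppm, window_ppm = 0.5, min_z = 0.05) {
  keep <- is.finite(z) & abs(offset_ppm) <= window_ppm & z >= min_z
  if (sum(keep) < 5)
    return(list(shift_ppm = NA_real_, width_ppm = NA_real_,
                amplitude = NA_real_, valid = FALSE))
  zz <- z[keep]; off <- offset_ppm[keep]
  p0 <- c(a = min(1 - min(zz), 1.1), w = 1, c = off[which.min(zz)])
  fit <- tryCatch(
    minpack.lm::nls.lm(p0, lower = c(0, 0.01, -window_ppm),
                       upper = c(1.2, 20, window_ppm),
                       fn = function(p) 1 - lorentz(off, p[1], p[2], p[3]) - zz,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4)
    return(list(shift_ppm = NA_real_, width_ppm = NA_real_,
                amplitude = NA_real_, valid = FALSE))
  p <- stats::coef(fit)
  list(shift_ppm = unname(p[3]), width_ppm = unname(p[2]),
       amplitude = unname(p[1]), valid = TRUE)
}

#' B0 shift from a low-B1 Z-spectrum by two-Lorentzian decomposition
#'
#' Fits the sum of a narrow direct-saturation Lorentzian and a broad MT
#' Lorentzian sharing the same centre; the centre is the B0 shift.  The
#' known solute resonance bands (amide/guanidinium around +2 to +4 ppm,
#' aliphatic rNOE around -3 ppm) are excluded by default: their dips are
#' not part of the DE+MT model and would bias the fitted centre.
#'
#' @param z normalized signals of a 0.5 or 2 µT spectrum
#' @param offset_ppm offsets, ppm (should span at least ±4 ppm)
#' @param min_z lower Z cutoff for inclusion
#' @param exclude_bands list of c(lo, hi) ppm intervals removed from the
#'   fit; NULL to fit all points
#' @return list as in \code{\link{fit_b0_wassr}} plus the MT component
#'   (\code{amplitude_mt}, \code{width_mt_ppm})
#' @export
fit_b0_lowb1 <- function(z, offset_ppm, min_z = 0.05,
                         exclude_bands = list(c(1.2, 4.8),
                                              c(-4.8, -1.8))) {
  keep <- is.finite(z) & z >= min_z
  for (b in exclude_bands)
    keep <- keep & !(offset_ppm >= b[1] & offset_ppm <= b[2])
  if (sum(keep) < 8 || max(offset_ppm[keep]) < 4 || min(offset_ppm[keep]) > -4)
    return(list(shift_ppm = NA_real_, valid = FALSE))
  zz <- z[keep]; off <- offset_ppm[keep]
  resid_fn <- function(p)
    1 - lorentz(off, p[1], p[2], p[3]) - lorentz(off, p[4], p[5], p[3]) - zz
  # multi-start over the DE width: the excluded dip core and solute bands
  # leave a profile whose single-start fit can stall on a boundary
  fit <- NULL
  for (w0 in c(1, 3, 6)) {
    p0 <- c(a1 = min(1 - min(zz), 1.1), w1 = w0,
            c = off[which.min(zz)], a2 = 0.1, w2 = 50)
    cand <- tryCatch(
      minpack.lm::nls.lm(p0, lower = c(0, 0.05, -1, 0, 5),
                         upper = c(1.2, 12, 1, 1.2, 500),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand) && cand$info %in% 1:4 &&
        (is.null(fit) || stats::deviance(cand) < stats::deviance(fit)))
      fit <- cand
  }
  if (is.null(fit))
    return(list(shift_ppm = NA_real_, valid = FALSE))
  p <- stats::coef(fit)
  list(shift_ppm = unname(p[3]), width_ppm = unname(p[2]),
       amplitude = unname(p[1]), amplitude_mt = unname(p[4]),
       width_mt_ppm = unname(p[5]), valid = TRUE)
}

#' Re-centre a Z-spectrum onto its nominal offset grid
#'
#' Linearly interpolates the measured spectrum at \code{offset + shift} so
#' that the direct-saturation dip sits at 0 ppm; offsets falling outside
#' the sampled range become NA.
#'
#' @param z measured signals
#' @param offset_ppm nominal offsets, ppm
#' @param shift_ppm fitted B0 shift, ppm
#' @return re-centred signals on the original grid
#' @export
recenter <- function(z, offset_ppm, shift_ppm) {
  if (!is.finite(shift_ppm)) return(rep(NA_real_, length(z)))
  if (shift_ppm == 0) return(z)
  ok <- is.finite(z)
  stats::approx(offset_ppm[ok], z[ok], xout = offset_ppm + shift_ppm,
                method = "linear", rule = 1)$y
}

#' Binary mask erosion with the full 3x3 structuring element
#'
#' A pixel survives iff itself and all 8 neighbours are set
#' (8-connectivity), removing the partial-volume-contaminated edge
#' layer.  Pixels outside the image count as background, so the image
#' border is always eroded.
#'
#' @param mask logical or 0/1 matrix
#' @return logical matrix of the same shape
#' @export
erode_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- as.logical(mask)
  out <- matrix(TRUE, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    out <- out & p[(1 + di):(nr + di), (1 + dj):(nc + dj)]
  out
}

#' Validity mask from a B0 shift map
#'
#' Voxels with |shift| strictly greater than the threshold, or with an
#' invalid (non-finite) shift, are excluded.
#'
#' @param shift_map per-voxel B0 shifts, ppm
#' @param threshold_ppm exclusion threshold, ppm
#' @return logical matrix, TRUE where retained
#' @export
exclude_b0_outliers <- function(shift_map, threshold_ppm = 0.5) {
  ok <- is.finite(shift_map) & abs(shift_map) <= threshold_ppm
  ok[!is.finite(shift_map)] <- FALSE
  ok
}

#' Normalize T1/T2 maps to the segmentation feature range
#'
#' T1 is divided by 4000 ms and T2 by 300 ms (values slightly above the
#' highest seen in tumours), matching the range of the normalized
#' saturation-transfer images; no clipping is applied.
#'
#' @param t1_map,t2_map maps in ms
#' @return list with \code{t1}, \code{t2}
#' @export
normalize_maps <- function(t1_map, t2_map) {
  list(t1 = t1_map / 4000, t2 = t2_map / 300)
}

#' Full Z-spectrum preprocessing of a simulated study
#'
#' Per B1 stack: drift correction and reference normalization; then
#' spectrum-wise B0 estimation and re-centring for the WASSR (single
#' Lorentzian, ±0.5 ppm window) and low-B1 (two shared-centre Lorentzians)
#' stacks.  High-B1 stacks (log-spaced offsets from 3 ppm) are not
#' B0-corrected.  The voxel validity mask combines 3x3 erosion of the
#' foreground with exclusion of WASSR B0 shifts above the threshold.
#'
#' @param study \code{\link{simulate_study}} output
#' @param b0_threshold_ppm B0 exclusion threshold, ppm
#' @param mask optional foreground mask (defaults to non-background labels)
#' @return list of class \code{preprocessed_study}: \code{zs} (per B1:
#'   \code{z} array of corrected measurement frames, \code{offset_ppm}),
#'   \code{b0_wassr}, \code{b0_lowb1} (per low-B1 level), \code{valid},
#'   \code{drift} (per B1: slope/intercept maps), \code{report}
#' @export
preprocess_study <- function(study, b0_threshold_ppm = 0.5, mask = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  if (is.null(mask)) mask <- study$label != 1L
  nr <- nrow(mask); nc <- ncol(mask)
  zs <- list(); drift <- list(); b0_lowb1 <- list()
  for (nm in names(study$stacks)) {
    st <- study$stacks[[nm]]
    dc <- drift_correct(st$frames, st$table)
    zs[[nm]] <- list(b1_ut = st$b1_ut, z = dc$z,
                     offset_ppm = st$table$offset_ppm[dc$offsets_kept])
    drift[[nm]] <- list(slope = dc$slope, intercept = dc$intercept,
                        valid = dc$valid)
  }
  b1s <- vapply(zs, `[[`, numeric(1), "b1_ut")
  wassr_nm <- names(zs)[which.min(b1s)]
  # keep the drift-corrected but un-recentred WASSR: the T2 fit corrects
  # B0 by shifting the model, avoiding interpolation across the narrow dip
  wassr_raw <- zs[[wassr_nm]]
  b0_wassr <- matrix(NA_real_, nr, nc)
  for (v in which(mask)) {
    row <- (v - 1) %% nr + 1; col <- (v - 1) %/% nr + 1
    f <- fit_b0_wassr(zs[[wassr_nm]]$z[row, col, ],
                      zs[[wassr_nm]]$offset_ppm)
    b0_wassr[row, col] <- f$shift_ppm
    if (f$valid)
      zs[[wassr_nm]]$z[row, col, ] <-
        recenter(zs[[wassr_nm]]$z[row, col, ], zs[[wassr_nm]]$offset_ppm,
                 f$shift_ppm)
  }
  for (nm in names(zs)) {
    b1 <- zs[[nm]]$b1_ut
    if (b1 <= 0.3 || b1 > 2.5) next  # WASSR handled; high B1 not corrected
    sh <- matrix(NA_real_, nr, nc)
    for (v in which(mask)) {
      row <- (v - 1) %% nr + 1; col <- (v - 1) %/% nr + 1
      f <- fit_b0_lowb1(zs[[nm]]$z[row, col, ], zs[[nm]]$offset_ppm)
      sh[row, col] <- f$shift_ppm
      if (f$valid)
        zs[[nm]]$z[row, col, ] <-
          recenter(zs[[nm]]$z[row, col, ], zs[[nm]]$offset_ppm, f$shift_ppm)
    }
    b0_lowb1[[nm]] <- sh
  }
  valid <- erode_mask(mask) & exclude_b0_outliers(b0_wassr, b0_threshold_ppm)
  report <- list(
    n_mask = sum(mask), n_valid = sum(valid),
    n_b0_excluded = sum(erode_mask(mask) &
                          !exclude_b0_outliers(b0_wassr, b0_threshold_ppm)),
    drift_slope_mean = mean(vapply(drift, function(d)
      mean(d$slope[mask]), numeric(1))))
  structure(list(zs = zs, wassr_raw = wassr_raw, b0_wassr = b0_wassr,
                 b0_lowb1 = b0_lowb1, valid = valid, drift = drift,
                 report = report),
            class = "preprocessed_study")
}
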