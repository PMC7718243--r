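#' Digital tumour-phantom specification
#'
#' Defines the geometry and generative parameters of a single-slice
#' phantom: a muscle rim enclosing a ring of muscle/connective tissue, a
#' tumour interior with a necrotic core, and sparse blood/edema specks.
#' Ellipses are given in normalized image coordinates (fractions of the
#' grid); they must nest (core inside tumour inside connective ring inside
#' muscle), otherwise the spec is rejected as overlapping.
#'
#' @param grid_shape c(rows, cols), at least 16 x 16
#' @param regions named list of \code{\link{region_spec}} (see
#'   \code{\link{default_regions}})
#' @param geometry list of ellipse definitions; see Details.  Each ellipse
#'   is \code{c(cx, cy, rx, ry)} in fractions of the grid.
#' @param b0 list with \code{amplitude_ppm} (peak-to-peak scale of the
#'   smooth second-order polynomial off-resonance field) and optional
#'   \code{n_outliers}/\code{outlier_ppm} for badly shimmed specks
#' @param seed integer seed controlling all phantom randomness
#' @return object of class \code{phantom_spec}
#' @export
phantom_spec <- function(grid_shape = c(64, 64),
                         regions = default_regions("22Rv1"),
                         geometry = list(
                           muscle = c(0.5, 0.5, 0.44, 0.42),
                           muscle_connective = c(0.5, 0.5, 0.34, 0.32),
                           tumour = c(0.5, 0.5, 0.30, 0.28),
                           necrosis = c(0.5, 0.5, 0.11, 0.10),
                           n_specks = 8, speck_radius = 0.03),
                         b0 = list(amplitude_ppm = 0.1, n_outliers = 0,
                                   outlier_ppm = 0.8),
                         seed = 1) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 16))
  for (r in regions) stopifnot(inherits(r, "region_spec"))
  ell <- geometry[c("muscle", "muscle_connective", "tumour", "necrosis")]
  for (i in 2:4) {
    inner <- ell[[i]]; outer <- ell[[i - 1]]
    # the inner ellipse must fit inside the outer one along both axes
    if (abs(inner[1] - outer[1]) + inner[3] > outer[3] ||
        abs(inner[2] - outer[2]) + inner[4] > outer[4])
      stop("overlapping regions: '", names(ell)[i],
           "' is not nested inside '", names(ell)[i - 1], "'")
  }
  structure(list(grid_shape = grid_shape, regions = regions,
                 geometry = geometry, b0 = b0, seed = as.integer(seed)),
            class = "phantom_spec")
}

in_ellipse <- function(rows, cols, nr, nc, e) {
  ((rows - e[1] * nr) / (e[3] * nr))^2 +
    ((cols - e[2] * nc) / (e[4] * nc))^2 <= 1
}

# Gaussian draws truncated at zero by redrawing
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= 0)
  }
  x
}

#' Rasterize the phantom geometry and draw per-voxel ground truth
#'
#' Paints the region label image (later regions overwrite earlier ones, in
#' the order muscle, muscle/connective, tumour, necrosis, blood/edema
#' specks) and draws every voxel's generative parameters from its region's
#' truncated Gaussians.  Also generates the smooth per-voxel B0 offset
#' field.
#'
#' @param spec \code{\link{phantom_spec}}
#' @return list of class \code{phantom_geometry} with \code{label}
#'   (integer matrix, levels \code{REGION_LABELS}), \code{truth} (named
#'   list of per-voxel matrices: t1_obs_ms, t2_obs_ms, t2_f_ms,
#'   mt_effect_hz, r_mt_hz, m0_mt, t2_mt_us, b0_ppm, and one
#'   \code{pool_<offset>} amplitude map per pool offset), and the spec
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  rows <- matrix(seq_len(nr) - 0.5, nr, nc)
  cols <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  lab <- matrix(1L, nr, nc)  # background
  paint <- function(lab, name) {
    if (!name %in% names(spec$regions)) return(lab)
    m <- in_ellipse(rows, cols, nr, nc, spec$geometry[[name]])
    lab[m] <- match(name, REGION_LABELS)
    lab
  }
  set.seed(spec$seed)
  for (name in c("muscle", "muscle_connective", "tumour", "necrosis"))
    lab <- paint(lab, name)
  if ("blood_edema" %in% names(spec$regions) && spec$geometry$n_specks > 0) {
    tum_idx <- which(lab == match("tumour", REGION_LABELS))
    n_specks <- min(spec$geometry$n_specks, length(tum_idx))
    centres <- sample(tum_idx, n_specks)
    rad <- spec$geometry$speck_radius * nr
    for (ct in centres) {
      cr <- (ct - 1) %% nr + 1; cc <- (ct - 1) %/% nr + 1
      m <- (rows - cr + 0.5)^2 + (cols - cc + 0.5)^2 <= rad^2
      # specks stay inside the tumour interior
      m <- m & lab == match("tumour", REGION_LABELS)
      lab[m] <- match("blood_edema", REGION_LABELS)
    }
  }
  pool_offsets <- unlist(lapply(spec$regions, function(r)
    vapply(r$cest_pools, `[[`, numeric(1), "offset_ppm")))
  pool_offsets <- if (is.null(pool_offsets)) numeric(0) else
    sort(unique(pool_offsets), decreasing = TRUE)
  blank <- matrix(NA_real_, nr, nc)
  truth <- list(t1_obs_ms = blank, t2_obs_ms = blank, t2_f_ms = blank,
                mt_effect_hz = blank, r_mt_hz = blank, m0_mt = blank,
                t2_mt_us = blank)
  pool_width <- stats::setNames(rep(1, length(pool_offsets)),
                                if (length(pool_offsets))
                                  paste0("pool_", pool_offsets)
                                else character(0))
  for (po in pool_offsets) truth[[paste0("pool_", po)]] <- blank
  for (r in spec$regions) {
    idx <- which(lab == match(r$label, REGION_LABELS))
    if (!length(idx)) next
    n <- length(idx)
    truth$t1_obs_ms[idx] <- rnorm_pos(n, r$t1_obs_ms[1], r$t1_obs_ms[2])
    truth$t2_obs_ms[idx] <- pmin(
      rnorm_pos(n, r$t2_obs_ms[1], r$t2_obs_ms[2]),
      0.95 * truth$t1_obs_ms[idx])
    truth$t2_f_ms[idx] <- rnorm_pos(n, r$t2_f_ms[1], r$t2_f_ms[2])
    truth$mt_effect_hz[idx] <- rnorm_pos(n, r$mt_effect_hz[1],
                                         r$mt_effect_hz[2])
    truth$r_mt_hz[idx] <- r$r_mt_ref_hz
    truth$m0_mt[idx] <- truth$mt_effect_hz[idx] / r$r_mt_ref_hz
    truth$t2_mt_us[idx] <- rnorm_pos(n, r$t2_mt_us[1], r$t2_mt_us[2])
    for (p in r$cest_pools) {
      nm <- paste0("pool_", p$offset_ppm)
      truth[[nm]][idx] <- p$amplitude_hz
      pool_width[nm] <- p$width_ppm
    }
    for (po in pool_offsets) {
      nm <- paste0("pool_", po)
      truth[[nm]][idx][is.na(truth[[nm]][idx])] <- 0
    }
  }
  # smooth second-order polynomial B0 field, scaled to the requested
  # amplitude; optional badly shimmed outlier specks
  x <- (cols - nc / 2) / (nc / 2); y <- (rows - nr / 2) / (nr / 2)
  cf <- stats::runif(5, -1, 1)
  b0 <- cf[1] * x + cf[2] * y + cf[3] * x * y + cf[4] * x^2 + cf[5] * y^2
  mx <- max(abs(b0))
  b0 <- if (mx > 0) b0 / mx * spec$b0$amplitude_ppm else b0
  n_out <- spec$b0$n_outliers %||% 0
  if (n_out > 0) {
    fg <- which(lab != 1L)
    out_idx <- sample(fg, min(n_out, length(fg)))
    b0[out_idx] <- b0[out_idx] +
      sample(c(-1, 1), length(out_idx), TRUE) * spec$b0$outlier_ppm
  }
  truth$b0_ppm <- b0
  structure(list(label = lab, truth = truth, pool_offsets = pool_offsets,
                 pool_width = pool_width, spec = spec),
            class = "phantom_geometry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Region mask from a phantom geometry or study
#'
#' @param x \code{phantom_geometry} or \code{synthetic_study}
#' @param region region name (see \code{REGION_LABELS}), or "foreground"
#'   for all non-background voxels
#' @return logical matrix
#' @export
region_mask <- function(x, region = "foreground") {
  lab <- x$label
  if (region == "foreground") return(lab != 1L)
  lab == match(match.arg(region, REGION_LABELS), REGION_LABELS)
}
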