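# Fast super-Lorentzian evaluation via the scaling identity
# g(offset, T2) = T2 * h(x), x = 2*pi*offset_Hz*T2, with h tabulated once
# from the same adaptive quadrature and spline-interpolated in log-log
# space (relative error ~1e-8 against the exact integral).
.sl_cache <- new.env(parent = emptyenv())

sl_h_exact <- function(x) {
  u0 <- 1 / sqrt(3)
  f <- function(u) {
    s <- 3 * u^2 - 1
    ifelse(s == 0, 0, 1 / abs(s) * exp(-2 * (x / s)^2))
  }
  q <- function(lo, hi)
    stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 1e-300,
                     subdivisions = 1000L, stop.on.error = FALSE)$value
  sqrt(2 / pi) * (q(0, u0) + q(u0, 1))
}

sl_h_spline <- function() {
  if (is.null(.sl_cache$fun)) {
    xs <- exp(seq(log(1e-4), log(80), length.out = 1500))
    hs <- vapply(xs, sl_h_exact, numeric(1))
    pos <- hs > 1e-280
    .sl_cache$xmax <- max(xs[pos])
    .sl_cache$xmin <- min(xs)
    .sl_cache$fun <- stats::splinefun(log(xs[pos]), log(hs[pos]),
                                      method = "natural")
  }
  .sl_cache
}

superlorentzian_fast <- function(offset_ppm, t2_mt_us,
                                 f0_mhz = DEFAULT_F0_MHZ, cutoff_ppm = 1) {
  cache <- sl_h_spline()
  t2 <- t2_mt_us * 1e-6
  x <- 2 * pi * ppm_to_hz(pmax(abs(offset_ppm), cutoff_ppm), f0_mhz) * t2
  out <- numeric(length(x))
  inside <- x >= cache$xmin & x <= cache$xmax
  out[inside] <- t2 * exp(cache$fun(log(x[inside])))
  small <- x < cache$xmin
  if (any(small))
    out[small] <- superlorentzian_g(offset_ppm[small], t2_mt_us, f0_mhz,
                                    cutoff_ppm)
  out  # x > xmax: lineshape underflows to zero
}

#' Acquisition protocol for a simulated saturation-transfer study
#'
#' @param b1_levels saturation amplitudes, µT.  The lowest level (0.1 µT by
#'   default) is the WASSR acquisition.
#' @param offsets named list (one entry per B1 level, names
#'   \code{as.character(b1)}) of offset grids in ppm; defaults: ±1 ppm in
#'   0.1 ppm steps for WASSR, ±6 ppm in 0.2 ppm steps for 0.5/2 µT, and 30
#'   log-spaced points over ±(3–300) ppm for 3/6 µT
#' @param reference_offset_ppm offset of the normalization reference scans
#' @param reference_every interleave a reference after this many
#'   Z-spectrum measurements (plus one before and one after the series)
#' @param f0_mhz proton frequency, MHz
#' @param ti_ms inversion times of the IR series, ms
#' @param tr_ms IR repetition time, ms
#' @param noise_sd Gaussian noise SD as a fraction of the equilibrium
#'   signal
#' @param drift_slope fractional signal drift per acquisition index
#' @param cest_b1_ut B1 levels into which CEST/rNOE pools are injected
#' @param rician if TRUE apply noise as the magnitude of a complex signal
#' @return object of class \code{st_protocol}
#' @export
protocol <- function(b1_levels = c(0.1, 0.5, 2, 3, 6),
                     offsets = default_offsets(b1_levels),
                     reference_offset_ppm = 667, reference_every = 5,
                     f0_mhz = DEFAULT_F0_MHZ,
                     ti_ms = c(30, 110, 390, 1400, 5000), tr_ms = 10000,
                     noise_sd = 0.01, drift_slope = 2e-4,
                     cest_b1_ut = c(0.5, 2), rician = FALSE) {
  stopifnot(noise_sd >= 0, all(b1_levels > 0),
            all(as.character(b1_levels) %in% names(offsets)))
  for (o in offsets) stopifnot(all(is.finite(o)))
  if (reference_offset_ppm < 2 * max(abs(unlist(offsets))))
    stop("reference offset must lie far outside all fitting windows")
  structure(list(b1_levels = b1_levels, offsets = offsets,
                 reference_offset_ppm = reference_offset_ppm,
                 reference_every = reference_every, f0_mhz = f0_mhz,
                 ti_ms = ti_ms, tr_ms = tr_ms, noise_sd = noise_sd,
                 drift_slope = drift_slope, cest_b1_ut = cest_b1_ut,
                 rician = rician), class = "st_protocol")
}

#' Default offset grids per B1 level
#' @param b1_levels saturation amplitudes, µT
#' @return named list of offset vectors (ppm)
#' @export
default_offsets <- function(b1_levels) {
  hi <- exp(seq(log(3), log(300), length.out = 15))
  out <- lapply(b1_levels, function(b1) {
    if (b1 <= 0.3) seq(-1, 1, by = 0.1)
    else if (b1 <= 2.5) round(seq(-6, 6, by = 0.1), 10)
    else sort(c(-hi, hi))
  })
  stats::setNames(out, as.character(b1_levels))
}

#' Acquisition-order frame table for one Z-spectrum stack
#'
#' References are acquired before and after the measurement series and
#' interleaved after every \code{every} measurements.
#'
#' @param offsets measurement offsets, ppm
#' @param reference_offset_ppm reference offset, ppm
#' @param every interleave period
#' @return data.frame with \code{acq_index} (0-based), \code{offset_ppm},
#'   \code{is_reference}
#' @export
acquisition_table <- function(offsets, reference_offset_ppm = 667,
                              every = 5) {
  off <- numeric(0); is_ref <- logical(0)
  n <- length(offsets); i <- 0
  while (i < n) {
    off <- c(off, reference_offset_ppm); is_ref <- c(is_ref, TRUE)
    blk <- offsets[(i + 1):min(i + every, n)]
    off <- c(off, blk); is_ref <- c(is_ref, rep(FALSE, length(blk)))
    i <- i + every
  }
  off <- c(off, reference_offset_ppm); is_ref <- c(is_ref, TRUE)
  data.frame(acq_index = seq_along(off) - 1L, offset_ppm = off,
             is_reference = is_ref)
}

# noiseless Z-spectrum of one voxel at one B1 level, including B0 shift
# and (for the CEST levels) inverse-additive pool injection.  The WASSR
# level (wassr = TRUE) follows the direct-saturation model with the
# voxel's observed T1/T2 — T2,obs is by definition the apparent T2 that
# the WASSR fit recovers; MT-weighted levels follow the two-pool model.
voxel_zspec <- function(truth_row, b1, offsets, f0_mhz, with_pools,
                        pool_offsets, pool_width, wassr = FALSE) {
  eff <- offsets - truth_row[["b0_ppm"]]
  if (wassr) {
    return(eq1_signal(eff, b1, truth_row[["t1_obs_ms"]],
                      truth_row[["t2_obs_ms"]], f0_mhz))
  }
  pars <- mt_params(truth_row[["t2_f_ms"]], truth_row[["r_mt_hz"]],
                    truth_row[["m0_mt"]], truth_row[["t2_mt_us"]])
  g <- superlorentzian_fast(eff, truth_row[["t2_mt_us"]], f0_mhz)
  z <- two_pool_z(pars, truth_row[["t1_obs_ms"]], b1, eff, f0_mhz,
                  lineshape = g)
  if (with_pools && length(pool_offsets)) {
    rex <- numeric(length(eff))
    for (po in pool_offsets) {
      a <- truth_row[[paste0("pool_", po)]]
      w <- pool_width[[paste0("pool_", po)]]
      if (a > 0) rex <- rex + a * w^2 / (w^2 + 4 * (eff - po)^2)
    }
    z <- 1 / (1 / z + truth_row[["t1_obs_ms"]] / 1000 * rex)
  }
  z
}

#' Forward-simulate a complete saturation-transfer acquisition
#'
#' For every non-background voxel and B1 level the Z-spectrum is generated
#' from the two-pool MT steady state with the voxel's ground-truth
#' parameters; CEST/rNOE pools are injected inverse-additively,
#' 1/Z_lab = 1/Z_2pool + T1,obs * sum R_ex(offset), into the levels listed
#' in \code{protocol$cest_b1_ut} — this construction makes ground-truth
#' AREX equal the summed pool R_ex exactly.  The WASSR stack is the lowest
#' B1 level; the inversion-recovery series uses the magnitude IR model.
#' Multiplicative linear drift over acquisition order and additive
#' Gaussian noise are then applied, reference frames included.
#'
#' @param geometry \code{\link{make_phantom}} output
#' @param protocol \code{\link{protocol}}
#' @param seed seed for noise generation
#' @return object of class \code{synthetic_study}: \code{label},
#'   \code{truth}, \code{stacks} (per B1: \code{frames} array rows x cols
#'   x nframes in acquisition order, \code{table}, \code{b1_ut}),
#'   \code{ir} (frames + ti_ms), \code{protocol}
#' @export
simulate_study <- function(geometry, protocol = qmtcest::protocol(),
                           seed = 1) {
  stopifnot(inherits(geometry, "phantom_geometry"),
            inherits(protocol, "st_protocol"))
  nr <- nrow(geometry$label); nc <- ncol(geometry$label)
  fg <- which(geometry$label != 1L)
  truth_mat <- do.call(cbind, lapply(geometry$truth, as.vector))
  set.seed(seed)
  stacks <- list()
  for (b1 in protocol$b1_levels) {
    offs <- protocol$offsets[[as.character(b1)]]
    tab <- acquisition_table(offs, protocol$reference_offset_ppm,
                             protocol$reference_every)
    frames <- array(0, c(nr, nc, nrow(tab)))
    meas_i <- which(!tab$is_reference)
    ref_i <- which(tab$is_reference)
    with_pools <- b1 %in% protocol$cest_b1_ut
    is_wassr <- b1 == min(protocol$b1_levels) && b1 <= 0.3
    for (v in fg) {
      tr <- truth_mat[v, ]
      z <- voxel_zspec(tr, b1, offs, protocol$f0_mhz, with_pools,
                       geometry$pool_offsets, geometry$pool_width,
                       wassr = is_wassr)
      zref <- voxel_zspec(tr, b1, protocol$reference_offset_ppm,
                          protocol$f0_mhz, FALSE, NULL, NULL,
                          wassr = is_wassr)
      row <- (v - 1) %% nr + 1; col <- (v - 1) %/% nr + 1
      frames[row, col, meas_i] <- z
      frames[row, col, ref_i] <- zref
    }
    drift <- 1 + protocol$drift_slope * tab$acq_index
    frames <- sweep(frames, 3, drift, `*`)
    if (protocol$noise_sd > 0) {
      if (protocol$rician) {
        frames <- sqrt((frames + stats::rnorm(length(frames), 0,
                                              protocol$noise_sd))^2 +
                       stats::rnorm(length(frames), 0, protocol$noise_sd)^2)
      } else {
        frames <- frames + stats::rnorm(length(frames), 0, protocol$noise_sd)
      }
    }
    stacks[[as.character(b1)]] <- list(b1_ut = b1, frames = frames,
                                       table = tab)
  }
  ir <- array(0, c(nr, nc, length(protocol$ti_ms)))
  for (v in fg) {
    row <- (v - 1) %% nr + 1; col <- (v - 1) %/% nr + 1
    ir[row, col, ] <- ir_signal(protocol$ti_ms,
                                truth_mat[v, "t1_obs_ms"], 1,
                                protocol$tr_ms)
  }
  if (protocol$noise_sd > 0)
    ir <- ir + stats::rnorm(length(ir), 0, protocol$noise_sd)
  structure(list(label = geometry$label, truth = geometry$truth,
                 pool_offsets = geometry$pool_offsets,
                 pool_width = geometry$pool_width,
                 stacks = stacks, ir = list(frames = ir,
                                            ti_ms = protocol$ti_ms),
                 protocol = protocol, seed = seed),
            class = "synthetic_study")
}
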