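#' Simulate the MT-fitting spectra for one parameter set
#'
#' Forward-simulates noiseless Z-spectra at the MT-informative protocol
#' (0.1 µT over ±1 ppm and 3/6 µT over 30 log-spaced points ±(3–300) ppm)
#' from the two-pool model — the standard input for parameter-recovery
#' benchmarks of \code{\link{fit_two_pool}}.
#'
#' @param params \code{\link{mt_params}}
#' @param t1_obs_ms observed T1, ms
#' @param f0_mhz proton frequency, MHz
#' @return list of spectra as consumed by \code{\link{fit_two_pool}}
#' @export
simulate_mt_spectra <- function(params, t1_obs_ms,
                                f0_mhz = DEFAULT_F0_MHZ) {
  hi <- exp(seq(log(3), log(300), length.out = 15))
  lg <- sort(c(-hi, hi))
  de <- seq(-1, 1, by = 0.1)
  lapply(list(c(0.1), c(3), c(6)), function(b1) {
    off <- if (b1 < 0.3) de else lg
    list(b1_ut = b1, offset_ppm = off,
         z = two_pool_z(params, t1_obs_ms, b1, off, f0_mhz))
  })
}

#' Two-pool recovery benchmark at a published region parameter set
#'
#' Simulates noiseless spectra at the group-mean parameters of one
#' (tumour type, region) cell of \code{\link{region_parameter_table}} and
#' refits them, returning generating and recovered values.
#'
#' @param tumour_type "22Rv1" or "DU145"
#' @param region "tumour" or "necrosis"
#' @param r_mt_hz exchange rate used to split the generating MT-effect
#'   product
#' @return list with \code{truth} (named generating values), \code{fit}
#'   (the \code{\link{fit_two_pool}} result)
#' @export
mt_recovery_benchmark <- function(tumour_type, region, r_mt_hz = 20) {
  tab <- region_parameter_table()
  get <- function(metric)
    tab$mean[tab$tumour_type == tumour_type & tab$region == region &
               tab$metric == metric]
  truth <- c(t1_obs_ms = get("t1_obs_ms"), t2_f_ms = get("t2_f_ms"),
             mt_effect_hz = get("mt_effect_hz"), t2_mt_us = get("t2_mt_us"))
  pars <- mt_params(truth[["t2_f_ms"]], r_mt_hz,
                    truth[["mt_effect_hz"]] / r_mt_hz, truth[["t2_mt_us"]])
  spectra <- simulate_mt_spectra(pars, truth[["t1_obs_ms"]])
  fit <- fit_two_pool(spectra, truth[["t1_obs_ms"]])
  list(truth = truth, fit = fit)
}

#' Phantom relaxometry + segmentation pipeline run
#'
#' Simulates one phantom study at the given seed (WASSR + high-B1
#' protocol), preprocesses it, fits the T1/T2 maps, segments, and scores
#' per-class Dice overlap against the ground-truth labels restricted to
#' the validity mask.
#'
#' @param seed phantom and noise seed
#' @param noise_sd acquisition noise SD
#' @param tumour_type region parameter set for the phantom
#' @param rule label-assignment branch passed to
#'   \code{\link{assign_labels}}; the phantom's reflected IC2 ordering
#'   follows the brightness ordering of the classes, which corresponds
#'   to the DU145 sequence
#' @param grid_shape phantom size
#' @return list with \code{dice} (named: active_tumour,
#'   necrosis_apoptosis, muscle), the \code{segmentation_result}, the
#'   validity mask and the truth labels
#' @export
phantom_segmentation_run <- function(seed, noise_sd = 0.01,
                                     tumour_type = "22Rv1",
                                     rule = "DU145",
                                     grid_shape = c(64, 64)) {
  g <- make_phantom(phantom_spec(grid_shape = grid_shape,
                                 regions = default_regions(tumour_type),
                                 seed = seed))
  pr <- protocol(b1_levels = c(0.1, 3, 6),
                 offsets = default_offsets(c(0.1, 3, 6)),
                 noise_sd = noise_sd)
  st <- simulate_study(g, pr, seed = seed + 100)
  pp <- preprocess_study(st)
  t1m <- fit_t1_map(st)
  t2m <- fit_t2_map(pp, t1m$t1_ms)
  seg <- segment_study(t1m$t1_ms, t2m$t2_ms, pp, tumour_type = rule,
                       seed = 0)
  truth_of <- c(active_tumour = "tumour", necrosis_apoptosis = "necrosis",
                muscle = "muscle")
  dice <- vapply(names(truth_of), function(cl) {
    pred <- !is.na(seg$label_map) &
      seg$label_map == match(cl, SEGMENT_CLASSES)
    truth <- (g$label == match(truth_of[[cl]], REGION_LABELS)) & pp$valid
    dice_coefficient(pred, truth)
  }, numeric(1))
  list(dice = dice, segmentation = seg, valid = pp$valid,
       label = g$label, preproc = pp, t1_map = t1m$t1_ms,
       t2_map = t2m$t2_ms)
}
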