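#' CEST/rNOE pool description
#'
#' A solute pool contributing an exchange-mediated relaxation term to the
#' Z-spectrum, modelled as a Lorentzian in offset:
#' R_ex(offset) = amplitude * w^2 / (w^2 + 4 (offset - centre)^2),
#' with w the full width at half maximum.
#'
#' @param offset_ppm resonance offset from water, ppm (amide 3.5,
#'   guanidinium 2.0, aliphatic rNOE -3.3)
#' @param amplitude_hz peak exchange-mediated relaxation rate R_ex,max, Hz
#' @param width_ppm Lorentzian FWHM, ppm
#' @return object of class \code{cest_pool}
#' @export
cest_pool <- function(offset_ppm, amplitude_hz, width_ppm = 1) {
  stopifnot(amplitude_hz >= 0, width_ppm > 0, is.finite(offset_ppm))
  structure(list(offset_ppm = offset_ppm, amplitude_hz = amplitude_hz,
                 width_ppm = width_ppm), class = "cest_pool")
}

#' Exchange-mediated relaxation rate of a set of pools
#'
#' @param pools list of \code{\link{cest_pool}}
#' @param offset_ppm offsets, ppm
#' @return summed R_ex at each offset, Hz
#' @export
pools_rex <- function(pools, offset_ppm) {
  out <- numeric(length(offset_ppm))
  for (p in pools) {
    out <- out + p$amplitude_hz * p$width_ppm^2 /
      (p$width_ppm^2 + 4 * (offset_ppm - p$offset_ppm)^2)
  }
  out
}

#' Phantom region labels, in label-image integer order
#' @export
REGION_LABELS <- c("background", "muscle", "muscle_connective", "tumour",
                   "necrosis", "blood_edema")

#' Generative parameters for one phantom tissue region
#'
#' Each scalar parameter is given as c(mean, sd); per-voxel values are drawn
#' from the corresponding Gaussian truncated at zero.  The MT effect is
#' parameterized directly as the product R_MT * M0,MT (the two factors are
#' coupled in the fit); forward simulation uses a fixed reference exchange
#' rate \code{r_mt_ref_hz} and sets M0,MT = mt_effect / R_MT.
#'
#' @param label one of background, muscle, muscle_connective, tumour,
#'   necrosis, blood_edema
#' @param t1_obs_ms,t2_obs_ms observed relaxation times, c(mean, sd), ms
#' @param t2_f_ms free-pool T2, c(mean, sd), ms
#' @param mt_effect_hz R_MT * M0,MT, c(mean, sd), Hz
#' @param t2_mt_us semisolid T2, c(mean, sd), µs
#' @param cest_pools list of \code{\link{cest_pool}}
#' @param r_mt_ref_hz exchange rate used to split the MT-effect product
#' @return object of class \code{region_spec}
#' @export
region_spec <- function(label, t1_obs_ms, t2_obs_ms, t2_f_ms, mt_effect_hz,
                        t2_mt_us, cest_pools = list(), r_mt_ref_hz = 20) {
  label <- match.arg(label, REGION_LABELS)
  chk <- function(x, nm) {
    if (length(x) == 1) x <- c(x, 0)
    if (x[1] <= 0 || x[2] < 0) stop("invalid mean/sd for ", nm)
    x
  }
  t1_obs_ms <- chk(t1_obs_ms, "t1_obs"); t2_obs_ms <- chk(t2_obs_ms, "t2_obs")
  t2_f_ms <- chk(t2_f_ms, "t2_f"); mt_effect_hz <- chk(mt_effect_hz, "mt_effect")
  t2_mt_us <- chk(t2_mt_us, "t2_mt")
  if (t2_obs_ms[1] >= t1_obs_ms[1]) stop("t2_obs mean must be below t1_obs mean")
  structure(list(label = label, t1_obs_ms = t1_obs_ms, t2_obs_ms = t2_obs_ms,
                 t2_f_ms = t2_f_ms, mt_effect_hz = mt_effect_hz,
                 t2_mt_us = t2_mt_us, cest_pools = cest_pools,
                 r_mt_ref_hz = r_mt_ref_hz), class = "region_spec")
}

#' Group-mean saturation-transfer parameters of the xenograft study
#'
#' Mean and SD of observed T1/T2 and two-pool MT parameters for the tumour
#' and necrotic regions of 22Rv1 and DU145 prostate-cancer xenografts, as
#' used for default phantom generation and recovery benchmarks.  Values for
#' tumour-region T1,obs/T2,obs and for the DU145 tumour T2,F are plausible
#' synthetic defaults (marked \code{synthetic = TRUE}); the remainder are
#' the published group means.
#'
#' @return data.frame with one row per (tumour_type, region, metric)
#' @export
region_parameter_table <- function() {
  rbind(
    data.frame(tumour_type = "22Rv1", region = "tumour",
               metric = c("t1_obs_ms", "t2_obs_ms", "t2_f_ms",
                          "mt_effect_hz", "t2_mt_us"),
               mean = c(2200, 50, 47, 1.8, 7.8),
               sd = c(100, 5, 6, 0.2, 0.1),
               synthetic = c(TRUE, TRUE, FALSE, FALSE, FALSE)),
    data.frame(tumour_type = "22Rv1", region = "necrosis",
               metric = c("t1_obs_ms", "t2_obs_ms", "t2_f_ms",
                          "mt_effect_hz", "t2_mt_us"),
               mean = c(2000, 44, 39, 2.3, 7.4),
               sd = c(50, 4, 5, 0.6, 0.1),
               synthetic = FALSE),
    data.frame(tumour_type = "DU145", region = "tumour",
               metric = c("t1_obs_ms", "t2_obs_ms", "t2_f_ms",
                          "mt_effect_hz", "t2_mt_us"),
               mean = c(2400, 60, 60, 1.2, 8.2),
               sd = c(150, 8, 8, 0.1, 0.2),
               synthetic = c(TRUE, TRUE, TRUE, FALSE, FALSE)),
    data.frame(tumour_type = "DU145", region = "necrosis",
               metric = c("t1_obs_ms", "t2_obs_ms", "t2_f_ms",
                          "mt_effect_hz", "t2_mt_us"),
               mean = c(2500, 70, 69, 1.1, 7.9),
               sd = c(200, 20, 15, 0.4, 0.4),
               synthetic = FALSE))
}

#' Default region set for a phantom of a given tumour type
#'
#' Tumour and necrosis use the group-mean parameters of
#' \code{\link{region_parameter_table}}; muscle, muscle/connective tissue
#' and blood/edema parameters are synthetic choices (high MT effect in
#' muscle, long relaxation times and negligible MT in blood/edema).
#' Tumour regions carry amide (3.5 ppm), guanidinium (2.0 ppm) and
#' aliphatic rNOE (-3.3 ppm) pools; necrosis the same pools at lower
#' amplitude; muscle a negligible CEST effect.
#'
#' @param tumour_type "22Rv1" or "DU145"
#' @return named list of \code{\link{region_spec}}
#' @export
default_regions <- function(tumour_type = c("22Rv1", "DU145")) {
  tumour_type <- match.arg(tumour_type)
  tab <- region_parameter_table()
  get <- function(region, metric) {
    r <- tab[tab$tumour_type == tumour_type & tab$region == region &
               tab$metric == metric, ]
    c(r$mean, r$sd)
  }
  tum_pools <- list(cest_pool(3.5, 0.20, 1.2), cest_pool(2.0, 0.30, 1.0),
                    cest_pool(-3.3, 0.25, 1.5))
  nec_pools <- list(cest_pool(3.5, 0.08, 1.2), cest_pool(2.0, 0.10, 1.0),
                    cest_pool(-3.3, 0.12, 1.5))
  if (tumour_type == "DU145") {
    tum_pools <- list(cest_pool(3.5, 0.14, 1.2), cest_pool(2.0, 0.18, 1.0),
                      cest_pool(-3.3, 0.17, 1.5))
    nec_pools <- list(cest_pool(3.5, 0.05, 1.2), cest_pool(2.0, 0.06, 1.0),
                      cest_pool(-3.3, 0.08, 1.5))
  }
  list(
    tumour = region_spec("tumour", get("tumour", "t1_obs_ms"),
                         get("tumour", "t2_obs_ms"), get("tumour", "t2_f_ms"),
                         get("tumour", "mt_effect_hz"),
                         get("tumour", "t2_mt_us"), tum_pools),
    necrosis = region_spec("necrosis", get("necrosis", "t1_obs_ms"),
                           get("necrosis", "t2_obs_ms"),
                           get("necrosis", "t2_f_ms"),
                           get("necrosis", "mt_effect_hz"),
                           get("necrosis", "t2_mt_us"), nec_pools),
    muscle = region_spec("muscle", c(1800, 50), c(35, 3), c(35, 4),
                         c(3.5, 0.3), c(8.5, 0.2),
                         list(cest_pool(2.0, 0.02, 1.0))),
    muscle_connective = region_spec("muscle_connective", c(1900, 60),
                                    c(38, 4), c(37, 4), c(2.9, 0.3),
                                    c(7.9, 0.3),
                                    list(cest_pool(2.0, 0.04, 1.0))),
    blood_edema = region_spec("blood_edema", c(2800, 100), c(150, 15),
                              c(150, 15), c(0.4, 0.1), c(8.0, 0.5),
                              list())
  )
}
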