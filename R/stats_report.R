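#' ROI-averaged Z-spectrum
#'
#' Per-offset mean and standard deviation of the preprocessed Z values
#' over the mask voxels.
#'
#' @param z array (rows x cols x frames) of Z values
#' @param offset_ppm offsets, one per frame
#' @param mask logical ROI matrix (non-empty)
#' @return data.frame with \code{offset_ppm}, \code{mean}, \code{sd},
#'   \code{n}
#' @export
roi_zspectrum <- function(z, offset_ppm, mask) {
  if (!any(mask)) stop("empty mask")
  stopifnot(dim(z)[3] == length(offset_ppm))
  idx <- which(mask)
  stats_k <- vapply(seq_along(offset_ppm), function(k) {
    v <- z[, , k][idx]
    v <- v[is.finite(v)]
    c(mean(v), if (length(v) > 1) stats::sd(v) else 0, length(v))
  }, numeric(3))
  data.frame(offset_ppm = offset_ppm, mean = stats_k[1, ],
             sd = stats_k[2, ], n = stats_k[3, ])
}

#' Significance star code used in the group comparisons
#'
#' @param p p value
#' @return "***" if p < 0.001, "**" if p < 0.01, otherwise "ns"
#' @export
star_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", "ns"))
}

#' Unpaired Student's t-test
#'
#' Classical two-sided pooled-variance t-test (Welch's correction behind a
#' flag), with the star coding of the group-comparison figures.
#'
#' @param a,b numeric samples (n >= 2 each)
#' @param welch if TRUE use the Welch (unequal-variance) test
#' @return list with \code{t}, \code{df}, \code{p}, \code{stars},
#'   \code{mean_a}, \code{mean_b}
#' @export
ttest_unpaired <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (!welch && stats::var(a) + stats::var(b) == 0)
    stop("zero pooled variance")
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, stars = star_code(ht$p.value),
       mean_a = mean(a), mean_b = mean(b))
}

#' Calliper tumour volume
#'
#' volume = length x width^2 / 2, the standard ellipsoid approximation for
#' subcutaneous xenografts.
#'
#' @param length_mm longest diameter, mm
#' @param width_mm perpendicular width, mm (must satisfy
#'   0 < width <= length)
#' @return volume in mm^3
#' @export
tumour_volume <- function(length_mm, width_mm) {
  if (any(width_mm <= 0) || any(length_mm < width_mm))
    stop("require length >= width > 0")
  length_mm * width_mm^2 / 2
}

#' Group summary and comparison report
#'
#' Aggregates per-animal ROI means into group summaries (mean, SD, n per
#' tumour type x region x metric) and runs the four standard pairwise
#' comparisons per metric: tumour vs necrosis within each type and each
#' region across types.
#'
#' @param values long data.frame with columns \code{animal},
#'   \code{tumour_type}, \code{region}, \code{metric}, \code{value}; one
#'   row per animal x region x metric
#' @param welch use Welch's test instead of pooled variance
#' @return list of class \code{st_report} with \code{summary} and
#'   \code{tests} data.frames
#' @export
build_report <- function(values, welch = FALSE) {
  need <- c("animal", "tumour_type", "region", "metric", "value")
  stopifnot(all(need %in% names(values)))
  agg <- stats::aggregate(value ~ tumour_type + region + metric, values,
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        n = length(v)))
  summary <- data.frame(agg[, 1:3], mean = agg$value[, "mean"],
                        sd = agg$value[, "sd"], n = agg$value[, "n"])
  pull <- function(type, region, metric)
    values$value[values$tumour_type == type & values$region == region &
                   values$metric == metric]
  tests <- NULL
  for (m in unique(values$metric)) {
    cmp <- list(
      c("22Rv1 tumour", "22Rv1 necrosis"), c("DU145 tumour", "DU145 necrosis"),
      c("22Rv1 tumour", "DU145 tumour"), c("22Rv1 necrosis", "DU145 necrosis"))
    for (cc in cmp) {
      g <- lapply(cc, function(s) {
        parts <- strsplit(s, " ")[[1]]
        pull(parts[1], parts[2], m)
      })
      if (length(g[[1]]) < 2 || length(g[[2]]) < 2) next
      tt <- tryCatch(ttest_unpaired(g[[1]], g[[2]], welch),
                     error = function(e) NULL)
      if (is.null(tt)) next
      tests <- rbind(tests, data.frame(
        metric = m, group_a = cc[1], group_b = cc[2], t = tt$t, df = tt$df,
        p = tt$p, stars = tt$stars, mean_a = tt$mean_a, mean_b = tt$mean_b))
    }
  }
  structure(list(summary = summary, tests = tests), class = "st_report")
}

#' Write a report bundle to disk
#'
#' Emits the group summary and test tables as CSV (fixed 6-significant-
#' digit formatting, so identical inputs give byte-identical files) and a
#' run-parameter JSON.
#'
#' @param report \code{\link{build_report}} output
#' @param dir output directory (created if needed)
#' @param run_params named list stored as JSON alongside the tables
#' @return invisibly, the paths written
#' @export
write_report <- function(report, dir, run_params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, 6))
    df
  }
  paths <- c(summary = file.path(dir, "region_summary.csv"),
             tests = file.path(dir, "group_tests.csv"),
             params = file.path(dir, "run_params.json"))
  utils::write.csv(fmt(report$summary), paths["summary"], row.names = FALSE)
  if (!is.null(report$tests))
    utils::write.csv(fmt(report$tests), paths["tests"], row.names = FALSE)
  jsonlite::write_json(run_params, paths["params"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

#' Star-rate of a simulated two-group comparison
#'
#' Draws many replicate cohorts from two Gaussian group distributions and
#' reports how often the pooled t-test reaches each significance level —
#' a power (different means) or type-I-error (identical means) simulation.
#'
#' @param mean_a,sd_a,n_a first group's distribution and size
#' @param mean_b,sd_b,n_b second group's distribution and size
#' @param reps number of replicate cohorts
#' @param seed RNG seed
#' @return list with \code{frac_three_star} (p < 0.001),
#'   \code{frac_two_star} (p < 0.01) and the vector of p values
#' @export
comparison_star_rate <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                 reps = 100, seed = 1) {
  set.seed(seed)
  p <- vapply(seq_len(reps), function(i) {
    ttest_unpaired(stats::rnorm(n_a, mean_a, sd_a),
                   stats::rnorm(n_b, mean_b, sd_b))$p
  }, numeric(1))
  list(frac_three_star = mean(p < 0.001), frac_two_star = mean(p < 0.01),
       p = p)
}
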