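test_that("ROI Z-spectrum statistics reduce to per-offset moments", {
  z <- array(0, c(2, 2, 3))
  z[1, 1, ] <- c(0.4, 0.5, 0.6)
  z[2, 1, ] <- c(0.6, 0.7, 0.8)
  m1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  r1 <- roi_zspectrum(z, c(1, 2, 3), m1)
  expect_equal(r1$mean, c(0.4, 0.5, 0.6))
  expect_equal(r1$sd, c(0, 0, 0))
  m2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  r2 <- roi_zspectrum(z, c(1, 2, 3), m2)
  expect_equal(r2$mean[1], 0.5)
  expect_equal(r2$sd[1], sd(c(0.4, 0.6)))
  expect_equal(r2$sd[1], 0.1414, tolerance = 1e-3)
  expect_error(roi_zspectrum(z, c(1, 2, 3), m1 & FALSE), "empty")
})

test_that("ROI-mean spectra are close to the forward model at ROI-mean parameters", {
  cs <- clean_study()
  g <- cs$geom; pp <- cs$preproc
  tum <- region_mask(g, "tumour") & pp$valid
  zset <- pp$zs[["6"]]
  roi <- roi_zspectrum(zset$z, zset$offset_ppm, tum)
  pars <- mt_params(mean(g$truth$t2_f_ms[tum]),
                    mean(g$truth$r_mt_hz[tum]),
                    mean(g$truth$m0_mt[tum]),
                    mean(g$truth$t2_mt_us[tum]))
  model <- two_pool_z(pars, mean(g$truth$t1_obs_ms[tum]), 6,
                      zset$offset_ppm)
  expect_equal(roi$mean, model, tolerance = 0.02)
})

test_that("the unpaired pooled t-test matches the closed-form arithmetic", {
  a <- c(2.0, 2.1, 1.9); b <- c(2.5, 2.4, 2.6)
  tt <- ttest_unpaired(a, b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(tt$t, t_hand, tolerance = 1e-10)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  t0 <- ttest_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t0$t, 0)
  expect_equal(t0$p, 1)
  expect_equal(t0$stars, "ns")
  # clear separation
  expect_lt(ttest_unpaired(c(1, 2, 3), c(11, 12, 13))$p, 0.001)
  expect_error(ttest_unpaired(c(1, 1, 1), c(1, 1, 1)), "variance")
})

test_that("pooled-t p-values agree with a permutation oracle", {
  set.seed(9)
  a <- rnorm(8, 0.3); b <- rnorm(9, 0)
  t_obs <- abs(ttest_unpaired(a, b)$t)
  pool <- c(a, b)
  perm <- replicate(4000, {
    i <- sample(17, 8)
    abs(ttest_unpaired(pool[i], pool[-i])$t)
  })
  p_perm <- mean(perm >= t_obs - 1e-12)
  expect_lt(abs(p_perm - ttest_unpaired(a, b)$p), 0.05)
})

test_that("star codes follow the figure-legend thresholds", {
  expect_equal(star_code(c(0.5, 0.009, 0.0009)), c("ns", "**", "***"))
})

test_that("calliper volume uses length x width^2 / 2", {
  expect_equal(tumour_volume(10, 10), 500)
  expect_equal(tumour_volume(12, 8), 384)
  expect_error(tumour_volume(10, 0))
  expect_error(tumour_volume(5, 8))
})

test_that("the report aggregates per-animal ROI means and runs the four comparisons", {
  set.seed(2)
  vals <- expand.grid(animal = 1:6, tumour_type = c("22Rv1", "DU145"),
                      region = c("tumour", "necrosis"),
                      metric = "mt_effect_hz",
                      stringsAsFactors = FALSE)
  vals$value <- rnorm(nrow(vals), 1.5, 0.2)
  rep <- build_report(vals)
  expect_equal(nrow(rep$summary), 4)     # 2 types x 2 regions
  expect_equal(nrow(rep$tests), 4)       # the four standard comparisons
  expect_true(all(rep$summary$n == 6))
  # byte-identical output for identical input
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  write_report(rep, d1, run_params = list(seed = 1))
  write_report(rep, d2, run_params = list(seed = 1))
  expect_identical(readLines(file.path(d1, "region_summary.csv")),
                   readLines(file.path(d2, "region_summary.csv")))
})

test_that("identical-parameter cohorts rarely reach significance", {
  r <- comparison_star_rate(1.8, 0.2, 32, 1.8, 0.2, 34, reps = 200,
                            seed = 11)
  expect_lte(r$frac_two_star, 0.05)
})
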