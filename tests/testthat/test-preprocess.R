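test_that("drift line fit matches the closed-form least squares", {
  # references {1.00, 0.98, 0.96} at indices {0, 6, 12}: slope -1/300
  tab <- data.frame(acq_index = 0:12, offset_ppm = 10,
                    is_reference = FALSE)
  tab$is_reference[c(1, 7, 13)] <- TRUE
  tab$offset_ppm[tab$is_reference] <- 667
  frames <- rep(0.5, 13)
  frames[c(1, 7, 13)] <- c(1.00, 0.98, 0.96)
  dc <- drift_correct(frames, tab)
  expect_equal(as.numeric(dc$slope), -1 / 300, tolerance = 1e-12)
  expect_equal(as.numeric(dc$intercept), 1, tolerance = 1e-12)
})

test_that("drift correction inverts the generator's drift exactly", {
  off <- seq(-6, 6, 0.5)
  tab <- acquisition_table(off, 667, 5)
  z_true <- eq1_signal(off, 0.5, 2000, 44)
  frames <- numeric(nrow(tab))
  frames[!tab$is_reference] <- z_true
  frames[tab$is_reference] <- 1
  drifted <- frames * (1 + 3e-4 * tab$acq_index)
  dc <- drift_correct(drifted, tab)
  expect_equal(as.numeric(dc$z), z_true, tolerance = 1e-10)
  # constant references: output equals input / S_ref
  dc0 <- drift_correct(frames * 2, tab)
  expect_equal(as.numeric(dc0$z), z_true, tolerance = 1e-12)
  expect_error(drift_correct(frames[1:3],
                             data.frame(acq_index = 0:2, offset_ppm = 1,
                                        is_reference = c(TRUE, FALSE, FALSE))),
               "reference")
})

test_that("WASSR B0 fitting finds the dip centre", {
  off <- seq(-1, 1, 0.1)
  f0 <- fit_b0_wassr(eq1_signal(off, 0.1, 2000, 44), off)
  expect_equal(f0$shift_ppm, 0, tolerance = 1e-6)
  f1 <- fit_b0_wassr(eq1_signal(off - 0.12, 0.1, 2000, 44), off)
  expect_equal(f1$shift_ppm, 0.12, tolerance = 5e-3)
})

test_that("WASSR B0 fitting is unbiased under noise (Monte Carlo)", {
  off <- seq(-1, 1, 0.1)
  z0 <- eq1_signal(off - 0.1, 0.1, 2000, 44)
  set.seed(7)
  shifts <- replicate(200, fit_b0_wassr(z0 + rnorm(21, 0, 0.01),
                                        off)$shift_ppm)
  shifts <- shifts[is.finite(shifts)]
  se <- sd(shifts) / sqrt(length(shifts))
  expect_lt(abs(mean(shifts) - 0.1), 2 * se + 1e-3)
})

test_that("two-Lorentzian B0 fitting recovers the shift of a low-B1 spectrum", {
  off <- round(seq(-6, 6, 0.1), 10)
  p <- mt_params(47, 20, 0.09, 7.8)
  mk <- function(shift) {
    z <- two_pool_z(p, 2200, 2, off - shift)
    rex <- pools_rex(list(cest_pool(3.5, 0.2, 1.2), cest_pool(2, 0.3, 1),
                          cest_pool(-3.3, 0.25, 1.5)), off - shift)
    1 / (1 / z + 2.2 * rex)
  }
  expect_lt(abs(fit_b0_lowb1(mk(0), off)$shift_ppm), 5e-3)
  expect_lt(abs(fit_b0_lowb1(mk(0.12), off)$shift_ppm - 0.12), 5e-3)
})

test_that("re-centring interpolates correctly", {
  off <- seq(-3, 3, 0.5)
  z <- sin(off) + 2
  expect_equal(recenter(z, off, 0), z)
  # exact one-grid-step shift: interior points slide by one sample
  r <- recenter(z, off, 0.5)
  expect_equal(r[1:(length(z) - 1)], z[2:length(z)])
  expect_true(is.na(r[length(z)]))
  # piecewise-linear spectrum, half-step shift: midpoint averages
  zl <- abs(off)
  rh <- recenter(zl, off, 0.25)
  inner <- 2:(length(off) - 1)
  expect_equal(rh[inner], (abs(off + 0.5) / 2 + abs(off) / 2)[inner],
               tolerance = 1e-12)
})

test_that("recentring a B0-shifted low-B1 spectrum reproduces the unshifted one", {
  off <- round(seq(-6, 6, 0.1), 10)
  p <- mt_params(47, 20, 0.09, 7.8)
  z0 <- two_pool_z(p, 2200, 2, off)
  zs <- two_pool_z(p, 2200, 2, off - 0.12)
  f <- fit_b0_lowb1(zs, off)
  # assessed outside the steep direct-saturation flank, where linear
  # interpolation of the broad spectrum is accurate
  zr <- recenter(zs, off, f$shift_ppm)
  interior <- abs(off) <= 5 & abs(off) >= 1 & is.finite(zr)
  expect_lt(max(abs(zr[interior] / z0[interior] - 1)), 0.005)
})

test_that("erosion implements the full 8-neighbour structuring element", {
  m <- matrix(FALSE, 7, 7); m[3:5, 3:5] <- TRUE
  e <- erode_mask(m)
  expect_equal(sum(e), 1)
  expect_true(e[4, 4])
  big <- matrix(FALSE, 10, 12); big[2:9, 2:11] <- TRUE
  expect_equal(erode_mask(big), erode_oracle(big))
  set.seed(1)
  for (i in 1:5) {
    r <- matrix(runif(16 * 16) > 0.4, 16, 16)
    expect_equal(erode_mask(r), erode_oracle(r))
  }
})

test_that("erosion matches the oracle on every 3x3 configuration", {
  for (code in 0:511) {
    m <- matrix(FALSE, 5, 5)
    m[2:4, 2:4] <- matrix(bitwAnd(bitwShiftR(code, 0:8), 1L) == 1L, 3, 3)
    expect_identical(erode_mask(m), erode_oracle(m))
  }
})

test_that("B0 outlier exclusion uses a strict threshold", {
  m <- matrix(c(0.2, 0.6, -0.7, 0.4), 2, 2)
  expect_identical(as.vector(exclude_b0_outliers(m)),
                   c(TRUE, FALSE, FALSE, TRUE))
  expect_true(all(exclude_b0_outliers(matrix(0, 3, 3))))
  # exactly 0.5 ppm is retained ("greater than" is strict)
  expect_true(exclude_b0_outliers(matrix(0.5, 1, 1))[1, 1])
  expect_false(exclude_b0_outliers(matrix(NA_real_, 1, 1))[1, 1])
})

test_that("map normalization divides by 4000 and 300 ms without clipping", {
  n <- normalize_maps(matrix(c(2000, 0, 4400), 1), matrix(c(300, 150, 330), 1))
  expect_equal(as.vector(n$t1), c(0.5, 0, 1.1))
  expect_equal(as.vector(n$t2), c(1, 0.5, 1.1))
})
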