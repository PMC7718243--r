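test_that("zero-variance regions give constant truth maps and seeds reproduce", {
  regs <- default_regions("22Rv1")
  regs$tumour$t1_obs_ms[2] <- 0
  regs$tumour$mt_effect_hz[2] <- 0
  g1 <- make_phantom(phantom_spec(seed = 5, regions = regs))
  tum <- region_mask(g1, "tumour")
  expect_equal(unique(g1$truth$t1_obs_ms[tum]), regs$tumour$t1_obs_ms[1])
  expect_equal(unique(g1$truth$mt_effect_hz[tum]),
               regs$tumour$mt_effect_hz[1])
  g2 <- make_phantom(phantom_spec(seed = 5, regions = regs))
  expect_identical(g1$truth, g2$truth)
  g3 <- make_phantom(phantom_spec(seed = 6, regions = regs))
  expect_false(identical(g1$truth$t2_obs_ms, g3$truth$t2_obs_ms))
})

test_that("the rasterized necrotic core matches the analytic ellipse area", {
  spec <- phantom_spec(seed = 1)
  g <- make_phantom(spec)
  e <- spec$geometry$necrosis
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  # independent brute-force rasterization over pixel centres
  count <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (((i - 0.5 - e[1] * nr) / (e[3] * nr))^2 +
        ((j - 0.5 - e[2] * nc) / (e[4] * nc))^2 <= 1) count <- count + 1
  }
  n_core <- sum(region_mask(g, "necrosis"))
  expect_equal(n_core, count)
  # and the count sits within one boundary ring of the analytic area
  area <- pi * e[3] * nr * e[4] * nc
  perim <- pi * (3 * (e[3] * nr + e[4] * nc) -
                 sqrt((3 * e[3] * nr + e[4] * nc) *
                      (e[3] * nr + 3 * e[4] * nc)))
  expect_lt(abs(n_core - area), perim)
})

test_that("non-nested region geometry is rejected", {
  expect_error(phantom_spec(geometry = list(
    muscle = c(0.5, 0.5, 0.44, 0.42),
    muscle_connective = c(0.5, 0.5, 0.34, 0.32),
    tumour = c(0.5, 0.5, 0.30, 0.28),
    necrosis = c(0.5, 0.5, 0.32, 0.30),   # larger than the tumour
    n_specks = 5, speck_radius = 0.025)), "overlapping")
  expect_error(phantom_spec(grid_shape = c(8, 8)))
})

test_that("every voxel carries exactly one label and truth only on foreground", {
  g <- make_phantom(phantom_spec(seed = 2))
  expect_true(all(g$label %in% seq_along(REGION_LABELS)))
  fg <- g$label != 1L
  expect_true(all(is.finite(g$truth$t1_obs_ms[fg])))
  expect_true(all(is.na(g$truth$t1_obs_ms[!fg])))
  expect_true(all(g$truth$t2_obs_ms[fg] < g$truth$t1_obs_ms[fg]))
})

test_that("with no MT pool and matched T2 the low-B1 spectrum reduces to direct saturation", {
  regs <- list(tumour = region_spec("tumour", c(2000, 0), c(47, 0),
                                    c(47, 0), c(1e-6, 0), c(7.8, 0),
                                    list()))
  geo <- list(muscle = c(0.5, 0.5, 0.44, 0.42),
              muscle_connective = c(0.5, 0.5, 0.34, 0.32),
              tumour = c(0.5, 0.5, 0.30, 0.28),
              necrosis = c(0.5, 0.5, 0.11, 0.10),
              n_specks = 0, speck_radius = 0.03)
  g <- make_phantom(phantom_spec(c(24, 24), regions = regs,
                                 geometry = geo,
                                 b0 = list(amplitude_ppm = 0),
                                 seed = 1))
  pr <- protocol(b1_levels = c(0.1, 0.5),
                 offsets = default_offsets(c(0.1, 0.5)),
                 noise_sd = 0, drift_slope = 0, cest_b1_ut = numeric(0))
  st <- simulate_study(g, pr, seed = 1)
  v <- which(region_mask(g, "tumour"))[1]
  row <- (v - 1) %% 24 + 1; col <- (v - 1) %/% 24 + 1
  tab <- st$stacks[["0.5"]]$table
  z <- st$stacks[["0.5"]]$frames[row, col, !tab$is_reference]
  expect_equal(z, eq1_signal(tab$offset_ppm[!tab$is_reference], 0.5,
                             2000, 47), tolerance = 1e-5)
})

test_that("acquisition ordering interleaves references every five measurements", {
  tab <- acquisition_table(1:12, 667, 5)
  expect_true(tab$is_reference[1])
  expect_true(tab$is_reference[nrow(tab)])
  expect_equal(sum(tab$is_reference), 4)   # before, 2 interleaves, after
  expect_equal(tab$offset_ppm[!tab$is_reference], 1:12)
  expect_equal(tab$acq_index, seq_len(nrow(tab)) - 1L)
})

test_that("reference-frame noise matches the configured level", {
  g <- make_phantom(phantom_spec(seed = 4))
  pr <- protocol(b1_levels = 6, offsets = default_offsets(6),
                 noise_sd = 0.01, drift_slope = 0)
  st <- simulate_study(g, pr, seed = 9)
  fg <- which(g$label != 1L)
  refs <- st$stacks[["6"]]$table$is_reference
  vals <- apply(st$stacks[["6"]]$frames[, , refs], 3, `[`, fg)
  resid <- sweep(vals, 1, rowMeans(vals))
  expect_equal(sd(resid), 0.01, tolerance = 0.05)
})

test_that("adding CEST pools never increases the simulated signal", {
  regs <- default_regions("22Rv1")
  regs_nopool <- lapply(regs, function(r) { r$cest_pools <- list(); r })
  pr <- protocol(b1_levels = c(0.1, 2), offsets = default_offsets(c(0.1, 2)),
                 noise_sd = 0, drift_slope = 0)
  s1 <- simulate_study(make_phantom(phantom_spec(seed = 3, regions = regs)),
                       pr, seed = 3)
  s0 <- simulate_study(make_phantom(phantom_spec(seed = 3,
                                                 regions = regs_nopool)),
                       pr, seed = 3)
  expect_true(all(s1$stacks[["2"]]$frames <= s0$stacks[["2"]]$frames + 1e-12))
  # and noiseless signals are proper normalized Z values
  fg <- s1$label != 1L
  z <- s1$stacks[["2"]]$frames[, , 3][fg]
  expect_true(all(z > 0 & z <= 1 + 1e-6))
})

test_that("seeded simulation is bit-reproducible", {
  g <- make_phantom(phantom_spec(seed = 8))
  pr <- protocol(b1_levels = 3, offsets = default_offsets(3))
  a <- simulate_study(g, pr, seed = 2)
  b <- simulate_study(g, pr, seed = 2)
  expect_identical(a$stacks[["3"]]$frames, b$stacks[["3"]]$frames)
  expect_identical(a$ir$frames, b$ir$frames)
})
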