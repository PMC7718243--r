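test_that("the observation matrix concatenates maps and frames per retained voxel", {
  mask <- matrix(FALSE, 4, 4); mask[c(2, 7)] <- TRUE
  t1 <- matrix(seq_len(16) / 16, 4, 4); t2 <- t1 * 2
  hz <- list(list(z = array(seq_len(16 * 4) / 64, c(4, 4, 4))))
  obs <- build_observation_matrix(t1, t2, hz, mask)
  expect_equal(dim(obs$x), c(2, 6))
  expect_equal(obs$x[, 1], t1[c(2, 7)])
  expect_error(build_observation_matrix(t1, t2, hz, mask & FALSE), "empty")
})

test_that("observation rows equal the eroded, B0-valid voxel count", {
  cs <- clean_study()
  nm <- normalize_maps(cs$geom$truth$t1_obs_ms, cs$geom$truth$t2_obs_ms)
  b1s <- vapply(cs$preproc$zs, `[[`, numeric(1), "b1_ut")
  obs <- build_observation_matrix(nm$t1, nm$t2,
                                  cs$preproc$zs[b1s %in% c(3, 6)],
                                  cs$preproc$valid)
  expect_equal(nrow(obs$x), sum(cs$preproc$valid))
})

test_that("FastICA recovers independently mixed sources up to sign and order", {
  set.seed(3)
  s_true <- cbind(runif(3000, -1, 1), runif(3000, -1, 1),
                  runif(3000, -1, 1))
  a <- matrix(rnorm(18), 6, 3)
  x <- s_true %*% t(a)
  ica <- run_ica(x, 3, seed = 1)
  cors <- abs(cor(ica$s, s_true))
  # each source matched by exactly one component
  expect_true(all(apply(cors, 2, max) > 0.95))
  expect_equal(sort(apply(cors, 2, which.max)), 1:3)
  # determinism under a fixed seed
  expect_identical(ica$s, run_ica(x, 3, seed = 1)$s)
  # rank-deficient input cannot be decomposed
  x1 <- cbind(rnorm(500)) %*% t(rep(1, 5))
  expect_error(run_ica(x1, 3, seed = 1), "rank")
})

test_that("normalized mutual information matches an entropy-counting oracle", {
  nmi_oracle <- function(qx, qy) {
    joint <- table(qx, qy) / length(qx)
    ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    hx <- ent(rowSums(joint)); hy <- ent(colSums(joint))
    (hx + hy - ent(as.vector(joint))) / ((hx + hy) / 2)
  }
  set.seed(5)
  x <- rnorm(2000); y <- x + rnorm(2000, 0, 0.5)
  qz <- function(v) cut(v, seq(min(v), max(v), length.out = 33),
                        include.lowest = TRUE, labels = FALSE)
  expect_equal(nmi_score(x, y), nmi_oracle(qz(x), qz(y)), tolerance = 1e-12)
  # self-information: identical images have NMI 1
  expect_equal(nmi_score(x, x), 1)
  # independence: NMI near zero (finite-sample bias of the 32^2-bin
  # histogram keeps it slightly positive); constants are defined as zero
  expect_lt(nmi_score(x, sample(x)), 0.1)
  expect_equal(nmi_score(rep(1, 100), rnorm(100)), 0)
})

test_that("ICs are sorted ascending by NMI and weighted", {
  set.seed(8)
  base <- rnorm(1500)
  x <- cbind(base + rnorm(1500, 0, 2), rnorm(1500),
             base + rnorm(1500, 0, 0.2))
  ica <- structure(list(s = scale(x), unmixing = diag(3),
                        voxel_idx = NULL, dims = NULL),
                   class = "ic_result")
  out <- sort_and_weight_ics(ica, base, weights = c(2, 3, 1))
  expect_equal(order(out$nmi_scores), 1:3)    # ascending after sorting
  # the component most similar to the reference image became IC3
  expect_equal(which.max(abs(cor(out$s, base))), 3)
  expect_equal(apply(out$s, 2, sd),
               c(2, 3, 1) * apply(ica$s, 2, sd)[order(
                 apply(ica$s, 2, nmi_score, y = base))],
               tolerance = 1e-12)
})

test_that("the Gaussian mixture recovers well-separated clusters deterministically", {
  set.seed(12)
  centres <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0), c(0, 0, 6),
                   c(5, 5, 5))
  truth <- rep(1:5, each = 120)
  s <- centres[truth, ] + matrix(rnorm(600 * 3, 0, 0.5), 600, 3)
  g <- fit_gmm(s, k = 5, seed = 0)
  expect_gte(mclust::adjustedRandIndex(g$cluster, truth), 0.95)
  expect_identical(g$cluster, fit_gmm(s, k = 5, seed = 0)$cluster)
  # single-component fit returns the sample moments
  g1 <- fit_gmm(s[truth == 1, ], k = 1, seed = 0)
  expect_equal(drop(g1$cluster_means), colMeans(s[truth == 1, ]),
               tolerance = 0.01, ignore_attr = TRUE)
})

test_that("label assignment follows the published three-step rule", {
  mk <- function(means, weights = rep(0.2, 5))
    structure(list(cluster_means = means, cluster_weights = weights,
                   cluster = rep(1:5, 20), posterior = NULL,
                   s = NULL, voxel_idx = NULL, dims = NULL),
              class = "segmentation_result")
  # step 1: largest |IC1| mean is blood/edema
  m <- cbind(c(5, 1, 0.5, -0.2, 0.1), c(0, -2, -1, 0.5, 2),
             c(0, 0, 0, 0, 0))
  r <- assign_labels(mk(m), "DU145")
  expect_equal(r$class_labels[1], "blood_edema")
  # step 3 (DU145): ascending IC2 means -> muscle, mc, necrosis, tumour
  expect_equal(r$class_labels[2:5],
               c("muscle", "muscle_connective", "necrosis_apoptosis",
                 "active_tumour"))
  # 22Rv1 replaces the sequence applied to the same ranking
  r22 <- assign_labels(mk(m), "22Rv1")
  expect_equal(r22$class_labels[2:5],
               c("active_tumour", "muscle_connective",
                 "necrosis_apoptosis", "muscle"))
  # step 2: reflections bring the blood/edema mean into the first octant
  m2 <- cbind(c(-3, 1, 0.5, -0.2, 0.1), c(2, -2, -1, 0.5, 1.8),
              c(-1, 0, 0, 0, 0))
  r2 <- assign_labels(mk(m2), "DU145")
  expect_equal(r2$reflections, c(-1, 1, -1))
  expect_equal(r2$cluster_means_reflected[1, ], c(3, 2, 1))
  # labels are a bijection onto the five classes
  expect_setequal(r$class_labels, SEGMENT_CLASSES)
})

test_that("final labels are invariant to global IC sign flips", {
  set.seed(30)
  centres <- rbind(c(4, 0.2, 0.1), c(-0.5, -2, 0), c(-0.2, -1, 0.5),
                   c(0.1, 0.8, -1), c(-0.3, 2, 1.5))
  truth <- rep(1:5, times = c(40, 200, 150, 250, 160))
  s <- centres[truth, ] + matrix(rnorm(length(truth) * 3, 0, 0.3),
                                 ncol = 3)
  lab_of <- function(scores) {
    g <- fit_gmm(scores, k = 5, seed = 0)
    as.character(assign_labels(g, "DU145")$label)
  }
  expect_identical(lab_of(s), lab_of(-s))
  expect_identical(lab_of(s), lab_of(s %*% diag(c(-1, 1, -1))))
})
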