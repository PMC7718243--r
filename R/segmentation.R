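#' Anatomical classes assigned by the segmentation, in factor-level order
#' @export
SEGMENT_CLASSES <- c("active_tumour", "necrosis_apoptosis", "muscle",
                     "muscle_connective", "blood_edema")

#' Observation matrix for intratumoural segmentation
#'
#' Concatenates, per retained voxel, the normalized T1 and T2 maps and
#' every high-B1 Z-spectrum frame into a feature matrix.  Rows follow a
#' deterministic row-major scan (row index varies slowest) of the mask.
#'
#' @param t1_norm,t2_norm normalized relaxation maps (see
#'   \code{\link{normalize_maps}})
#' @param highb1_z list of preprocessed high-B1 stacks, each with a
#'   \code{z} array (rows x cols x frames)
#' @param mask logical matrix of retained voxels
#' @return list of class \code{observation_matrix} with \code{x} (voxels x
#'   features), \code{voxel_idx} (linear indices into the grid) and
#'   \code{dims}
#' @export
build_observation_matrix <- function(t1_norm, t2_norm, highb1_z, mask) {
  if (!any(mask)) stop("empty mask")
  nr <- nrow(mask); nc <- ncol(mask)
  pos <- which(mask, arr.ind = TRUE)
  ord <- order(pos[, 1], pos[, 2])   # row-major scan
  idx <- (pos[ord, 2] - 1) * nr + pos[ord, 1]
  cols <- list(t1_norm[idx], t2_norm[idx])
  for (st in highb1_z) {
    nf <- dim(st$z)[3]
    for (k in seq_len(nf)) cols[[length(cols) + 1]] <- st$z[, , k][idx]
  }
  x <- do.call(cbind, cols)
  keep <- stats::complete.cases(x)
  structure(list(x = x[keep, , drop = FALSE], voxel_idx = idx[keep],
                 dims = c(nr, nc)), class = "observation_matrix")
}

# symmetric-decorrelation orthogonalization W <- (W W^T)^(-1/2) W
sym_orth <- function(w) {
  e <- eigen(w %*% t(w), symmetric = TRUE)
  if (any(e$values < 1e-12)) stop("degenerate unmixing matrix")
  e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors) %*% w
}

#' FastICA decomposition of an observation matrix
#'
#' Symmetric FastICA with the logcosh contrast: the columns are centred,
#' whitened by eigendecomposition of the covariance, and the unmixing
#' matrix iterated with symmetric decorrelation from a seeded random
#' orthonormal start.  Deterministic under a fixed seed.
#'
#' @param obs \code{\link{build_observation_matrix}} output, or a plain
#'   numeric matrix (voxels x features)
#' @param n_components number of independent components
#' @param seed RNG seed for the initial unmixing matrix
#' @param max_iter,tol iteration control
#' @return list of class \code{ic_result}: \code{s} (voxels x components
#'   scores), \code{unmixing}, \code{whitening}, \code{center},
#'   \code{voxel_idx}, \code{dims}, \code{nmi_scores} and \code{weights}
#'   (NULL until \code{\link{sort_and_weight_ics}})
#' @export
run_ica <- function(obs, n_components = 3, seed = 0, max_iter = 1000,
                    tol = 1e-8) {
  x <- if (inherits(obs, "observation_matrix")) obs$x else obs
  stopifnot(is.matrix(x), all(is.finite(x)))
  n <- nrow(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  ev <- eigen(crossprod(xc) / n, symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-10
  if (sum(pos) < n_components)
    stop("ICA did not converge: observation matrix has rank ", sum(pos),
         " < ", n_components)
  k <- diag(1 / sqrt(ev$values[seq_len(n_components)])) %*%
    t(ev$vectors[, seq_len(n_components), drop = FALSE])
  z <- xc %*% t(k)                      # whitened, n x comp
  w <- local({
    set.seed(seed)
    sym_orth(matrix(stats::rnorm(n_components^2), n_components))
  })
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wx <- z %*% t(w)                    # n x comp
    gwx <- tanh(wx)
    g_wx <- 1 - gwx^2
    w_new <- sym_orth(t(gwx) %*% z / n - diag(colMeans(g_wx)) %*% w)
    delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("ICA did not converge within ", max_iter, " iterations (delta ",
         signif(delta, 3), ")")
  structure(list(s = z %*% t(w), unmixing = w %*% k, whitening = k,
                 center = ctr,
                 voxel_idx = if (inherits(obs, "observation_matrix"))
                   obs$voxel_idx else NULL,
                 dims = if (inherits(obs, "observation_matrix"))
                   obs$dims else NULL,
                 nmi_scores = NULL, weights = NULL),
            class = "ic_result")
}

#' Normalized mutual information between two continuous images
#'
#' Both inputs are quantized into \code{bins} equal-width bins over their
#' own range; NMI = I(X;Y) / ((H(X) + H(Y)) / 2) computed from the joint
#' histogram (arithmetic-mean normalization).  A constant input has zero
#' entropy and NMI is defined as 0.
#'
#' @param x,y numeric vectors of equal length
#' @param bins number of quantization bins
#' @return NMI in [0, 1]
#' @export
nmi_score <- function(x, y, bins = 32) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  qz <- function(v) {
    if (diff(range(v)) == 0) return(NULL)
    cut(v, breaks = seq(min(v), max(v), length.out = bins + 1),
        include.lowest = TRUE, labels = FALSE)
  }
  qx <- qz(x); qy <- qz(y)
  if (is.null(qx) || is.null(qy)) return(0)
  joint <- table(qx, qy) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hx <- ent(px); hy <- ent(py)
  if (hx == 0 || hy == 0) return(0)
  mi <- ent(px) + ent(py) - ent(as.vector(joint))
  mi / ((hx + hy) / 2)
}

#' Sort ICs by mutual information with the protocol mean and weight them
#'
#' Components are relabelled IC1..IC3 in ascending order of NMI between
#' each component's score image and the voxelwise mean of all protocol
#' inputs, then multiplied by tumour-type-specific weights.
#'
#' @param ica \code{\link{run_ica}} output
#' @param protocol_mean per-voxel mean over all observation-matrix
#'   columns (same row order as the ICA input)
#' @param weights numeric length-3 multipliers applied to IC1..IC3 after
#'   sorting (2:3:1 for 22Rv1, 1:3:2 for DU145)
#' @return updated \code{ic_result}, with \code{s} sorted and weighted and
#'   \code{nmi_scores}/\code{weights} filled in
#' @export
sort_and_weight_ics <- function(ica, protocol_mean, weights = c(2, 3, 1)) {
  stopifnot(inherits(ica, "ic_result"),
            length(protocol_mean) == nrow(ica$s),
            length(weights) == ncol(ica$s), all(weights > 0))
  nmi <- apply(ica$s, 2, nmi_score, y = protocol_mean)
  ord <- order(nmi)
  ica$s <- sweep(ica$s[, ord, drop = FALSE], 2, weights, `*`)
  ica$unmixing <- ica$unmixing[ord, , drop = FALSE] * weights
  ica$nmi_scores <- nmi[ord]
  ica$weights <- weights
  ica
}

#' Five-cluster full-covariance Gaussian mixture in IC space
#'
#' EM fit of a k-component Gaussian mixture with unconstrained (full)
#' covariance matrices; every voxel receives the label of its maximum
#' posterior responsibility.  Model-based hierarchical initialization
#' makes the fit deterministic; on a degenerate solution the fit is
#' retried with jittered data (up to 5 attempts).
#'
#' @param ica sorted/weighted \code{\link{sort_and_weight_ics}} output (or
#'   any matrix of scores)
#' @param k number of clusters
#' @param seed RNG seed for the jittered retries
#' @return list of class \code{segmentation_result}: \code{cluster_means}
#'   (k x d), \code{cluster_covariances} (d x d x k),
#'   \code{cluster_weights}, \code{cluster} (per-voxel hard assignment),
#'   \code{posterior}, plus the score matrix and voxel bookkeeping
#' @export
fit_gmm <- function(ica, k = 5, seed = 0) {
  s <- if (inherits(ica, "ic_result")) ica$s else ica
  if (nrow(s) < 50) stop("need at least 50 voxels for the mixture fit")
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  fit <- NULL
  set.seed(seed)
  for (attempt in 1:5) {
    sj <- if (attempt == 1) s else
      s + stats::rnorm(length(s), 0, 1e-6 * stats::sd(s))
    fit <- tryCatch(
      mclust::Mclust(sj, G = k, modelNames = "VVV", verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(fit) && !is.null(fit$parameters)) break
  }
  if (is.null(fit)) stop("Gaussian mixture fit failed after 5 attempts")
  structure(list(cluster_means = t(fit$parameters$mean),
                 cluster_covariances = fit$parameters$variance$sigma,
                 cluster_weights = fit$parameters$pro,
                 cluster = as.integer(fit$classification),
                 posterior = fit$z,
                 s = s,
                 voxel_idx = if (inherits(ica, "ic_result"))
                   ica$voxel_idx else NULL,
                 dims = if (inherits(ica, "ic_result")) ica$dims else NULL),
            class = "segmentation_result")
}

#' Rule-based anatomical labelling of the GMM clusters
#'
#' (1) the cluster with the largest |mean IC1| is blood/edema; (2) the IC
#' axes are reflected (sign-flipped) as required to bring that cluster's
#' mean into the first octant — ICA does not fix source signs; (3) the
#' remaining four clusters, ranked by ascending mean IC2, are labelled
#' muscle, muscle/connective, necrosis/apoptosis, active tumour for DU145
#' and active tumour, muscle/connective, necrosis/apoptosis, muscle for
#' 22Rv1.  Ties in cluster means are broken by larger mixture weight.
#'
#' @param result \code{\link{fit_gmm}} output
#' @param tumour_type "22Rv1" or "DU145"
#' @return updated \code{segmentation_result} with \code{class_labels}
#'   (per-cluster class names), per-voxel \code{label} (factor),
#'   \code{reflections} (the sign vector applied), and — when voxel
#'   bookkeeping is present — \code{label_map} (factor-level integer
#'   matrix, NA outside the observation rows)
#' @export
assign_labels <- function(result, tumour_type = c("22Rv1", "DU145")) {
  tumour_type <- match.arg(tumour_type)
  mu <- result$cluster_means
  k <- nrow(mu)
  stopifnot(k == 5, ncol(mu) == 3)
  wts <- result$cluster_weights
  # step 1: blood/edema, |IC1| mean, weight breaks ties
  o <- order(-abs(mu[, 1]), -wts)
  blood <- o[1]
  if (k > 1 && abs(abs(mu[o[1], 1]) - abs(mu[o[2], 1])) < 1e-12)
    message("tie on |IC1| cluster means broken by mixture weight")
  # step 2: reflect axes so the blood/edema mean is in the first octant
  refl <- ifelse(mu[blood, ] < 0, -1, 1)
  mu <- sweep(mu, 2, refl, `*`)
  # step 3: rank remaining clusters by ascending IC2 mean
  rest <- setdiff(seq_len(k), blood)
  rest <- rest[order(mu[rest, 2], -wts[rest])]
  ordered_classes <- if (tumour_type == "DU145")
    c("muscle", "muscle_connective", "necrosis_apoptosis", "active_tumour")
  else
    c("active_tumour", "muscle_connective", "necrosis_apoptosis", "muscle")
  class_labels <- character(k)
  class_labels[blood] <- "blood_edema"
  class_labels[rest] <- ordered_classes
  result$class_labels <- class_labels
  result$reflections <- refl
  result$cluster_means_reflected <- mu
  result$label <- factor(class_labels[result$cluster],
                         levels = SEGMENT_CLASSES)
  if (!is.null(result$voxel_idx)) {
    lm <- matrix(NA_integer_, result$dims[1], result$dims[2])
    lm[result$voxel_idx] <- as.integer(result$label)
    result$label_map <- lm
  }
  result
}

#' End-to-end ICA + GMM segmentation of one study
#'
#' Convenience wrapper: observation matrix from the normalized T1/T2 maps
#' and high-B1 stacks, 3-component FastICA, NMI sorting, tumour-type
#' weighting, 5-cluster GMM and rule-based labelling.
#'
#' @param t1_map,t2_map relaxation maps in ms (normalized internally)
#' @param preproc \code{\link{preprocess_study}} output
#' @param mask voxels to segment (default: the validity mask)
#' @param tumour_type "22Rv1" or "DU145" (selects IC weights and label
#'   order)
#' @param highb1_ut B1 levels treated as MT-weighted features, µT
#' @param seed RNG seed for ICA and the GMM retries
#' @return labelled \code{segmentation_result}
#' @export
segment_study <- function(t1_map, t2_map, preproc, mask = preproc$valid,
                          tumour_type = c("22Rv1", "DU145"),
                          highb1_ut = c(3, 6), seed = 0) {
  tumour_type <- match.arg(tumour_type)
  nm <- normalize_maps(t1_map, t2_map)
  b1s <- vapply(preproc$zs, `[[`, numeric(1), "b1_ut")
  hz <- preproc$zs[b1s %in% highb1_ut]
  obs <- build_observation_matrix(nm$t1, nm$t2, hz, mask)
  ica <- run_ica(obs, n_components = 3, seed = seed)
  weights <- if (tumour_type == "22Rv1") c(2, 3, 1) else c(1, 3, 2)
  ica <- sort_and_weight_ics(ica, rowMeans(obs$x), weights)
  gmm <- fit_gmm(ica, k = 5, seed = seed)
  assign_labels(gmm, tumour_type)
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b logical matrices/vectors
#' @return 2|A ∩ B| / (|A| + |B|); NA if both masks are empty
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  a[is.na(a)] <- FALSE; b[is.na(b)] <- FALSE
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}
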