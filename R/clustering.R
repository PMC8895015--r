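# Selection of mutually consistent reconstructions: register the ensemble
# to a common frame, embed each image with a fixed convolutional feature
# bank, reduce with PCA, partition with k-means++ and average the best
# members of the most data-consistent cluster.

#' Register an ensemble to a common frame
#'
#' The Fourier magnitudes constrain a CDI reconstruction only up to an
#' arbitrary translation and the Friedel twin (the point-inverted
#' duplicate), so independent runs must be aligned before any pixel-wise
#' comparison. Member 1 is the reference; every other member is replaced by
#' the better-matching of itself and its twin, cyclically shifted by the
#' integer offset maximizing the real-space cross-correlation with the
#' reference. The twin is taken only when it strictly beats the original, so
#' registration is idempotent. In complex mode the global phase is also
#' rotated so the support-mean phase is zero.
#'
#' @param set a `reconstruction_set` with at least 2 members.
#' @return The registered `reconstruction_set`.
#' @export
register_reconstructions <- function(set) {
  stopifnot(inherits(set, "reconstruction_set"))
  if (length(set$members) < 2L)
    stop_sk("registration needs at least two members")
  ref <- registration_image(set$members[[1L]])
  members <- set$members
  members[[1L]] <- align_phase(members[[1L]])
  for (i in seq_along(members)[-1L]) {
    members[[i]] <- align_phase(register_to(members[[i]], ref))
  }
  new_reconstruction_set(members, set$pattern, registered = TRUE)
}

# real comparison image used for shift/twin matching
registration_image <- function(member) {
  img <- if (inherits(member, "reconstruction")) member$image else member
  if (is.complex(img)) Mod(img) else img
}

# align one member (twin choice + integer shift) to a real reference image
register_to <- function(member, ref) {
  img <- if (inherits(member, "reconstruction")) member$image else member
  cmp <- registration_image(member)
  direct <- best_shift(ref, cmp)
  twin <- best_shift(ref, point_invert(cmp))
  use_twin <- twin$score > direct$score
  if (use_twin) {
    img <- point_invert(img)
    supp <- if (inherits(member, "reconstruction"))
      point_invert(member$support) else NULL
    sh <- twin$shift
  } else {
    supp <- if (inherits(member, "reconstruction")) member$support else NULL
    sh <- direct$shift
  }
  img <- circshift2(img, sh)
  if (!is.null(supp)) supp <- circshift2(supp, sh)
  if (inherits(member, "reconstruction")) {
    out <- member
    out$image <- img
    out$support <- supp
    out
  } else img
}

# rotate the global phase so the support-mean phase is zero (complex mode)
align_phase <- function(member) {
  img <- if (inherits(member, "reconstruction")) member$image else member
  if (!is.complex(img)) return(member)
  supp <- if (inherits(member, "reconstruction")) member$support else
    array(TRUE, dim(img))
  z <- mean(img[supp])
  if (Mod(z) > 0) img <- img * Conj(z) / Mod(z)
  if (inherits(member, "reconstruction")) {
    out <- member
    out$image <- img
    out
  } else img
}

#' Fixed multi-scale convolutional feature backbone
#'
#' A deterministic, training-free stand-in for a learned convolutional
#' embedding: a seeded bank of zero-mean, unit-norm random kernels at
#' several spatial scales. Features are computed by circular convolution,
#' rectification (ReLU) and coarse average pooling, then concatenated. The
#' bank is fixed by its seed, so identical images always map to identical
#' vectors. Any alternative backbone can be supplied to
#' [extract_features()] as a function `image -> numeric vector`.
#'
#' @param seed seed fixing the kernel bank.
#' @param scales kernel edge lengths in pixels.
#' @param n_kernels kernels per scale.
#' @param pool_grid pooling grid edge (features per kernel = `pool_grid^2`).
#' @return An object of class `"conv_backbone"`.
#' @export
conv_backbone <- function(seed = 42L, scales = c(3L, 7L, 15L),
                          n_kernels = 8L, pool_grid = 4L) {
  kernels <- with_seed(seed, {
    lapply(scales, function(s) {
      lapply(seq_len(n_kernels), function(i) {
        k <- matrix(stats::rnorm(s * s), s, s)
        k <- k - mean(k)                     # zero response to flat images
        k / sqrt(sum(k^2))
      })
    })
  })
  structure(list(kernels = kernels, scales = scales,
                 n_kernels = n_kernels, pool_grid = pool_grid, seed = seed),
            class = "conv_backbone")
}

#' Extract a feature vector from a registered image
#'
#' @param image numeric matrix (a registered reconstruction; complex images
#'   are reduced to their modulus). The image is L2-normalized internally.
#' @param backbone a [conv_backbone()], or a function mapping an image
#'   matrix to a numeric vector.
#' @return Numeric feature vector of fixed length.
#' @export
extract_features <- function(image, backbone = conv_backbone()) {
  if (is.function(backbone)) return(as.numeric(backbone(image)))
  if (!inherits(backbone, "conv_backbone")) stop_sk("unknown backbone")
  x <- registration_image(image)
  nrm <- sqrt(sum(x^2))
  if (nrm > 0) x <- x / nrm
  fx <- fft2(x)
  d <- dim(x)
  feats <- lapply(unlist(backbone$kernels, recursive = FALSE), function(k) {
    kp <- matrix(0, d[1L], d[2L])
    kp[seq_len(nrow(k)), seq_len(ncol(k))] <- k
    conv <- Re(ifft2(fx * fft2(kp)))
    as.numeric(pool_average(pmax(conv, 0), backbone$pool_grid))
  })
  unlist(feats, use.names = FALSE)
}

# feature matrix (rows = members) for a registered set
set_features <- function(set, backbone = conv_backbone()) {
  t(vapply(set$members, function(m) extract_features(m, backbone),
           extract_features(set$members[[1L]], backbone) * 0))
}

# seeded k-means++ centre initialization (Arthur & Vassilvitskii)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k)[-1L]) {
    if (sum(d2) <= 0) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2 / sum(d2))
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

#' Cluster reconstructions in feature space
#'
#' Centres the feature vectors, projects them onto the leading principal
#' components, and partitions the projections with k-means using k-means++
#' seeding. The selected cluster is the one with the lowest mean Fourier
#' R-factor among its members (ties broken towards the larger cluster, then
#' the lower index); when no R-factors are supplied the largest cluster is
#' selected.
#'
#' @param features numeric matrix, one row per reconstruction (see
#'   [extract_features()]).
#' @param n_components number of principal components retained (capped at
#'   the available rank).
#' @param k number of clusters, `2 <= k <=` number of members.
#' @param seed seed for the k-means++ initialization.
#' @param rfactors optional per-member Fourier R-factors used for cluster
#'   selection.
#' @return A `cluster_result`.
#' @export
cluster_reconstructions <- function(features, n_components = 10L, k = 4L,
                                    seed = 1L, rfactors = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 2L) stop_sk("`k` must be at least 2 (k = 1 is degenerate)")
  if (k > n) stop_sk("`k` exceeds the number of members")
  if (!is.null(rfactors) && length(rfactors) != n)
    stop_sk("`rfactors` must have one value per member")
  ncomp <- min(n_components, ncol(features), n - 1L)
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(max(1L, ncomp)), drop = FALSE]
  labels <- if (k == n) {
    seq_len(n)            # degenerate partition: one member per cluster
  } else {
    with_seed(seed, {
      centers <- kmeanspp_centers(scores, k)
      centers <- centers[!duplicated(centers), , drop = FALSE]
      km <- suppressWarnings(
        stats::kmeans(scores, centers = centers, iter.max = 100L))
      km$cluster
    })
  }
  selected <- select_cluster(labels, rfactors)
  new_cluster_result(labels, selected, which(labels == selected),
                     rfactors = rfactors)
}

# lowest mean R-factor, ties -> larger cluster, then lower index
select_cluster <- function(labels, rfactors = NULL) {
  ids <- sort(unique(labels))
  sizes <- vapply(ids, function(l) sum(labels == l), integer(1))
  score <- if (is.null(rfactors)) -sizes else
    vapply(ids, function(l) mean(rfactors[labels == l]), numeric(1))
  ord <- order(score, -sizes, ids)
  ids[ord[1L]]
}

#' Average the best members of the selected cluster
#'
#' Takes the `n_best` lowest-R-factor members of the selected cluster (all
#' of them when fewer), re-registers each to the running mean, and returns
#' the pixel-wise mean image together with a report of the averaged member
#' indices and their mean R-factor. Averaging mutually consistent
#' reconstructions suppresses the irreproducible (noise-driven) part of the
#' phases, which is exactly what the PRTF then measures.
#'
#' @param set a registered `reconstruction_set`.
#' @param cluster_result a `cluster_result` for that set.
#' @param n_best maximum number of members averaged.
#' @return A list with elements `image`, `support`, `members` (indices
#'   averaged) and `mean_rfactor`, of class `"speckle_average"`.
#' @export
select_and_average <- function(set, cluster_result, n_best = 24L) {
  stopifnot(inherits(set, "reconstruction_set"),
            inherits(cluster_result, "cluster_result"))
  chosen <- cluster_result$chosen_members
  if (length(chosen) == 0L) stop_sk("selected cluster is empty")
  r <- member_rfactors(set)[chosen]
  chosen <- chosen[order(r)]
  chosen <- chosen[seq_len(min(n_best, length(chosen)))]
  acc <- registration_image(set$members[[chosen[1L]]])
  if (length(chosen) > 1L) {
    for (i in seq_along(chosen)[-1L]) {
      img <- register_to(registration_image(set$members[[chosen[i]]]),
                         acc / (i - 1L))
      acc <- acc + img
    }
  }
  avg <- acc / length(chosen)
  structure(list(image = avg, support = set$members[[chosen[1L]]]$support,
                 members = sort(chosen),
                 mean_rfactor = mean(member_rfactors(set)[chosen])),
            class = "speckle_average")
}

#' @export
print.speckle_average <- function(x, ...) {
  cat(sprintf("<speckle_average> of %d members, mean R-factor %.4g\n",
              length(x$members), x$mean_rfactor))
  invisible(x)
}

#' Baseline clustering by pairwise real-space correlation
#'
#' A deliberately simple comparator for the feature-based path: hierarchical
#' (average-linkage) grouping on the matrix of pairwise Pearson correlations
#' between registered member images, cut at correlation `cut`. Cluster
#' selection follows the same lowest-mean-R rule.
#'
#' @param set a registered `reconstruction_set`.
#' @param method only `"pairwise-cc"`.
#' @param cut correlation level at which the dendrogram is cut.
#' @return A `cluster_result` (the correlation matrix is attached as
#'   attribute `"cc"`).
#' @export
baseline_cluster <- function(set, method = "pairwise-cc", cut = 0.7) {
  stopifnot(inherits(set, "reconstruction_set"))
  method <- match.arg(method, "pairwise-cc")
  n <- length(set$members)
  if (n < 2L) stop_sk("need at least two members")
  mats <- vapply(set$members, function(m) as.numeric(registration_image(m)),
                 numeric(length(set$members[[1L]]$image)))
  cc <- suppressWarnings(stats::cor(mats))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  labels <- if (n == 2L) {
    if (cc[1L, 2L] >= cut) c(1L, 1L) else c(1L, 2L)
  } else {
    h <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    stats::cutree(h, h = 1 - cut)
  }
  r <- member_rfactors(set)
  res <- new_cluster_result(labels, select_cluster(labels, r),
                            which(labels == select_cluster(labels, r)),
                            rfactors = r, method = "pairwise-cc")
  attr(res, "cc") <- cc
  res
}

#' One-call ensemble selection
#'
#' Convenience wrapper running the full selection path on an ensemble:
#' registration, feature extraction, PCA + k-means++ clustering, and
#' averaging of the best members of the selected cluster.
#'
#' @param set a `reconstruction_set`.
#' @param backbone a [conv_backbone()] or feature function.
#' @param k,n_components,seed passed to [cluster_reconstructions()].
#' @param n_best passed to [select_and_average()].
#' @return A list with the registered `set`, the `clusters` result and the
#'   `average` (a `"speckle_average"`).
#' @export
cluster_ensemble <- function(set, backbone = conv_backbone(), k = 4L,
                             n_components = 10L, n_best = 24L, seed = 1L) {
  reg <- register_reconstructions(set)
  feats <- set_features(reg, backbone)
  cl <- cluster_reconstructions(feats, n_components = n_components, k = k,
                                seed = seed, rfactors = member_rfactors(reg))
  avg <- select_and_average(reg, cl, n_best = n_best)
  list(set = reg, clusters = cl, average = avg)
}
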