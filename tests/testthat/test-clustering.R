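test_that("registration recovers constructed shifts and Friedel twins exactly", {
  ph <- make_phantom(seed = 8, grid_size = 64, object_fraction = 0.08)
  pat <- diffract(ph)
  base <- ph$density
  mk <- function(img, s) specklekit:::new_reconstruction(
    img, ph$support, 0.1, s, rfactor = 0.1)
  members <- list(
    mk(base, 1),
    mk(specklekit:::circshift2(base, c(4, -7)), 2),
    mk(specklekit:::point_invert(base), 3),
    mk(specklekit:::circshift2(specklekit:::point_invert(base), c(-3, 5)), 4))
  set <- specklekit:::new_reconstruction_set(members, pat)
  reg <- register_reconstructions(set)
  for (m in reg$members) expect_equal(m$image, base, tolerance = 1e-12)

  # idempotence: registering a registered set changes nothing
  reg2 <- register_reconstructions(reg)
  expect_equal(reg2$members, reg$members, tolerance = 1e-12)

  # already-aligned identical members pass through unchanged
  same <- specklekit:::new_reconstruction_set(list(mk(base, 1), mk(base, 2)),
                                              pat)
  regs <- register_reconstructions(same)
  expect_equal(regs$members[[2]]$image, base, tolerance = 1e-12)
})

test_that("the fixed convolutional backbone is deterministic and structure-sensitive", {
  ph <- make_phantom(seed = 9, grid_size = 64, object_fraction = 0.08)
  bb <- conv_backbone()
  f1 <- extract_features(ph$density, bb)
  f2 <- extract_features(ph$density, bb)
  expect_identical(f1, f2)
  expect_length(f1, length(bb$scales) * bb$n_kernels * bb$pool_grid^2)
  expect_true(all(is.finite(f1)))

  # all-zero image maps to the zero vector (zero-bias kernels + ReLU)
  expect_equal(extract_features(matrix(0, 64, 64), bb), rep(0, length(f1)))

  # a strong blur moves the features further than tiny noise does
  blur <- Re(specklekit:::ifft2(specklekit:::fft2(ph$density) *
    exp(-specklekit:::ifftshift2(specklekit:::freq_radius(c(64, 64)))^2 / 8)))
  set.seed(1)
  noisy <- ph$density + matrix(rnorm(64^2, 0, 1e-6), 64, 64)
  d_blur <- sqrt(sum((extract_features(blur, bb) - f1)^2))
  d_noise <- sqrt(sum((extract_features(noisy, bb) - f1)^2))
  expect_gt(d_blur, d_noise)

  # a plain function is accepted as a custom backbone
  expect_equal(extract_features(ph$density, function(x) c(sum(x), max(x))),
               c(sum(ph$density), max(ph$density)))
  expect_error(extract_features(ph$density, "vgg"), "backbone")
})

test_that("feature -> PCA -> k-means++ recovers planted two-group partitions", {
  ph_a <- make_phantom(seed = 10, grid_size = 64, object_fraction = 0.08)
  ph_b <- make_phantom(seed = 20, grid_size = 64, object_fraction = 0.08)
  pat <- diffract(ph_a)
  set.seed(2)
  mk <- function(img, s, r) specklekit:::new_reconstruction(
    img, ph_a$support, r, s, rfactor = r)
  members <- c(
    lapply(1:5, function(i) mk(ph_a$density +
      matrix(rnorm(64^2, 0, 0.01), 64, 64), i, 0.05 + i / 1000)),
    lapply(1:4, function(i) mk(ph_b$density +
      matrix(rnorm(64^2, 0, 0.01), 64, 64), 10 + i, 0.2 + i / 1000)))
  set <- specklekit:::new_reconstruction_set(members, pat)
  feats <- specklekit:::set_features(set)
  cl <- cluster_reconstructions(feats, k = 2, seed = 1,
                                rfactors = member_rfactors(set))
  expect_length(unique(cl$labels[1:5]), 1)
  expect_length(unique(cl$labels[6:9]), 1)
  expect_false(cl$labels[1] == cl$labels[6])
  # selection picks the lower-R (phantom A) group
  expect_identical(cl$chosen_members, 1:5)

  # determinism and contract errors
  cl2 <- cluster_reconstructions(feats, k = 2, seed = 1,
                                 rfactors = member_rfactors(set))
  expect_identical(cl$labels, cl2$labels)
  expect_error(cluster_reconstructions(feats, k = 1), "at least 2")
  expect_error(cluster_reconstructions(feats, k = 99), "exceeds")

  # the pairwise-correlation baseline recovers the same partition
  bl <- baseline_cluster(register_reconstructions(set), cut = 0.8)
  expect_length(unique(bl$labels[1:5]), 1)
  expect_length(unique(bl$labels[6:9]), 1)
  expect_false(bl$labels[1] == bl$labels[6])
  cc <- attr(bl, "cc")
  expect_equal(cc, t(cc))
  expect_equal(diag(cc), rep(1, 9))
})

test_that("select_and_average honours n_best and improves on single members", {
  ph <- make_phantom(seed = 11, grid_size = 64, object_fraction = 0.08)
  pat <- add_poisson_noise(diffract(ph), 1e6, seed = 1)
  set.seed(3)
  mk <- function(img, s, r) specklekit:::new_reconstruction(
    img, ph$support, r, s, rfactor = r)
  members <- lapply(1:6, function(i) mk(
    pmax(ph$density + matrix(rnorm(64^2, 0, 0.05), 64, 64) * ph$support, 0),
    i, fourier_rfactor(ph$density, pat) + i / 100))
  set <- specklekit:::new_reconstruction_set(members, pat, registered = TRUE)
  cl <- specklekit:::new_cluster_result(rep(1L, 6), 1L, 1:6,
                                        rfactors = member_rfactors(set))
  # n_best = 1 returns the single best member unchanged
  one <- select_and_average(set, cl, n_best = 1)
  expect_equal(one$image, Re(members[[1]]$image))
  expect_identical(one$members, 1L)

  avg <- select_and_average(set, cl, n_best = 24)
  expect_identical(avg$members, 1:6)
  # averaging beats the median single member against the ground truth
  cors <- vapply(members, function(m) truth_correlation(m$image, ph),
                 numeric(1))
  expect_gte(truth_correlation(avg$image, ph), median(cors))

  # a cluster of identical images averages to any member
  same <- specklekit:::new_reconstruction_set(
    lapply(1:3, function(i) mk(ph$density, i, 0.1)), pat, registered = TRUE)
  cls <- specklekit:::new_cluster_result(rep(1L, 3), 1L, 1:3,
                                         rfactors = rep(0.1, 3))
  expect_equal(select_and_average(same, cls)$image, ph$density,
               tolerance = 1e-12)
})
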