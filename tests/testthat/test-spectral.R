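toy_cluster_config <- function(...) {
  defaults <- list(k = 3L, nystrom_m = 150L, fibers_per_subject = 1000L,
                   min_fiber_length = 0, sigma_cluster = 30, n_eigenvectors = 3L,
                   bilateral = FALSE, seed = 5L)
  do.call(cluster_config, utils::modifyList(defaults, list(...)))
}

test_that("Nystrom embedding with m = N matches the dense spectral oracle", {
  pool <- toy_fiber_pool(100)
  cfg <- toy_cluster_config(nystrom_m = 300L)
  basis <- fit_embedding_basis(pool$fibers, cfg)
  coords <- embed_fibers(basis, pool$fibers)
  km <- kmeans_embed(coords, 3, seed = 5)

  # independent dense oracle: full affinity, degree scaling, eigen, row
  # normalization, base-R kmeans
  dcf <- distance_config(n_points = 15)
  flat <- tractatlas:::flatten_fibers(pool$fibers, 15)
  A <- affinity(tractatlas:::fiber_distance_matrix(flat, flat, dcf), 30)
  deg <- rowMeans(A)
  S <- A / sqrt(outer(deg, deg))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  V <- es$vectors[, 1:3]
  V <- V / sqrt(rowSums(V^2))
  set.seed(5)
  okm <- kmeans(V, 3, nstart = 10)

  expect_equal(rand_index_adj(km$labels, okm$cluster), 1.0)
  expect_equal(rand_index_adj(km$labels, pool$labels), 1.0)
  # coordinates agree up to per-axis sign
  expect_lt(max(abs(abs(coords) - abs(V))), 1e-8)
  # eigenvalues nonincreasing, led by the largest
  expect_true(all(diff(basis$eigvals) <= 1e-12))
})

test_that("out-of-sample embedding is self-consistent and reflection symmetric", {
  pool <- toy_fiber_pool(60)
  cfg <- toy_cluster_config(nystrom_m = 120L, bilateral = TRUE)
  basis <- fit_embedding_basis(pool$fibers, cfg)
  coords_all <- embed_fibers(basis, pool$fibers)
  # a basis sample fiber re-embeds onto its own coordinate
  probe_idx <- basis$sample_index[c(1, 50, 120)]
  probe <- embed_fibers(basis, pool$fibers[probe_idx])
  expect_lt(max(abs(probe - coords_all[probe_idx, ])), 1e-6)
  # mirrored fiber embeds identically under bilateral affinity
  mirrored <- embed_fibers(basis, lapply(pool$fibers[1:10], reflect_fiber))
  expect_lt(max(abs(mirrored - coords_all[1:10, ])), 1e-6)
  # a far-away fiber gets near-zero coordinates and the low-affinity flag
  far <- embed_fibers(basis, list(straight_fiber(c(5000, 5000, 5000),
                                                 c(5080, 5000, 5000), 10)))
  expect_lt(sqrt(sum(far^2)), 1e-3)
  expect_true(attr(far, "low_affinity"))
})

test_that("seeded k-means recovers separated blobs deterministically", {
  set.seed(30)
  blobs <- rbind(matrix(rnorm(100, 0, 0.05), ncol = 2),
                 matrix(rnorm(100, 5, 0.05), ncol = 2),
                 cbind(rnorm(50, -5, 0.05), rnorm(50, 5, 0.05)))
  truth <- rep(1:3, each = 50)
  km <- kmeans_embed(blobs, 3, seed = 9)
  expect_equal(rand_index_adj(km$labels, truth), 1.0)
  expect_identical(km, kmeans_embed(blobs, 3, seed = 9))
  km1 <- kmeans_embed(blobs, 1, seed = 9)
  expect_true(all(km1$labels == 1L))
  expect_equal(as.numeric(km1$centroids), colMeans(blobs))
  expect_error(kmeans_embed(blobs[1:2, ], 3), "fewer points")
})

test_that("leave-one-out probabilities rank inliers above displaced fibers", {
  base <- straight_fiber(c(0, 0, 0), c(80, 0, 0), 10)
  fibers <- lapply(1:12, function(i) base + matrix(rnorm(3, sd = 0.3), 10, 3, byrow = TRUE))
  subjects <- rep(c("a", "b", "c"), each = 4)
  labels <- rep(1L, 12)
  # identical fibers from several subjects: probability 1
  ident <- lapply(1:6, function(i) base)
  p1 <- fiber_probabilities(ident, rep(1L, 6), rep(c("a", "b", "c"), 2), sigma = 30)
  expect_equal(as.numeric(p1), rep(1, 6), tolerance = 1e-12)
  # one fiber displaced by 5 sigma has the strict minimum probability
  fibers[[5]] <- base + matrix(c(150, 0, 0), 10, 3, byrow = TRUE)
  p <- fiber_probabilities(fibers, labels, subjects, sigma = 30)
  expect_equal(which.min(p), 5L)
  expect_lt(p[5], min(p[-5]))
  # subject-level exclusion with a single-subject cluster: all 0, flagged
  p0 <- fiber_probabilities(fibers[1:4], rep(1L, 4), rep("a", 4), sigma = 30,
                            leave_one_out = "subject")
  expect_true(all(p0 == 0))
  expect_true(all(attr(p0, "isolated")))
})

test_that("outlier rejection implements the mean - k*sd rule per cluster", {
  # equal probabilities: sd 0, nothing rejected
  r <- reject_outliers(rep(1L, 5), rep(0.8, 5), 2)
  expect_true(all(r$kept))
  expect_equal(r$stats$sd, 0)
  # planted {0.9 x19, 0.1}: mean 0.86, sd ~0.179, cutoff ~0.502
  p <- c(rep(0.9, 19), 0.1)
  r2 <- reject_outliers(rep(1L, 20), p, 2)
  expect_identical(which(!r2$kept), 20L)
  expect_equal(r2$stats$mu, mean(p))
  expect_equal(r2$stats$sd, sd(p))
  expect_equal(r2$stats$n, 20)
  # infinite threshold rejects nothing
  expect_true(all(reject_outliers(rep(1L, 20), p, Inf)$kept))
})

test_that("default clustering settings record the standard operating point", {
  cfg <- cluster_config()
  expect_equal(cfg$k, 800L)
  expect_equal(cfg$nystrom_m, 2500L)
  expect_equal(cfg$fibers_per_subject, 10000L)
  expect_equal(cfg$min_fiber_length, 60)
  expect_equal(cfg$outlier_rounds, 2L)
  expect_equal(cfg$outlier_threshold_sd, 2)
  rcfg <- registration_config()
  expect_equal(rcfg$fibers_per_subject, 20000L)
  expect_equal(rcfg$min_fiber_length, 40)
  expect_equal(range(rcfg$sigma_schedule), c(2, 20))
  expect_equal(rcfg$bspline_grid, c(8L, 8L, 8L))
})

test_that("clusters stay separated across a 2x kernel-width sweep", {
  pool <- toy_fiber_pool(60)
  labels_ref <- NULL
  for (sg in c(15, 30)) {
    cfg <- toy_cluster_config(nystrom_m = 120L, sigma_cluster = sg)
    basis <- fit_embedding_basis(pool$fibers, cfg)
    km <- kmeans_embed(embed_fibers(basis, pool$fibers), 3, seed = 5)
    expect_equal(rand_index_adj(km$labels, pool$labels), 1.0)
    if (!is.null(labels_ref))
      expect_equal(rand_index_adj(km$labels, labels_ref), 1.0)
    labels_ref <- km$labels
  }
})
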