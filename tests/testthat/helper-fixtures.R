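# shared fixtures, all generated in code

straight_fiber <- function(from = c(0, 0, 0), to = c(10, 0, 0), n = 5) {
  t_ <- seq(0, 1, length.out = n)
  cbind(from[1] + t_ * (to[1] - from[1]),
        from[2] + t_ * (to[2] - from[2]),
        from[3] + t_ * (to[3] - from[3]))
}

semicircle_fiber <- function(radius = 1, n = 100) {
  a <- seq(0, pi, length.out = n)
  cbind(radius * cos(a), radius * sin(a), 0)
}

random_fibers <- function(n, seed = 1, scale = 20, npts = 8) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    start <- rnorm(3, sd = scale)
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    t_ <- seq(0, 1, length.out = npts)
    sweep(outer(t_ * 50, dir), 2, start, "+")
  })
}

# three well-separated single-hemisphere bundles for spectral toys
toy_bundle_specs <- function(n_fibers = 100, dispersion = 2) {
  list(bundle_spec("straight", length = 80, n_fibers = n_fibers,
                   dispersion = dispersion, center = c(0, -40, 0), seed = 11),
       bundle_spec("arc", length = 90, n_fibers = n_fibers,
                   dispersion = dispersion, center = c(0, 40, 0), radius = 100, seed = 12),
       bundle_spec("c_shape", length = 100, n_fibers = n_fibers,
                   dispersion = dispersion, center = c(0, 0, 60), seed = 13))
}

toy_fiber_pool <- function(n_per_bundle = 100, dispersion = 2) {
  specs <- toy_bundle_specs(n_per_bundle, dispersion)
  tgs <- lapply(seq_along(specs), function(i) make_bundle(specs[[i]], label = i))
  list(fibers = do.call(c, lapply(tgs, `[[`, "fibers")),
       labels = rep(seq_along(specs), each = n_per_bundle))
}

# adjusted Rand index (independent of any clustering package)
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

# mean distance between corresponding fibers across all subject pairs
# (cohort subjects share one template, so fiber k matches fiber k)
mean_corresponding_distance <- function(subjects, n_points = 10) {
  flats <- lapply(subjects, function(tg)
    tractatlas:::flatten_fibers(tg$fibers, n_points))
  dcf <- distance_config(n_points = n_points)
  v <- c()
  for (i in seq_len(length(flats) - 1))
    for (j in (i + 1):length(flats))
      v <- c(v, mean(diag(tractatlas:::fiber_distance_matrix(flats[[i]], flats[[j]], dcf))))
  mean(v)
}

# majority map from ground-truth bundle labels to atlas cluster labels
bundle_cluster_map <- function(truth, clusters) {
  tab <- table(truth, clusters)
  stats::setNames(as.integer(colnames(tab)[apply(tab, 1, which.max)]), rownames(tab))
}
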