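#' Clustering settings for atlas construction
#'
#' Defaults follow the pipeline's standard operating point: 800 clusters,
#' 2500 fibers sampled for the Nystrom approximation, 10,000 fibers per
#' subject with a 60 mm minimum length, and two rounds of outlier
#' rejection at two standard deviations below the cluster mean
#' probability.  Bilateral clustering (fiber vs mirror-of-fiber affinity)
#' is on by default so clusters form across hemispheres.
#'
#' @param k number of clusters.
#' @param nystrom_m number of sample fibers for the Nystrom approximation.
#' @param fibers_per_subject fibers sampled per subject.
#' @param min_fiber_length minimum fiber length in mm.
#' @param sigma_cluster Gaussian kernel width in mm for fiber affinity.
#' @param n_eigenvectors embedding dimensionality (<= nystrom_m).
#' @param outlier_rounds rounds of cluster-then-reject iteration.
#' @param outlier_threshold_sd rejection threshold in cluster-probability
#'   standard deviations.
#' @param bilateral use the mirrored-fiber minimum distance.
#' @param n_points fiber resampling count for distances.
#' @param seed integer seed (sampling and k-means).
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(k = 800L, nystrom_m = 2500L, fibers_per_subject = 10000L,
                           min_fiber_length = 60, sigma_cluster = 30,
                           n_eigenvectors = 20L, outlier_rounds = 2L,
                           outlier_threshold_sd = 2, bilateral = TRUE,
                           n_points = 15L, seed = 1L) {
  if (k < 1L) stop("k must be >= 1")
  if (n_eigenvectors < 1L || n_eigenvectors > nystrom_m)
    stop("n_eigenvectors must lie in [1, nystrom_m]")
  if (outlier_threshold_sd <= 0) stop("outlier_threshold_sd must be > 0")
  structure(list(k = as.integer(k), nystrom_m = as.integer(nystrom_m),
                 fibers_per_subject = as.integer(fibers_per_subject),
                 min_fiber_length = as.numeric(min_fiber_length),
                 sigma_cluster = as.numeric(sigma_cluster),
                 n_eigenvectors = as.integer(n_eigenvectors),
                 outlier_rounds = as.integer(outlier_rounds),
                 outlier_threshold_sd = as.numeric(outlier_threshold_sd),
                 bilateral = isTRUE(bilateral),
                 n_points = as.integer(n_points),
                 seed = as.integer(seed)),
            class = "cluster_config")
}

#' Fit a Nystrom spectral embedding basis
#'
#' Draws `nystrom_m` seeded random sample fibers from the pooled set,
#' computes their Gaussian-kernel affinity matrix (bilateral-combined when
#' configured), estimates normalized-cut degrees from the sample-to-all
#' affinities, and eigendecomposes the degree-scaled sample affinity
#' `D^{-1/2} A D^{-1/2}`, keeping the top `n_eigenvectors` eigenpairs.
#' Degrees are the mean affinity to the sample fibers, a Nystrom estimate
#' (up to a constant factor) of the full-graph row sums.
#'
#' @param fibers pooled fiber list (n x 3 matrices), typically
#'   multi-subject and already in the atlas frame.
#' @param config a [cluster_config].
#' @return An `embedding_basis`: sample fibers (flattened), kernel width,
#'   bilateral flag, eigenvectors (m x p), eigenvalues (nonincreasing) and
#'   per-sample degree estimates.
#' @export
fit_embedding_basis <- function(fibers, config = cluster_config()) {
  m <- config$nystrom_m
  if (length(fibers) < m)
    stop("pooled fiber count (", length(fibers), ") is below nystrom_m (", m, ")")
  set.seed(config$seed)
  idx <- sort(sample.int(length(fibers), m))
  flat_all <- flatten_fibers(fibers, config$n_points)
  flat_s <- flat_all[idx, , drop = FALSE]
  dconf <- distance_config(n_points = config$n_points, bilateral = config$bilateral)
  A <- affinity(fiber_distance_matrix(flat_s, flat_s, dconf), config$sigma_cluster)
  # degree estimate: mean affinity of each sample to all pooled fibers
  C <- affinity(fiber_distance_matrix(flat_s, flat_all, dconf), config$sigma_cluster)
  deg <- rowMeans(C)
  scaled <- A / sqrt(outer(deg, deg))
  scaled <- (scaled + t(scaled)) / 2
  es <- eigen(scaled, symmetric = TRUE)
  p <- config$n_eigenvectors
  structure(list(sample_flat = flat_s,
                 sigma = config$sigma_cluster,
                 bilateral = config$bilateral,
                 n_points = config$n_points,
                 eigvecs = es$vectors[, seq_len(p), drop = FALSE],
                 eigvals = es$values[seq_len(p)],
                 degrees = deg,
                 sample_index = idx),
            class = "embedding_basis")
}

#' @export
print.embedding_basis <- function(x, ...) {
  cat(sprintf("embedding_basis: %d sample fibers, %d eigenvectors, sigma %.3g mm%s\n",
              nrow(x$sample_flat), ncol(x$eigvecs), x$sigma,
              if (x$bilateral) ", bilateral" else ""))
  invisible(x)
}

#' Out-of-sample spectral embedding of fibers
#'
#' Embeds arbitrary fibers into the space spanned by the basis: each
#' fiber's affinity row to the sample fibers is degree-normalized and
#' projected onto the basis eigenvectors scaled by the reciprocal
#' eigenvalues (the Nystrom extension).  Deterministic given the basis.
#' A fiber with essentially zero affinity to every sample fiber lands at
#' the origin and is flagged in the `"low_affinity"` attribute.
#'
#' @param basis an `embedding_basis` from [fit_embedding_basis()].
#' @param fibers list of fibers (n x 3 matrices), or a [tractogram].
#' @return An n x p coordinate matrix with logical attribute
#'   `"low_affinity"`.
#' @export
embed_fibers <- function(basis, fibers) {
  if (inherits(fibers, "tractogram")) fibers <- fibers$fibers
  flat <- flatten_fibers(fibers, basis$n_points)
  embed_flat(basis, flat)
}

embed_flat <- function(basis, flat) {
  dconf <- distance_config(n_points = basis$n_points, bilateral = basis$bilateral)
  C <- affinity(fiber_distance_matrix(flat, basis$sample_flat, dconf), basis$sigma)
  deg_f <- rowMeans(C)
  low <- deg_f < 1e-8
  deg_f[low] <- 1 # coordinates are zeroed below; avoid 0/0
  Cn <- C / sqrt(outer(deg_f, basis$degrees))
  coords <- Cn %*% sweep(basis$eigvecs, 2, basis$eigvals, "/")
  # unit-length embedding vectors: cluster separation then depends on
  # direction, not on how central a fiber is within its cluster
  nrm <- sqrt(rowSums(coords^2))
  ok <- nrm > 1e-12
  coords[ok, ] <- coords[ok, , drop = FALSE] / nrm[ok]
  coords[low, ] <- 0
  structure(coords, low_affinity = low)
}

#' Seeded k-means in embedding space
#'
#' k-means++-style initialisation followed by Lloyd iterations, repeated
#' for 10 restarts with the best total within-cluster sum of squares
#' kept.  Deterministic given the seed.
#'
#' @param embedding n x p coordinate matrix.
#' @param k number of clusters (<= n).
#' @param seed integer seed.
#' @return List with `labels` (1..k, canonicalized by descending cluster
#'   size) and `centroids` (k x p).
#' @export
kmeans_embed <- function(embedding, k, seed = 1L) {
  x <- as.matrix(embedding)
  if (nrow(x) < k) stop("fewer points (", nrow(x), ") than clusters (", k, ")")
  if (k == 1L) {
    return(list(labels = rep(1L, nrow(x)),
                centroids = matrix(colMeans(x), 1)))
  }
  set.seed(seed)
  best <- NULL
  for (r in 1:10) {
    centers <- kmeanspp_init(x, k)
    km <- suppressWarnings(kmeans(x, centers = centers, iter.max = 100,
                                  algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  canonicalize_labels(best$cluster, best$centers)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in 2:k) {
    prob <- d2 / sum(d2)
    if (!all(is.finite(prob)) || sum(d2) <= 0) i <- sample.int(n, 1)
    else i <- sample.int(n, 1, prob = prob)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

# relabel clusters by descending size (ties: first occurrence) so runs are
# comparable across seeds
canonicalize_labels <- function(labels, centroids) {
  sizes <- tabulate(labels, nbins = nrow(centroids))
  ord <- order(-sizes, seq_along(sizes))
  remap <- integer(length(sizes))
  remap[ord] <- seq_along(ord)
  list(labels = remap[labels], centroids = centroids[ord, , drop = FALSE])
}

#' Leave-one-out fiber probabilities
#'
#' For each fiber, the mean Gaussian-kernel affinity to the other fibers
#' of its cluster, excluding either the fiber itself
#' (`leave_one_out = "fiber"`) or every fiber from the same subject
#' (`"subject"`, the form used during atlas construction).  A fiber with
#' nothing left to compare against after exclusion gets probability 0 and
#' is flagged.
#'
#' @param fibers fiber list or flattened fiber matrix.
#' @param labels integer cluster labels, one per fiber.
#' @param subjects character subject tags, one per fiber.
#' @param sigma Gaussian kernel width in mm.
#' @param leave_one_out `"fiber"` or `"subject"`.
#' @param config a [distance_config] (bilateral etc.).
#' @return Numeric vector of probabilities in \[0, 1\] with logical
#'   attribute `"isolated"` marking fibers left without comparators.
#' @export
fiber_probabilities <- function(fibers, labels, subjects, sigma,
                                leave_one_out = c("subject", "fiber"),
                                config = distance_config()) {
  leave_one_out <- match.arg(leave_one_out)
  flat <- if (is.matrix(fibers)) fibers else flatten_fibers(fibers, config$n_points)
  stopifnot(length(labels) == nrow(flat), length(subjects) == nrow(flat))
  p <- numeric(nrow(flat))
  isolated <- logical(nrow(flat))
  for (cl in unique(labels)) {
    ii <- which(labels == cl)
    D <- fiber_distance_matrix(flat[ii, , drop = FALSE], flat[ii, , drop = FALSE], config)
    aff <- affinity(D, sigma)
    excl <- if (leave_one_out == "fiber") diag(length(ii)) == 1
            else outer(subjects[ii], subjects[ii], "==")
    aff[excl] <- NA_real_
    n_ok <- rowSums(!excl)
    pi_ <- rowMeans(aff, na.rm = TRUE)
    pi_[n_ok == 0L] <- 0
    isolated[ii] <- n_ok == 0L
    p[ii] <- pi_
  }
  structure(p, isolated = isolated)
}

#' Reject low-probability outlier fibers
#'
#' Per cluster, computes the mean and standard deviation of the member
#' fiber probabilities (before any rejection) and rejects fibers whose
#' probability falls more than `threshold_sd` standard deviations below
#' the cluster mean.
#'
#' @param labels integer cluster labels.
#' @param probabilities per-fiber probabilities from
#'   [fiber_probabilities()].
#' @param threshold_sd rejection threshold (default 2).
#' @return List with logical `kept`, and `stats`: a data.frame of
#'   per-cluster `cluster`, `mu`, `sd`, `n` (computed before rejection).
#' @export
reject_outliers <- function(labels, probabilities, threshold_sd = 2) {
  clusters <- sort(unique(labels))
  mu <- s <- n <- numeric(length(clusters))
  kept <- rep(TRUE, length(labels))
  for (ci in seq_along(clusters)) {
    ii <- which(labels == clusters[ci])
    mu[ci] <- mean(probabilities[ii])
    s[ci] <- if (length(ii) > 1L) sd(probabilities[ii]) else 0
    n[ci] <- length(ii)
    if (is.finite(threshold_sd))
      kept[ii] <- probabilities[ii] >= mu[ci] - threshold_sd * s[ci]
  }
  list(kept = kept,
       stats = data.frame(cluster = clusters, mu = mu, sd = s, n = n))
}
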