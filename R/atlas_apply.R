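#' Apply a fiber-cluster atlas to a new subject
#'
#' Registers the subject's tractography to the atlas frame (affine,
#' entropy objective against the atlas sample fibers), embeds every fiber
#' of at least the atlas minimum length by the Nystrom out-of-sample
#' extension, assigns each to the nearest cluster centroid in embedding
#' space, computes each fiber's probability as its mean affinity to the
#' atlas's kept sample fibers of that cluster, flags outliers falling more
#' than `outlier_threshold_sd` standard deviations below the cluster's
#' stored mean probability, and labels each fiber's hemisphere from its
#' position relative to the midsagittal plane x = 0.
#'
#' A tractogram already tagged `frame = "atlas"` skips registration (the
#' identity transform is recorded).
#'
#' @param atlas a `fiber_atlas` from [build_atlas()] or [load_atlas()].
#' @param subject a [tractogram].
#' @param reg_config a [registration_config] for the subject-to-atlas
#'   affine stage.
#' @return A `cluster_assignment`: list with `fiber_index` (indices into
#'   the subject tractogram of the fibers long enough to assign), integer
#'   `labels`, numeric `probability`, logical `outlier`, character
#'   `hemisphere` (`"left"`, `"right"`, `"commissural"`), the
#'   subject-to-atlas [linear_transform] `transform`, and `k`.
#' @export
assign_subject <- function(atlas, subject, reg_config = registration_config()) {
  stopifnot(inherits(atlas, "fiber_atlas"), inherits(subject, "tractogram"))
  if (!subject$frame %in% c("subject", "atlas"))
    stop("subject tractogram frame must be 'subject' or 'atlas'")
  if (length(subject$fibers) == 0L)
    return(empty_assignment(atlas))
  if (subject$frame == "atlas") {
    transform <- linear_transform(diag(4))
  } else {
    pool <- tractogram(lapply(seq_len(nrow(atlas$basis$sample_flat)), function(i)
      matrix(atlas$basis$sample_flat[i, ], ncol = 3)),
      subject_id = "atlas", frame = "atlas")
    reg_config$min_fiber_length <- min(reg_config$min_fiber_length,
                                       atlas$config$min_fiber_length)
    transform <- register_affine_to_pool(subject, pool, reg_config)
    attr(transform, "trajectory") <- NULL
  }
  lens <- vapply(subject$fibers, fiber_length, numeric(1))
  fiber_index <- which(lens >= atlas$config$min_fiber_length)
  if (length(fiber_index) == 0L) return(empty_assignment(atlas))
  fibers_atlas <- lapply(subject$fibers[fiber_index], function(f)
    transform_points(f, transform))
  flat <- flatten_fibers(fibers_atlas, atlas$basis$n_points)
  coords <- embed_flat(atlas$basis, flat)
  labels <- nearest_centroid(coords, atlas$centroids)

  dconf <- distance_config(n_points = atlas$basis$n_points,
                           bilateral = atlas$basis$bilateral)
  prob <- numeric(length(labels))
  for (cl in unique(labels)) {
    rep_rows <- which(atlas$sample_labels == cl)
    ii <- which(labels == cl)
    if (length(rep_rows) == 0L) { prob[ii] <- 0; next }
    D <- fiber_distance_matrix(flat[ii, , drop = FALSE],
                               atlas$basis$sample_flat[rep_rows, , drop = FALSE], dconf)
    prob[ii] <- rowMeans(affinity(D, atlas$basis$sigma))
  }
  st <- atlas$cluster_stats
  mu <- st$mu[match(labels, st$cluster)]
  sdv <- st$sd[match(labels, st$cluster)]
  thr <- atlas$config$outlier_threshold_sd
  outlier <- is.na(mu) | prob < (mu - thr * sdv)

  assignment <- structure(list(fiber_index = fiber_index,
                               labels = labels,
                               probability = prob,
                               outlier = outlier,
                               hemisphere = rep(NA_character_, length(labels)),
                               transform = transform,
                               k = nrow(atlas$centroids)),
                          class = "cluster_assignment")
  split_hemisphere(assignment, fibers_atlas)
}

empty_assignment <- function(atlas) {
  structure(list(fiber_index = integer(0), labels = integer(0),
                 probability = numeric(0), outlier = logical(0),
                 hemisphere = character(0),
                 transform = linear_transform(diag(4)),
                 k = nrow(atlas$centroids)),
            class = "cluster_assignment")
}

nearest_centroid <- function(coords, centroids) {
  # squared Euclidean distances to each centroid via the expansion trick
  cross <- coords %*% t(centroids)
  d2 <- outer(rowSums(coords^2), rowSums(centroids^2), "+") - 2 * cross
  max.col(-d2, ties.method = "first")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d fibers, %d clusters, %d outliers (L/R/comm: %d/%d/%d)\n",
              length(x$labels), x$k, sum(x$outlier),
              sum(x$hemisphere == "left", na.rm = TRUE),
              sum(x$hemisphere == "right", na.rm = TRUE),
              sum(x$hemisphere == "commissural", na.rm = TRUE)))
  invisible(x)
}

#' Hemisphere labels from midsagittal position
#'
#' A fiber is `"left"` if at least `threshold` of its points lie at x < 0
#' in the atlas frame, `"right"` if at least `threshold` lie at x > 0,
#' otherwise `"commissural"`.
#'
#' @param assignment a `cluster_assignment`.
#' @param fibers_atlas the assigned fibers in the atlas frame (list of
#'   n x 3 matrices, in `assignment$fiber_index` order).
#' @param threshold fraction of points required on one side (default 0.8).
#' @return The assignment with `hemisphere` filled in.
#' @export
split_hemisphere <- function(assignment, fibers_atlas, threshold = 0.8) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            length(fibers_atlas) == length(assignment$labels))
  hemi <- vapply(fibers_atlas, function(f) {
    fl <- mean(f[, 1] < 0)
    fr <- mean(f[, 1] > 0)
    if (fl >= threshold) "left" else if (fr >= threshold) "right" else "commissural"
  }, character(1))
  assignment$hemisphere <- hemi
  assignment
}

#' Per-cluster presence in an assignment
#'
#' A cluster counts as present when at least `min_fibers` non-outlier
#' fibers are assigned to it (in either hemisphere).
#'
#' @param assignment a `cluster_assignment`.
#' @param k number of atlas clusters (defaults to `assignment$k`).
#' @param min_fibers minimum non-outlier fiber count (default 1).
#' @return Logical vector of length `k`.
#' @export
cluster_presence <- function(assignment, k = assignment$k, min_fibers = 1L) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  tabulate(assignment$labels[!assignment$outlier], nbins = k) >= min_fibers
}

#' Extract a named tract from an assigned subject
#'
#' Collects the non-outlier fibers whose cluster belongs to the hierarchy
#' node's transitive leaf set, optionally restricted to one hemisphere,
#' and returns them either in the subject's native frame or mapped into
#' the atlas frame via the stored subject-to-atlas transform.
#'
#' @param assignment a `cluster_assignment` from [assign_subject()].
#' @param subject the subject [tractogram] the assignment was made on.
#' @param hierarchy a [hierarchy] (e.g. `atlas$hierarchy`).
#' @param node hierarchy node name.
#' @param hemisphere optional `"left"`, `"right"` or `"commissural"`.
#' @param frame `"subject"` (native coordinates) or `"atlas"`.
#' @return A [tractogram] of the selected fibers.
#' @export
select_tract <- function(assignment, subject, hierarchy, node,
                         hemisphere = NULL, frame = c("subject", "atlas")) {
  frame <- match.arg(frame)
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(subject, "tractogram"))
  clusters <- hierarchy_clusters(hierarchy, node)
  sel <- !assignment$outlier & assignment$labels %in% clusters
  if (!is.null(hemisphere))
    sel <- sel & assignment$hemisphere == hemisphere
  fibers <- subject$fibers[assignment$fiber_index[sel]]
  if (frame == "atlas")
    fibers <- lapply(fibers, transform_points, assignment$transform)
  tractogram(fibers, subject_id = subject$subject_id, frame = frame)
}
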