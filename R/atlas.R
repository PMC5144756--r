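#' Build a fiber-cluster atlas from registered tractography
#'
#' The atlas-construction core: per-subject seeded sampling of
#' length-thresholded fibers, Nystrom spectral embedding of the pooled
#' fibers, k-means clustering in embedding space, then
#' `config$outlier_rounds` iterations of subject-level leave-one-out fiber
#' probabilities, rejection of fibers more than
#' `config$outlier_threshold_sd` standard deviations below their cluster's
#' mean probability, and re-embedding/re-clustering of the survivors
#' (reusing the same Nystrom sample minus its rejected members).  The
#' returned atlas holds the final embedding basis, cluster centroids,
#' per-cluster probability statistics, per-subject cluster presence and an
#' optional anatomical hierarchy.
#'
#' @param subjects list of [tractogram]s already in the atlas (groupwise)
#'   frame.
#' @param config a [cluster_config].
#' @param hierarchy optional [hierarchy] of named tracts.
#' @return An object of class `fiber_atlas`.
#' @export
build_atlas <- function(subjects, config = cluster_config(), hierarchy = NULL) {
  set.seed(config$seed)
  fibers <- list()
  subj_tags <- character(0)
  for (tg in subjects) {
    keep <- vapply(tg$fibers, fiber_length, numeric(1)) >= config$min_fiber_length
    fs <- tg$fibers[keep]
    if (length(fs) > config$fibers_per_subject)
      fs <- fs[sort(sample.int(length(fs), config$fibers_per_subject))]
    fibers <- c(fibers, fs)
    subj_tags <- c(subj_tags, rep(tg$subject_id, length(fs)))
  }
  if (length(fibers) < max(config$k, config$nystrom_m))
    stop("pooled fiber count (", length(fibers),
         ") is below max(k, nystrom_m); reduce k/nystrom_m or supply more fibers")
  flat <- flatten_fibers(fibers, config$n_points)
  dconf <- distance_config(n_points = config$n_points, bilateral = config$bilateral)

  set.seed(config$seed)
  sample_idx <- sort(sample.int(nrow(flat), config$nystrom_m))
  basis <- basis_from_samples(flat[sample_idx, , drop = FALSE], flat, config)
  coords <- embed_flat(basis, flat)
  km <- kmeans_embed(coords, config$k, seed = config$seed)
  labels <- km$labels

  kept <- rep(TRUE, nrow(flat))
  for (round_i in seq_len(config$outlier_rounds)) {
    idx <- which(kept)
    p <- fiber_probabilities(flat[idx, , drop = FALSE], labels[idx], subj_tags[idx],
                             config$sigma_cluster, leave_one_out = "subject",
                             config = dconf)
    rej <- reject_outliers(labels[idx], p, config$outlier_threshold_sd)
    kept[idx[!rej$kept]] <- FALSE
    sample_idx <- sample_idx[kept[sample_idx]]
    basis <- basis_from_samples(flat[sample_idx, , drop = FALSE],
                                flat[kept, , drop = FALSE], config)
    coords_kept <- embed_flat(basis, flat[kept, , drop = FALSE])
    km <- kmeans_embed(coords_kept, config$k, seed = config$seed)
    labels <- integer(nrow(flat))
    labels[kept] <- km$labels
  }

  idx <- which(kept)
  p_final <- fiber_probabilities(flat[idx, , drop = FALSE], labels[idx], subj_tags[idx],
                                 config$sigma_cluster, leave_one_out = "subject",
                                 config = dconf)
  stats <- reject_outliers(labels[idx], p_final, Inf)$stats

  sample_labels <- labels[sample_idx]
  presence <- vapply(sort(unique(subj_tags)), function(sid) {
    tab <- tabulate(labels[kept & subj_tags == sid], nbins = config$k)
    tab >= 1L
  }, logical(config$k))

  structure(list(basis = basis,
                 centroids = km$centroids,
                 cluster_stats = stats,
                 sample_labels = sample_labels,
                 presence = presence,
                 kept = kept,
                 labels = labels,
                 subject_tags = subj_tags,
                 config = config,
                 hierarchy = hierarchy),
            class = "fiber_atlas")
}

# construct an embedding basis from a given (already flattened) sample and
# reference pool; fit_embedding_basis draws the sample then delegates here
basis_from_samples <- function(flat_s, flat_all, config) {
  dconf <- distance_config(n_points = config$n_points, bilateral = config$bilateral)
  A <- affinity(fiber_distance_matrix(flat_s, flat_s, dconf), config$sigma_cluster)
  C <- affinity(fiber_distance_matrix(flat_s, flat_all, dconf), config$sigma_cluster)
  deg <- rowMeans(C)
  scaled <- A / sqrt(outer(deg, deg))
  scaled <- (scaled + t(scaled)) / 2
  es <- eigen(scaled, symmetric = TRUE)
  p <- min(config$n_eigenvectors, nrow(flat_s))
  structure(list(sample_flat = flat_s,
                 sigma = config$sigma_cluster,
                 bilateral = config$bilateral,
                 n_points = config$n_points,
                 eigvecs = es$vectors[, seq_len(p), drop = FALSE],
                 eigvals = es$values[seq_len(p)],
                 degrees = deg,
                 sample_index = NA_integer_),
            class = "embedding_basis")
}

#' @export
print.fiber_atlas <- function(x, ...) {
  cat(sprintf("fiber_atlas: %d clusters, %d sample fibers, %d training subjects\n",
              nrow(x$centroids), nrow(x$basis$sample_flat), ncol(x$presence)))
  invisible(x)
}

## ---- anatomical hierarchy ----

#' Anatomical hierarchy of named tracts
#'
#' A tree of named nodes; leaves carry lists of atlas cluster indices
#' (1-based), inner nodes carry children.  A cluster may appear under
#' several nodes.  Serialized as JSON:
#' `{"name": ..., "children": [...]}` or `{"name": ..., "clusters": [...]}`.
#'
#' @param name node name (e.g. `"CST"`).
#' @param children list of child [hierarchy] nodes.
#' @param clusters integer cluster indices for a leaf node.
#' @return A `hierarchy` node.
#' @export
hierarchy <- function(name, children = NULL, clusters = NULL) {
  if (is.null(children) == is.null(clusters))
    stop("a hierarchy node has either children or clusters")
  node <- list(name = as.character(name))
  if (!is.null(children)) node$children <- children
  if (!is.null(clusters)) node$clusters <- as.integer(clusters)
  structure(node, class = "hierarchy")
}

#' @rdname hierarchy
#' @param path JSON file.
#' @export
read_hierarchy <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  as_hierarchy_node(obj)
}

as_hierarchy_node <- function(obj) {
  if (is.null(obj$name)) stop("hierarchy JSON is missing required field 'name'")
  if (!is.null(obj$children))
    hierarchy(as.character(obj$name),
              children = lapply(obj$children, as_hierarchy_node))
  else if (!is.null(obj$clusters))
    hierarchy(as.character(obj$name), clusters = unlist(obj$clusters))
  else stop("hierarchy node '", obj$name, "' has neither children nor clusters")
}

#' @rdname hierarchy
#' @param h a [hierarchy].
#' @export
write_hierarchy <- function(h, path) {
  jsonlite::write_json(unclass_hierarchy(h), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

unclass_hierarchy <- function(h) {
  out <- list(name = h$name)
  if (!is.null(h$children)) out$children <- lapply(h$children, unclass_hierarchy)
  if (!is.null(h$clusters)) out$clusters <- as.integer(h$clusters)
  out
}

hierarchy_node_names <- function(h) {
  c(h$name, if (!is.null(h$children)) unlist(lapply(h$children, hierarchy_node_names)))
}

#' Clusters under a hierarchy node
#'
#' The transitive union of cluster indices below the named node.
#'
#' @param h a [hierarchy].
#' @param node node name.
#' @return Sorted unique integer cluster indices.
#' @export
hierarchy_clusters <- function(h, node) {
  found <- find_node(h, node)
  if (is.null(found))
    stop("unknown hierarchy node '", node, "'; available: ",
         paste(hierarchy_node_names(h), collapse = ", "))
  sort(unique(collect_clusters(found)))
}

find_node <- function(h, node) {
  if (identical(h$name, node)) return(h)
  for (ch in h$children) {
    f <- find_node(ch, node)
    if (!is.null(f)) return(f)
  }
  NULL
}

collect_clusters <- function(h) {
  c(h$clusters, unlist(lapply(h$children, collect_clusters)))
}

## ---- atlas persistence ----

#' Save or load a fiber atlas
#'
#' The atlas directory holds the Nystrom sample fibers as VTK polydata
#' (with their cluster labels as the `ClusterId` cell array) and all
#' numeric blocks, configuration, cluster statistics and the hierarchy as
#' full-precision JSON.  Roundtrips are lossless.
#'
#' @param atlas a `fiber_atlas`.
#' @param dir directory to create/read.
#' @return `load_atlas()` returns the `fiber_atlas`; `save_atlas()` the
#'   directory, invisibly.
#' @export
save_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "fiber_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  np <- atlas$config$n_points
  sample_fibers <- lapply(seq_len(nrow(atlas$basis$sample_flat)), function(i)
    matrix(atlas$basis$sample_flat[i, ], ncol = 3))
  write_tractogram(tractogram(sample_fibers, "atlas_samples", frame = "atlas"),
                   file.path(dir, "sample_fibers.vtk"), format = "vtk",
                   labels = atlas$sample_labels)
  obj <- list(config = unclass(atlas$config),
              centroids = atlas$centroids,
              eigvecs = atlas$basis$eigvecs,
              eigvals = atlas$basis$eigvals,
              degrees = atlas$basis$degrees,
              sigma = atlas$basis$sigma,
              bilateral = atlas$basis$bilateral,
              n_points = atlas$basis$n_points,
              cluster_stats = atlas$cluster_stats,
              sample_labels = atlas$sample_labels,
              presence = atlas$presence,
              hierarchy = if (!is.null(atlas$hierarchy)) unclass_hierarchy(atlas$hierarchy))
  jsonlite::write_json(obj, file.path(dir, "atlas.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_atlas
#' @export
load_atlas <- function(dir) {
  fj <- file.path(dir, "atlas.json")
  ff <- file.path(dir, "sample_fibers.vtk")
  for (f in c(fj, ff))
    if (!file.exists(f)) stop("atlas directory is missing component file '", basename(f), "'")
  obj <- jsonlite::read_json(fj, simplifyVector = TRUE)
  # hierarchy nesting must not be simplified into data.frames
  raw <- jsonlite::read_json(fj, simplifyVector = FALSE)
  obj$hierarchy <- raw$hierarchy
  cfg <- do.call(cluster_config, obj$config[setdiff(names(obj$config), character(0))])
  tg <- suppressWarnings(read_tractogram(ff, format = "vtk"))
  # sample fibers were saved already resampled: take their points as-is
  # (re-resampling would redistribute points along curved polylines)
  flat_s <- t(vapply(tg$fibers, function(f) as.numeric(f),
                     numeric(3L * as.integer(obj$n_points))))
  basis <- structure(list(sample_flat = flat_s,
                          sigma = obj$sigma,
                          bilateral = obj$bilateral,
                          n_points = as.integer(obj$n_points),
                          eigvecs = as_num_matrix(obj$eigvecs),
                          eigvals = as.numeric(obj$eigvals),
                          degrees = as.numeric(obj$degrees),
                          sample_index = NA_integer_),
                     class = "embedding_basis")
  structure(list(basis = basis,
                 centroids = as_num_matrix(obj$centroids),
                 cluster_stats = as.data.frame(obj$cluster_stats),
                 sample_labels = as.integer(obj$sample_labels),
                 presence = as_logical_matrix(obj$presence),
                 kept = NULL, labels = NULL, subject_tags = NULL,
                 config = cfg,
                 hierarchy = if (!is.null(obj$hierarchy)) as_hierarchy_node(obj$hierarchy)),
            class = "fiber_atlas")
}

as_num_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

as_logical_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "logical"
  m
}
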