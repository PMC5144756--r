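#' Signed Euclidean distance volume of a binary mask
#'
#' For every voxel centre, the Euclidean distance in mm (anisotropic voxel
#' sizes honoured) to the nearest voxel centre of the opposite class:
#' positive outside the mask, negative inside.  Computed with an exact
#' separable distance transform.
#'
#' @param mask a [volume_mask] with at least one foreground voxel.
#' @return A `signed_distance_volume`: list with `values` (3-D array, mm)
#'   and `voxel_to_world`.
#' @export
signed_distance_volume <- function(mask) {
  stopifnot(inherits(mask, "volume_mask"))
  fg <- mask$data > 0
  if (!any(fg)) stop("mask has no foreground voxels")
  spacing <- mask_spacing(mask)
  dims <- dim(mask$data)
  d_out <- sqrt(.edt_sq(as.numeric(fg), as.integer(dims), as.numeric(spacing)))
  vals <- array(d_out, dims)
  if (any(!fg)) {
    d_in <- sqrt(.edt_sq(as.numeric(!fg), as.integer(dims), as.numeric(spacing)))
    vals[fg] <- -array(d_in, dims)[fg]
  } else {
    vals[fg] <- -Inf # no background anywhere: depth is unbounded
  }
  structure(list(values = vals, voxel_to_world = mask$voxel_to_world),
            class = "signed_distance_volume")
}

#' @export
print.signed_distance_volume <- function(x, ...) {
  cat(sprintf("signed_distance_volume: %s voxels, range [%.2f, %.2f] mm\n",
              paste(dim(x$values), collapse = "x"), min(x$values), max(x$values)))
  invisible(x)
}

# trilinear interpolation of a 3-D array at 0-based voxel coordinates;
# returns NA for coordinates outside the voxel-centre lattice
trilinear <- function(vol, vox) {
  dims <- dim(vol)
  out <- rep(NA_real_, nrow(vox))
  inside <- vox[, 1] >= 0 & vox[, 1] <= dims[1] - 1 &
            vox[, 2] >= 0 & vox[, 2] <= dims[2] - 1 &
            vox[, 3] >= 0 & vox[, 3] <= dims[3] - 1
  if (!any(inside)) return(out)
  v <- vox[inside, , drop = FALSE]
  l <- pmin(floor(v), matrix(rep(dims - 2, each = nrow(v)), ncol = 3))
  l <- pmax(l, 0)
  u <- v - l
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * u[, 1] + (1 - dx) * (1 - u[, 1])) *
         (dy * u[, 2] + (1 - dy) * (1 - u[, 2])) *
         (dz * u[, 3] + (1 - dz) * (1 - u[, 3]))
    idx <- cbind(l[, 1] + dx + 1, l[, 2] + dy + 1, l[, 3] + dz + 1)
    acc <- acc + w * vol[idx]
  }
  out[inside] <- acc
  out
}

#' Minimum signed distance from a tract to an activation
#'
#' Fibers are resampled to at most `step` mm spacing, each point's signed
#' distance is trilinearly interpolated from the volume, and the minimum
#' over all points of all fibers is returned.  A negative minimum means
#' the tract enters the activation (its magnitude is the maximum depth);
#' a positive minimum is the closest-approach gap.  Points outside the
#' volume contribute their positive distance to the volume bounds plus
#' the boundary value, and set the `clamped` flag.
#'
#' @param tract a non-empty [tractogram] in the same world frame as the
#'   volume.
#' @param sdv a `signed_distance_volume`.
#' @param tract_name,activation_name labels carried into the result.
#' @param step maximum sampling step along fibers, mm (default 1).
#' @return A `tract_eval_result`: list with `tract`, `activation`,
#'   `min_signed_distance` (mm), `intersects` (distance <= 0; boundary
#'   contact counts) and `clamped`.
#' @export
tract_min_signed_distance <- function(tract, sdv, tract_name = tract$subject_id,
                                      activation_name = "activation", step = 1) {
  stopifnot(inherits(tract, "tractogram"), inherits(sdv, "signed_distance_volume"))
  if (length(tract$fibers) == 0L) stop("tract is empty")
  inv <- solve(sdv$voxel_to_world)
  dims <- dim(sdv$values)
  spacing <- sqrt(colSums(sdv$voxel_to_world[1:3, 1:3]^2))
  best <- Inf
  clamped <- FALSE
  for (f in tract$fibers) {
    n <- max(2L, ceiling(fiber_length(f) / step) + 1L)
    pts <- resample_fiber(f, n)
    vox <- cbind(pts, 1) %*% t(inv)
    vox <- vox[, 1:3, drop = FALSE]
    vals <- trilinear(sdv$values, vox)
    out <- is.na(vals)
    if (any(out)) {
      clamped <- TRUE
      cl <- pmin(pmax(vox[out, , drop = FALSE], 0),
                 matrix(rep(dims - 1, each = sum(out)), ncol = 3))
      gap <- sqrt(rowSums((sweep(vox[out, , drop = FALSE] - cl, 2, spacing, "*"))^2))
      vals[out] <- pmax(trilinear(sdv$values, cl), 0) + gap
    }
    best <- min(best, vals)
  }
  structure(list(tract = tract_name, activation = activation_name,
                 min_signed_distance = best, intersects = best <= 0,
                 clamped = clamped),
            class = "tract_eval_result")
}

#' @export
print.tract_eval_result <- function(x, ...) {
  cat(sprintf("%s vs %s: min signed distance %.2f mm (%s)\n", x$tract, x$activation,
              x$min_signed_distance, if (x$intersects) "intersects" else "no overlap"))
  invisible(x)
}

#' Intersection summary over groups of activations
#'
#' Counts, per group (e.g. functional region x hemisphere), how many
#' activations are intersected by their related tract, in the X-of-Y form
#' used to summarise tract-fMRI colocalization, plus the totals over all
#' groups.
#'
#' @param group character/factor group tag per activation.
#' @param intersects logical per activation.
#' @return A data.frame with columns `group`, `x` (intersected), `y`
#'   (total), with attributes `total_x`, `total_y`; zero rows (with the
#'   totals 0/0 and attribute `empty = TRUE`) for empty input.
#' @export
intersection_summary <- function(group, intersects) {
  stopifnot(length(group) == length(intersects))
  if (length(group) == 0L) {
    out <- data.frame(group = character(0), x = integer(0), y = integer(0))
    attr(out, "total_x") <- 0L
    attr(out, "total_y") <- 0L
    attr(out, "empty") <- TRUE
    return(out)
  }
  group <- as.character(group)
  ug <- unique(group)
  x <- vapply(ug, function(g) sum(intersects[group == g]), integer(1))
  y <- vapply(ug, function(g) sum(group == g), integer(1))
  out <- data.frame(group = ug, x = as.integer(x), y = as.integer(y),
                    row.names = NULL)
  attr(out, "total_x") <- sum(out$x)
  attr(out, "total_y") <- sum(out$y)
  out
}

#' Cluster consistency across subjects
#'
#' Given one per-cluster presence vector per subject, reports how many
#' clusters are detected in all n subjects, in at least n-1 and in at
#' least n-2, as counts and integer percentages of the cluster count.
#'
#' @param presence logical k x n matrix (clusters x subjects), or a list
#'   of n logical vectors of equal length.
#' @return A `consistency_report`: list with the presence `matrix`,
#'   `n_subjects`, `k`, and data.frame `summary` with columns
#'   `min_subjects`, `count`, `percent`.
#' @export
consistency_summary <- function(presence) {
  if (is.list(presence)) {
    k <- unique(lengths(presence))
    if (length(k) != 1L) stop("presence vectors differ in cluster count")
    presence <- do.call(cbind, presence)
  }
  presence <- as.matrix(presence)
  storage.mode(presence) <- "logical"
  n <- ncol(presence)
  k <- nrow(presence)
  detected_in <- rowSums(presence)
  bins <- unique(pmax(c(n, n - 1L, n - 2L), 0L))
  counts <- vapply(bins, function(b) sum(detected_in >= b), integer(1))
  structure(list(matrix = presence, n_subjects = n, k = k,
                 summary = data.frame(min_subjects = bins,
                                      count = counts,
                                      percent = as.integer(round(100 * counts / k)))),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("consistency over %d subjects, %d clusters:\n", x$n_subjects, x$k))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  detected in >= %d subjects: %d (%d%%)\n",
                x$summary$min_subjects[i], x$summary$count[i], x$summary$percent[i]))
  invisible(x)
}

#' Tract volume by voxel counting
#'
#' Fibers are resampled to at most half the voxel size, points are binned
#' on a regular grid of the given voxel size over the tract bounding box,
#' and the volume is the count of occupied voxels times the voxel volume,
#' in cubic centimetres.
#'
#' @param tract a [tractogram].
#' @param voxel_size grid edge length in mm (default 2, the patient-data
#'   scale).
#' @return Volume in cc (0 for an empty tract).
#' @export
tract_volume <- function(tract, voxel_size = 2) {
  stopifnot(inherits(tract, "tractogram"))
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  if (length(tract$fibers) == 0L) return(0)
  pts <- do.call(rbind, lapply(tract$fibers, function(f) {
    n <- max(2L, ceiling(fiber_length(f) / (voxel_size / 2)) + 1L)
    resample_fiber(f, n)
  }))
  lo <- apply(pts, 2, min)
  vox <- floor(sweep(sweep(pts, 2, lo), 2, voxel_size, "/"))
  n_occ <- nrow(unique(vox))
  n_occ * voxel_size^3 / 1000
}
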