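#' Synthetic bundle specification
#'
#' Describes one fiber bundle by its centerline family and spread.
#' `"straight"` is a straight segment; `"arc"` a circular arc (a
#' corticospinal-like gentle curve); `"c_shape"` a 180-degree arc (an
#' arcuate-like C).  The centerline is placed at `center`, rotated by
#' `orient` (Euler angles, degrees), and fibers are drawn around it with
#' smooth Gaussian radial offsets of scale `dispersion`.
#'
#' @param type `"straight"`, `"arc"` or `"c_shape"`.
#' @param length centerline arc length in mm.
#' @param n_fibers fibers in the bundle.
#' @param dispersion radial spread in mm (>= 0).
#' @param center length-3 world position of the bundle centre.
#' @param orient Euler rotation angles (degrees) about x, y, z.
#' @param radius arc radius in mm (arc and c_shape types).
#' @param seed integer seed.
#' @return A `bundle_spec` list.
#' @export
bundle_spec <- function(type = c("straight", "arc", "c_shape"), length = 80,
                        n_fibers = 50L, dispersion = 2, center = c(0, 0, 0),
                        orient = c(0, 0, 0), radius = length / pi, seed = 1L) {
  type <- match.arg(type)
  if (length <= 0) stop("bundle length must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (n_fibers < 1L) stop("n_fibers must be >= 1")
  structure(list(type = type, length = as.numeric(length),
                 n_fibers = as.integer(n_fibers), dispersion = as.numeric(dispersion),
                 center = as.numeric(center), orient = as.numeric(orient),
                 radius = as.numeric(radius), seed = as.integer(seed)),
            class = "bundle_spec")
}

bundle_centerline <- function(spec, n = 30L) {
  t_ <- seq(0, 1, length.out = n)
  base <- switch(spec$type,
    straight = cbind(0, 0, (t_ - 0.5) * spec$length),
    arc = {
      ang <- spec$length / spec$radius         # subtended angle
      a <- (t_ - 0.5) * ang
      cbind(0, spec$radius * sin(a), spec$radius * (cos(a) - 1))
    },
    c_shape = {
      a <- pi * t_                              # half-turn C
      r <- spec$length / pi
      cbind(0, r * cos(a), r * sin(a))
    })
  R <- rotation_matrix(spec$orient)
  sweep(base %*% t(R), 2, spec$center, "+")
}

#' Generate one synthetic fiber bundle
#'
#' Fibers are the centerline perturbed by smooth offsets: a few Gaussian
#' control offsets per fiber (scale `dispersion`), spline-interpolated
#' along arc length, so fibers stay parallel-ish and bundle-like.
#' Deterministic per seed.
#'
#' @param spec a [bundle_spec].
#' @param label integer ground-truth label attached to every fiber.
#' @return A [tractogram] with attribute `"labels"`.
#' @export
make_bundle <- function(spec, label = 1L) {
  set.seed(spec$seed)
  cl <- bundle_centerline(spec)
  n <- nrow(cl)
  t_ <- seq(0, 1, length.out = n)
  tk <- seq(0, 1, length.out = 4L) # control knots for the smooth offset
  fibers <- lapply(seq_len(spec$n_fibers), function(i) {
    off <- vapply(1:3, function(j) {
      ctrl <- rnorm(length(tk), 0, spec$dispersion)
      spline(tk, ctrl, xout = t_)$y
    }, numeric(n))
    cl + off
  })
  tg <- tractogram(fibers, subject_id = "bundle", frame = "atlas")
  attr(tg, "labels") <- rep(as.integer(label), spec$n_fibers)
  tg
}

#' Generate a synthetic subject
#'
#' Concatenates the given bundles (each labelled by its position in
#' `specs`); with `bilateral = TRUE` every bundle is mirrored across
#' x = 0 and the mirror shares the original's label.  Outliers —
#' `outlier_fraction` of the resulting fiber count — are smooth random
#' polylines spanning the subject bounding box, labelled -1
#' (plausible-but-wrong fibers present in no consistent structure).
#'
#' @param specs list of [bundle_spec]s.
#' @param bilateral mirror each bundle across the midsagittal plane.
#' @param outlier_fraction fraction in \[0, 1) of fibers that are planted
#'   outliers.
#' @param subject_id subject identifier.
#' @param seed integer seed for the outlier draw.
#' @param bundle_seed integer seed for the bundle fiber draw (defaults to
#'   `seed`; a cohort passes one shared value so all subjects share the
#'   same anatomy while outliers stay subject-specific).
#' @return A [tractogram] (frame `"atlas"`) with attribute `"labels"`.
#' @export
make_subject <- function(specs, bilateral = TRUE, outlier_fraction = 0,
                         subject_id = "synth", seed = 1L, bundle_seed = seed) {
  fibers <- list()
  labels <- integer(0)
  for (b in seq_along(specs)) {
    spec <- specs[[b]]
    spec$seed <- spec$seed + 1000L * bundle_seed + b
    tg <- make_bundle(spec, label = b)
    fibers <- c(fibers, tg$fibers)
    labels <- c(labels, attr(tg, "labels"))
    if (bilateral) { # exact mirrored copy sharing the label
      fibers <- c(fibers, lapply(tg$fibers, reflect_fiber))
      labels <- c(labels, attr(tg, "labels"))
    }
  }
  set.seed(seed)
  n_out <- round(outlier_fraction * length(fibers))
  if (outlier_fraction > 0 && n_out > 0) {
    pts <- do.call(rbind, fibers)
    lo <- apply(pts, 2, min)
    hi <- apply(pts, 2, max)
    mean_len <- mean(vapply(fibers, fiber_length, numeric(1)))
    for (i in seq_len(n_out)) {
      fibers <- c(fibers, list(random_smooth_polyline(lo, hi, mean_len)))
      labels <- c(labels, -1L)
    }
  }
  tg <- tractogram(fibers, subject_id = subject_id, frame = "atlas")
  attr(tg, "labels") <- labels
  tg
}

# smooth random polyline roughly spanning the box: spline through a few
# random control points, scaled toward a target length
random_smooth_polyline <- function(lo, hi, target_len, n = 30L) {
  k <- 4L
  ctrl <- vapply(1:3, function(j) runif(k, lo[j], hi[j]), numeric(k))
  t_ <- seq(0, 1, length.out = n)
  f <- vapply(1:3, function(j) spline(seq(0, 1, length.out = k), ctrl[, j], xout = t_)$y,
              numeric(n))
  f <- matrix(f, ncol = 3)
  len <- fiber_length(f)
  ctr <- colMeans(f)
  # rescale about its centre so outliers have plausible lengths
  sweep(sweep(f, 2, ctr), 2, rep(min(2, max(0.5, target_len / len)), 3), "*") +
    matrix(ctr, n, 3, byrow = TRUE)
}

#' Generate a synthetic multi-subject cohort
#'
#' Every subject shares one template brain (same bundle fiber draw, keyed
#' to the cohort seed), carries its own planted outliers, and is mapped
#' through a random affine jitter (translation, rotation, scale within
#' the given ranges); with zero jitter and no outliers all subjects are
#' identical.  The applied transforms are returned so inverse-recovery
#' can be scored.
#' With `center_jitter = TRUE` (default) the jitters are composed with
#' the inverse of their group average, so the cohort as a whole carries
#' no net transform — the component a groupwise registration cannot
#' identify.
#'
#' @param specs list of [bundle_spec]s shared by all subjects.
#' @param n_subjects number of subjects.
#' @param bilateral,outlier_fraction passed to [make_subject()].
#' @param max_translation,max_rotation per-subject jitter bounds (mm,
#'   degrees).
#' @param scale_range length-2 multiplicative scale range.
#' @param warp_amplitude optional smooth sinusoidal warp amplitude in mm
#'   (0 disables); the warp is applied after the affine.
#' @param center_jitter remove the cohort's net (group-average) transform.
#' @param seed integer seed.
#' @return List with `subjects` (list of [tractogram]s, frame
#'   `"subject"`), `true_transforms` (list of [linear_transform]s mapping
#'   the shared template frame to each subject), and `labels` (list of
#'   ground-truth label vectors).
#' @export
make_cohort <- function(specs, n_subjects = 5L, bilateral = TRUE,
                        outlier_fraction = 0, max_translation = 10,
                        max_rotation = 10, scale_range = c(0.9, 1.1),
                        warp_amplitude = 0, center_jitter = TRUE, seed = 1L) {
  set.seed(seed)
  jitters <- lapply(seq_len(n_subjects), function(i) {
    params <- c(runif(3, -max_translation, max_translation),
                runif(3, -max_rotation, max_rotation),
                log(runif(3, scale_range[1], scale_range[2])),
                0, 0, 0)
    params_to_affine(params)
  })
  if (center_jitter && n_subjects > 1L) {
    # compose a common right factor B = mean(J_i^{-1}) so the centred
    # jitters satisfy mean(A_i^{-1}) = I: a groupwise registration whose
    # average transform is the identity then maps every subject exactly
    # back onto the template frame
    B <- Reduce(`+`, lapply(jitters, function(j) solve(j$matrix))) / n_subjects
    jitters <- lapply(jitters, function(j) linear_transform(j$matrix %*% B))
  }
  subjects <- vector("list", n_subjects)
  labels <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    tg <- make_subject(specs, bilateral = bilateral,
                       outlier_fraction = outlier_fraction,
                       subject_id = sprintf("subj%02d", i), seed = seed + i,
                       bundle_seed = seed)
    labels[[i]] <- attr(tg, "labels")
    tg <- apply_transform(tg, jitters[[i]], frame = "subject")
    if (warp_amplitude > 0) {
      pts <- do.call(rbind, tg$fibers)
      lo <- apply(pts, 2, min)
      hi <- apply(pts, 2, max)
      tg$fibers <- lapply(tg$fibers, function(f)
        f + sinusoidal_warp(f, lo, hi, warp_amplitude))
    }
    subjects[[i]] <- tg
  }
  list(subjects = subjects, true_transforms = jitters, labels = labels)
}

# smooth single-period sinusoidal displacement field over the box
sinusoidal_warp <- function(pts, lo, hi, amplitude) {
  u <- sweep(sweep(pts, 2, lo), 2, pmax(hi - lo, 1e-6), "/")
  amplitude * cbind(sin(pi * u[, 2]) * sin(pi * u[, 3]),
                    sin(pi * u[, 3]) * sin(pi * u[, 1]),
                    sin(pi * u[, 1]) * sin(pi * u[, 2]))
}

#' Simulate a spherical tumor in a subject
#'
#' Fibers with any point within `radius` of `center` are removed
#' (disruption); every remaining fiber point is pushed radially away from
#' the centre by `displacement_scale * exp(-(r/radius)^2)` (mass effect).
#'
#' @param subject a [tractogram].
#' @param center length-3 tumor centre (same frame as the subject).
#' @param radius tumor radius in mm.
#' @param displacement_scale peak radial push in mm.
#' @return The modified [tractogram]; attribute `"tumor_report"` lists
#'   `removed` and `displaced` original fiber indices, and any
#'   ground-truth `"labels"` attribute is subset accordingly.
#' @export
simulate_tumor <- function(subject, center, radius, displacement_scale = 0) {
  stopifnot(inherits(subject, "tractogram"), radius > 0)
  center <- as.numeric(center)
  hit <- vapply(subject$fibers, function(f)
    any(rowSums(sweep(f, 2, center)^2) < radius^2), logical(1))
  kept_idx <- which(!hit)
  fibers <- lapply(subject$fibers[kept_idx], function(f) {
    d <- sweep(f, 2, center)
    r <- sqrt(rowSums(d^2))
    push <- displacement_scale * exp(-(r / radius)^2)
    f + d * (push / pmax(r, 1e-9))
  })
  out <- tractogram(fibers, subject_id = subject$subject_id, frame = subject$frame)
  if (!is.null(attr(subject, "labels")))
    attr(out, "labels") <- attr(subject, "labels")[kept_idx]
  attr(out, "tumor_report") <- list(removed = which(hit),
                                    displaced = kept_idx)
  out
}

#' Spherical activation mask
#'
#' A stand-in for a thresholded fMRI activation: voxels whose centre lies
#' within `radius` of `center` are foreground.  The grid is axis-aligned
#' with its first voxel centre at `origin`.
#'
#' @param center length-3 sphere centre in world mm.
#' @param radius sphere radius in mm.
#' @param grid_shape integer length-3 voxel grid dimensions.
#' @param voxel_size scalar or length-3 voxel edge length in mm.
#' @param origin world position of voxel (0,0,0)'s centre.
#' @return A [volume_mask].
#' @export
make_activation_mask <- function(center, radius, grid_shape = c(32L, 32L, 32L),
                                 voxel_size = 1,
                                 origin = center - (grid_shape - 1) / 2 * voxel_size) {
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3)
  grid_shape <- as.integer(grid_shape)
  center <- as.numeric(center)
  lo <- origin
  hi <- origin + (grid_shape - 1) * voxel_size
  if (any(center - radius < lo - voxel_size / 2) ||
      any(center + radius > hi + voxel_size / 2))
    stop("sphere does not fit inside the mask grid")
  xs <- lo[1] + (seq_len(grid_shape[1]) - 1) * voxel_size[1]
  ys <- lo[2] + (seq_len(grid_shape[2]) - 1) * voxel_size[2]
  zs <- lo[3] + (seq_len(grid_shape[3]) - 1) * voxel_size[3]
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  dz2 <- (zs - center[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  aff <- diag(c(voxel_size, 1))
  aff[1:3, 4] <- origin
  volume_mask(array(d2 <= radius^2, dim = grid_shape), aff)
}

#' Default bilateral test cohort specification
#'
#' Six well-separated bundles per hemisphere at brain scale (an arcuate-
#' like C, corticospinal-like arcs, and straight association-like
#' segments), mirrored about x = 0.  Bundle centres are >= 45 mm apart so
#' that the default 30 mm clustering kernel separates them cleanly.
#'
#' @param n_fibers fibers per bundle (each hemisphere).
#' @param dispersion within-bundle spread in mm.
#' @return List of six [bundle_spec]s, all centred at x > 0 (mirroring
#'   adds the left hemisphere).
#' @export
default_bundle_specs <- function(n_fibers = 25L, dispersion = 2) {
  list(
    bundle_spec("c_shape", length = 110, n_fibers = n_fibers, dispersion = dispersion,
                center = c(35, 0, 20), orient = c(0, 90, 0)),
    bundle_spec("arc", length = 90, n_fibers = n_fibers, dispersion = dispersion,
                center = c(25, 10, -35), orient = c(90, 0, 0), radius = 120),
    bundle_spec("straight", length = 80, n_fibers = n_fibers, dispersion = dispersion,
                center = c(30, -50, 10), orient = c(0, 20, 0)),
    bundle_spec("straight", length = 85, n_fibers = n_fibers, dispersion = dispersion,
                center = c(20, 55, 15), orient = c(90, 0, 0)),
    bundle_spec("arc", length = 95, n_fibers = n_fibers, dispersion = dispersion,
                center = c(45, 5, 60), orient = c(0, 0, 90), radius = 100),
    bundle_spec("c_shape", length = 100, n_fibers = n_fibers, dispersion = dispersion,
                center = c(15, -15, -70), orient = c(0, 0, 0))
  )
}
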