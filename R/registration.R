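#' Registration settings
#'
#' Configuration for entropy-based tractography registration.  Defaults
#' follow the pipeline's standard operating point: 20,000 fibers sampled
#' per subject, a 40 mm minimum fiber length, a multiscale kernel schedule
#' from 20 mm down to 2 mm, and a final 8 x 8 x 8 b-spline control grid.
#'
#' @param sigma_schedule strictly decreasing Gaussian kernel widths (mm),
#'   coarse to fine.
#' @param fibers_per_subject fibers sampled per subject for the objective.
#' @param min_fiber_length minimum fiber length (mm) for registration.
#' @param stages character vector of stages to run, from
#'   `c("affine", "bspline")`.
#' @param max_iterations_per_stage pattern-search sweeps per kernel level.
#' @param bspline_grid final control grid (3 integers, each >= 4).
#' @param bspline_grids coarse-to-fine grid sequence ending at
#'   `bspline_grid`.
#' @param n_points fiber resampling count used inside the objective.
#' @param seed integer seed for the per-run fiber subsample.
#' @return A `registration_config` list.
#' @export
registration_config <- function(sigma_schedule = c(20, 10, 5, 2),
                                fibers_per_subject = 20000L,
                                min_fiber_length = 40,
                                stages = "affine",
                                max_iterations_per_stage = 3L,
                                bspline_grid = c(8L, 8L, 8L),
                                bspline_grids = list(c(4L, 4L, 4L), bspline_grid),
                                n_points = 10L,
                                seed = 1L) {
  if (any(diff(sigma_schedule) >= 0) || any(sigma_schedule <= 0))
    stop("sigma_schedule must be strictly decreasing and positive")
  if (fibers_per_subject < 1L) stop("fibers_per_subject must be >= 1")
  if (!all(stages %in% c("affine", "bspline")))
    stop("stages must be drawn from 'affine', 'bspline'")
  if (any(bspline_grid < 4L)) stop("b-spline grid needs >= 4 control points per axis")
  structure(list(sigma_schedule = as.numeric(sigma_schedule),
                 fibers_per_subject = as.integer(fibers_per_subject),
                 min_fiber_length = as.numeric(min_fiber_length),
                 stages = stages,
                 max_iterations_per_stage = as.integer(max_iterations_per_stage),
                 bspline_grid = as.integer(bspline_grid),
                 bspline_grids = lapply(bspline_grids, as.integer),
                 n_points = as.integer(n_points),
                 seed = as.integer(seed)),
            class = "registration_config")
}

ENTROPY_EPS <- 1e-12

#' Entropy objective for tractography alignment
#'
#' The cost of a set of moving fibers against a pool is
#' `-sum_i log(mean_j exp(-d(f_i, f_j)^2 / sigma^2) + eps)`, the negative
#' log of each moving fiber's mean Gaussian-kernel affinity to the pool.
#' Lower is better; well-aligned fibers sit in dense parts of the pool and
#' have affinity means near 1.  With `exclude_same_subject = TRUE` pool
#' fibers sharing a moving fiber's subject tag are excluded from its mean
#' (the leave-one-out form used in groupwise registration).
#'
#' @param moving a [tractogram] (or list of fibers) being aligned.
#' @param pool a [tractogram] or list of tractograms forming the
#'   reference pool.
#' @param sigma Gaussian kernel width in mm.
#' @param exclude_same_subject drop pool fibers from the moving fiber's own
#'   subject.
#' @param n_points fiber resampling count.
#' @return Scalar cost (finite for eps > 0).
#' @export
entropy_objective <- function(moving, pool, sigma, exclude_same_subject = FALSE,
                              n_points = 10L) {
  mv <- as_tagged_fibers(moving)
  pl <- as_tagged_fibers(pool)
  if (length(mv$fibers) == 0L || length(pl$fibers) == 0L)
    stop("moving and pool fiber sets must be non-empty")
  A <- flatten_fibers(mv$fibers, n_points)
  B <- flatten_fibers(pl$fibers, n_points)
  mask <- if (exclude_same_subject) outer(mv$subjects, pl$subjects, "==") else NULL
  if (!is.null(mask) && any(rowSums(!mask) == 0L))
    stop("pool is empty after same-subject exclusion")
  entropy_cost_flat(A, B, sigma, distance_config(n_points = n_points), mask)
}

# moving/pool normalizer: returns list(fibers, subjects)
as_tagged_fibers <- function(x) {
  if (inherits(x, "tractogram"))
    return(list(fibers = x$fibers, subjects = rep(x$subject_id, length(x$fibers))))
  if (is.list(x) && length(x) && inherits(x[[1]], "tractogram")) {
    fibers <- do.call(c, lapply(x, `[[`, "fibers"))
    subjects <- unlist(lapply(x, function(tg) rep(tg$subject_id, length(tg$fibers))))
    return(list(fibers = fibers, subjects = subjects))
  }
  list(fibers = x, subjects = rep("", length(x)))
}

entropy_cost_flat <- function(A, B, sigma, dconf, exclude_mask = NULL) {
  D <- fiber_distance_matrix(A, B, dconf)
  aff <- exp(-(D^2) / sigma^2)
  if (!is.null(exclude_mask)) aff[exclude_mask] <- NA_real_
  means <- rowMeans(aff, na.rm = TRUE)
  -sum(log(means + ENTROPY_EPS))
}

## ---- derivative-free optimisation over affine parameter groups ----

# transform flattened fibers (rows [x...|y...|z...]) by a 4x4 affine
transform_flat <- function(A, m) {
  np <- ncol(A) / 3L
  xs <- A[, 1:np, drop = FALSE]
  ys <- A[, np + 1:np, drop = FALSE]
  zs <- A[, 2L * np + 1:np, drop = FALSE]
  cbind(m[1, 1] * xs + m[1, 2] * ys + m[1, 3] * zs + m[1, 4],
        m[2, 1] * xs + m[2, 2] * ys + m[2, 3] * zs + m[2, 4],
        m[3, 1] * xs + m[3, 2] * ys + m[3, 3] * zs + m[3, 4])
}

flat_centroid <- function(A) {
  np <- ncol(A) / 3L
  c(mean(A[, 1:np]), mean(A[, np + 1:np]), mean(A[, 2L * np + 1:np]))
}

# Powell-style per-parameter line search over parameter groups
# (translation, rotation, scale, shear).  Only cost-decreasing steps are
# accepted, so the objective is non-increasing along the trajectory.
optimize_affine_params <- function(cost_fn, params, steps, n_sweeps) {
  groups <- list(1:3, 4:6, 7:9, 10:12)
  cost <- cost_fn(params)
  trajectory <- cost
  for (sweep in seq_len(n_sweeps)) {
    for (g in groups) {
      for (p in g) {
        for (dir in c(1, -1)) {
          repeat {
            cand <- params
            cand[p] <- cand[p] + dir * steps[p]
            cc <- cost_fn(cand)
            if (cc < cost - 1e-12) {
              params <- cand
              cost <- cc
              trajectory <- c(trajectory, cost)
            } else break
          }
        }
      }
    }
    steps <- steps / 2
  }
  list(params = params, cost = cost, trajectory = trajectory)
}

affine_steps <- function(sigma) {
  c(rep(sigma / 2, 3),              # translation, mm
    rep(max(2, sigma / 4), 3),      # rotation, degrees
    rep(0.04, 3),                   # log-scale
    rep(0.04, 3))                   # shear
}

# length-filter then seeded subsample, returned flattened
prepare_flat <- function(tg, config) {
  keep <- vapply(tg$fibers, fiber_length, numeric(1)) >= config$min_fiber_length
  fibers <- tg$fibers[keep]
  if (length(fibers) == 0L)
    stop("no fibers of length >= ", config$min_fiber_length, " mm in subject '",
         tg$subject_id, "'")
  if (length(fibers) > config$fibers_per_subject)
    fibers <- fibers[sample.int(length(fibers), config$fibers_per_subject)]
  flatten_fibers(fibers, config$n_points)
}

#' Affine registration of a subject to a fiber pool
#'
#' Minimises the entropy objective over the multiscale kernel schedule
#' (coarse to fine), optimising translation, rotation, scale and shear
#' parameter groups with a derivative-free per-parameter line search.
#' Rotation/scale/shear act about the moving set's centroid.
#'
#' @param subject moving [tractogram].
#' @param pool reference [tractogram] (e.g. pooled atlas sample fibers).
#' @param config a [registration_config].
#' @return A [linear_transform] mapping subject to pool space, with
#'   attribute `"trajectory"` holding the accepted objective values
#'   (non-increasing).
#' @export
register_affine_to_pool <- function(subject, pool, config = registration_config()) {
  stopifnot(inherits(subject, "tractogram"), inherits(pool, "tractogram"))
  set.seed(config$seed)
  A <- prepare_flat(subject, config)
  B <- prepare_flat(pool, config)
  center <- flat_centroid(A)
  dconf <- distance_config(n_points = config$n_points)
  params <- identity_params()
  trajectory <- list()
  for (sigma in config$sigma_schedule) {
    cost_fn <- function(p) {
      M <- params_to_affine(p, center)$matrix
      entropy_cost_flat(transform_flat(A, M), B, sigma, dconf)
    }
    res <- optimize_affine_params(cost_fn, params, affine_steps(sigma),
                                  config$max_iterations_per_stage)
    params <- res$params
    trajectory[[length(trajectory) + 1L]] <- res$trajectory
  }
  out <- params_to_affine(params, center)
  # one accepted-cost sequence per kernel level, each non-increasing
  attr(out, "trajectory") <- trajectory
  out
}

#' Unbiased groupwise registration of tractography
#'
#' Simultaneous joint alignment of several subjects: per kernel level each
#' subject is registered in turn against the pooled fibers of all other
#' subjects (leave-one-out), and after each sweep every transform is
#' composed with the inverse of the group-average affine, so the group mean
#' transform stays at identity and the common frame does not drift.
#'
#' @param subjects list of [tractogram]s (>= 2).
#' @param config a [registration_config].
#' @return A `transform_set`: list with `subject_ids` and `transforms`
#'   (one [linear_transform] per subject, mapping that subject into the
#'   group frame).
#' @export
register_groupwise <- function(subjects, config = registration_config()) {
  if (length(subjects) < 2L) stop("groupwise registration needs at least 2 subjects")
  set.seed(config$seed)
  flats <- lapply(subjects, prepare_flat, config)
  centers <- lapply(flats, flat_centroid)
  dconf <- distance_config(n_points = config$n_points)
  mats <- rep(list(diag(4)), length(subjects))
  for (sigma in config$sigma_schedule) {
    for (i in seq_along(subjects)) {
      pool <- do.call(rbind, lapply(seq_along(subjects)[-i], function(j)
        transform_flat(flats[[j]], mats[[j]])))
      base <- mats[[i]]
      cost_fn <- function(p) {
        M <- params_to_affine(p, centers[[i]])$matrix %*% base
        entropy_cost_flat(transform_flat(flats[[i]], M), pool, sigma, dconf)
      }
      res <- optimize_affine_params(cost_fn, identity_params(), affine_steps(sigma),
                                    config$max_iterations_per_stage)
      mats[[i]] <- params_to_affine(res$params, centers[[i]])$matrix %*% base
    }
    # remove the group-average transform (unbiasedness: no global drift)
    mbar <- Reduce(`+`, mats) / length(mats)
    mats <- lapply(mats, function(m) solve(mbar) %*% m)
  }
  transform_set(vapply(subjects, `[[`, character(1), "subject_id"),
                lapply(mats, linear_transform))
}

#' @rdname register_groupwise
#' @param subject_ids character vector of subject identifiers.
#' @param transforms list of per-subject transforms (a [linear_transform]
#'   or a list of a linear then a [grid_transform]).
#' @export
transform_set <- function(subject_ids, transforms) {
  if (length(subject_ids) != length(transforms))
    stop("one transform per subject is required")
  structure(list(subject_ids = as.character(subject_ids), transforms = transforms),
            class = "transform_set")
}

#' @export
print.transform_set <- function(x, ...) {
  cat(sprintf("transform_set: %d subjects (%s)\n", length(x$subject_ids),
              paste(head(x$subject_ids, 5), collapse = ", ")))
  invisible(x)
}

#' Groupwise b-spline refinement
#'
#' Refines an affine groupwise solution with a cubic b-spline free-form
#' displacement field over the group bounding box, coarse-to-fine control
#' grids ending at `config$bspline_grid` (default 8 x 8 x 8), using the
#' same entropy objective.  Control-point displacements are bounded by
#' 0.4 x the control spacing as a folding guard.  With
#' `max_iterations_per_stage = 0` the input transforms are returned
#' unchanged.
#'
#' @param subjects list of [tractogram]s in their native frames.
#' @param initial `transform_set` from [register_groupwise()].
#' @param config a [registration_config].
#' @return A `transform_set` whose per-subject transforms are lists
#'   (affine, grid_transform).
#' @export
register_groupwise_bspline <- function(subjects, initial,
                                       config = registration_config(stages = c("affine", "bspline"))) {
  stopifnot(inherits(initial, "transform_set"))
  if (any(unlist(lapply(config$bspline_grids, function(g) any(g < 4L)))))
    stop("b-spline grid needs >= 4 control points per axis")
  if (config$max_iterations_per_stage == 0L) return(initial)
  set.seed(config$seed + 1L)
  flats <- lapply(seq_along(subjects), function(i) {
    m <- initial$transforms[[i]]$matrix
    transform_flat(prepare_flat(subjects[[i]], config), m)
  })
  allpts <- do.call(rbind, lapply(flats, flat_to_points))
  lo <- apply(allpts, 2, min)
  hi <- apply(allpts, 2, max)
  margin <- 0.05 * (hi - lo)
  bounds <- as.numeric(rbind(lo - margin, hi + margin))
  dconf <- distance_config(n_points = config$n_points)
  n_levels <- length(config$bspline_grids)
  sig_idx <- round(seq(1, length(config$sigma_schedule), length.out = n_levels))
  grids <- vector("list", length(subjects))
  for (lev in seq_len(n_levels)) {
    gs <- config$bspline_grids[[lev]]
    sigma <- config$sigma_schedule[sig_idx[lev]]
    spacing <- (bounds[c(2, 4, 6)] - bounds[c(1, 3, 5)]) / (gs - 3)
    bound_disp <- 0.4 * min(spacing)
    grids <- lapply(grids, function(g) upsample_grid(g, gs, bounds))
    for (i in seq_along(subjects)) {
      pool <- do.call(rbind, lapply(seq_along(subjects)[-i], function(j)
        warp_flat(flats[[j]], grids[[j]])))
      grids[[i]] <- optimize_bspline(flats[[i]], pool, grids[[i]], bounds, sigma,
                                     dconf, bound_disp,
                                     config$max_iterations_per_stage)
    }
  }
  transform_set(initial$subject_ids,
                lapply(seq_along(subjects), function(i)
                  list(initial$transforms[[i]], grids[[i]])))
}

flat_to_points <- function(A) {
  np <- ncol(A) / 3L
  cbind(as.numeric(A[, 1:np]), as.numeric(A[, np + 1:np]), as.numeric(A[, 2L * np + 1:np]))
}

points_to_flat <- function(pts, nrow_flat, np) {
  cbind(matrix(pts[, 1], nrow_flat, np), matrix(pts[, 2], nrow_flat, np),
        matrix(pts[, 3], nrow_flat, np))
}

warp_flat <- function(A, grid) {
  if (is.null(grid)) return(A)
  np <- ncol(A) / 3L
  pts <- flat_to_points(A)
  pts <- pts + bspline_displacement(grid, pts)
  points_to_flat(pts, nrow(A), np)
}

# resample an existing displacement grid onto a finer control grid by
# evaluating the field at the new control locations (identity if NULL)
upsample_grid <- function(grid, gs, bounds) {
  zero <- grid_transform(array(0, dim = c(gs, 3L)), bounds)
  if (is.null(grid)) return(zero)
  if (all(grid$grid_shape == gs)) return(grid)
  lo <- bounds[c(1, 3, 5)]
  hi <- bounds[c(2, 4, 6)]
  delta <- (hi - lo) / (gs - 3)
  cp <- as.matrix(expand.grid(x = lo[1] + (seq_len(gs[1]) - 2) * delta[1],
                              y = lo[2] + (seq_len(gs[2]) - 2) * delta[2],
                              z = lo[3] + (seq_len(gs[3]) - 2) * delta[3]))
  disp <- bspline_displacement(grid, cp)
  # control values approximating the field at control locations (the
  # interpolation is then re-smoothed by the b-spline basis; adequate as a
  # warm start for the finer level)
  grid_transform(array(disp, dim = c(gs, 3L)), bounds)
}

optimize_bspline <- function(A, pool, grid, bounds, sigma, dconf, bound_disp, n_sweeps) {
  gs <- grid$grid_shape
  cd <- grid$control_displacements
  pts <- flat_to_points(A)
  np <- ncol(A) / 3L
  # active control points: those whose support touches the moving points
  lo <- bounds[c(1, 3, 5)]
  hi <- bounds[c(2, 4, 6)]
  delta <- (hi - lo) / (gs - 3)
  active <- array(FALSE, dim = gs)
  tt <- sweep(sweep(pts, 2, lo), 2, delta, "/")
  l <- pmin(pmax(floor(tt), 0), matrix(rep(gs - 4, each = nrow(tt)), ncol = 3))
  for (a in 0:3) {
    idx <- unique(l + a) # each row a control index triple (0-based)
    idx <- idx[idx[, 1] >= 0 & idx[, 1] < gs[1] &
               idx[, 2] >= 0 & idx[, 2] < gs[2] &
               idx[, 3] >= 0 & idx[, 3] < gs[3], , drop = FALSE]
    active[cbind(idx[, 1] + 1, idx[, 2] + 1, idx[, 3] + 1)] <- TRUE
  }
  act <- which(active, arr.ind = TRUE)
  cost_of <- function(cdv) {
    g <- grid_transform(cdv, bounds)
    entropy_cost_flat(warp_flat(A, g), pool, sigma, dconf)
  }
  cost <- cost_of(cd)
  # step on the scale of the residual misalignment (kernel width), not of
  # the control spacing, which is far coarser
  step <- min(sigma, 0.2 * min(delta))
  for (sweep_i in seq_len(n_sweeps)) {
    for (r in seq_len(nrow(act))) {
      i <- act[r, 1]; j <- act[r, 2]; k <- act[r, 3]
      for (axis in 1:3) {
        for (dir in c(1, -1)) {
          repeat {
            cand <- cd
            newv <- cand[i, j, k, axis] + dir * step
            if (abs(newv) > bound_disp) break
            cand[i, j, k, axis] <- newv
            cc <- cost_of(cand)
            if (cc < cost - 1e-12) { cd <- cand; cost <- cc } else break
          }
        }
      }
    }
    step <- step / 2
  }
  grid_transform(cd, bounds)
}
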