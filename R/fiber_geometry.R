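#' Distance settings for fiber comparison
#'
#' Controls how two fibers are compared: the number of equal-arclength
#' sample points, the distance variant, and whether the comparison is
#' *bilateral* (a fiber may match either the other fiber or its mirror
#' image across the midsagittal plane x = 0 of the atlas frame, whichever
#' is closer).
#'
#' @param n_points points per fiber after equal-arclength resampling
#'   (default 15; fibers are smooth at the 40-120 mm scale, so a modest
#'   count bounds the pairwise point comparisons).
#' @param mode `"mean_corresponding"`: mean of corresponding-point
#'   distances, minimised over forward/reversed point order (the default —
#'   deterministic and symmetric by construction);
#'   `"mean_closest_point"`: symmetrised mean over each point of its
#'   distance to the closest point of the other fiber.
#' @param bilateral if `TRUE`, the distance is the minimum of the direct
#'   distance and the distance to the mirrored fiber.
#' @return A `distance_config` list.
#' @export
distance_config <- function(n_points = 15L,
                            mode = c("mean_corresponding", "mean_closest_point"),
                            bilateral = FALSE) {
  mode <- match.arg(mode)
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("n_points must be at least 2")
  structure(list(n_points = n_points, mode = mode, bilateral = isTRUE(bilateral)),
            class = "distance_config")
}

#' Fiber arc length
#'
#' Sum of consecutive-point Euclidean distances along the polyline, in mm.
#'
#' @param fiber an n x 3 coordinate matrix.
#' @return Length in millimetres (>= 0).
#' @export
fiber_length <- function(fiber) {
  fiber <- as_fiber(fiber)
  seg <- diff(fiber)
  sum(sqrt(rowSums(seg^2)))
}

#' Resample a fiber to equally spaced points
#'
#' Linear interpolation along cumulative arc length; the two endpoints are
#' preserved exactly.
#'
#' @param fiber an n x 3 coordinate matrix.
#' @param n_points number of output points (>= 2).
#' @return An `n_points` x 3 matrix.
#' @export
resample_fiber <- function(fiber, n_points) {
  fiber <- as_fiber(fiber)
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("n_points must be at least 2")
  s <- c(0, cumsum(sqrt(rowSums(diff(fiber)^2))))
  total <- s[length(s)]
  if (total <= 0) stop("cannot resample a degenerate fiber of zero length")
  # collapse duplicate arc-length knots (repeated points)
  keep <- c(TRUE, diff(s) > 0)
  s <- s[keep]
  fiber <- fiber[keep, , drop = FALSE]
  at <- seq(0, total, length.out = n_points)
  out <- vapply(1:3, function(j) approx(s, fiber[, j], xout = at)$y,
                numeric(n_points))
  matrix(out, ncol = 3L)
}

#' Mirror a fiber across the midsagittal plane
#'
#' Negates the x coordinate (the atlas frame places the midsagittal plane
#' at x = 0); y and z are unchanged.
#'
#' @param fiber an n x 3 coordinate matrix in the atlas frame.
#' @return The reflected fiber.
#' @export
reflect_fiber <- function(fiber) {
  fiber <- as_fiber(fiber)
  fiber[, 1] <- -fiber[, 1]
  fiber
}

#' Pairwise distance between two fibers
#'
#' Both fibers are resampled to `config$n_points` equal-arclength points,
#' then compared according to `config$mode`; with `config$bilateral` the
#' minimum over the direct and mirrored comparison is returned.  The
#' result is symmetric, non-negative and zero for identical fibers (in
#' either point order).
#'
#' @param f1,f2 fibers (n x 3 matrices).
#' @param config a [distance_config].
#' @return Distance in millimetres.
#' @export
fiber_distance <- function(f1, f2, config = distance_config()) {
  A <- flatten_fibers(list(f1), config$n_points)
  B <- flatten_fibers(list(f2), config$n_points)
  fiber_distance_matrix(A, B, config)[1, 1]
}

# Resample each fiber to n_points and stack as rows [x... | y... | z...].
flatten_fibers <- function(fibers, n_points) {
  t(vapply(fibers, function(f) as.numeric(resample_fiber(f, n_points)),
           numeric(3L * n_points)))
}

# All-pairs fiber distances between two flattened sets (rows as produced by
# flatten_fibers).  The computational core behind registration, clustering
# and probabilities.
fiber_distance_matrix <- function(A, B, config = distance_config()) {
  mode <- match(config$mode, c("mean_corresponding", "mean_closest_point")) - 1L
  .pairwise_fiber_dist(A, B, config$bilateral, mode)
}

#' Gaussian kernel affinity
#'
#' Maps a fiber distance through `exp(-d^2 / sigma^2)`: 1 for identical
#' fibers, strictly decreasing in distance.
#'
#' @param distance distance(s) in mm, >= 0.
#' @param sigma kernel width in mm, > 0.
#' @return Affinity value(s) in (0, 1].
#' @export
affinity <- function(distance, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive kernel width in mm")
  exp(-(distance^2) / sigma^2)
}
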