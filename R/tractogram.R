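#' Streamline containers
#'
#' A *fiber* is an ordered 3-D polyline through white matter, stored as an
#' n x 3 numeric matrix of world RAS coordinates in millimetres (n >= 2, all
#' values finite).  A *tractogram* is one subject's fiber set together with a
#' subject identifier and a coordinate-frame tag (`"subject"` for native
#' space, `"atlas"` for the groupwise/atlas space whose midsagittal plane is
#' x = 0).
#'
#' @param fibers list of n x 3 numeric matrices (each a fiber polyline).
#' @param subject_id character scalar identifying the subject.
#' @param frame `"subject"` or `"atlas"`.
#' @return An object of class `tractogram`: a list with elements
#'   `subject_id`, `fibers` and `frame`.
#' @examples
#' tg <- tractogram(list(cbind(0:9, 0, 0)), subject_id = "s1")
#' n_fibers(tg)
#' @export
tractogram <- function(fibers = list(), subject_id = "", frame = c("subject", "atlas")) {
  frame <- match.arg(frame)
  fibers <- lapply(fibers, as_fiber)
  structure(list(subject_id = as.character(subject_id), fibers = fibers, frame = frame),
            class = "tractogram")
}

as_fiber <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("a fiber must be an n x 3 matrix of coordinates")
  if (nrow(x) < 2L) stop("a fiber needs at least 2 points")
  if (!all(is.finite(x))) stop("fiber coordinates must be finite")
  dimnames(x) <- NULL
  x
}

#' @rdname tractogram
#' @param x a `tractogram`.
#' @export
n_fibers <- function(x) {
  stopifnot(inherits(x, "tractogram"))
  length(x$fibers)
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("tractogram: subject '%s', %d fibers, frame '%s'\n",
              x$subject_id, length(x$fibers), x$frame))
  if (length(x$fibers)) {
    npts <- vapply(x$fibers, nrow, integer(1))
    cat(sprintf("  points per fiber: %d-%d\n", min(npts), max(npts)))
  }
  invisible(x)
}

#' Binary volume mask
#'
#' A 3-D binary volume with its voxel-to-world (RAS mm) affine. Voxel
#' indices are 0-based when mapped through the affine.
#'
#' @param data 3-D array; any value > 0 is treated as foreground.
#' @param voxel_to_world 4 x 4 invertible affine mapping 0-based voxel
#'   indices to world RAS millimetres.
#' @return An object of class `volume_mask` with binarized `data`
#'   (values 0/1) and `voxel_to_world`.
#' @export
volume_mask <- function(data, voxel_to_world = diag(4)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("mask data must be a 3-D array")
  voxel_to_world <- as_affine_matrix(voxel_to_world)
  if (abs(det(voxel_to_world)) < .Machine$double.eps)
    stop("voxel_to_world affine must be invertible")
  bin <- array(as.double(data > 0), dim = dim(data))
  structure(list(data = bin, voxel_to_world = voxel_to_world), class = "volume_mask")
}

#' @export
print.volume_mask <- function(x, ...) {
  cat(sprintf("volume_mask: %s voxels, %d foreground, voxel size %s mm\n",
              paste(dim(x$data), collapse = "x"), sum(x$data > 0),
              paste(signif(mask_spacing(x), 4), collapse = "x")))
  invisible(x)
}

# per-axis voxel spacing in mm from the affine column norms
mask_spacing <- function(mask) {
  A <- mask$voxel_to_world[1:3, 1:3]
  sqrt(colSums(A^2))
}

as_affine_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (!all(dim(m) == c(4L, 4L))) stop("affine must be a 4 x 4 matrix")
  m
}

#' Spatial transforms
#'
#' `linear_transform()` wraps a 4 x 4 homogeneous affine (last row must be
#' (0,0,0,1), upper 3 x 3 with positive determinant — orientation
#' preserving).  `grid_transform()` is a cubic b-spline free-form
#' displacement field: a (gx, gy, gz, 3) array of control-point
#' displacements in mm over a world-space bounding box.
#'
#' @param matrix 4 x 4 homogeneous affine matrix.
#' @return A `linear_transform` or `grid_transform` object.
#' @export
linear_transform <- function(matrix = diag(4)) {
  m <- as_affine_matrix(matrix)
  if (!isTRUE(all.equal(m[4, ], c(0, 0, 0, 1), tolerance = 1e-8)))
    stop("last row of an affine must be (0, 0, 0, 1)")
  if (det(m[1:3, 1:3]) <= 0)
    stop("affine must be orientation preserving (det of upper 3x3 > 0)")
  structure(list(matrix = m), class = "linear_transform")
}

#' @rdname linear_transform
#' @param control_displacements (gx, gy, gz, 3) array of control-point
#'   displacements in mm.
#' @param domain_bounds numeric length-6 vector
#'   (xmin, xmax, ymin, ymax, zmin, zmax) in world mm.
#' @export
grid_transform <- function(control_displacements, domain_bounds) {
  d <- as.array(control_displacements)
  if (length(dim(d)) != 4L || dim(d)[4] != 3L)
    stop("control_displacements must be a (gx, gy, gz, 3) array")
  if (any(dim(d)[1:3] < 4L))
    stop("b-spline grid needs at least 4 control points per axis")
  if (!all(is.finite(d))) stop("control displacements must be finite")
  b <- as.double(domain_bounds)
  if (length(b) != 6L || any(b[c(2, 4, 6)] <= b[c(1, 3, 5)]))
    stop("domain_bounds must be (xmin, xmax, ymin, ymax, zmin, zmax) with max > min")
  structure(list(control_displacements = d, grid_shape = dim(d)[1:3],
                 domain_bounds = b), class = "grid_transform")
}

#' @export
print.linear_transform <- function(x, ...) {
  cat("linear_transform (world mm):\n")
  print(signif(x$matrix, 5))
  invisible(x)
}

#' @export
print.grid_transform <- function(x, ...) {
  cat(sprintf("grid_transform: %s control grid, max |displacement| %.3g mm\n",
              paste(x$grid_shape, collapse = "x"),
              max(abs(x$control_displacements))))
  invisible(x)
}
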