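#' Apply a spatial transform to a tractogram
#'
#' Affine transforms map every point through the homogeneous matrix;
#' b-spline grid transforms add the interpolated displacement field
#' (forward application only).  A list of transforms is applied in order.
#'
#' @param tractogram a [tractogram].
#' @param transform a [linear_transform], [grid_transform], or a list of
#'   them applied left to right.
#' @param frame optional frame tag for the result (`"subject"` or
#'   `"atlas"`); defaults to the input frame.
#' @return The transformed [tractogram].
#' @export
apply_transform <- function(tractogram, transform, frame = NULL) {
  stopifnot(inherits(tractogram, "tractogram"))
  transforms <- if (inherits(transform, c("linear_transform", "grid_transform")))
    list(transform) else transform
  fibers <- tractogram$fibers
  for (tr in transforms) fibers <- lapply(fibers, transform_points, tr)
  out <- tractogram
  out$fibers <- fibers
  if (!is.null(frame)) out$frame <- match.arg(frame, c("subject", "atlas"))
  out
}

transform_points <- function(pts, transform) {
  if (inherits(transform, "linear_transform")) {
    out <- cbind(pts, 1) %*% t(transform$matrix)
    out[, 1:3, drop = FALSE]
  } else if (inherits(transform, "grid_transform")) {
    pts + bspline_displacement(transform, pts)
  } else stop("unsupported transform class: ", paste(class(transform), collapse = "/"))
}

#' Invert a linear transform
#'
#' Grid (b-spline) transforms have no closed-form inverse and are refused.
#'
#' @param transform a [linear_transform].
#' @return The inverse [linear_transform].
#' @export
invert_transform <- function(transform) {
  if (inherits(transform, "grid_transform"))
    stop("inverting a grid (b-spline) transform is not supported")
  stopifnot(inherits(transform, "linear_transform"))
  linear_transform(solve(transform$matrix))
}

## ---- affine parameterisation ----
# 12 parameters: translation (mm), rotation about x/y/z (degrees),
# log-scale per axis, shear (xy, xz, yz).  Rotation/scale/shear act about a
# fixed centre so that rotating far-from-origin anatomy does not translate it.

rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

params_to_affine <- function(params, center = c(0, 0, 0)) {
  t3 <- params[1:3]
  R <- rotation_matrix(params[4:6])
  S <- diag(exp(params[7:9]))
  Sh <- diag(3)
  Sh[1, 2] <- params[10]; Sh[1, 3] <- params[11]; Sh[2, 3] <- params[12]
  A <- R %*% Sh %*% S
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- t3 + center - A %*% center
  linear_transform(m)
}

identity_params <- function() numeric(12)

# mean of a list of affines (elementwise on the 4x4 matrices); adequate for
# the near-identity transforms groupwise normalization deals with
mean_affine <- function(transforms) {
  mats <- lapply(transforms, function(tr) tr$matrix)
  linear_transform(Reduce(`+`, mats) / length(mats))
}

## ---- cubic b-spline free-form displacement ----
# Control point i (0-based) of a gx-point axis sits at
# lo + (i - 1) * delta with delta = (hi - lo) / (g - 3), so the domain
# [lo, hi] is fully supported by the grid.

bspline_basis <- function(u) {
  # the four cubic b-spline blending weights at fractional offset u in [0,1)
  cbind((1 - u)^3 / 6,
        (3 * u^3 - 6 * u^2 + 4) / 6,
        (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
        u^3 / 6)
}

# displacements (n x 3) interpolated from the control grid at given points
bspline_displacement <- function(gt, pts) {
  gs <- gt$grid_shape
  b <- gt$domain_bounds
  lo <- b[c(1, 3, 5)]
  hi <- b[c(2, 4, 6)]
  delta <- (hi - lo) / (gs - 3)
  n <- nrow(pts)
  idx <- matrix(0L, n, 3)
  W <- vector("list", 3)
  for (a in 1:3) {
    t_ <- (pts[, a] - lo[a]) / delta[a]
    l <- pmin(pmax(floor(t_), 0), gs[a] - 4)  # clamp so 4-point support stays in grid
    u <- pmin(pmax(t_ - l, 0), 1)
    idx[, a] <- as.integer(l)
    W[[a]] <- bspline_basis(u)
  }
  disp <- matrix(0, n, 3)
  cd <- gt$control_displacements
  for (a in 1:4) for (bb in 1:4) for (cc in 1:4) {
    w <- W[[1]][, a] * W[[2]][, bb] * W[[3]][, cc]
    ii <- idx[, 1] + a; jj <- idx[, 2] + bb; kk <- idx[, 3] + cc  # 1-based grid indices
    lin <- ii + gs[1] * (jj - 1L + gs[2] * (kk - 1L))
    ncp <- prod(gs)
    disp[, 1] <- disp[, 1] + w * cd[lin]
    disp[, 2] <- disp[, 2] + w * cd[lin + ncp]
    disp[, 3] <- disp[, 3] + w * cd[lin + 2L * ncp]
  }
  disp
}
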