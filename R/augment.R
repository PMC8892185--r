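#' Geometric augmentation: in-plane rotations and axis mirroring
#'
#' Training cases are expanded 96-fold: 24 in-plane rotations (15 degree
#' steps about the z axis) crossed with an optional in-plane mirror and an
#' optional z mirror. The decomposition 24 x 2 x 2 = 96 is the unique one
#' yielding distinct geometric maps: combining independent x- and y-mirrors
#' with all rotations would double-count, because mirror-x followed by
#' mirror-y equals a 180 degree rotation.
#'
#' @name augment
NULL

#' Enumerate the 96 augmentation operations
#'
#' @return a data.frame with columns `rotation_deg` (multiples of 15 in
#'   \[0, 345\]), `mirror_inplane` and `mirror_z`; 96 rows, the identity
#'   operation first.
#' @export
augment_ops <- function() {
  ops <- expand.grid(rotation_deg = seq(0, 345, by = 15),
                     mirror_inplane = c(FALSE, TRUE),
                     mirror_z = c(FALSE, TRUE),
                     KEEP.OUT.ATTRS = FALSE)
  ops[order(ops$mirror_z, ops$mirror_inplane, ops$rotation_deg), ,
      drop = FALSE] -> ops
  rownames(ops) <- NULL
  ops
}

# Rotate the raw array about the z axis through the grid center.
# Exact index permutations for multiples of 90; otherwise resampled with
# linear (intensities) or nearest (masks) interpolation.
rotate_xy_array <- function(a, angle_deg, interpolation, fill) {
  d <- dim(a)
  angle_deg <- angle_deg %% 360
  if (angle_deg == 0) return(a)
  if (angle_deg %% 90 == 0 && d[1] == d[2]) {
    # exact lattice rotations (counter-clockwise in the x-y plane)
    k <- angle_deg / 90
    for (i in seq_len(k)) {
      # (x, y) -> (-y, x): reverse y then transpose the first two axes
      a <- aperm(a[, d[2]:1, , drop = FALSE], c(2, 1, 3))
    }
    return(a)
  }
  th <- angle_deg * pi / 180
  # pull coordinates: output voxel (0-based) samples input at R(-th)
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
  xo <- rep(0:(d[1] - 1), times = d[2]) - cx
  yo <- rep(0:(d[2] - 1), each = d[1]) - cy
  xs <- cos(th) * xo + sin(th) * yo + cx
  ys <- -sin(th) * xo + cos(th) * yo + cy
  nslice <- d[1] * d[2]
  m <- matrix(a, nrow = nslice)          # (x,y) flattened by z columns
  out <- matrix(fill, nrow = nslice, ncol = d[3])
  if (interpolation == "nearest") {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 0 & xi < d[1] & yi >= 0 & yi < d[2]
    src <- xi[ok] + d[1] * yi[ok] + 1
    out[ok, ] <- m[src, , drop = FALSE]
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    acc <- matrix(0, nrow = nslice, ncol = d[3])
    wsum <- numeric(nslice)
    for (dx in 0:1) for (dy in 0:1) {
      xi <- x0 + dx; yi <- y0 + dy
      w <- (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy)
      ok <- xi >= 0 & xi < d[1] & yi >= 0 & yi < d[2] & w > 0
      src <- xi[ok] + d[1] * yi[ok] + 1
      acc[ok, ] <- acc[ok, ] + w[ok] * m[src, , drop = FALSE]
      wsum[ok] <- wsum[ok] + w[ok]
    }
    inside <- wsum > 1e-12
    out[inside, ] <- acc[inside, , drop = FALSE] / wsum[inside]
  }
  array(out, d)
}

#' Rotate a volume or mask in the x-y slice plane
#'
#' Rotation about the z axis through the VOI center, in steps of 15
#' degrees. Masks are resampled with nearest-neighbour interpolation and
#' stay binary; multiples of 90 degrees on square slices are exact index
#' permutations.
#'
#' @param x a [vol3d] or [mask3d].
#' @param angle_deg rotation angle, a multiple of 15 in \[0, 345\]
#'   (counter-clockwise).
#' @param interpolation `"linear"` or `"nearest"`; masks always use
#'   nearest.
#' @param fill value for voxels rotated in from outside the frame; defaults
#'   to the volume minimum (0 for masks).
#' @return object of the same class as `x`.
#' @export
rotate_xy <- function(x, angle_deg,
                      interpolation = c("linear", "nearest"), fill = NULL) {
  stopifnot(inherits(x, "vol3d"))
  interpolation <- match.arg(interpolation)
  if (angle_deg %% 15 != 0)
    stop("`angle_deg` must be a multiple of 15, got ", angle_deg)
  is_mask <- inherits(x, "mask3d")
  if (is_mask) interpolation <- "nearest"
  if (is.null(fill)) fill <- if (is_mask) 0L else min(x$data)
  out <- rotate_xy_array(x$data, angle_deg, interpolation, fill)
  if (is_mask) mask3d(out, x$spacing, x$origin)
  else vol3d(out, x$spacing, x$origin)
}

#' Mirror a volume or mask along one axis
#'
#' Reflection about the axis midline; applying it twice is the identity.
#'
#' @param x a [vol3d] or [mask3d].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return object of the same class as `x`.
#' @export
mirror <- function(x, axis = c("x", "y", "z")) {
  stopifnot(inherits(x, "vol3d"))
  axis <- match.arg(axis)
  d <- dim(x$data)
  out <- switch(axis,
                x = x$data[d[1]:1, , , drop = FALSE],
                y = x$data[, d[2]:1, , drop = FALSE],
                z = x$data[, , d[3]:1, drop = FALSE])
  if (inherits(x, "mask3d")) mask3d(out, x$spacing, x$origin)
  else vol3d(out, x$spacing, x$origin)
}

# Apply one augmentation op (a row of augment_ops()) to a vol3d/mask3d.
apply_augment_op <- function(x, op, fill = NULL) {
  out <- rotate_xy(x, op$rotation_deg, fill = fill)
  if (isTRUE(op$mirror_inplane)) out <- mirror(out, "x")
  if (isTRUE(op$mirror_z)) out <- mirror(out, "z")
  out
}

#' Expand one case into its 96 augmented variants
#'
#' Applies every operation from [augment_ops()] to the paired volume and
#' mask; both receive the same geometric transform, intensities with linear
#' and masks with nearest interpolation.
#'
#' @param volume a [vol3d].
#' @param mask the paired [mask3d] (same shape).
#' @return a list of 96 elements, each a list with `volume`, `mask` and
#'   `op` (one row of [augment_ops()]); the identity variant comes first.
#' @export
augment_case <- function(volume, mask) {
  stopifnot(inherits(volume, "vol3d"), inherits(mask, "mask3d"))
  stopifnot_same_shape(volume, mask)
  ops <- augment_ops()
  lapply(seq_len(nrow(ops)), function(i) {
    op <- ops[i, ]
    list(volume = apply_augment_op(volume, op),
         mask = apply_augment_op(mask, op),
         op = op)
  })
}
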