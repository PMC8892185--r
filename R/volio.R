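#' 3D volume and mask containers
#'
#' A `vol3d` is a 3D scalar grid (CT-like intensities) with voxel spacing in
#' mm and a world-space origin. A `mask3d` is a binary grid aligned
#' voxel-for-voxel with its volume. Voxel indices are 0-based in all
#' user-facing coordinate arguments, with axis order (x, y, z); z is the
#' slice axis, so "in-plane" operations act on x-y slices.
#'
#' @param data numeric 3D array; for masks, values must be 0/1 (logical
#'   arrays are accepted and coerced).
#' @param spacing length-3 positive numeric, mm per voxel along (x, y, z).
#' @param origin length-3 numeric, world coordinates (mm) of voxel (0,0,0).
#' @return An object of class `vol3d` or `mask3d`: a list with elements
#'   `data`, `spacing`, `origin`.
#' @examples
#' v <- vol3d(array(0, c(4, 4, 2)))
#' m <- mask3d(array(0L, c(4, 4, 2)))
#' dim(v$data)
#' @export
vol3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", paste(dim(data), collapse = "x"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "vol3d")
}

#' @rdname vol3d
#' @export
mask3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask `data` must be a 3D array")
  if (is.logical(data)) data <- array(as.integer(data), dim(data))
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    stop("mask values must all be 0 or 1")
  m <- vol3d(array(as.integer(data), dim(data)), spacing, origin)
  class(m) <- c("mask3d", "vol3d")
  m
}

#' @export
print.vol3d <- function(x, ...) {
  kind <- if (inherits(x, "mask3d")) "mask3d" else "vol3d"
  cat(sprintf("<%s> %s voxels, spacing %s mm\n", kind,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  if (inherits(x, "mask3d"))
    cat(sprintf("  foreground voxels: %d\n", sum(x$data)))
  else
    cat(sprintf("  intensity range: [%.4g, %.4g]\n",
                min(x$data), max(x$data)))
  invisible(x)
}

stopifnot_same_shape <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("shape mismatch: ", paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  invisible(TRUE)
}

#' Read and write volumes as NIfTI
#'
#' Volumes and masks are serialized as NIfTI-1 (`.nii` / `.nii.gz`). Masks
#' are stored as unsigned 8-bit integers. A write followed by a read
#' preserves the voxel grid bit-exactly and the spacing within floating
#' point tolerance.
#'
#' @param path file path to a NIfTI image.
#' @param as_mask read the file as a binary `mask3d` (values are checked).
#' @return `read_volume` returns a [vol3d] (or [mask3d]); `write_volume`
#'   invisibly returns `path`.
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stop("no such NIfTI file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI '", path,
                                           "': ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image in '", path, "', got ",
         length(d), " dimensions")
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  orig <- tryCatch(unname(RNifti::xform(img)[seq_len(3), 4L]),
                   error = function(e) c(0, 0, 0))
  arr <- array(as.vector(img), dim = d)
  if (as_mask) mask3d(arr, spacing = spacing, origin = orig)
  else vol3d(arr, spacing = spacing, origin = orig)
}

#' @rdname read_volume
#' @param volume a [vol3d] or [mask3d].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "vol3d"))
  dtype <- if (inherits(volume, "mask3d")) "uint8" else "double"
  arr <- volume$data
  attr(arr, "pixdim") <- volume$spacing
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = dtype)
  invisible(path)
}

#' Crop a fixed volume of interest
#'
#' Extracts a VOI of the requested shape centered on a voxel, padding with a
#' fill value where the VOI extends beyond the volume. The default shape,
#' 128 x 128 x 64, is the standard nodule VOI used throughout the package.
#'
#' @param volume a [vol3d] or [mask3d].
#' @param center length-3 integer, 0-based voxel index of the VOI center.
#' @param shape length-3 positive integers, output shape.
#' @param fill scalar used outside the original volume; defaults to the
#'   volume minimum (air-like background) and to 0 for masks.
#' @return object of the same class as `volume` with dimensions `shape`.
#' @examples
#' v <- vol3d(array(seq_len(8^3), c(8, 8, 8)))
#' cr <- crop_voi(v, center = c(4, 4, 4), shape = c(4, 4, 2))
#' dim(cr$data)
#' @export
crop_voi <- function(volume, center, shape = c(128, 128, 64), fill = NULL) {
  stopifnot(inherits(volume, "vol3d"))
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0L))
    stop("`shape` must be 3 positive integers")
  center <- as.integer(round(center))
  if (is.null(fill))
    fill <- if (inherits(volume, "mask3d")) 0L else min(volume$data)
  d <- dim(volume$data)
  # 0-based start so that `center` sits at floor(shape/2) in the output
  start <- center - shape %/% 2L
  out <- array(fill, shape)
  src_lo <- pmax(start, 0L)
  src_hi <- pmin(start + shape, d)
  if (all(src_hi > src_lo)) {
    dst_lo <- src_lo - start
    out[(dst_lo[1] + 1L):(dst_lo[1] + src_hi[1] - src_lo[1]),
        (dst_lo[2] + 1L):(dst_lo[2] + src_hi[2] - src_lo[2]),
        (dst_lo[3] + 1L):(dst_lo[3] + src_hi[3] - src_lo[3])] <-
      volume$data[(src_lo[1] + 1L):src_hi[1],
                  (src_lo[2] + 1L):src_hi[2],
                  (src_lo[3] + 1L):src_hi[3]]
  }
  new_origin <- volume$origin + start * volume$spacing
  if (inherits(volume, "mask3d"))
    mask3d(out, volume$spacing, new_origin)
  else vol3d(out, volume$spacing, new_origin)
}

#' Intensity window
#'
#' A window maps the HU-like interval \[lo, hi\] affinely onto \[0, 1\];
#' values outside are clipped. Network inputs are normalized this way.
#'
#' @param lo,hi window bounds, `lo < hi`.
#' @export
intensity_window <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("invalid window: need lo < hi, got [", lo, ", ", hi, "]")
  structure(list(lo = lo, hi = hi), class = "intensity_window")
}

#' Normalize a volume into an intensity window
#'
#' @param volume a [vol3d].
#' @param win an [intensity_window] object; the default (-1000, 200)
#'   covers aerated
#'   lung through soft tissue on the HU scale.
#' @return a [vol3d] with values in \[0, 1\].
#' @export
normalize_volume <- function(volume, win = intensity_window(-1000, 200)) {
  stopifnot(inherits(volume, "vol3d"), inherits(win, "intensity_window"))
  x <- (volume$data - win$lo) / (win$hi - win$lo)
  x[x < 0] <- 0
  x[x > 1] <- 1
  vol3d(x, volume$spacing, volume$origin)
}
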