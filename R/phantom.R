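#' Parametric CT nodule phantoms
#'
#' The phantom generator produces CT-like volumes containing a single
#' synthetic lung nodule together with its exact ground-truth mask. Four
#' morphologies are modeled, chosen because they span the easy and the
#' hard cases for nodule segmenters:
#'
#' * `solid` - a high-contrast sphere in aerated lung,
#' * `ggo` - a ground-glass nodule: low contrast with blurred, faint
#'   margins (thresholding-hostile),
#' * `wall_attached` - a sphere abutting a chest-wall slab of similar
#'   intensity on one VOI face,
#' * `vessel_attached` - a sphere with a vessel-like cylinder attached.
#'
#' Intensities are on an HU-like scale: aerated lung background -800,
#' solid nodule +20, GGO nodule -500, chest wall +40, vessel +30. The ideal
#' scene is blurred with a Gaussian (a cheap stand-in for the partial
#' volume effect, and the source of the faint GGO margins) and corrupted
#' with additive i.i.d. Gaussian noise. The ground-truth mask is the
#' noise-free, pre-blur nodule support: it never depends on
#' `edge_blur_sigma`, `noise_sigma` or `seed`.
#'
#' @param nodule_type one of `"solid"`, `"ggo"`, `"wall_attached"`,
#'   `"vessel_attached"`.
#' @param radius_vox nodule radius in voxels; must satisfy
#'   `radius_vox < min(volume_shape)/2`.
#' @param center 0-based voxel coordinates of the nodule center; default is
#'   the volume center (shifted to touch the wall for `wall_attached`).
#' @param nodule_intensity,background_intensity,wall_intensity,vessel_intensity
#'   HU-like scene intensities; defaults follow the scale above (`ggo`
#'   defaults to -500).
#' @param edge_blur_sigma Gaussian blur sd in voxels applied to the ideal
#'   scene (0 = none); must be > 0 for `ggo`.
#' @param noise_sigma sd of additive Gaussian noise (HU-like units).
#' @param volume_shape length-3 positive integers; the default is the
#'   128 x 128 x 64 nodule VOI.
#' @param seed nonnegative integer; identical spec + seed gives
#'   bit-identical output.
#' @param wall_thickness slab thickness in voxels on the x-min face
#'   (`wall_attached` only).
#' @param vessel_radius,vessel_length cylinder radius and length beyond the
#'   nodule surface, voxels (`vessel_attached` only).
#' @return `phantom_spec` returns an object of class `phantom_spec`.
#' @examples
#' sp <- phantom_spec("solid", radius_vox = 6, volume_shape = c(32, 32, 16),
#'                    noise_sigma = 0, edge_blur_sigma = 0)
#' ph <- make_phantom(sp)
#' sum(ph$mask$data)
#' @export
phantom_spec <- function(nodule_type = c("solid", "ggo", "wall_attached",
                                         "vessel_attached"),
                         radius_vox,
                         center = NULL,
                         nodule_intensity = NULL,
                         background_intensity = -800,
                         wall_intensity = 40,
                         vessel_intensity = 30,
                         edge_blur_sigma = 0.8,
                         noise_sigma = 20,
                         volume_shape = c(128, 128, 64),
                         seed = 0,
                         wall_thickness = 4,
                         vessel_radius = 2.5,
                         vessel_length = NULL) {
  nodule_type <- match.arg(nodule_type)
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape <= 0L))
    stop("`volume_shape` must be 3 positive integers")
  if (!is.numeric(radius_vox) || radius_vox <= 0)
    stop("`radius_vox` must be positive")
  if (radius_vox >= min(volume_shape) / 2)
    stop("`radius_vox` must be < min(volume_shape)/2 so the nodule fits")
  if (edge_blur_sigma < 0) stop("`edge_blur_sigma` must be nonnegative")
  if (noise_sigma < 0) stop("`noise_sigma` must be nonnegative")
  if (seed < 0) stop("`seed` must be nonnegative")
  if (is.null(nodule_intensity))
    nodule_intensity <- if (nodule_type == "ggo") -500 else 20
  if (nodule_type == "ggo") {
    solid_tissue <- 20
    if (!(nodule_intensity > background_intensity &&
          nodule_intensity < solid_tissue))
      stop("GGO nodule intensity must lie strictly between background (",
           background_intensity, ") and solid tissue (", solid_tissue, ")")
    if (edge_blur_sigma <= 0)
      stop("GGO phantoms require edge_blur_sigma > 0 (faint margins)")
  }
  if (is.null(center)) {
    center <- (volume_shape - 1) / 2
    if (nodule_type == "wall_attached") {
      # integer y/z center so the sphere touches the slab on a lattice
      # voxel at distance exactly radius_vox
      center <- c(wall_thickness + radius_vox,
                  floor(center[2]), floor(center[3]))
    }
  }
  center <- as.numeric(center)
  if (length(center) != 3L) stop("`center` must have length 3")
  if (any(center - radius_vox < -0.5) ||
      any(center + radius_vox > volume_shape - 0.5))
    stop("nodule extends outside volume bounds")
  if (is.null(vessel_length)) vessel_length <- 3 * radius_vox
  structure(list(nodule_type = nodule_type, radius_vox = radius_vox,
                 center = center, nodule_intensity = nodule_intensity,
                 background_intensity = background_intensity,
                 wall_intensity = wall_intensity,
                 vessel_intensity = vessel_intensity,
                 edge_blur_sigma = edge_blur_sigma,
                 noise_sigma = noise_sigma,
                 volume_shape = volume_shape, seed = as.integer(seed),
                 wall_thickness = as.integer(wall_thickness),
                 vessel_radius = vessel_radius,
                 vessel_length = vessel_length),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %s nodule, r = %.2f vox, VOI %s, blur %.2f, noise %.1f, seed %d\n",
    x$nodule_type, x$radius_vox, paste(x$volume_shape, collapse = "x"),
    x$edge_blur_sigma, x$noise_sigma, x$seed))
  invisible(x)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Separable Gaussian blur with edge-renormalized truncated kernels.
gaussian_blur3d <- function(a, sigma, truncate = 3) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  for (axis in 1:3) {
    n <- d[axis]
    r <- max(1L, as.integer(ceiling(truncate * sigma)))
    k <- stats::dnorm(seq(-r, r), sd = sigma)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- (i - r):(i + r)
      ok <- idx >= 1 & idx <= n
      K[i, idx[ok]] <- k[ok] / sum(k[ok])
    }
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(a, perm), nrow = n)
    out <- K %*% m
    a <- aperm(array(out, d[perm]), order(perm))
  }
  a
}

# 0-based coordinate grids for a volume shape, as three arrays.
coord_grids <- function(shape) {
  list(x = array(rep(0:(shape[1] - 1), times = shape[2] * shape[3]), shape),
       y = array(rep(rep(0:(shape[2] - 1), each = shape[1]), shape[3]),
                 shape),
       z = array(rep(0:(shape[3] - 1), each = shape[1] * shape[2]), shape))
}

#' Generate a phantom volume and its ground-truth mask
#'
#' @param spec a [phantom_spec].
#' @return a list with elements `volume` ([vol3d]), `mask` ([mask3d]) and
#'   `spec`.
#' @seealso [phantom_spec], [make_benchmark_set]
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$volume_shape
  g <- coord_grids(shp)
  cc <- spec$center
  dist2 <- (g$x - cc[1])^2 + (g$y - cc[2])^2 + (g$z - cc[3])^2
  nodule <- dist2 <= spec$radius_vox^2

  wall <- NULL
  if (spec$nodule_type == "wall_attached") {
    wall <- g$x < spec$wall_thickness
    nodule <- nodule & !wall
  }
  vessel <- NULL
  if (spec$nodule_type == "vessel_attached") {
    r2 <- (g$y - cc[2])^2 + (g$z - cc[3])^2
    vessel <- r2 <= spec$vessel_radius^2 &
      g$x >= cc[1] &
      g$x <= cc[1] + spec$radius_vox + spec$vessel_length
    vessel <- vessel & !nodule
  }

  if (!any(nodule))
    warning("phantom mask is empty: no voxel center falls inside the nodule")

  scene <- array(spec$background_intensity, shp)
  if (!is.null(wall)) scene[wall] <- spec$wall_intensity
  if (!is.null(vessel)) scene[vessel] <- spec$vessel_intensity
  scene[nodule] <- spec$nodule_intensity

  scene <- gaussian_blur3d(scene, spec$edge_blur_sigma)
  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed,
                       stats::rnorm(prod(shp), sd = spec$noise_sigma))
    scene <- scene + array(noise, shp)
  }
  list(volume = vol3d(scene),
       mask = mask3d(array(as.integer(nodule), shp)),
       spec = spec)
}

#' Generate a reproducible phantom benchmark set
#'
#' Draws `n_per_type` phantoms of each requested morphology with parameters
#' sampled uniformly from the given ranges. Each case gets its own derived
#' seed, so the set is fully reproducible from `seed`.
#'
#' @param n_per_type cases per nodule type, >= 1.
#' @param ranges named list of length-2 numeric ranges for `radius_vox`,
#'   `edge_blur_sigma` and `noise_sigma` (a degenerate range `c(a, a)` pins
#'   the parameter).
#' @param types character vector of nodule types to include.
#' @param volume_shape VOI shape for all cases.
#' @param seed master seed for the draw.
#' @return list of cases, each a list with `volume`, `mask`, `spec` and a
#'   `case_id` string.
#' @examples
#' set <- make_benchmark_set(1, ranges = list(radius_vox = c(4, 6),
#'   edge_blur_sigma = c(0, 0), noise_sigma = c(0, 10)),
#'   types = "solid", volume_shape = c(32, 32, 16), seed = 1)
#' length(set)
#' @export
make_benchmark_set <- function(n_per_type,
                               ranges = list(radius_vox = c(8, 16),
                                             edge_blur_sigma = c(0.5, 1.5),
                                             noise_sigma = c(10, 30)),
                               types = c("solid", "ggo", "wall_attached",
                                         "vessel_attached"),
                               volume_shape = c(128, 128, 64),
                               seed = 0) {
  if (n_per_type < 1) stop("`n_per_type` must be >= 1")
  needed <- c("radius_vox", "edge_blur_sigma", "noise_sigma")
  for (nm in needed) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2])
      stop("invalid or empty range for `", nm, "`")
  }
  types <- match.arg(types, several.ok = TRUE)
  draw <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
  cases <- list()
  i <- 0L
  for (tp in types) {
    for (j in seq_len(n_per_type)) {
      i <- i + 1L
      case_seed <- (seed * 10007L + i) %% .Machine$integer.max
      pars <- with_seed(case_seed, list(
        radius_vox = draw(ranges$radius_vox),
        blur = draw(ranges$edge_blur_sigma),
        noise = draw(ranges$noise_sigma)))
      blur <- pars$blur
      if (tp == "ggo" && blur <= 0) blur <- 1.0
      sp <- phantom_spec(tp, radius_vox = pars$radius_vox,
                         edge_blur_sigma = blur,
                         noise_sigma = pars$noise,
                         volume_shape = volume_shape,
                         seed = case_seed)
      ph <- make_phantom(sp)
      ph$case_id <- sprintf("case_%04d_%s", i, tp)
      cases[[i]] <- ph
    }
  }
  cases
}

#' Write a phantom set to disk as paired NIfTI files
#'
#' Emits `case_%04d_img.nii.gz` / `case_%04d_mask.nii.gz` pairs plus a JSON
#' manifest of the generating specs.
#'
#' @param cases output of [make_benchmark_set].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_phantom_set <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    img <- file.path(dir, sprintf("case_%04d_img.nii.gz", i))
    msk <- file.path(dir, sprintf("case_%04d_mask.nii.gz", i))
    write_volume(cases[[i]]$volume, img)
    write_volume(cases[[i]]$mask, msk)
    sp <- cases[[i]]$spec
    manifest[[i]] <- c(list(case_id = cases[[i]]$case_id,
                            image = basename(img), mask = basename(msk)),
                       unclass(sp))
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
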