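#' Watershed segmentation parameters
#'
#' The watershed segmenter runs in two steps. Step 1 thresholds the volume
#' to a rough foreground region (the nodule plus attached vessels) and
#' removes structures touching the VOI faces, which excludes the chest
#' wall. Step 2 builds a nodule model by Euclidean distance transformation
#' inside the rough region, places markers at distance maxima separated by
#' at least `marker_min_distance`, floods the negated distance map by
#' marker-based watershed (splitting touching structures at their
#' constriction), and returns one region according to `select`.
#'
#' @param rough_threshold HU-like threshold separating nodule tissue from
#'   aerated lung, or `"otsu"` to derive it from the intensity histogram.
#' @param marker_min_distance minimum spacing between markers, voxels
#'   (>= 1).
#' @param select `"center_marker"` (region at/nearest the VOI center, the
#'   default since the VOI is centered on the nodule) or `"largest"`.
#' @param connectivity neighborhood used for components and flooding.
#' @return an object of class `watershed_params`.
#' @export
watershed_params <- function(rough_threshold = "otsu",
                             marker_min_distance = 5,
                             select = c("center_marker", "largest"),
                             connectivity = 6) {
  select <- match.arg(select)
  if (!identical(rough_threshold, "otsu") &&
      !(is.numeric(rough_threshold) && length(rough_threshold) == 1))
    stop("`rough_threshold` must be a number or \"otsu\"")
  if (marker_min_distance < 1) stop("`marker_min_distance` must be >= 1")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  structure(list(rough_threshold = rough_threshold,
                 marker_min_distance = marker_min_distance,
                 select = select, connectivity = as.integer(connectivity)),
            class = "watershed_params")
}

# Otsu's threshold from a 256-bin intensity histogram.
otsu_threshold <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  breaks <- seq(r[1], r[2], length.out = 257)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = 256)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

face_touching_components <- function(labels, dims) {
  lab <- array(labels, dims)
  unique(c(lab[1, , ], lab[dims[1], , ], lab[, 1, ], lab[, dims[2], ],
           lab[, , 1], lab[, , dims[3]]))
}

#' Segment a nodule with the two-step watershed pipeline
#'
#' @param volume a [vol3d] with HU-like intensities.
#' @param params a [watershed_params].
#' @return a [mask3d] with attributes `flag` (character, e.g.
#'   `"empty_rough_region"` when nothing survives thresholding, in which
#'   case the mask is empty) and `n_labels` (number of watershed regions
#'   found).
#' @export
watershed_segment <- function(volume, params = watershed_params()) {
  stopifnot(inherits(volume, "vol3d"), inherits(params, "watershed_params"))
  arr <- volume$data
  if (any(!is.finite(arr))) stop("volume contains non-finite values")
  dims <- dim(arr)
  thr <- if (identical(params$rough_threshold, "otsu"))
    otsu_threshold(as.vector(arr)) else params$rough_threshold
  fg <- as.integer(arr > thr)

  empty_result <- function(flag) {
    m <- mask3d(array(0L, dims), volume$spacing, volume$origin)
    attr(m, "flag") <- flag
    attr(m, "n_labels") <- 0L
    m
  }
  if (!any(fg == 1L)) return(empty_result("empty_rough_region"))

  # step 1: rough region = thresholded foreground minus components that
  # touch the VOI faces (chest wall and other border-attached structures)
  comp <- .label_components(fg, as.integer(dims), params$connectivity)
  border <- setdiff(face_touching_components(comp, dims), 0L)
  rough <- as.integer(comp != 0L & !(comp %in% border))
  if (!any(rough == 1L)) return(empty_result("empty_rough_region"))

  # step 2: nodule model by distance transformation
  dt <- .edt_squared(rough, as.integer(dims))
  markers <- place_markers(dt, dims, params$marker_min_distance)
  # flooding in order of decreasing distance = watershed of the negated
  # distance map: regions grow from the cores and meet at constrictions
  labels <- .watershed_flood(dt, markers$grid, rough, as.integer(dims),
                             params$connectivity)
  n_labels <- nrow(markers$coords)

  pick <- if (params$select == "largest") {
    tab <- tabulate(labels[labels > 0], nbins = n_labels)
    which.max(tab)
  } else {
    ctr <- (dims - 1) / 2
    ctr_idx <- round(ctr)
    lab_at_ctr <- labels[1 + ctr_idx[1] + dims[1] *
                           (ctr_idx[2] + dims[2] * ctr_idx[3])]
    if (lab_at_ctr > 0) lab_at_ctr else {
      d2 <- colSums((t(markers$coords) - ctr)^2)
      which.min(d2)
    }
  }
  out <- mask3d(array(as.integer(labels == pick), dims),
                volume$spacing, volume$origin)
  attr(out, "flag") <- "ok"
  attr(out, "n_labels") <- n_labels
  attr(out, "rough_threshold") <- thr
  out
}

# Local maxima of the (squared) distance map, greedily thinned so kept
# markers are at least `min_dist` voxels apart (strongest first).
place_markers <- function(dt, dims, min_dist) {
  arr <- array(dt, dims)
  cand <- which(arr > 0)
  if (!length(cand)) return(list(grid = array(0L, dims),
                                 coords = matrix(numeric(0), 0, 3)))
  coords <- arrayInd(cand, dims)
  is_max <- vapply(seq_along(cand), function(i) {
    c0 <- coords[i, ]
    lo <- pmax(c0 - 1L, 1L); hi <- pmin(c0 + 1L, dims)
    arr[c0[1], c0[2], c0[3]] >=
      max(arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
  }, logical(1))
  coords <- coords[is_max, , drop = FALSE]
  vals <- arr[coords]
  ord <- order(-vals, coords[, 1], coords[, 2], coords[, 3])
  coords <- coords[ord, , drop = FALSE]
  kept <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(coords))) {
    c0 <- coords[i, ]
    if (!nrow(kept) ||
        min(colSums((t(kept) - c0)^2)) >= min_dist^2)
      kept <- rbind(kept, c0)
  }
  grid <- array(0L, dims)
  for (i in seq_len(nrow(kept)))
    grid[kept[i, 1], kept[i, 2], kept[i, 3]] <- i
  list(grid = grid, coords = kept - 1) # coords 0-based
}

#' Graph-cut segmentation parameters
#'
#' The labeling energy is the linear sum of a region term and a boundary
#' term, \eqn{E(L) = Region(L) + Boundary(L)}. The region term scores each
#' voxel's intensity under a Gaussian likelihood of its assigned label
#' (means `fg_mean` / `bg_mean`, common sd `sigma_region`); the boundary
#' term charges each neighboring pair with differing labels the contrast
#' weight \eqn{w \exp(-(I_i - I_j)^2 / 2\sigma_b^2)}, scaled by the
#' inverse voxel distance for diagonal neighbors under 26-connectivity.
#'
#' @param fg_mean,bg_mean expected foreground / background intensities
#'   (HU-like).
#' @param sigma_region Gaussian sd of the intensity likelihoods (> 0).
#' @param sigma_boundary contrast scale of the boundary term (> 0).
#' @param boundary_weight nonnegative multiplier of the boundary term.
#' @param neighborhood 6 or 26.
#' @return an object of class `graphcut_params`.
#' @export
graphcut_params <- function(fg_mean = 20, bg_mean = -800,
                            sigma_region = 150, sigma_boundary = 100,
                            boundary_weight = 1, neighborhood = 6) {
  if (sigma_region <= 0 || sigma_boundary <= 0)
    stop("sigmas must be positive")
  if (boundary_weight < 0) stop("`boundary_weight` must be nonnegative")
  if (!neighborhood %in% c(6, 26)) stop("neighborhood must be 6 or 26")
  structure(list(fg_mean = fg_mean, bg_mean = bg_mean,
                 sigma_region = sigma_region,
                 sigma_boundary = sigma_boundary,
                 boundary_weight = boundary_weight,
                 neighborhood = as.integer(neighborhood)),
            class = "graphcut_params")
}

# Per-voxel region costs: -log Gaussian likelihood under each label.
gc_region_costs <- function(vals, params) {
  nll <- function(mu) -stats::dnorm(vals, mu, params$sigma_region,
                                    log = TRUE)
  list(bg = nll(params$bg_mean), fg = nll(params$fg_mean))
}

# Neighbor pairs (i, j, weight) for the boundary term, 1-based voxel
# indices; diagonal weights are scaled by 1/distance.
gc_neighbor_pairs <- function(vals, dims, params) {
  offs <- if (params$neighborhood == 6) {
    list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    o <- o[o$dx != 0 | o$dy != 0 | o$dz != 0, ]
    # keep one direction per unordered pair
    o <- o[o$dz > 0 | (o$dz == 0 & o$dy > 0) |
             (o$dz == 0 & o$dy == 0 & o$dx > 0), ]
    lapply(seq_len(nrow(o)), function(i) as.numeric(o[i, ]))
  }
  arr <- array(seq_len(prod(dims)), dims)
  out_i <- integer(0); out_j <- integer(0); out_w <- numeric(0)
  for (off in offs) {
    xr <- seq_len(dims[1] - abs(off[1]))
    yr <- seq_len(dims[2] - abs(off[2]))
    zr <- seq_len(dims[3] - abs(off[3]))
    i <- as.vector(arr[xr, yr, zr, drop = FALSE])
    j <- as.vector(arr[xr + abs(off[1]), yr + abs(off[2]),
                       zr + abs(off[3]), drop = FALSE])
    dist <- sqrt(sum(off^2))
    w <- params$boundary_weight *
      exp(-(vals[i] - vals[j])^2 / (2 * params$sigma_boundary^2)) / dist
    out_i <- c(out_i, i); out_j <- c(out_j, j); out_w <- c(out_w, w)
  }
  list(i = out_i, j = out_j, w = out_w)
}

#' Evaluate the graph-cut labeling energy
#'
#' @param labeling a [mask3d] (1 = foreground).
#' @param volume the [vol3d] being segmented, same shape.
#' @param params a [graphcut_params].
#' @return the nonnegative energy `Region(L) + Boundary(L)`; region costs
#'   are shifted per voxel so the pointwise minimum is zero, which leaves
#'   the minimizer unchanged and keeps the energy nonnegative.
#' @export
graphcut_energy <- function(labeling, volume, params = graphcut_params()) {
  stopifnot(inherits(volume, "vol3d"), inherits(params, "graphcut_params"))
  stopifnot_same_shape(labeling, volume)
  lab <- as.vector(labeling$data)
  vals <- as.vector(volume$data)
  rc <- gc_region_costs(vals, params)
  shift <- pmin(rc$bg, rc$fg)
  region <- sum(ifelse(lab == 1, rc$fg, rc$bg) - shift)
  np <- gc_neighbor_pairs(vals, dim(volume$data), params)
  boundary <- sum(np$w[lab[np$i] != lab[np$j]])
  region + boundary
}

#' Graph-cut segmentation by s-t minimum cut
#'
#' Minimizes the labeling energy globally by reduction to a minimum s-t
#' cut (solved with a max-flow algorithm): terminal links carry the
#' shifted region costs, neighbor links the boundary weights. Hard seeds,
#' when given, are enforced with infinite-capacity terminal links.
#'
#' @param volume a [vol3d].
#' @param params a [graphcut_params].
#' @param fg_seeds,bg_seeds optional matrices of 0-based voxel coordinates
#'   (rows are (x, y, z)) forced to foreground / background.
#' @return a [mask3d] with attribute `energy` (the energy of the returned
#'   labeling, as computed by [graphcut_energy]).
#' @export
graphcut_segment <- function(volume, params = graphcut_params(),
                             fg_seeds = NULL, bg_seeds = NULL) {
  stopifnot(inherits(volume, "vol3d"), inherits(params, "graphcut_params"))
  dims <- dim(volume$data)
  V <- prod(dims)
  vals <- as.vector(volume$data)
  rc <- gc_region_costs(vals, params)
  shift <- pmin(rc$bg, rc$fg)
  cost_fg <- rc$fg - shift   # paid when labeled foreground
  cost_bg <- rc$bg - shift   # paid when labeled background

  seed_idx <- function(seeds) {
    if (is.null(seeds)) return(integer(0))
    seeds <- matrix(seeds, ncol = 3)
    1L + seeds[, 1] + dims[1] * (seeds[, 2] + dims[2] * seeds[, 3])
  }
  fg_i <- seed_idx(fg_seeds); bg_i <- seed_idx(bg_seeds)
  if (length(intersect(fg_i, bg_i)))
    stop("infeasible seeds: the same voxel is forced both fg and bg")

  np <- gc_neighbor_pairs(vals, dims, params)
  big <- sum(cost_fg) + sum(cost_bg) + sum(np$w) + 1
  cost_bg[fg_i] <- big   # forbid background label on fg seeds
  cost_fg[bg_i] <- big

  # source = foreground side: cutting v->t (cap cost_fg) pays the fg
  # region cost; cutting s->v (cap cost_bg) pays the bg region cost.
  s <- V + 1L; t <- V + 2L
  from <- c(rep(s, V), seq_len(V), np$i, np$j)
  to <- c(seq_len(V), rep(t, V), np$j, np$i)
  cap <- c(cost_bg, cost_fg, np$w, np$w)
  keep <- cap > 0
  g <- igraph::graph_from_edgelist(cbind(from[keep], to[keep]),
                                   directed = TRUE)
  if (igraph::vcount(g) < t)
    g <- igraph::add_vertices(g, t - igraph::vcount(g))
  mf <- igraph::max_flow(g, s, t, capacity = cap[keep])
  fg_side <- as.integer(mf$partition1)
  lab <- integer(V)
  lab[fg_side[fg_side <= V]] <- 1L
  out <- mask3d(array(lab, dims), volume$spacing, volume$origin)
  attr(out, "energy") <- graphcut_energy(out, volume, params)
  out
}
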