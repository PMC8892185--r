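# Fixture builders shared across test files. Everything is generated in
# code; no data files.

TEST_SHAPE <- c(32L, 32L, 16L)

solid_case <- function(radius = 6, noise = 0, blur = 0, seed = 0,
                       shape = TEST_SHAPE) {
  ph <- make_phantom(phantom_spec("solid", radius_vox = radius,
                                  volume_shape = shape,
                                  noise_sigma = noise,
                                  edge_blur_sigma = blur, seed = seed))
  ph$case_id <- sprintf("solid_r%g_s%d", radius, seed)
  ph
}

# Two equal spheres touching along x; the VOI center lies inside sphere A.
touching_spheres_volume <- function(radius = 6, shape = c(48L, 32L, 16L)) {
  g <- noduleseg:::coord_grids(shape)
  ctr <- (shape - 1) / 2
  cA <- c(ctr[1] - radius + 2, ctr[2], ctr[3])  # center voxel inside A
  cB <- c(cA[1] + 2 * radius, ctr[2], ctr[3])
  inA <- (g$x - cA[1])^2 + (g$y - cA[2])^2 + (g$z - cA[3])^2 <= radius^2
  inB <- (g$x - cB[1])^2 + (g$y - cB[2])^2 + (g$z - cB[3])^2 <= radius^2
  list(volume = vol3d(array(-800 + 820 * (inA | inB), shape)),
       A = mask3d(array(as.integer(inA), shape)),
       B = mask3d(array(as.integer(inB & !inA), shape)))
}

# An asymmetric binary probe mask: distinguishes all 96 augmentation ops.
probe_mask <- function(shape = c(17L, 17L, 6L), seed = 99) {
  arr <- noduleseg:::with_seed(seed,
    array(as.integer(stats::runif(prod(shape)) > 0.7), shape))
  mask3d(arr)
}

mask_signature <- function(m) paste(which(m$data == 1L), collapse = ",")

# Set-counting overlap oracle, independent of dice()/iou(): explicit voxel
# index sets and base set operations.
oracle_counts <- function(R, S) {
  r <- which(as.vector(R) != 0)
  s <- which(as.vector(S) != 0)
  list(nR = length(r), nS = length(s),
       inter = length(intersect(r, s)), union = length(union(r, s)))
}

oracle_dice <- function(R, S) {
  oc <- oracle_counts(R, S)
  if (oc$nR + oc$nS == 0) 1 else 2 * oc$inter / (oc$nR + oc$nS)
}

oracle_iou <- function(R, S) {
  oc <- oracle_counts(R, S)
  if (oc$union == 0) 1 else oc$inter / oc$union
}
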