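test_that("solid sphere mask matches the exhaustive voxel enumeration", {
  shape <- c(48L, 48L, 24L)
  ph <- make_phantom(phantom_spec("solid", radius_vox = 8,
                                  center = c(23, 24, 11),
                                  volume_shape = shape,
                                  noise_sigma = 0, edge_blur_sigma = 0))
  count <- 0L
  inside <- array(FALSE, shape)
  for (x in 0:(shape[1] - 1)) for (y in 0:(shape[2] - 1))
    for (z in 0:(shape[3] - 1))
      if ((x - 23)^2 + (y - 24)^2 + (z - 11)^2 <= 64) {
        count <- count + 1L
        inside[x + 1, y + 1, z + 1] <- TRUE
      }
  expect_equal(sum(ph$mask$data), count)
  expect_identical(ph$mask$data == 1L, inside)
})

test_that("a nodule too small to cover any voxel center warns and is empty", {
  sp <- phantom_spec("solid", radius_vox = 0.3, center = c(8.5, 8.5, 4.5),
                     volume_shape = c(16, 16, 8), noise_sigma = 0,
                     edge_blur_sigma = 0)
  expect_warning(ph <- make_phantom(sp), "empty")
  expect_equal(sum(ph$mask$data), 0)
})

test_that("ground truth is invariant to noise seed; intensities are not", {
  mk <- function(seed) make_phantom(
    phantom_spec("solid", radius_vox = 5, volume_shape = c(24, 24, 12),
                 noise_sigma = 15, edge_blur_sigma = 0.5, seed = seed))
  a <- mk(1); b <- mk(2)
  expect_identical(a$mask$data, b$mask$data)
  expect_false(identical(a$volume$data, b$volume$data))
  # same seed: bit-identical output
  expect_identical(a$volume$data, mk(1)$volume$data)
})

test_that("thresholding a blur-free noise-free phantom recovers the mask", {
  ph <- make_phantom(phantom_spec("solid", radius_vox = 6,
                                  volume_shape = c(32, 32, 16),
                                  noise_sigma = 0, edge_blur_sigma = 0))
  thr <- (-800 + 20) / 2
  expect_identical(array(as.integer(ph$volume$data > thr),
                         dim(ph$volume$data)),
                   ph$mask$data)
})

test_that("wall-attached masks touch the wall slab but never overlap it", {
  sp <- phantom_spec("wall_attached", radius_vox = 6,
                     volume_shape = c(32, 32, 16), noise_sigma = 0,
                     edge_blur_sigma = 0, wall_thickness = 4)
  ph <- make_phantom(sp)
  wall <- noduleseg:::coord_grids(sp$volume_shape)$x < 4
  expect_equal(sum(ph$mask$data[wall]), 0)
  # 6-connectivity adjacency: some mask voxel in the plane next to the wall
  expect_gt(sum(ph$mask$data[5, , ]), 0)
  # wall intensity present in the volume
  expect_gt(mean(ph$volume$data[wall]), -100)
})

test_that("vessel-attached phantoms add a cylinder outside the mask", {
  sp <- phantom_spec("vessel_attached", radius_vox = 5,
                     volume_shape = c(32, 32, 16), noise_sigma = 0,
                     edge_blur_sigma = 0)
  ph <- make_phantom(sp)
  bright <- ph$volume$data > -400
  expect_gt(sum(bright), sum(ph$mask$data))  # vessel voxels beyond nodule
  # mask itself is still exactly the sphere
  g <- noduleseg:::coord_grids(sp$volume_shape)
  d2 <- (g$x - sp$center[1])^2 + (g$y - sp$center[2])^2 +
    (g$z - sp$center[3])^2
  expect_identical(ph$mask$data, array(as.integer(d2 <= 25), dim(d2)))
})

test_that("spec validation rejects invalid geometry and GGO contrast", {
  expect_error(phantom_spec("solid", radius_vox = 20,
                            volume_shape = c(32, 32, 16)), "fits")
  expect_error(phantom_spec("solid", radius_vox = 6,
                            center = c(2, 16, 8),
                            volume_shape = c(32, 32, 16)), "bounds")
  expect_error(phantom_spec("ggo", radius_vox = 5, nodule_intensity = 100,
                            volume_shape = c(32, 32, 16)), "between")
  expect_error(phantom_spec("ggo", radius_vox = 5, edge_blur_sigma = 0,
                            volume_shape = c(32, 32, 16)), "blur")
  expect_error(phantom_spec("solid", radius_vox = 5, edge_blur_sigma = -1,
                            volume_shape = c(32, 32, 16)), "nonneg")
})

test_that("benchmark sets count, reproduce and honour degenerate ranges", {
  rng <- list(radius_vox = c(4, 6), edge_blur_sigma = c(0, 0),
              noise_sigma = c(0, 10))
  a <- make_benchmark_set(2, ranges = rng, volume_shape = c(32, 32, 16),
                          seed = 3)
  expect_length(a, 8)  # 2 per type x 4 types
  b <- make_benchmark_set(2, ranges = rng, volume_shape = c(32, 32, 16),
                          seed = 3)
  expect_identical(lapply(a, function(cs) cs$volume$data),
                   lapply(b, function(cs) cs$volume$data))
  # point ranges pin all parameters: specs identical except type and seed
  pt <- list(radius_vox = c(5, 5), edge_blur_sigma = c(0.5, 0.5),
             noise_sigma = c(10, 10))
  cases <- make_benchmark_set(3, ranges = pt, types = "solid",
                              volume_shape = c(32, 32, 16), seed = 1)
  specs <- lapply(cases, `[[`, "spec")
  strip <- function(sp) { sp$seed <- NULL; unclass(sp) }
  expect_identical(strip(specs[[1]]), strip(specs[[2]]))
  expect_identical(strip(specs[[1]]), strip(specs[[3]]))
  expect_error(make_benchmark_set(1, ranges = list(radius_vox = c(6, 4))),
               "range")
  expect_error(make_benchmark_set(0), ">= 1")
})
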