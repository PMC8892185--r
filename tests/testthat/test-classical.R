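test_that("watershed recovers a clean solid sphere almost exactly", {
  ph <- solid_case(radius = 6, noise = 0, blur = 0)
  S <- watershed_segment(ph$volume, watershed_params(rough_threshold = -390))
  expect_gte(dice(ph$mask, S), 0.95)
  expect_identical(attr(S, "flag"), "ok")
  # the Otsu mode finds an equivalent threshold on this bimodal volume
  S2 <- watershed_segment(ph$volume, watershed_params())
  expect_gte(dice(ph$mask, S2), 0.95)
})

test_that("watershed output is a subset of the rough thresholded region", {
  ph <- solid_case(radius = 6, noise = 15, blur = 0.8, seed = 4)
  S <- watershed_segment(ph$volume, watershed_params(rough_threshold = -390))
  thr_fg <- ph$volume$data > attr(S, "rough_threshold")
  expect_true(all(thr_fg[S$data == 1L]))
})

test_that("two touching spheres split into two labels; center rule picks
          the sphere holding the VOI center", {
  tw <- touching_spheres_volume(radius = 6)
  S <- watershed_segment(tw$volume,
                         watershed_params(rough_threshold = -390,
                                          marker_min_distance = 6))
  expect_equal(attr(S, "n_labels"), 2)
  expect_gt(dice(tw$A, S), 0.9)
  expect_lt(dice(tw$B, S), 0.1)
  # largest rule is indifferent here (equal spheres) but must return one
  S2 <- watershed_segment(tw$volume,
                          watershed_params(rough_threshold = -390,
                                           marker_min_distance = 6,
                                           select = "largest"))
  expect_gt(sum(S2$data), 0)
})

test_that("an all-background volume yields an empty flagged mask", {
  vb <- vol3d(array(-800, c(16, 16, 8)))
  S <- watershed_segment(vb, watershed_params(rough_threshold = -390))
  expect_equal(sum(S$data), 0)
  expect_identical(attr(S, "flag"), "empty_rough_region")
})

test_that("watershed and graph cut are deterministic", {
  ph <- solid_case(radius = 5, noise = 20, blur = 0.8, seed = 9)
  p1 <- watershed_segment(ph$volume, watershed_params(rough_threshold = -390))
  p2 <- watershed_segment(ph$volume, watershed_params(rough_threshold = -390))
  expect_identical(p1$data, p2$data)
  gp <- graphcut_params(boundary_weight = 0.5)
  g1 <- graphcut_segment(ph$volume, gp)
  g2 <- graphcut_segment(ph$volume, gp)
  expect_identical(g1$data, g2$data)
})

test_that("graph-cut energy matches hand arithmetic on a 2-voxel volume", {
  # volume (I1, I2) = (-700, -50); fg N(20, 150), bg N(-800, 150),
  # boundary w * exp(-(I1-I2)^2 / (2 * 100^2))
  par <- graphcut_params(fg_mean = 20, bg_mean = -800, sigma_region = 150,
                         sigma_boundary = 100, boundary_weight = 2)
  v <- vol3d(array(c(-700, -50), c(2, 1, 1)))
  nll <- function(x, mu) -stats::dnorm(x, mu, 150, log = TRUE)
  shift <- function(x) min(nll(x, 20), nll(x, -800))
  cost <- function(x, lab) nll(x, if (lab == 1) 20 else -800) - shift(x)
  w12 <- 2 * exp(-(-700 - -50)^2 / (2 * 100^2))
  for (l1 in 0:1) for (l2 in 0:1) {
    e_hand <- cost(-700, l1) + cost(-50, l2) + (l1 != l2) * w12
    m <- mask3d(array(c(l1, l2), c(2, 1, 1)))
    expect_equal(graphcut_energy(m, v, par), e_hand)
  }
  # uniform image, uniform labeling: boundary term is zero
  vu <- vol3d(array(-300, c(3, 3, 2)))
  e_all_fg <- graphcut_energy(mask3d(array(1L, c(3, 3, 2))), vu, par)
  expect_equal(e_all_fg, 18 * cost(-300, 1))
  expect_error(graphcut_energy(mask3d(array(0L, c(2, 2, 2))), v, par),
               "shape")
})

test_that("with boundary weight zero the optimum is the voxelwise argmax", {
  set.seed(31)
  v <- vol3d(array(stats::runif(60, -900, 100), c(5, 4, 3)))
  par <- graphcut_params(boundary_weight = 0)
  S <- graphcut_segment(v, par)
  nll <- function(x, mu) -stats::dnorm(x, mu, par$sigma_region, log = TRUE)
  want <- array(as.integer(nll(v$data, par$fg_mean) <
                             nll(v$data, par$bg_mean)), dim(v$data))
  expect_identical(S$data, want)
})

test_that("returned energy attains the exhaustive minimum on tiny volumes", {
  set.seed(13)
  shapes <- list(c(2, 2, 1), c(2, 2, 2), c(3, 2, 1), c(2, 3, 1),
                 c(2, 4, 1), c(3, 2, 1))
  for (draw in 1:6) {
    dims <- shapes[[draw]]
    v <- vol3d(array(stats::rnorm(prod(dims), -400, 400), dims))
    par <- graphcut_params(fg_mean = stats::runif(1, -100, 100),
                           bg_mean = stats::runif(1, -900, -600),
                           sigma_region = stats::runif(1, 80, 300),
                           sigma_boundary = stats::runif(1, 50, 300),
                           boundary_weight = stats::runif(1, 0, 2))
    S <- graphcut_segment(v, par)
    n <- prod(dims)
    energies <- vapply(0:(2^n - 1), function(code) {
      lab <- as.integer(intToBits(code)[seq_len(n)] == 1)
      graphcut_energy(mask3d(array(lab, dims)), v, par)
    }, numeric(1))
    expect_equal(attr(S, "energy"), min(energies), tolerance = 1e-10)
  }
})

test_that("energy of the cut never exceeds sampled labelings at scale", {
  set.seed(17)
  ph <- solid_case(radius = 1.8, noise = 30, blur = 0.5, seed = 8,
                   shape = c(8L, 8L, 4L))
  par <- graphcut_params(boundary_weight = 1)
  S <- graphcut_segment(ph$volume, par)
  e <- attr(S, "energy")
  n <- prod(dim(ph$volume$data))
  for (i in 1:1000) {
    lab <- array(as.integer(stats::runif(n) > stats::runif(1)),
                 dim(ph$volume$data))
    expect_gte(graphcut_energy(mask3d(lab), ph$volume, par) + 1e-9, e)
  }
})

test_that("hard seeds are respected and infeasible seeds rejected", {
  ph <- solid_case(radius = 3, noise = 0, blur = 0,
                   shape = c(16L, 16L, 8L))
  par <- graphcut_params(boundary_weight = 0.5)
  all_vox <- as.matrix(expand.grid(x = 0:15, y = 0:15, z = 0:7))
  S <- graphcut_segment(ph$volume, par, bg_seeds = all_vox)
  expect_equal(sum(S$data), 0)
  ctr <- matrix(c(8, 8, 4), 1)
  S2 <- graphcut_segment(ph$volume, par, fg_seeds = ctr)
  expect_equal(S2$data[9, 9, 5], 1L)
  expect_error(graphcut_segment(ph$volume, par, fg_seeds = ctr,
                                bg_seeds = ctr), "infeasible")
})
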