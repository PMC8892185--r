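ns <- asNamespace("noduleseg")

small_cfg <- function(...) net_config(base_width = 2, seed = 1,
                                      dropout_rate = 0.2, ...)

test_that("residual unit with F zeroed returns its input bit-for-bit", {
  set.seed(1)
  x <- array(rnorm(5 * 5 * 4 * 3), c(5, 5, 4, 3))
  w <- residual_unit(x, width = 3, seed = 2)$weights
  for (nm in c("u.c1.W", "u.c1.b", "u.c2.W", "u.c2.b")) w[[nm]][] <- 0
  out <- residual_unit(x, width = 3, weights = w)$output
  expect_identical(out, x)
})

test_that("residual unit of zeros with zero biases is zeros", {
  x <- array(0, c(4, 4, 4, 2))
  w <- residual_unit(x, width = 2, seed = 3)$weights
  for (nm in grep("\\.b$", names(w), value = TRUE)) w[[nm]][] <- 0
  out <- residual_unit(x, width = 2, weights = w, norm = FALSE)$output
  expect_equal(out, x)
  expect_error(residual_unit(array(0, c(2, 2, 2, 1)), width = 2),
               "kernel support")
})

test_that("residual unit input gradient matches finite differences", {
  set.seed(4)
  d <- c(4L, 4L, 4L)
  cin <- 2L
  x <- matrix(rnorm(cin * prod(d)), cin)
  y <- matrix(as.numeric(runif(prod(d)) > 0.5), 1)
  ps <- ns$new_param_store()
  ns$with_seed(5, ns$init_res_unit(ps, "u", cin, 1L, TRUE))
  lossf <- function(xmat) {
    tape <- ns$new_tape()
    xin <- ns$nd_input(tape, xmat, d)
    h <- ns$res_unit_fwd(tape, ps, "u", xin, cin, 1L, 0, FALSE, TRUE,
                         FALSE)
    l <- ns$nd_dice_loss(tape, ns$nd_sigmoid(tape, h), y, eps = 1)
    list(tape = tape, node = l, xin = xin)
  }
  L <- lossf(x)
  ns$tape_backward(L$tape, L$node)
  an <- L$xin$grad
  for (i in sample(length(x), 8)) {
    eps <- 1e-6
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    fd <- (lossf(xp)$node$val - lossf(xm)$node$val) / (2 * eps)
    expect_equal(an[i], fd, tolerance = 1e-4)
  }
})

test_that("the nested model emits four full-resolution maps in [0,1]", {
  m <- build_nested_fcn(small_cfg())
  v <- vol3d(array(stats::runif(16 * 16 * 16), c(16, 16, 16)))
  p <- predict_probs(m, v)
  expect_length(p, 4)
  for (h in p) {
    expect_identical(dim(h), c(16L, 16L, 16L))
    expect_true(all(h >= 0 & h <= 1))
  }
  expect_error(predict_probs(m, vol3d(array(0.5, c(20, 20, 20)))),
               "divisible")
})

test_that("evaluation-mode forward passes are deterministic", {
  v <- vol3d(array(stats::runif(16 * 16 * 16), c(16, 16, 16)))
  for (build in list(build_nested_fcn, build_unet3d, build_segnet3d)) {
    m <- build(small_cfg())
    expect_identical(predict_probs(m, v), predict_probs(m, v))
  }
})

test_that("the nested model has strictly more parameters than the U-Net", {
  cfg <- small_cfg()
  expect_gt(ns$n_params(build_nested_fcn(cfg)$ps),
            ns$n_params(build_unet3d(cfg)$ps))
})

test_that("U-Net concatenates a skip at every resolution; SegNet none", {
  count_ops <- function(model, what) {
    tape <- ns$new_tape()
    ns$forward_model(model, tape,
                     array(stats::runif(16^3), c(16, 16, 16)))
    sum(vapply(seq_len(tape$n), function(i)
      identical(tape$nodes[[i]]$op, what), logical(1)))
  }
  mu <- build_unet3d(small_cfg())
  expect_equal(count_ops(mu, "concat"), 4)  # depth 5: 4 resolutions
  expect_equal(count_ops(mu, "unpool"), 0)
  msg <- build_segnet3d(small_cfg())
  expect_equal(count_ops(msg, "concat"), 0)
  expect_equal(count_ops(msg, "unpool"), 4)
  expect_equal(count_ops(msg, "upconv"), 0)
  mn <- build_nested_fcn(small_cfg())
  expect_equal(count_ops(mn, "concat"), 10)  # one per nested decoder node
})

test_that("index unpooling restores values only at recorded argmax", {
  set.seed(6)
  x <- matrix(rnorm(32), 1, 32)          # one channel on a 4x4x2 grid
  p <- ns$.maxpool2(x, c(4L, 4L, 2L))
  # hand trace: each 2x2x2 block contributes its max at the max's index
  blocks <- list(c(1, 2, 5, 6, 17, 18, 21, 22),
                 c(3, 4, 7, 8, 19, 20, 23, 24),
                 c(9, 10, 13, 14, 25, 26, 29, 30),
                 c(11, 12, 15, 16, 27, 28, 31, 32))
  for (b in seq_along(blocks)) {
    expect_equal(p$out[1, b], max(x[1, blocks[[b]]]))
    expect_equal(p$argmax[1, b] + 1L, blocks[[b]][which.max(x[1, blocks[[b]]])])
  }
  u <- ns$.maxunpool2(p$out, p$argmax, c(4L, 4L, 2L))
  expect_equal(sum(u != 0), 4)
  for (b in seq_along(blocks))
    expect_equal(u[1, p$argmax[1, b] + 1L], p$out[1, b])
})

test_that("binarization is strict and warns on unnormalized input", {
  m <- build_nested_fcn(small_cfg())
  m$ps$values <- lapply(m$ps$values, function(v) v * 0)  # all heads 0.5
  v <- vol3d(array(0.5, c(16, 16, 16)))
  expect_equal(sum(predict_mask(m, v, threshold = 0.5)$data), 0)
  expect_equal(sum(predict_mask(m, v, threshold = 0.4)$data), 16^3)
  expect_equal(sum(predict_mask(m, v, threshold = 0)$data), 16^3)
  expect_warning(predict_mask(m, vol3d(array(100, c(16, 16, 16)))),
                 "normalize")
})

test_that("gradient from the deep-supervision loss reaches e1", {
  m <- build_nested_fcn(net_config(base_width = 2, seed = 2,
                                   dropout_rate = 0))
  ph <- solid_case(radius = 6, seed = 1)
  arr <- normalize_volume(ph$volume)$data
  y <- matrix(as.numeric(ph$mask$data), 1)
  tape <- ns$new_tape()
  outs <- ns$forward_model(m, tape, arr, training = TRUE)
  loss <- ns$sample_loss_node(tape, outs, y, "nested", loss_config())
  ns$ps_zero_grads(m$ps)
  ns$tape_backward(tape, loss)
  g1 <- m$ps$grads[["x1_0.c1.W"]]
  expect_false(is.null(g1))
  expect_gt(max(abs(g1)), 0)
})

test_that("checkpoints round-trip arch, config and weights", {
  m <- build_unet3d(small_cfg())
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$arch, "unet")
  expect_identical(m2$config, m$config)
  expect_identical(m2$ps$values, m$ps$values)
  s <- model_summary(m)
  expect_true(s$n_params > 0)
  expect_identical(s$arch, "unet")
  expect_no_error(jsonlite::toJSON(s, auto_unbox = TRUE))
})
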