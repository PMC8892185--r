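test_that("folds partition the cases with near-equal test sets", {
  ids <- sprintf("c%02d", 1:10)
  folds <- make_folds(ids, k = 5, seed = 3)
  tests <- lapply(folds, `[[`, "test")
  expect_true(all(lengths(tests) == 2))
  expect_setequal(unlist(tests), ids)
  expect_equal(anyDuplicated(unlist(tests)), 0)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), ids)
  }
  expect_identical(make_folds(ids, 5, seed = 3), folds)
  expect_false(identical(make_folds(ids, 5, seed = 4), folds))
  expect_error(make_folds(ids, k = 11), "folds")
  # uneven split: sizes differ by at most one
  f7 <- make_folds(sprintf("c%d", 1:7), k = 3, seed = 1)
  expect_setequal(lengths(lapply(f7, `[[`, "test")), c(3, 2, 2))
})

test_that("zero training steps leave the model unchanged", {
  m <- build_unet3d(net_config(base_width = 2, seed = 1))
  ph <- solid_case(radius = 5, seed = 1)
  case <- list(volume = normalize_volume(ph$volume), mask = ph$mask)
  fit <- train_model(m, list(case),
                     train_config(max_steps = 0, batch_size = 1))
  expect_identical(fit$model$ps$values, m$ps$values)
  expect_length(fit$history, 0)
})

test_that("training is reproducible and decreases the loss", {
  ph <- solid_case(radius = 6, noise = 5, blur = 0.5, seed = 2)
  case <- list(volume = normalize_volume(ph$volume), mask = ph$mask)
  cfg <- train_config(lr = 2e-3, batch_size = 1, max_steps = 12, seed = 5,
                      augment = TRUE)
  m <- build_nested_fcn(net_config(base_width = 2, seed = 3))
  f1 <- train_model(m, list(case), cfg)
  f2 <- train_model(m, list(case), cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$ps$values, f2$model$ps$values)
  expect_length(f1$history, 12)
  expect_lt(mean(tail(f1$history, 3)), f1$history[1])
  # the original model was not touched
  expect_identical(m$ps$values, build_nested_fcn(
    net_config(base_width = 2, seed = 3))$ps$values)
})

test_that("classical cross-validation emits one record per case and
          ignores the fold structure", {
  set.seed(1)
  dataset <- make_benchmark_set(
    3, ranges = list(radius_vox = c(4, 6), edge_blur_sigma = c(0, 0.5),
                     noise_sigma = c(0, 10)),
    types = "solid", volume_shape = c(32, 32, 16), seed = 2)
  cfg2 <- train_config(folds = 2, seed = 1)
  cfg3 <- train_config(folds = 3, seed = 9)
  r2 <- cross_validate("watershed", dataset, cfg2,
                       method_params = watershed_params(
                         rough_threshold = -390))
  r3 <- cross_validate("watershed", dataset, cfg3,
                       method_params = watershed_params(
                         rough_threshold = -390))
  expect_equal(nrow(r2$records), 3)
  expect_equal(anyDuplicated(r2$records$case_id), 0)
  expect_identical(r2$records, r3$records)
  expect_equal(r2$summary$method, "watershed")
  expect_gte(r2$summary$ds_mean, 0.9)
  expect_error(cross_validate("voodoo", dataset, cfg2), "arg")
})

test_that("a trained nested model generalizes across folds at small scale", {
  dataset <- make_benchmark_set(
    4, ranges = list(radius_vox = c(4, 7), edge_blur_sigma = c(0, 0),
                     noise_sigma = c(2, 5)),
    types = "solid", volume_shape = c(32, 32, 16), seed = 6)
  cfg <- train_config(lr = 2e-3, batch_size = 2, max_steps = 40, seed = 4,
                      folds = 2, augment = FALSE)
  res <- cross_validate("nested", dataset, cfg,
                        net_cfg = net_config(base_width = 2, seed = 4))
  expect_equal(nrow(res$records), 4)
  expect_equal(anyDuplicated(res$records$case_id), 0)
  expect_true(all(res$records$ds >= 0 & res$records$ds <= 1))
  expect_gt(res$summary$ds_mean, 0.5)
})

test_that("a lambda sweep returns one Dice score per lambda", {
  tr <- list(solid_case(radius = 5, noise = 2, seed = 1),
             solid_case(radius = 6, noise = 2, seed = 2))
  te <- list(solid_case(radius = 5.5, noise = 2, seed = 3))
  cfg <- train_config(lr = 2e-3, batch_size = 1, max_steps = 15, seed = 2,
                      augment = FALSE)
  sw <- lambda_sweep(tr, te, lambdas = c(0, 1), config = cfg,
                     net_cfg = net_config(base_width = 2, seed = 2))
  expect_equal(sw$lambda, c(0, 1))
  expect_true(all(sw$ds >= 0 & sw$ds <= 1))
})
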