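#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param batch_size volumes per optimization step.
#' @param max_steps number of Adam updates.
#' @param seed seed controlling batch sampling, augmentation draws and
#'   dropout; two runs with the same seed and inputs produce identical
#'   loss histories.
#' @param folds number of cross-validation folds (>= 2).
#' @param loss a [loss_config].
#' @param augment draw a random augmentation operation (one of the 96)
#'   for every training volume at every step.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, batch_size = 2, max_steps = 100,
                         seed = 0, folds = 5, loss = loss_config(),
                         augment = TRUE) {
  if (lr <= 0) stop("`lr` must be positive")
  if (batch_size < 1) stop("`batch_size` must be >= 1")
  if (max_steps < 0) stop("`max_steps` must be >= 0")
  if (folds < 2) stop("`folds` must be >= 2")
  stopifnot(inherits(loss, "loss_config"))
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps), seed = as.integer(seed),
                 folds = as.integer(folds), loss = loss,
                 augment = isTRUE(augment)),
            class = "train_config")
}

#' Split case ids into cross-validation folds
#'
#' The k test sets partition the cases: pairwise disjoint, their union is
#' the full set, and sizes differ by at most one. Augmentation is applied
#' downstream only to training members, so no augmented variant of a case
#' ever appears in the fold where the case is tested.
#'
#' @param case_ids character vector of case identifiers.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return list of k elements, each `list(train = ..., test = ...)`.
#' @export
make_folds <- function(case_ids, k = 5, seed = 0) {
  n <- length(case_ids)
  if (k > n) stop("cannot make ", k, " folds from ", n, " cases")
  perm <- with_seed(seed, sample(case_ids))
  assign_fold <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f)
    list(train = perm[assign_fold != f], test = perm[assign_fold == f]))
}

# Deep-supervision loss (nested), combined loss (unet) or plain BCE
# (segnet) on the tape, for one sample.
sample_loss_node <- function(tape, outs, y, arch, lcf) {
  if (arch == "nested") {
    ls <- lapply(outs, function(o) {
      nd_wsum(tape, list(nd_bce(tape, o, y),
                         nd_dice_loss(tape, o, y, lcf$smooth_eps)),
              c(lcf$lam, 1 - lcf$lam))
    })
    nd_wsum(tape, ls, lcf$ds_weights)
  } else if (arch == "unet") {
    o <- outs[[1]]
    nd_wsum(tape, list(nd_bce(tape, o, y),
                       nd_dice_loss(tape, o, y, lcf$smooth_eps)),
            c(lcf$lam, 1 - lcf$lam))
  } else {
    nd_bce(tape, outs[[1]], y)
  }
}

#' Train a segmentation network
#'
#' Mini-batch Adam on the architecture's training loss: the
#' deep-supervision aggregate of the lambda-weighted BCE+Dice loss for the
#' nested model, the plain combined loss for the U-Net, and cross-entropy
#' for the SegNet. Volumes are expected normalized to \[0, 1\]; when
#' `config$augment` is TRUE each sampled volume receives a random one of
#' the 96 geometric augmentation operations.
#'
#' The input model is not modified; a trained copy is returned.
#'
#' @param model a `seg_model`.
#' @param cases list of cases, each with elements `volume` ([vol3d],
#'   normalized) and `mask` ([mask3d]); all shapes equal.
#' @param config a [train_config].
#' @return list with `model` (trained copy) and `history` (numeric vector
#'   of per-step losses, length `max_steps`).
#' @export
train_model <- function(model, cases, config = train_config()) {
  stopifnot(inherits(model, "seg_model"), inherits(config, "train_config"))
  if (!length(cases)) stop("no training cases")
  shp <- dim(cases[[1]]$volume$data)
  for (cs in cases)
    if (!identical(dim(cs$volume$data), shp) ||
        !identical(dim(cs$mask$data), shp))
      stop("all training volumes and masks must share one shape")
  check_divisible(shp, model$config$depth)
  model <- new_seg_model(model$arch, model$config, ps_clone(model$ps))
  if (config$max_steps == 0L)
    return(list(model = model, history = numeric(0)))
  ops <- augment_ops()
  lcf <- config$loss
  st <- new_adam(model$ps, lr = config$lr)
  history <- numeric(config$max_steps)
  with_seed(config$seed, {
    for (step in seq_len(config$max_steps)) {
      idx <- sample.int(length(cases), config$batch_size, replace = TRUE)
      tape <- new_tape()
      ps_zero_grads(model$ps)
      batch_losses <- vector("list", length(idx))
      for (b in seq_along(idx)) {
        cs <- cases[[idx[b]]]
        vol <- cs$volume; msk <- cs$mask
        if (config$augment) {
          op <- ops[sample.int(nrow(ops), 1), ]
          vol <- apply_augment_op(vol, op, fill = 0)
          msk <- apply_augment_op(msk, op)
        }
        outs <- forward_model(model, tape, vol$data, training = TRUE)
        y <- matrix(as.numeric(msk$data), nrow = 1)
        batch_losses[[b]] <- sample_loss_node(tape, outs, y, model$arch,
                                              lcf)
      }
      total <- nd_wsum(tape, batch_losses,
                       rep(1 / length(idx), length(idx)))
      if (!is.finite(total$val))
        stop("non-finite loss at step ", step)
      tape_backward(tape, total)
      adam_step(st, model$ps)
      history[step] <- total$val
    }
  })
  list(model = model, history = history)
}

build_model_for <- function(method, net_cfg) {
  switch(method,
         nested = build_nested_fcn(net_cfg),
         unet = build_unet3d(net_cfg),
         segnet = build_segnet3d(net_cfg),
         stop("unknown learning method: ", method))
}

#' Cross-validated comparison of segmentation methods
#'
#' Evaluates one method under k-fold cross-validation on a phantom
#' benchmark. Learning methods (`nested`, `unet`, `segnet`) are trained
#' per fold on the (augmented) training cases and evaluated on the
#' held-out cases; classical methods (`watershed`, `graphcut`) have no
#' training phase and are simply applied to every case. Every case is
#' evaluated exactly once.
#'
#' @param method one of `"nested"`, `"unet"`, `"segnet"`, `"watershed"`,
#'   `"graphcut"`.
#' @param dataset list of cases from [make_benchmark_set()] (elements
#'   `volume`, `mask`, `case_id`); raw HU-like intensities.
#' @param config a [train_config] (learning methods).
#' @param net_cfg a [net_config] (learning methods).
#' @param win [intensity_window] used to normalize network inputs.
#' @param method_params a [watershed_params] or [graphcut_params] for the
#'   classical methods (defaults chosen from the phantom intensity scale).
#' @param threshold binarization threshold for network outputs.
#' @return list with `records` (per-case data.frame) and `summary`
#'   (per-method [summarize_eval()] row).
#' @export
cross_validate <- function(method = c("nested", "unet", "segnet",
                                      "watershed", "graphcut"),
                           dataset, config = train_config(),
                           net_cfg = net_config(base_width = 4, seed =
                                                  config$seed),
                           win = intensity_window(-1000, 200),
                           method_params = NULL, threshold = 0.5) {
  method <- match.arg(method)
  if (!length(dataset)) stop("empty dataset")
  ids <- vapply(dataset, function(cs)
    cs$case_id %||% stop("dataset cases need case_id"), character(1))
  names(dataset) <- ids
  records <- list()
  if (method %in% c("watershed", "graphcut")) {
    for (cs in dataset) {
      S <- if (method == "watershed") {
        watershed_segment(cs$volume,
                          method_params %||% watershed_params())
      } else {
        graphcut_segment(cs$volume, method_params %||% graphcut_params())
      }
      records[[cs$case_id]] <- eval_record(cs$case_id, method, cs$mask, S)
    }
  } else {
    folds <- make_folds(ids, config$folds, config$seed)
    norm_cases <- lapply(dataset, function(cs)
      list(volume = normalize_volume(cs$volume, win), mask = cs$mask,
           case_id = cs$case_id))
    for (f in seq_along(folds)) {
      fit <- train_model(build_model_for(method, net_cfg),
                         norm_cases[folds[[f]]$train], config)
      for (id in folds[[f]]$test) {
        S <- predict_mask(fit$model, norm_cases[[id]]$volume, threshold)
        records[[id]] <- eval_record(id, method, dataset[[id]]$mask, S)
      }
    }
  }
  records <- do.call(rbind, records[ids[ids %in% names(records)]])
  rownames(records) <- NULL
  list(records = records, summary = summarize_eval(records))
}

#' Sweep the loss mixing coefficient lambda
#'
#' Trains the nested model at each lambda on a training set and records
#' mean Dice on a held-out set: the under-extraction regime at lambda = 0
#' (pure Dice loss) and the over-extraction regime at lambda = 1 (pure
#' BCE) bracket the tuned optimum.
#'
#' @param train_cases,test_cases lists of cases (raw intensities).
#' @param lambdas lambda values to evaluate.
#' @param config a [train_config]; its `loss$lam` is overridden.
#' @param net_cfg a [net_config].
#' @param win normalization [intensity_window].
#' @return data.frame with columns `lambda` and `ds`.
#' @export
lambda_sweep <- function(train_cases, test_cases,
                         lambdas = c(0, 0.25, 0.5, 0.75, 1),
                         config = train_config(),
                         net_cfg = net_config(base_width = 4,
                                              seed = config$seed),
                         win = intensity_window(-1000, 200)) {
  norm <- function(cs) list(volume = normalize_volume(cs$volume, win),
                            mask = cs$mask, case_id = cs$case_id)
  tr <- lapply(train_cases, norm)
  te <- lapply(test_cases, norm)
  res <- lapply(lambdas, function(lam) {
    cfg <- config
    cfg$loss$lam <- lam
    fit <- train_model(build_model_for("nested", net_cfg), tr, cfg)
    ds_vals <- vapply(te, function(cs)
      dice(cs$mask, predict_mask(fit$model, cs$volume)), numeric(1))
    data.frame(lambda = lam, ds = mean(ds_vals))
  })
  do.call(rbind, res)
}
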