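#' Network configuration
#'
#' Architecture hyperparameters shared by the three segmentation networks.
#' Channel widths double per level (`base_width * 2^level`) unless given
#' explicitly; the reference configuration uses base width 32
#' (32/64/128/256/512) and the desk-scale test configuration base width 4.
#'
#' @param base_width channels at the finest level.
#' @param depth number of resolution levels; input spatial dims must be
#'   divisible by `2^(depth-1)`.
#' @param in_channels input channels (1 for CT volumes).
#' @param dropout_rate spatial dropout probability in \[0, 1); applied
#'   before each block's final convolution, except in the first encoder
#'   block.
#' @param widths optional explicit channel widths (length `depth`).
#' @param norm use per-channel (instance) normalization inside blocks.
#' @param seed RNG seed for weight initialization.
#' @return an object of class `net_config`.
#' @export
net_config <- function(base_width = 32, depth = 5, in_channels = 1,
                       dropout_rate = 0.2, widths = NULL, norm = TRUE,
                       seed = 0) {
  if (depth < 2) stop("`depth` must be >= 2")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must be in [0, 1)")
  if (is.null(widths)) widths <- base_width * 2^(0:(depth - 1))
  if (length(widths) != depth) stop("`widths` must have length `depth`")
  structure(list(base_width = base_width, depth = depth,
                 in_channels = in_channels, dropout_rate = dropout_rate,
                 widths = as.integer(widths), norm = isTRUE(norm),
                 seed = as.integer(seed)),
            class = "net_config")
}

check_divisible <- function(dims, depth) {
  div <- 2^(depth - 1)
  if (any(dims %% div != 0))
    stop("input shape ", paste(dims, collapse = "x"),
         " must be divisible by ", div, " in every axis (depth ", depth, ")")
  invisible(div)
}

# ---- residual unit ----------------------------------------------------

init_res_unit <- function(ps, name, cin, w, norm) {
  if (norm) init_norm(ps, paste0(name, ".n1"), cin)
  init_conv3(ps, paste0(name, ".c1"), cin, w)
  if (norm) init_norm(ps, paste0(name, ".n2"), w)
  init_conv3(ps, paste0(name, ".c2"), w, w)
  if (cin != w) init_conv1(ps, paste0(name, ".proj"), cin, w)
}

# Pre-activation residual unit: out = shortcut(x) + F(x) with
# F = norm-relu-conv3, norm-relu-[dropout]-conv3. With F's weights and
# biases zeroed and matching widths, out == x exactly.
res_unit_fwd <- function(tape, ps, name, x, cin, w, dropout_rate,
                         use_dropout, norm, training) {
  p <- function(suffix) nd_param(tape, ps, paste0(name, suffix))
  h <- x
  if (norm) h <- nd_instnorm(tape, h, p(".n1.g"), p(".n1.b"))
  h <- nd_relu(tape, h)
  h <- nd_conv3(tape, h, p(".c1.W"), p(".c1.b"))
  if (norm) h <- nd_instnorm(tape, h, p(".n2.g"), p(".n2.b"))
  h <- nd_relu(tape, h)
  if (use_dropout && dropout_rate > 0)
    h <- nd_dropout_ch(tape, h, dropout_rate, training)
  h <- nd_conv3(tape, h, p(".c2.W"), p(".c2.b"))
  s <- if (cin != w) nd_conv1(tape, x, p(".proj.W"), p(".proj.b")) else x
  nd_add(tape, h, s)
}

#' Apply a residual unit to a feature grid
#'
#' A standalone functional form of the building block used by the nested
#' network: \eqn{H(x) = F(x) + x}, where F is two 3x3x3 convolutions with
#' per-channel normalization and rectification (pre-activation ordering)
#' and the skip path carries the input unchanged (a 1x1x1 projection is
#' inserted only when the channel widths differ). Zeroing F's weights
#' therefore returns the input exactly.
#'
#' @param x 4D numeric array (nx, ny, nz, channels).
#' @param width output channel count.
#' @param dropout_rate spatial dropout probability (training only).
#' @param weights optional named list of parameter matrices (names as
#'   produced by the initializer: `u.n1.g`, `u.c1.W`, ...); random
#'   He-initialized weights drawn under `seed` otherwise.
#' @param norm apply per-channel normalization inside F.
#' @param training enable dropout.
#' @param seed RNG seed for initialization (and dropout).
#' @return list with `output` (4D array, same spatial shape, `width`
#'   channels) and `weights` (the parameter list actually used).
#' @export
residual_unit <- function(x, width, dropout_rate = 0, weights = NULL,
                          norm = TRUE, training = FALSE, seed = 0) {
  d <- dim(x)
  if (length(d) != 4L) stop("`x` must be a 4D array (nx, ny, nz, channels)")
  if (any(d[1:3] < 3L))
    stop("spatial dims must be at least the 3x3x3 kernel support")
  cin <- d[4]
  ps <- new_param_store()
  with_seed(seed, init_res_unit(ps, "u", cin, width, norm))
  if (!is.null(weights)) {
    missing <- setdiff(names(ps$values), names(weights))
    if (length(missing))
      stop("missing residual-unit weights: ", paste(missing, collapse = ", "))
    ps$values <- weights[names(ps$values)]
  }
  xmat <- t(matrix(x, ncol = cin))        # channels x voxels
  tape <- new_tape()
  xin <- nd_input(tape, xmat, d[1:3])
  out <- with_seed(seed + 1L,
                   res_unit_fwd(tape, ps, "u", xin, cin, width,
                                dropout_rate, use_dropout = TRUE,
                                norm = norm, training = training))
  list(output = array(t(out$val), c(d[1:3], width)), weights = ps$values)
}

# ---- builders ---------------------------------------------------------

new_seg_model <- function(arch, config, ps) {
  structure(list(arch = arch, config = config, ps = ps),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> %s, depth %d, widths %s, %s parameters\n",
              x$arch, x$config$depth,
              paste(x$config$widths, collapse = "/"),
              format(n_params(x$ps), big.mark = ",")))
  invisible(x)
}

#' Build the nested residual 3D fully-convolutional network
#'
#' The proposed segmenter: a single encoder (blocks e1..e5 at five
#' resolution levels, 2x2x2 max-pool downsampling) whose feature maps are
#' decoded by a nested family of decoder chains. For every depth j = 2..5
#' a chain of j-1 upsampling blocks (transposed convolution) terminates in
#' an output head, giving four full-resolution region maps o1..o4; each
#' decoder node concatenates all same-resolution predecessor features
#' (dense nested skips) with the upsampled deeper feature. Every block is
#' a residual unit; spatial dropout precedes each block's final
#' convolution except in e1. The deep heads receive direct gradient
#' (deep supervision), which together with the residual shortcuts keeps
#' gradients alive in the deepest blocks; o4 (the deepest chain's head)
#' is the designated inference output.
#'
#' @param config a [net_config].
#' @return a `seg_model` object.
#' @export
build_nested_fcn <- function(config = net_config()) {
  stopifnot(inherits(config, "net_config"))
  D <- config$depth; w <- config$widths
  ps <- new_param_store()
  with_seed(config$seed, {
    for (l in seq_len(D))
      init_res_unit(ps, sprintf("x%d_0", l),
                    if (l == 1) config$in_channels else w[l - 1],
                    w[l], config$norm)
    for (s in seq_len(D - 1))
      for (l in seq_len(D - s)) {
        init_upconv2(ps, sprintf("up%d_%d", l, s), w[l + 1], w[l])
        init_res_unit(ps, sprintf("x%d_%d", l, s), (s + 1) * w[l], w[l],
                      config$norm)
      }
    for (j in seq_len(D - 1)) init_conv1(ps, sprintf("o%d", j), w[1], 1L)
  })
  new_seg_model("nested", config, ps)
}

forward_nested <- function(model, tape, xin, training) {
  cf <- model$config; ps <- model$ps
  D <- cf$depth; w <- cf$widths
  X <- vector("list", D)
  for (l in seq_len(D)) X[[l]] <- vector("list", D)
  cur <- xin
  for (l in seq_len(D)) {
    if (l > 1) cur <- nd_pool2(tape, cur)
    cin <- if (l == 1) cf$in_channels else w[l - 1]
    cur <- res_unit_fwd(tape, ps, sprintf("x%d_0", l), cur, cin, w[l],
                        cf$dropout_rate, use_dropout = l > 1, cf$norm,
                        training)
    X[[l]][[1]] <- cur
  }
  for (s in seq_len(D - 1))
    for (l in seq_len(D - s)) {
      up <- nd_upconv2(tape, X[[l + 1]][[s]],
                       nd_param(tape, ps, sprintf("up%d_%d.W", l, s)),
                       nd_param(tape, ps, sprintf("up%d_%d.b", l, s)),
                       cout = w[l])
      inputs <- c(X[[l]][seq_len(s)], list(up))
      X[[l]][[s + 1]] <- res_unit_fwd(tape, ps, sprintf("x%d_%d", l, s),
                                      nd_concat(tape, inputs),
                                      (s + 1) * w[l], w[l],
                                      cf$dropout_rate, use_dropout = TRUE,
                                      cf$norm, training)
    }
  lapply(seq_len(D - 1), function(j) {
    nd_sigmoid(tape, nd_conv1(tape, X[[1]][[j + 1]],
                              nd_param(tape, ps, sprintf("o%d.W", j)),
                              nd_param(tape, ps, sprintf("o%d.b", j))))
  })
}

# Plain double-convolution block (conv-norm-relu twice) for the U-Net and
# SegNet baselines.
init_plain_block <- function(ps, name, cin, w, norm) {
  init_conv3(ps, paste0(name, ".c1"), cin, w)
  if (norm) init_norm(ps, paste0(name, ".n1"), w)
  init_conv3(ps, paste0(name, ".c2"), w, w)
  if (norm) init_norm(ps, paste0(name, ".n2"), w)
}

plain_block_fwd <- function(tape, ps, name, x, norm, dropout_rate,
                            use_dropout, training) {
  p <- function(suffix) nd_param(tape, ps, paste0(name, suffix))
  h <- nd_conv3(tape, x, p(".c1.W"), p(".c1.b"))
  if (norm) h <- nd_instnorm(tape, h, p(".n1.g"), p(".n1.b"))
  h <- nd_relu(tape, h)
  if (use_dropout && dropout_rate > 0)
    h <- nd_dropout_ch(tape, h, dropout_rate, training)
  h <- nd_conv3(tape, h, p(".c2.W"), p(".c2.b"))
  if (norm) h <- nd_instnorm(tape, h, p(".n2.g"), p(".n2.b"))
  nd_relu(tape, h)
}

#' Build the 3D U-Net baseline
#'
#' Single encoder-decoder with skip concatenations: encoder features at
#' each resolution are concatenated into the decoder path, and upsampling
#' uses transposed convolutions. One output map.
#'
#' @param config a [net_config].
#' @return a `seg_model` object.
#' @export
build_unet3d <- function(config = net_config()) {
  stopifnot(inherits(config, "net_config"))
  D <- config$depth; w <- config$widths
  ps <- new_param_store()
  with_seed(config$seed, {
    for (l in seq_len(D))
      init_plain_block(ps, sprintf("e%d", l),
                       if (l == 1) config$in_channels else w[l - 1], w[l],
                       config$norm)
    for (l in seq_len(D - 1)) {
      init_upconv2(ps, sprintf("du%d", l), w[l + 1], w[l])
      init_plain_block(ps, sprintf("d%d", l), 2L * w[l], w[l], config$norm)
    }
    init_conv1(ps, "out", w[1], 1L)
  })
  new_seg_model("unet", config, ps)
}

forward_unet <- function(model, tape, xin, training) {
  cf <- model$config; ps <- model$ps
  D <- cf$depth; w <- cf$widths
  enc <- vector("list", D)
  cur <- xin
  for (l in seq_len(D)) {
    if (l > 1) cur <- nd_pool2(tape, cur)
    cur <- plain_block_fwd(tape, ps, sprintf("e%d", l), cur, cf$norm,
                           cf$dropout_rate, use_dropout = l > 1, training)
    enc[[l]] <- cur
  }
  for (l in seq(D - 1, 1)) {
    up <- nd_upconv2(tape, cur,
                     nd_param(tape, ps, sprintf("du%d.W", l)),
                     nd_param(tape, ps, sprintf("du%d.b", l)), cout = w[l])
    cur <- plain_block_fwd(tape, ps, sprintf("d%d", l),
                           nd_concat(tape, list(enc[[l]], up)), cf$norm,
                           cf$dropout_rate, use_dropout = TRUE, training)
  }
  list(nd_sigmoid(tape, nd_conv1(tape, cur,
                                 nd_param(tape, ps, "out.W"),
                                 nd_param(tape, ps, "out.b"))))
}

#' Build the 3D SegNet baseline
#'
#' Encoder-decoder without skip connections: the encoder records the
#' argmax positions of each max-pooling step and the decoder restores
#' resolution by index unpooling (values are placed back at the recorded
#' positions, zeros elsewhere). One output map.
#'
#' @param config a [net_config].
#' @return a `seg_model` object.
#' @export
build_segnet3d <- function(config = net_config()) {
  stopifnot(inherits(config, "net_config"))
  D <- config$depth; w <- config$widths
  ps <- new_param_store()
  with_seed(config$seed, {
    for (l in seq_len(D))
      init_plain_block(ps, sprintf("e%d", l),
                       if (l == 1) config$in_channels else w[l - 1], w[l],
                       config$norm)
    for (l in seq(D - 1, 1))
      init_plain_block(ps, sprintf("g%d", l), w[l + 1], w[l], config$norm)
    init_plain_block(ps, "g0", w[1], w[1], config$norm)
    init_conv1(ps, "out", w[1], 1L)
  })
  new_seg_model("segnet", config, ps)
}

forward_segnet <- function(model, tape, xin, training) {
  cf <- model$config; ps <- model$ps
  D <- cf$depth; w <- cf$widths
  pools <- vector("list", D - 1)
  cur <- xin
  for (l in seq_len(D)) {
    if (l > 1) {
      pools[[l - 1]] <- nd_pool2(tape, cur)
      cur <- pools[[l - 1]]
    }
    cur <- plain_block_fwd(tape, ps, sprintf("e%d", l), cur, cf$norm,
                           cf$dropout_rate, use_dropout = l > 1, training)
  }
  for (l in seq(D - 1, 1)) {
    cur <- plain_block_fwd(tape, ps, sprintf("g%d", l), cur, cf$norm,
                           cf$dropout_rate, use_dropout = TRUE, training)
    cur <- nd_unpool2(tape, cur, pools[[l]])
  }
  cur <- plain_block_fwd(tape, ps, "g0", cur, cf$norm, cf$dropout_rate,
                         use_dropout = TRUE, training)
  list(nd_sigmoid(tape, nd_conv1(tape, cur,
                                 nd_param(tape, ps, "out.W"),
                                 nd_param(tape, ps, "out.b"))))
}

# Run a model forward on a raw 3D array; returns list of probability
# map nodes (length 4 for the nested model, 1 for the baselines).
forward_model <- function(model, tape, arr, training = FALSE) {
  d <- dim(arr)
  check_divisible(d, model$config$depth)
  xin <- nd_input(tape, matrix(as.vector(arr), nrow = 1), as.integer(d))
  switch(model$arch,
         nested = forward_nested(model, tape, xin, training),
         unet = forward_unet(model, tape, xin, training),
         segnet = forward_segnet(model, tape, xin, training),
         stop("unknown architecture: ", model$arch))
}

#' Predict probability maps for a volume
#'
#' Runs the network in evaluation mode (dropout disabled; normalization
#' statistics are per-sample, so inference is deterministic).
#'
#' @param model a `seg_model`.
#' @param volume a normalized [vol3d] (values in \[0, 1\]).
#' @return list of 3D probability arrays (4 heads for the nested model,
#'   1 for the baselines); the last element is the designated inference
#'   output.
#' @export
predict_probs <- function(model, volume) {
  stopifnot(inherits(model, "seg_model"), inherits(volume, "vol3d"))
  arr <- volume$data
  rng <- range(arr)
  if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
    warning("input intensities outside [0, 1]; did you forget ",
            "normalize_volume()?")
  tape <- new_tape()
  outs <- forward_model(model, tape, arr, training = FALSE)
  lapply(outs, function(o) array(as.vector(o$val), dim(arr)))
}

#' Predict a binary mask for a volume
#'
#' Thresholds the designated output map (o4 for the nested model) at
#' `threshold`, strictly: a voxel is foreground iff its probability is
#' `> threshold`.
#'
#' @param model a `seg_model`.
#' @param volume a normalized [vol3d].
#' @param threshold binarization threshold in \[0, 1\].
#' @return a [mask3d] aligned with `volume`.
#' @export
predict_mask <- function(model, volume, threshold = 0.5) {
  probs <- predict_probs(model, volume)
  p <- probs[[length(probs)]]
  mask3d(array(as.integer(p > threshold), dim(p)),
         volume$spacing, volume$origin)
}

#' Architecture summary
#'
#' @param model a `seg_model`.
#' @return a list (JSON-serializable) with the architecture name, widths,
#'   parameter names/shapes and total parameter count.
#' @export
model_summary <- function(model) {
  stopifnot(inherits(model, "seg_model"))
  shapes <- lapply(model$ps$values, function(v)
    if (is.matrix(v)) dim(v) else length(v))
  list(arch = model$arch, depth = model$config$depth,
       widths = model$config$widths,
       dropout_rate = model$config$dropout_rate,
       norm = model$config$norm,
       n_params = n_params(model$ps),
       n_heads = if (model$arch == "nested") model$config$depth - 1 else 1L,
       params = shapes)
}

#' Save / load model checkpoints
#'
#' A checkpoint holds the architecture name, the full [net_config]
#' (including the initialization seed) and all weights in one file.
#'
#' @param model a `seg_model`.
#' @param path file path (.rds).
#' @return `load_model` returns the restored `seg_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(list(arch = model$arch, config = model$config,
               values = model$ps$values), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  ps <- new_param_store()
  ps$values <- obj$values
  new_seg_model(obj$arch, obj$config, ps)
}
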