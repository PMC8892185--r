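# Reverse-mode differentiation engine for small volumetric networks.
#
# Feature maps are C x V matrices (channels by voxels, voxel index
# x-fastest) with the spatial dims carried alongside. A "tape" records
# operation nodes in creation order (a topological order by construction);
# the backward pass walks it in reverse. Convolutions are im2col (compiled
# kernel) plus BLAS matrix products.

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

tape_push <- function(tape, nd) {
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

new_node <- function(tape, val, dims = NULL, parents = list(),
                     backfn = NULL, op = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$op <- op
  nd$val <- val
  nd$dims <- dims
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  tape_push(tape, nd)
}

accum_grad <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Run the backward pass from a scalar loss node.
tape_backward <- function(tape, root) {
  root$grad <- 1.0
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd)
  }
  invisible(NULL)
}

# ---- parameter store --------------------------------------------------

new_param_store <- function() {
  ps <- new.env(parent = emptyenv())
  ps$values <- list()
  ps$grads <- list()
  ps
}

ps_add <- function(ps, name, value) {
  ps$values[[name]] <- value
  invisible(NULL)
}

ps_zero_grads <- function(ps) {
  ps$grads <- list()
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ps_clone <- function(ps) {
  ps2 <- new_param_store()
  ps2$values <- ps$values
  ps2
}

n_params <- function(ps) sum(vapply(ps$values, length, numeric(1)))

# Leaf nodes -----------------------------------------------------------

nd_input <- function(tape, val, dims) new_node(tape, val, dims)

nd_param <- function(tape, ps, name) {
  new_node(tape, ps$values[[name]], NULL, list(),
           backfn = function(nd) {
             g <- ps$grads[[name]]
             ps$grads[[name]] <- if (is.null(g)) nd$grad else g + nd$grad
           })
}

# Convolution ops ------------------------------------------------------

# 3x3x3 convolution, zero padding 1. W: Cout x (27*Cin); b: Cout.
nd_conv3 <- function(tape, x, Wn, bn) {
  col <- .vol2col(x$val, x$dims)
  val <- Wn$val %*% col + bn$val
  nd <- new_node(tape, val, x$dims, list(x, Wn, bn), backfn = function(nd) {
    dY <- nd$grad
    accum_grad(Wn, dY %*% t(nd$cache_col))
    accum_grad(bn, rowSums(dY))
    accum_grad(x, .col2vol(crossprod(Wn$val, dY), x$dims))
  })
  nd$cache_col <- col
  nd
}

# 1x1x1 convolution (channel mixing). W: Cout x Cin; b: Cout.
nd_conv1 <- function(tape, x, Wn, bn) {
  val <- Wn$val %*% x$val + bn$val
  new_node(tape, val, x$dims, list(x, Wn, bn), backfn = function(nd) {
    dY <- nd$grad
    accum_grad(Wn, tcrossprod(dY, x$val))
    accum_grad(bn, rowSums(dY))
    accum_grad(x, crossprod(Wn$val, dY))
  })
}

# Column permutation sending input voxel v, offset o (2x2x2 block) to the
# doubled-resolution output voxel; cached per spatial shape.
upconv_perm <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  v <- 0:(nx * ny * nz - 1)
  xi <- v %% nx; yi <- (v %/% nx) %% ny; zi <- v %/% (nx * ny)
  perm <- integer(8 * length(v))
  o <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    o <- o + 1L
    u <- (2 * xi + dx) + (2 * nx) * ((2 * yi + dy) + (2 * ny) * (2 * zi + dz))
    perm[(v * 8L) + o] <- u + 1L
  }
  perm
}

# Transposed convolution, kernel 2x2x2, stride 2 (blocks do not overlap).
# W: (8*Cout) x Cin, offset-major blocks of Cout rows; b: Cout.
nd_upconv2 <- function(tape, x, Wn, bn, cout) {
  dims_out <- x$dims * 2L
  y8 <- Wn$val %*% x$val                    # (8*Cout) x Vin
  Y <- matrix(y8, nrow = cout)              # Cout x (8*Vin), o fastest
  perm <- upconv_perm(x$dims)
  val <- matrix(0, cout, prod(dims_out))
  val[, perm] <- Y
  val <- val + bn$val
  new_node(tape, val, dims_out, list(x, Wn, bn), op = "upconv",
           backfn = function(nd) {
    dY8 <- matrix(nd$grad[, perm, drop = FALSE], nrow = 8 * cout)
    accum_grad(Wn, tcrossprod(dY8, x$val))
    accum_grad(bn, rowSums(nd$grad))
    accum_grad(x, crossprod(Wn$val, dY8))
  })
}

# Pooling --------------------------------------------------------------

nd_pool2 <- function(tape, x) {
  p <- .maxpool2(x$val, x$dims)
  nd <- new_node(tape, p$out, x$dims %/% 2L, list(x), op = "pool",
                 backfn = function(nd) {
    accum_grad(x, .maxunpool2(nd$grad, nd$argmax, x$dims))
  })
  nd$argmax <- p$argmax
  nd
}

# Index unpooling to the argmax positions recorded by `pool_node`.
nd_unpool2 <- function(tape, x, pool_node) {
  dims_out <- pool_node$dims * 2L
  val <- .maxunpool2(x$val, pool_node$argmax, dims_out)
  arg <- pool_node$argmax
  new_node(tape, val, dims_out, list(x), op = "unpool",
           backfn = function(nd) {
    g <- nd$grad
    dx <- matrix(0, nrow(x$val), ncol(x$val))
    for (c in seq_len(nrow(x$val)))
      dx[c, ] <- g[c, arg[c, ] + 1L]
    accum_grad(x, dx)
  })
}

# Pointwise ops --------------------------------------------------------

nd_relu <- function(tape, x) {
  val <- x$val
  val[val < 0] <- 0
  new_node(tape, val, x$dims, list(x), backfn = function(nd) {
    accum_grad(x, nd$grad * (x$val > 0))
  })
}

nd_sigmoid <- function(tape, x) {
  val <- 1 / (1 + exp(-x$val))
  new_node(tape, val, x$dims, list(x), backfn = function(nd) {
    accum_grad(x, nd$grad * nd$val * (1 - nd$val))
  })
}

# Per-sample, per-channel normalization (instance normalization): each
# channel is standardized over its voxels, then scaled/shifted by learned
# gamma/beta. Batch-size independent and deterministic at inference.
nd_instnorm <- function(tape, x, gn, bn_, eps = 1e-5) {
  V <- ncol(x$val)
  mu <- rowMeans(x$val)
  xc <- x$val - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  val <- xhat * gn$val + bn_$val
  nd <- new_node(tape, val, x$dims, list(x, gn, bn_),
                 backfn = function(nd) {
    dy <- nd$grad
    accum_grad(gn, rowSums(dy * nd$cache_xhat))
    accum_grad(bn_, rowSums(dy))
    dxhat <- dy * gn$val
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * nd$cache_xhat)
    accum_grad(x, istd * (dxhat - m1 - nd$cache_xhat * m2))
  })
  nd$cache_xhat <- xhat
  nd
}

# Spatial (channel-wise) dropout: whole channels are zeroed with
# probability p during training and the rest rescaled by 1/(1-p).
nd_dropout_ch <- function(tape, x, p, training) {
  if (!training || p <= 0) return(x)
  keep <- stats::rbinom(nrow(x$val), 1, 1 - p) / (1 - p)
  val <- x$val * keep
  new_node(tape, val, x$dims, list(x), backfn = function(nd) {
    accum_grad(x, nd$grad * keep)
  })
}

# Structure ops --------------------------------------------------------

nd_concat <- function(tape, xs) {
  val <- do.call(rbind, lapply(xs, function(n) n$val))
  rows <- vapply(xs, function(n) nrow(n$val), integer(1))
  ends <- cumsum(rows)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  new_node(tape, val, xs[[1]]$dims, xs, op = "concat", backfn = function(nd) {
    for (i in seq_along(xs))
      accum_grad(xs[[i]], nd$grad[starts[i]:ends[i], , drop = FALSE])
  })
}

nd_add <- function(tape, x, y) {
  new_node(tape, x$val + y$val, x$dims, list(x, y), backfn = function(nd) {
    accum_grad(x, nd$grad)
    accum_grad(y, nd$grad)
  })
}

# Loss ops (scalar-valued) ---------------------------------------------

nd_bce <- function(tape, x, y) {
  p <- pmin(pmax(x$val, PROB_CLIP), 1 - PROB_CLIP)
  N <- length(p)
  val <- -sum(y * log(p) + (1 - y) * log(1 - p)) / N
  new_node(tape, val, NULL, list(x), backfn = function(nd) {
    inside <- x$val > PROB_CLIP & x$val < 1 - PROB_CLIP
    g <- (-(y / p) + (1 - y) / (1 - p)) / N
    accum_grad(x, nd$grad * g * inside)
  })
}

nd_dice_loss <- function(tape, x, y, eps = 1.0) {
  s <- 2 * sum(x$val * y) + eps
  t_ <- sum(x$val) + sum(y) + eps
  val <- 1 - s / t_
  new_node(tape, val, NULL, list(x), backfn = function(nd) {
    accum_grad(x, nd$grad * (s - 2 * y * t_) / t_^2)
  })
}

# Weighted sum of scalar nodes.
nd_wsum <- function(tape, nodes, weights) {
  val <- sum(vapply(seq_along(nodes), function(i)
    weights[i] * nodes[[i]]$val, numeric(1)))
  new_node(tape, val, NULL, nodes, backfn = function(nd) {
    for (i in seq_along(nodes))
      accum_grad(nodes[[i]], nd$grad * weights[i])
  })
}

# Parameter initialization ---------------------------------------------

he_init <- function(nrow_, ncol_, fan_in) {
  matrix(stats::rnorm(nrow_ * ncol_, sd = sqrt(2 / fan_in)), nrow_, ncol_)
}

init_conv3 <- function(ps, name, cin, cout) {
  ps_add(ps, paste0(name, ".W"), he_init(cout, 27 * cin, 27 * cin))
  ps_add(ps, paste0(name, ".b"), numeric(cout))
}

init_conv1 <- function(ps, name, cin, cout) {
  ps_add(ps, paste0(name, ".W"), he_init(cout, cin, cin))
  ps_add(ps, paste0(name, ".b"), numeric(cout))
}

init_upconv2 <- function(ps, name, cin, cout) {
  ps_add(ps, paste0(name, ".W"), he_init(8 * cout, cin, cin))
  ps_add(ps, paste0(name, ".b"), numeric(cout))
}

init_norm <- function(ps, name, c_) {
  ps_add(ps, paste0(name, ".g"), rep(1, c_))
  ps_add(ps, paste0(name, ".b"), rep(0, c_))
}

# Adam optimizer --------------------------------------------------------

new_adam <- function(ps, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(ps$values, function(v) v * 0)
  st$v <- lapply(ps$values, function(v) v * 0)
  st
}

adam_step <- function(st, ps) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  corr1 <- 1 - b1^st$t; corr2 <- 1 - b2^st$t
  for (nm in names(ps$values)) {
    g <- ps$grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    mhat <- st$m[[nm]] / corr1
    vhat <- st$v[[nm]] / corr2
    ps$values[[nm]] <- ps$values[[nm]] - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  invisible(NULL)
}
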