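#' Loss configuration
#'
#' The training loss is a convex combination of binary cross-entropy and
#' soft Dice loss,
#' \deqn{loss(x, y) = \lambda \, loss_b(x, y) + (1 - \lambda) \, loss_d(x, y),
#'   \quad \lambda \in [0, 1],}
#' where x is the predicted probability map and y the annotation. BCE
#' penalizes each voxel independently (sensitive to complex shapes but
#' prone to over-extraction when used alone); Dice loss scores region
#' overlap (robust to class imbalance but under-extracts and trains less
#' stably on its own). The deeply supervised networks aggregate this loss
#' over their four output heads with weights `ds_weights`.
#'
#' @param lam mixing coefficient lambda in \[0, 1\].
#' @param smooth_eps smoothing constant added to the soft-Dice numerator
#'   and denominator; keeps empty-target batches finite.
#' @param ds_weights 4 nonnegative deep-supervision weights; normalized to
#'   sum to 1.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(lam = 0.5, smooth_eps = 1.0,
                        ds_weights = rep(0.25, 4)) {
  if (!is.numeric(lam) || length(lam) != 1 || lam < 0 || lam > 1)
    stop("`lam` must be a single number in [0, 1]")
  if (smooth_eps < 0) stop("`smooth_eps` must be nonnegative")
  ds_weights <- as.numeric(ds_weights)
  if (length(ds_weights) != 4 || any(ds_weights < 0) ||
      sum(ds_weights) <= 0)
    stop("`ds_weights` must be 4 nonnegative numbers with positive sum")
  structure(list(lam = lam, smooth_eps = smooth_eps,
                 ds_weights = ds_weights / sum(ds_weights)),
            class = "loss_config")
}

PROB_CLIP <- 1e-7

as_num_grid <- function(x) if (inherits(x, "vol3d")) x$data else x

#' Binary cross-entropy loss
#'
#' Mean over voxels of \eqn{-[y \log x + (1-y) \log(1-x)]}, with
#' probabilities clipped to \[1e-7, 1 - 1e-7\] for numeric safety.
#'
#' @param x predicted probability grid (values in \[0, 1\]).
#' @param y binary annotation grid, same shape.
#' @return nonnegative scalar.
#' @export
bce_loss <- function(x, y) {
  x <- as_num_grid(x); y <- as_num_grid(y)
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("shape mismatch between prediction and annotation")
  p <- pmin(pmax(x, PROB_CLIP), 1 - PROB_CLIP)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Soft Dice loss
#'
#' \eqn{1 - (2\sum xy + \epsilon) / (\sum x + \sum y + \epsilon)} on the
#' raw (unthresholded) probabilities. With binary `x` and `eps = 0` this
#' equals one minus the Dice coefficient.
#'
#' @param x predicted probability grid.
#' @param y binary annotation grid, same shape.
#' @param eps smoothing constant.
#' @return scalar in \[0, 1\].
#' @export
dice_loss <- function(x, y, eps = 1.0) {
  x <- as_num_grid(x); y <- as_num_grid(y)
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("shape mismatch between prediction and annotation")
  1 - (2 * sum(x * y) + eps) / (sum(x) + sum(y) + eps)
}

#' Combined lambda-weighted loss
#'
#' @param x predicted probability grid.
#' @param y binary annotation grid.
#' @param config a [loss_config].
#' @return `lam * bce_loss(x, y) + (1 - lam) * dice_loss(x, y)`.
#' @export
combined_loss <- function(x, y, config = loss_config()) {
  stopifnot(inherits(config, "loss_config"))
  config$lam * bce_loss(x, y) +
    (1 - config$lam) * dice_loss(x, y, eps = config$smooth_eps)
}

#' Deep-supervision loss over the four output heads
#'
#' @param outputs list of 4 full-resolution probability grids (the o1..o4
#'   heads of the nested network).
#' @param y binary annotation grid.
#' @param config a [loss_config]; `ds_weights` weight the heads.
#' @return nonnegative scalar.
#' @export
deep_supervision_loss <- function(outputs, y, config = loss_config()) {
  if (!is.list(outputs) || length(outputs) != 4)
    stop("`outputs` must be a list of exactly 4 probability grids")
  w <- config$ds_weights
  sum(vapply(seq_len(4),
             function(k) w[k] * combined_loss(outputs[[k]], y, config),
             numeric(1)))
}

#' Tune the loss mixing coefficient lambda
#'
#' Maximizes a validation objective (typically mean validation Dice) over
#' lambda in \[0, 1\]. Two search modes are offered: a deterministic grid,
#' and a small tree-structured Parzen estimator (TPE): after a few
#' uniformly drawn startup trials, candidates are scored by the density
#' ratio of a "good" (top quantile) versus "bad" Parzen mixture and the
#' most promising candidate is evaluated next. Both modes are
#' deterministic given `seed`.
#'
#' @param objective function lambda -> validation score (higher is
#'   better).
#' @param budget number of objective evaluations, >= 1.
#' @param method `"grid"` or `"tpe"`.
#' @param seed RNG seed for TPE sampling.
#' @param grid lambda values for grid mode (defaults to `budget` equally
#'   spaced points in \[0, 1\]).
#' @param n_startup,gamma,n_candidates TPE controls: uniform startup
#'   trials, good-quantile fraction, candidates scored per step.
#' @return list with `best_lambda`, `best_score` and `trials` (a
#'   data.frame of lambda, score in evaluation order).
#' @export
tune_lambda <- function(objective, budget = 10, method = c("grid", "tpe"),
                        seed = 0, grid = NULL, n_startup = 5, gamma = 0.25,
                        n_candidates = 24) {
  method <- match.arg(method)
  if (budget < 1) stop("`budget` must be >= 1")
  evals <- data.frame(lambda = numeric(0), score = numeric(0))
  run_one <- function(lam, i) {
    sc <- tryCatch(objective(lam), error = function(e)
      stop("objective failed at trial ", i, " (lambda = ", lam, "): ",
           conditionMessage(e)))
    evals[nrow(evals) + 1L, ] <<- c(lam, sc)
  }
  if (method == "grid") {
    if (is.null(grid))
      grid <- if (budget == 1) 0.5 else seq(0, 1, length.out = budget)
    for (i in seq_len(min(budget, length(grid)))) run_one(grid[i], i)
  } else {
    with_seed(seed, {
      for (i in seq_len(budget)) {
        if (i <= n_startup || nrow(evals) < 2) {
          lam <- stats::runif(1)
        } else {
          ord <- order(-evals$score)
          n_good <- max(1L, ceiling(gamma * nrow(evals)))
          good <- evals$lambda[ord[seq_len(n_good)]]
          bad <- evals$lambda[ord[-seq_len(n_good)]]
          bw <- function(v)
            if (length(v) < 2) 0.1 else max(0.1, stats::bw.nrd0(v))
          parzen <- function(x, centers, h)
            rowMeans(outer(x, centers, function(a, b)
              stats::dnorm(a, b, h))) + 1e-12
          if (!length(bad)) bad <- 0.5
          cand <- pmin(pmax(stats::rnorm(n_candidates, sample(good, 1),
                                         bw(good)), 0), 1)
          score <- parzen(cand, good, bw(good)) /
            parzen(cand, bad, bw(bad))
          lam <- cand[which.max(score)]
        }
        run_one(lam, i)
      }
    })
  }
  best <- which.max(evals$score)
  list(best_lambda = evals$lambda[best], best_score = evals$score[best],
       trials = evals)
}
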