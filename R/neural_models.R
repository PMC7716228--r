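#' Network architecture and training settings
#'
#' Describes the densely connected feed-forward networks used for
#' single-trait (one output neuron) and multi-trait (L output neurons)
#' prediction: three hidden layers of equal width, rectified-linear
#' activations, dropout regularization after each hidden layer, and linear
#' outputs trained on mean squared error (summed over outputs for the
#' multi-trait case) with the Adam optimizer.
#'
#' @param neurons width of each hidden layer.
#' @param epochs training epochs.
#' @param n_hidden_layers number of hidden layers (default 3).
#' @param dropout dropout rate after each hidden layer (default 0.25).
#' @param n_outputs 1 for single-trait, L for multi-trait networks.
#' @param learning_rate,batch_size Adam step size and minibatch size.
#' @param seed integer seed for weight initialization, dropout and
#'   minibatch shuffling; fixed seed + one thread gives identical fits.
#' @return list of class `net_spec`.
#' @export
net_spec <- function(neurons, epochs, n_hidden_layers = 3, dropout = 0.25,
                     n_outputs = 1, learning_rate = 1e-3, batch_size = 32,
                     seed = NULL) {
  if (neurons <= 0 || epochs <= 0) stop("neurons and epochs must be positive")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(neurons = as.integer(neurons), epochs = as.integer(epochs),
                 n_hidden_layers = as.integer(n_hidden_layers),
                 dropout = dropout, n_outputs = as.integer(n_outputs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = seed),
            class = "net_spec")
}

#' Train a feed-forward network and predict held-out lines
#'
#' Standardizes inputs and responses with training-set statistics, trains
#' the network described by `spec` (ReLU hidden layers, inverted dropout,
#' linear outputs, Adam on mean squared error), and returns
#' de-standardized predictions for `x_new`. Environment membership should
#' be supplied as one-hot columns appended to the marker matrix when one
#' network serves several environments.
#'
#' @param x_train,y_train training inputs (n x p) and responses (n x L
#'   matrix or vector).
#' @param x_new inputs to predict.
#' @param spec a [net_spec()]; its `n_outputs` must match `ncol(y_train)`.
#' @return matrix of predictions (rows of `x_new` x outputs) with the
#'   per-epoch training loss as attribute `"history"`.
#' @export
train_network <- function(x_train, y_train, x_new, spec) {
  y_train <- as.matrix(y_train)
  if (ncol(y_train) != spec$n_outputs)
    stop("spec$n_outputs must equal the number of response columns")
  if (anyNA(x_train) || anyNA(y_train)) stop("inputs must be complete")
  if (!is.null(spec$seed)) set.seed(spec$seed)

  xm <- colMeans(x_train)
  xs <- apply(x_train, 2, stats::sd); xs[xs < 1e-12] <- 1
  Xtr <- sweep(sweep(x_train, 2, xm), 2, xs, "/")
  Xte <- sweep(sweep(as.matrix(x_new), 2, xm), 2, xs, "/")
  ym <- colMeans(y_train)
  ys <- apply(y_train, 2, stats::sd); ys[ys < 1e-12] <- 1
  Ytr <- sweep(sweep(y_train, 2, ym), 2, ys, "/")

  n <- nrow(Xtr); p <- ncol(Xtr)
  sizes <- c(p, rep(spec$neurons, spec$n_hidden_layers), spec$n_outputs)
  nl <- length(sizes) - 1L
  W <- lapply(seq_len(nl), function(k)
    matrix(stats::rnorm(sizes[k] * sizes[k + 1],
                        sd = sqrt(2 / sizes[k])), sizes[k]))
  b <- lapply(seq_len(nl), function(k) rep(0, sizes[k + 1]))
  mW <- vW <- lapply(W, function(w) w * 0)
  mb <- vb <- lapply(b, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- spec$learning_rate
  step <- 0L
  history <- numeric(spec$epochs)

  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = spec$batch_size)) {
      idx <- ord[start:min(start + spec$batch_size - 1L, n)]
      A <- Xtr[idx, , drop = FALSE]
      acts <- vector("list", nl + 1L); acts[[1]] <- A
      masks <- vector("list", nl)
      for (k in seq_len(nl)) {
        Zk <- sweep(acts[[k]] %*% W[[k]], 2, b[[k]], "+")
        if (k < nl + 0L && k <= spec$n_hidden_layers) {
          Zk[Zk < 0] <- 0                              # ReLU
          if (spec$dropout > 0) {
            mk <- matrix(stats::runif(length(Zk)) >= spec$dropout,
                         nrow(Zk)) / (1 - spec$dropout)
            Zk <- Zk * mk
            masks[[k]] <- mk
          }
        }
        acts[[k + 1]] <- Zk
      }
      delta <- 2 * (acts[[nl + 1]] - Ytr[idx, , drop = FALSE]) /
        length(idx)
      if (!all(is.finite(delta)))
        stop("NaN loss at epoch ", ep, "; lower the learning rate")
      ep_loss <- ep_loss + sum((acts[[nl + 1]] -
                                  Ytr[idx, , drop = FALSE])^2)
      for (k in rev(seq_len(nl))) {
        gW <- crossprod(acts[[k]], delta)
        gb <- colSums(delta)
        if (k > 1) {
          delta <- delta %*% t(W[[k]])
          if (!is.null(masks[[k - 1]])) delta <- delta * masks[[k - 1]]
          delta[acts[[k]] <= 0] <- 0                   # ReLU gradient
        }
        step_k <- step + 1L
        mW[[k]] <- b1 * mW[[k]] + (1 - b1) * gW
        vW[[k]] <- b2 * vW[[k]] + (1 - b2) * gW^2
        mb[[k]] <- b1 * mb[[k]] + (1 - b1) * gb
        vb[[k]] <- b2 * vb[[k]] + (1 - b2) * gb^2
        W[[k]] <- W[[k]] - lr * (mW[[k]] / (1 - b1^step_k)) /
          (sqrt(vW[[k]] / (1 - b2^step_k)) + eps)
        b[[k]] <- b[[k]] - lr * (mb[[k]] / (1 - b1^step_k)) /
          (sqrt(vb[[k]] / (1 - b2^step_k)) + eps)
      }
      step <- step + 1L
    }
    history[ep] <- ep_loss / n
  }

  predict_net <- function(X) {
    A <- X
    for (k in seq_len(nl)) {
      A <- sweep(A %*% W[[k]], 2, b[[k]], "+")
      if (k <= spec$n_hidden_layers) A[A < 0] <- 0
    }
    A
  }
  pred <- sweep(sweep(predict_net(Xte), 2, ys, "*"), 2, ym, "+")
  colnames(pred) <- colnames(y_train)
  attr(pred, "history") <- history
  pred
}

#' Quadratic-plateau fit
#'
#' Least-squares fit of the agronomic quadratic-plateau curve: a quadratic
#' rise \eqn{y = a + bx + cx^2} up to the join point \eqn{x_0 = -b/(2c)},
#' constant at the plateau value \eqn{a - b^2/(4c)} beyond it, with
#' continuity and zero slope at the join. The join point is profiled on a
#' grid and refined by golden-section search; for each candidate join the
#' remaining parameters are a linear least-squares solve.
#'
#' @param x,y numeric vectors (at least 4 points, 3 distinct x).
#' @return list of class `quadratic_plateau`: `intercept`, `slope`,
#'   `curvature`, `join`, `plateau`, `fitted`, `rss`, and `flag`
#'   (`"ok"`, `"boundary"` when the join hits the data edge, `"flat"` for
#'   constant data, `"degenerate"` when no concave fit exists and the
#'   argmax fallback is used).
#' @export
fit_quadratic_plateau <- function(x, y) {
  if (length(x) < 4 || length(unique(x)) < 3)
    stop("need at least 4 points with 3 distinct x values")
  if (stats::sd(y) < 1e-12) {
    return(structure(list(intercept = y[1], slope = 0, curvature = 0,
                          join = min(x), plateau = y[1],
                          fitted = rep(y[1], length(y)), rss = 0,
                          flag = "flat"), class = "quadratic_plateau"))
  }
  # profile over the join: y = P + c * (x - x0)^2 for x <= x0, P beyond
  prof <- function(x0) {
    basis <- pmin(x - x0, 0)^2
    f <- stats::lm.fit(cbind(1, basis), y)
    list(rss = sum(f$residuals^2), P = f$coefficients[1],
         c = f$coefficients[2], fitted = f$fitted.values)
  }
  lo <- min(x); hi <- max(x)
  grid <- seq(lo + 1e-6, hi, length.out = 64)
  rss <- vapply(grid, function(g) prof(g)$rss, numeric(1))
  g0 <- grid[which.min(rss)]
  opt <- stats::optimize(function(g) prof(g)$rss,
                         c(max(lo, g0 - diff(range(x)) / 16),
                           min(hi, g0 + diff(range(x)) / 16)))
  x0 <- opt$minimum
  fit <- prof(x0)
  cc <- unname(fit$c)
  if (!is.finite(cc) || cc >= 0) {
    i <- which.max(y)
    return(structure(list(intercept = NA_real_, slope = NA_real_,
                          curvature = cc, join = x[i], plateau = y[i],
                          fitted = rep(y[i], length(y)),
                          rss = sum((y - y[i])^2), flag = "degenerate"),
                     class = "quadratic_plateau"))
  }
  P <- unname(fit$P)
  a <- P + cc * x0^2
  bb <- -2 * cc * x0
  rng <- hi - lo
  flag <- if (x0 >= hi - 0.02 * rng || x0 <= lo + 0.02 * rng)
    "boundary" else "ok"
  structure(list(intercept = a, slope = bb, curvature = cc, join = x0,
                 plateau = P, fitted = fit$fitted, rss = fit$rss,
                 flag = flag), class = "quadratic_plateau")
}

#' @export
print.quadratic_plateau <- function(x, ...) {
  cat(sprintf("quadratic plateau: join = %.2f, plateau = %.3f (%s)\n",
              x$join, x$plateau, x$flag))
  invisible(x)
}

#' Response-surface search over neurons and epochs
#'
#' Evaluates a full factorial grid of hidden-layer width and training
#' epochs by cross-validated mean predictive correlation, fits a
#' quadratic-plateau curve in the number of neurons at each epoch level to
#' localize where added width stops paying, and selects the epoch level
#' whose plateau prediction is highest, with the neuron optimum at that
#' level's join point (snapped into the searched range).
#'
#' @param x,y inputs and response used for the cross-validated evaluation
#'   (ignored when `score_fun` is given).
#' @param neuron_grid,epoch_grid grids searched (defaults 5..70 by 5 and
#'   10..80 by 10, a 14 x 8 = 112-cell factorial).
#' @param folds cross-validation folds for the default evaluator.
#' @param spec_base a [net_spec()] supplying the non-searched settings.
#' @param score_fun optional `function(neurons, epochs)` returning the
#'   score for one cell, replacing the built-in cross-validated evaluator
#'   (useful for custom criteria or cached evaluations).
#' @param seed seed for fold assignment and network training.
#' @return list of class `surface_search`: `grid` (data frame: neurons,
#'   epochs, score), `plateau_fits` (one [fit_quadratic_plateau()] result
#'   per epoch level), `optimum` (list: neurons, epochs, score).
#' @export
surface_search <- function(x = NULL, y = NULL,
                           neuron_grid = seq(5, 70, by = 5),
                           epoch_grid = seq(10, 80, by = 10),
                           folds = 5, spec_base = NULL, score_fun = NULL,
                           seed = NULL) {
  if (length(neuron_grid) == 0 || length(epoch_grid) == 0)
    stop("grids must be nonempty")
  if (is.null(score_fun)) {
    if (is.null(x) || is.null(y)) stop("supply x and y or a score_fun")
    y <- as.matrix(y)
    fold_id <- make_folds(seq_len(nrow(x)), f = folds, scheme = "random",
                          seed = seed)$fold
    score_fun <- function(neurons, epochs) {
      sp <- net_spec(neurons, epochs,
                     n_hidden_layers = spec_base$n_hidden_layers %||% 3,
                     dropout = spec_base$dropout %||% 0.25,
                     n_outputs = ncol(y),
                     learning_rate = spec_base$learning_rate %||% 1e-3,
                     batch_size = spec_base$batch_size %||% 32,
                     seed = seed)
      rs <- vapply(seq_len(folds), function(k) {
        te <- fold_id == k
        pr <- train_network(x[!te, , drop = FALSE], y[!te, , drop = FALSE],
                            x[te, , drop = FALSE], sp)
        mean(diag(stats::cor(pr, y[te, , drop = FALSE])))
      }, numeric(1))
      mean(rs)
    }
  }
  grid <- expand.grid(neurons = neuron_grid, epochs = epoch_grid)
  grid$score <- mapply(score_fun, grid$neurons, grid$epochs)

  can_fit <- length(neuron_grid) >= 3
  plateau_fits <- list()
  best <- list(neurons = NA_real_, epochs = NA_real_, score = -Inf)
  for (e in epoch_grid) {
    sub <- grid[grid$epochs == e, ]
    pf <- if (can_fit && nrow(sub) >= 4)
      fit_quadratic_plateau(sub$neurons, sub$score) else NULL
    plateau_fits[[as.character(e)]] <- pf
    if (is.null(pf)) {
      i <- which.max(sub$score)
      cand <- list(neurons = sub$neurons[i], epochs = e,
                   score = sub$score[i])
    } else {
      cand <- list(neurons = min(max(pf$join, min(neuron_grid)),
                                 max(neuron_grid)),
                   epochs = e, score = pf$plateau)
    }
    if (cand$score > best$score) best <- cand
  }
  if (!can_fit)
    warning("fewer than 3 neuron levels: plateau fit impossible, ",
            "argmax fallback used")
  structure(list(grid = grid, plateau_fits = plateau_fits, optimum = best),
            class = "surface_search")
}

#' @export
print.surface_search <- function(x, ...) {
  cat("response-surface search:", nrow(x$grid), "grid cells\n")
  cat(sprintf("optimum: %.1f neurons, %d epochs (score %.3f)\n",
              x$optimum$neurons, as.integer(x$optimum$epochs),
              x$optimum$score))
  invisible(x)
}
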