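#' Fit a convolutional regression network to evacuation snapshots
#'
#' The main fitting function of the package.  A stack of binary occupancy
#' frames (one sample = `C` consecutive frames of an `H x W` room) is mapped
#' to a scalar label -- the rational parameter alpha, or the initial density
#' rho0 -- by a small convolutional network: `n_conv` valid 3x3 convolution
#' layers with ReLU (2x2 max-pooling after the first only), dropout before
#' flattening, one ReLU dense layer and a linear output.  Training minimises
#' mean squared error plus an L2 weight penalty with Adam, early-stopping on
#' the validation MSE and keeping the best-validation weights.
#'
#' All randomness (weight initialisation, epoch shuffling, dropout) is drawn
#' from the R RNG seeded with `seed`, so fits are exactly reproducible.
#'
#' @param data An `evac_dataset` (its train/val splits are used), or an
#'   `N x C x H x W` array of 0/1 values together with `y`.
#' @param y Numeric labels, only when `data` is an array.
#' @param n_conv Number of convolution layers, 1--4.
#' @param filters Filters per convolution layer; defaults to 32 for the
#'   first and 64 for each further layer.
#' @param dense Width of the dense hidden layer.
#' @param dropout Dropout rate applied to the last convolution activations.
#' @param l2 L2 penalty coefficient on the weight matrices (`l2 * sum(w^2)`
#'   added to the loss).
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience on validation MSE (0 disables).
#' @param lr_factor,lr_patience Learning-rate schedule: multiply `lr` by
#'   `lr_factor` after `lr_patience` epochs without validation improvement
#'   (`lr_patience = 0` keeps the rate constant).
#' @param val_fraction Validation fraction when `data` has no split.
#' @param seed RNG seed for the fit.
#' @param verbose Print per-epoch losses.
#'
#' @return An object of class `evac_cnn`: the fitted `weights`, the
#'   architecture `spec`, a training `history` data frame, `best_epoch`, and
#'   the hyperparameters.  Methods: [predict.evac_cnn()], `print`,
#'   `summary`, `plot` (loss curves), `residuals`, `coef`.
#' @examples
#' \donttest{
#' man <- dataset_manifest(rho0 = 0.3, alpha = alpha_grid(10), windows = 4,
#'                         channels = 2, seed = 7)
#' ds <- build_dataset(man)
#' fit <- evac_cnn(ds, epochs = 3, seed = 1)
#' fit
#' }
#' @export
evac_cnn <- function(data, y = NULL, n_conv = 2, filters = NULL, dense = 64,
                     dropout = 0.3, l2 = 1e-4, lr = 1e-3, batch_size = 32,
                     epochs = 50, patience = 5, lr_factor = 0.5,
                     lr_patience = 3, val_fraction = 0.1,
                     seed = 1L, verbose = FALSE) {
  if (!n_conv %in% 1:4)
    stop("`n_conv` must be 1, 2, 3 or 4", call. = FALSE)
  if (is.null(filters)) filters <- c(32L, rep(64L, n_conv - 1L))
  if (length(filters) != n_conv)
    stop("`filters` needs one entry per convolution layer", call. = FALSE)

  if (inherits(data, "evac_dataset")) {
    x <- data$x
    y <- data$y
    tr_idx <- which(data$split == "train")
    va_idx <- which(data$split == "val")
  } else {
    x <- data
    if (is.null(y)) stop("`y` is required when `data` is an array", call. = FALSE)
    n <- dim(x)[1]
    set.seed(derive_seed(seed, "valsplit"))
    va_idx <- if (val_fraction > 0) sample.int(n, max(1L, round(val_fraction * n))) else integer(0)
    tr_idx <- setdiff(seq_len(n), va_idx)
  }
  d <- dim(x)
  if (length(d) != 4)
    stop("samples must form an N x C x H x W array", call. = FALSE)
  if (min(d[3], d[4]) < 8)
    stop("input images with side < 8 carry too little information for this network",
         call. = FALSE)
  if (!is.integer(x)) storage.mode(x) <- "integer"
  spec <- list(n_conv = as.integer(n_conv), filters = as.integer(filters),
               dense = as.integer(dense), dropout = dropout, l2 = l2,
               C = d[2], H = d[3], W = d[4])
  set.seed(seed)
  weights0 <- cpp_cnn_init(spec)
  fit <- cpp_cnn_train(x, as.numeric(y), as.integer(tr_idx - 1L),
                       as.integer(va_idx - 1L), spec, weights0,
                       lr, as.integer(batch_size), as.integer(epochs),
                       as.integer(patience), lr_factor,
                       as.integer(lr_patience), isTRUE(verbose))
  history <- data.frame(
    epoch = seq_along(fit$train_mse),
    train_mse = fit$train_mse,
    val_mse = if (length(fit$val_mse)) fit$val_mse else NA_real_
  )
  structure(list(
    weights = fit$weights, spec = spec, history = history,
    best_epoch = fit$best_epoch, best_val_mse = fit$best_val,
    n_train = length(tr_idx), n_val = length(va_idx),
    hyper = list(lr = lr, batch_size = batch_size, epochs = epochs,
                 patience = patience, lr_factor = lr_factor,
                 lr_patience = lr_patience, seed = seed),
    label = if (inherits(data, "evac_dataset")) data$manifest$label else "y",
    call = match.call()
  ), class = "evac_cnn")
}

#' Predict labels for evacuation snapshots
#'
#' Deterministic inference (dropout off).
#'
#' @param object An `evac_cnn` fit.
#' @param newdata An `evac_dataset`, an `N x C x H x W` array, or a single
#'   `C x H x W` sample.
#' @param split Optional split level(s) to restrict to when `newdata` is a
#'   dataset (e.g. `"test"`).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.evac_cnn <- function(object, newdata, split = NULL, ...) {
  x <- if (inherits(newdata, "evac_dataset")) newdata$x else newdata
  if (length(dim(x)) == 3) dim(x) <- c(1L, dim(x))
  if (length(dim(x)) != 4)
    stop("`newdata` must be (N x) C x H x W", call. = FALSE)
  idx <- seq_len(dim(x)[1])
  if (!is.null(split)) {
    if (!inherits(newdata, "evac_dataset"))
      stop("`split` needs an evac_dataset", call. = FALSE)
    idx <- which(newdata$split %in% split)
  }
  if (!is.integer(x)) storage.mode(x) <- "integer"
  cpp_cnn_predict(x, as.integer(idx - 1L), object$spec, object$weights)
}

#' Regression accuracy metrics
#'
#' Mean squared error, mean absolute error and the coefficient of
#' determination `R2 = 1 - SSres/SStot`, with `SStot` the total sum of
#' squares of the observed labels.  Zero label variance makes R2 undefined
#' (`NA` with a warning).
#'
#' @param obs Observed labels.
#' @param pred Predictions.
#' @return A list with `mse`, `mae`, `r2` and `n`.
#' @export
regression_metrics <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) > 0)
  res <- obs - pred
  sstot <- sum((obs - mean(obs))^2)
  r2 <- if (sstot > 0) 1 - sum(res^2) / sstot else {
    warning("zero label variance: R2 undefined")
    NA_real_
  }
  list(mse = mean(res^2), mae = mean(abs(res)), r2 = r2, n = length(obs))
}

#' Evaluate a fitted network on a dataset split
#'
#' @param object An `evac_cnn` fit.
#' @param data An `evac_dataset`.
#' @param split Split level(s) to evaluate on (default `"test"`).
#' @return [regression_metrics()] of the chosen samples.
#' @export
evaluate_model <- function(object, data, split = "test") {
  idx <- which(data$split %in% split)
  if (!length(idx)) stop("no samples in the requested split", call. = FALSE)
  pred <- predict(object, data, split = split)
  regression_metrics(data$y[idx], pred)
}

#' @export
print.evac_cnn <- function(x, ...) {
  cat(sprintf("Convolutional regression fit (%d conv layer%s)\n",
              x$spec$n_conv, if (x$spec$n_conv > 1) "s" else ""))
  cat(sprintf("  input  : %d x %d x %d (C x H x W), label: %s\n",
              x$spec$C, x$spec$H, x$spec$W, x$label))
  cat(sprintf("  filters: %s | dense %d | dropout %.2f | L2 %g\n",
              paste(x$spec$filters, collapse = ", "), x$spec$dense,
              x$spec$dropout, x$spec$l2))
  cat(sprintf("  trained %d epochs on %d samples (best epoch %d, val MSE %.4g)\n",
              nrow(x$history), x$n_train, x$best_epoch, x$best_val_mse))
  invisible(x)
}

#' @export
summary.evac_cnn <- function(object, ...) {
  np <- sum(vapply(object$weights$Wc, length, 0)) +
    sum(vapply(object$weights$bc, length, 0)) +
    length(object$weights$Wd) + length(object$weights$bd) +
    length(object$weights$Wo) + 1L
  cat("Architecture:\n")
  h <- object$spec$H; w <- object$spec$W; cin <- object$spec$C
  for (l in seq_len(object$spec$n_conv)) {
    h <- h - 2; w <- w - 2
    cat(sprintf("  conv %d: 3x3, %d -> %d channels, out %d x %d (ReLU)\n",
                l, cin, object$spec$filters[l], h, w))
    cin <- object$spec$filters[l]
    if (l == 1) {
      h <- h %/% 2; w <- w %/% 2
      cat(sprintf("  maxpool 2x2            -> out %d x %d\n", h, w))
    }
  }
  cat(sprintf("  dropout %.2f, flatten %d -> dense %d (ReLU) -> 1 (linear)\n",
              object$spec$dropout, cin * h * w, object$spec$dense))
  cat(sprintf("  parameters: %d\n", np))
  print(object)
  invisible(list(n_parameters = np, history = object$history))
}

#' Plot the training history of a fit
#'
#' @param x An `evac_cnn` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.evac_cnn <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_mse, h$val_mse), type = "l",
                    lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "epoch", ylab = "MSE", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' @export
residuals.evac_cnn <- function(object, data, split = "test", ...) {
  idx <- which(data$split %in% split)
  data$y[idx] - predict(object, data, split = split)
}

#' @export
coef.evac_cnn <- function(object, ...) object$weights

#' @export
fitted.evac_cnn <- function(object, data, split = "train", ...) {
  predict(object, data, split = split)
}
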