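test_that("analytic gradients match finite differences", {
  set.seed(42)
  N <- 5; C <- 2; H <- 10; W <- 10
  x <- array(as.integer(runif(N * C * H * W) < 0.3), dim = c(N, C, H, W))
  y <- rnorm(N)
  spec <- list(n_conv = 2L, filters = c(3L, 4L), dense = 5L, dropout = 0,
               l2 = 1e-3, C = C, H = H, W = W)
  w <- evacnn:::cpp_cnn_init(spec)
  lg <- evacnn:::cpp_cnn_lossgrad(x, 0:(N - 1), y, spec, w)
  loss_at <- function(w) evacnn:::cpp_cnn_lossgrad(x, 0:(N - 1), y, spec, w)$loss

  ## Central differences agree with backprop except at the measure-zero
  ## ReLU kinks / pool-argmax ties a perturbation can cross; those show up
  ## as isolated large deviations, so the check is on the error profile:
  ## the bulk of sampled coordinates must agree to near machine precision.
  h <- 1e-5
  rel_errs <- c()
  check_block <- function(get, set, analytic, k = 12) {
    vals <- get(w)
    idx <- seq_len(min(k, length(vals)))
    for (i in idx) {
      up <- vals; up[i] <- up[i] + h
      dn <- vals; dn[i] <- dn[i] - h
      num <- (loss_at(set(w, up)) - loss_at(set(w, dn))) / (2 * h)
      rel_errs <<- c(rel_errs, abs(analytic[i] - num) /
                       max(abs(num), abs(analytic[i]), 1e-8))
    }
  }
  check_block(function(w) w$Wc[[1]], function(w, v) { w$Wc[[1]][] <- v; w },
              lg$grad$Wc[[1]])
  check_block(function(w) w$Wc[[2]], function(w, v) { w$Wc[[2]][] <- v; w },
              lg$grad$Wc[[2]])
  check_block(function(w) w$bc[[1]], function(w, v) { w$bc[[1]][] <- v; w },
              lg$grad$bc[[1]])
  check_block(function(w) w$Wd, function(w, v) { w$Wd[] <- v; w }, lg$grad$Wd)
  check_block(function(w) w$Wo, function(w, v) { w$Wo[] <- v; w }, lg$grad$Wo)
  check_block(function(w) w$bo, function(w, v) { w$bo <- v; w }, lg$grad$bo,
              k = 1)
  expect_lt(stats::median(rel_errs), 1e-7)
  expect_gte(mean(rel_errs < 1e-5), 0.9)
})

test_that("architecture contracts are enforced", {
  ds <- tiny_dataset()
  expect_error(evac_cnn(ds, n_conv = 5), "n_conv")
  expect_error(evac_cnn(ds, n_conv = 2, filters = c(8, 8, 8)), "filters")
  ## images below 8 x 8 are refused
  small <- crop_dataset(ds, 6, anchor = c(1, 1))
  expect_error(evac_cnn(small, epochs = 1), "side")
  ## too deep for the image after pooling
  expect_error(evac_cnn(crop_dataset(ds, 8, anchor = c(1, 1)),
                        n_conv = 3, epochs = 1), "small")
})

test_that("fits and predictions are reproducible and finite", {
  ds <- tiny_dataset()
  f1 <- evac_cnn(ds, filters = c(4, 8), dense = 8, epochs = 2, seed = 3)
  f2 <- evac_cnn(ds, filters = c(4, 8), dense = 8, epochs = 2, seed = 3)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)

  p1 <- predict(f1, ds, split = "test")
  p2 <- predict(f1, ds, split = "test")
  expect_identical(p1, p2)

  ## a single sample and an all-zero image both give finite scalars
  one <- ds$x[1, , , ]
  expect_length(predict(f1, one), 1)
  zero <- array(0L, dim = dim(ds$x[1, , , , drop = FALSE]))
  expect_true(is.finite(predict(f1, zero)))

  ## architecture is deterministic given the spec
  expect_identical(f1$spec, f2$spec)
  expect_identical(lapply(f1$weights$Wc, dim), list(c(4L, 18L), c(8L, 36L)))
})

test_that("the network can memorise a small sample", {
  set.seed(31)
  N <- 50; C <- 2; H <- 10; W <- 10
  x <- array(as.integer(runif(N * C * H * W) < 0.3), dim = c(N, C, H, W))
  y <- runif(N, 0, 5)
  fit <- evac_cnn(x, y, filters = c(8, 16), dense = 16, dropout = 0, l2 = 0,
                  epochs = 200, patience = 0, val_fraction = 0, seed = 2)
  pred <- predict(fit, x)
  expect_lt(mean((pred - y)^2), 0.05)
})

test_that("metrics match hand-computed values and degenerate cases", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$mse, 1 / 3)
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$r2, 0.5)        # SSres = 1, SStot = 2

  perfect <- regression_metrics(1:5, 1:5)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$r2, 1)

  at_mean <- regression_metrics(1:5, rep(3, 5))
  expect_equal(at_mean$r2, 0)

  expect_warning(z <- regression_metrics(rep(2, 4), c(1, 2, 3, 4)),
                 "variance")
  expect_true(is.na(z$r2))
})

test_that("label-shuffled training carries no signal to validation", {
  ds <- tiny_dataset()
  set.seed(99)
  shuffled <- ds
  shuffled$y <- sample(ds$y)
  fit <- evac_cnn(shuffled, filters = c(4, 8), dense = 8, epochs = 10,
                  patience = 0, seed = 7)
  m <- evaluate_model(fit, shuffled, "test")
  expect_lt(m$r2, 0.3)
})

test_that("training histories expose over-fitting the way the flags expect", {
  ds <- tiny_dataset()
  fit <- evac_cnn(ds, filters = c(4, 8), dense = 8, epochs = 4, patience = 2,
                  seed = 1)
  expect_true(all(c("epoch", "train_mse", "val_mse") %in% names(fit$history)))
  expect_true(all(is.finite(fit$history$train_mse)))
  expect_gte(fit$best_epoch, 1)
})
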