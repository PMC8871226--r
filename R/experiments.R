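## Scripted experiments: network-depth comparison, frame-count sweep,
## per-density evaluation, crop robustness, density regression, double-exit
## check and the crowd-rule transfer measurement of the deviation from
## optimal behaviour.  Every experiment re-runs end-to-end from its seed and
## embeds the configurations it used, so any reported number is
## recomputable.  Size arguments default to the full study conditions
## (5 densities x 100 alpha values x 20 windows = 10,000 samples); pass
## smaller values for quick runs.

#' Manifest for the standard mixed-density alpha-labelled dataset
#'
#' @param alpha_n Number of alpha grid values in `[0, 5)`.
#' @param windows Windows per simulation run.
#' @param channels Frames per window.
#' @param rho0 Densities included.
#' @param rule Behaviour rule of the simulations.
#' @param seed Root seed.
#' @param ... Further arguments to [dataset_manifest()].
#' @return An `evac_manifest`.
#' @export
mixed_manifest <- function(alpha_n = 100, windows = 20, channels = 8,
                           rho0 = seq(0.1, 0.5, by = 0.1),
                           rule = "rational", seed = 1L, ...) {
  dataset_manifest(rho0 = rho0, alpha = alpha_grid(alpha_n),
                   windows = windows, channels = channels, rule = rule,
                   seed = seed, ...)
}

new_report <- function(tag, ...) {
  structure(list(tag = tag, ...), class = "evac_report")
}

#' @export
print.evac_report <- function(x, ...) {
  cat(sprintf("Experiment report: %s\n", x$tag))
  if (!is.null(x$table)) {
    print(x$table, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$notes)) for (n in x$notes) cat(" -", n, "\n")
  invisible(x)
}

#' Compare network depths on the mixed dataset
#'
#' Trains the 1--4-convolution-layer variants for a fixed number of epochs
#' (no early stopping, so the full loss history is visible) and flags the
#' over-fitting signature (validation loss rising while training loss
#' falls) and validation instability (relative spread of the validation
#' loss across the later epochs).
#'
#' @param depths Convolution-layer counts to compare.
#' @param data Optional pre-built mixed `evac_dataset` (built from
#'   `mixed_manifest(seed = seed)` otherwise).
#' @param epochs Training epochs per depth.
#' @param seed Root seed.
#' @param ... Extra arguments passed to [mixed_manifest()] when `data` is
#'   not supplied.
#' @return An `evac_report` with per-depth histories, metrics and flags.
#' @export
exp_depth_comparison <- function(depths = 1:4, data = NULL, epochs = 20,
                                 seed = 1L, ...) {
  if (is.null(data)) data <- build_dataset(mixed_manifest(seed = seed, ...))
  rows <- list()
  histories <- list()
  for (d in depths) {
    fit <- evac_cnn(data, n_conv = d, epochs = epochs, patience = 0,
                    seed = derive_seed(seed, paste0("depth", d)))
    h <- fit$history
    m <- evaluate_model(fit, data, "test")
    late <- h$val_mse[h$epoch > epochs / 2]
    overfit <- which.min(h$val_mse) <= epochs / 2 &&
      h$val_mse[epochs] > 1.15 * min(h$val_mse)
    instab <- stats::sd(late) / mean(late)
    rows[[length(rows) + 1]] <- data.frame(
      n_conv = d, test_mse = m$mse, test_r2 = m$r2,
      best_val = min(h$val_mse), final_val = h$val_mse[epochs],
      overfit = overfit, val_instability = instab)
    histories[[as.character(d)]] <- h
  }
  new_report("depth_comparison", table = do.call(rbind, rows),
             histories = histories, seed = seed,
             manifest = data$manifest)
}

#' Frame-count sweep
#'
#' One wide dataset is built at the largest channel count and the leading
#' channels reused, so every channel count sees identical simulations.
#'
#' @param channels Channel counts to evaluate.
#' @param data Optional pre-built dataset with `max(channels)` channels.
#' @param epochs,patience Training control.
#' @inheritParams exp_depth_comparison
#' @return An `evac_report` with test MSE and R-squared per channel count.
#' @export
exp_frame_sweep <- function(channels = c(1, 2, 4, 8, 16, 32), data = NULL,
                            epochs = 40, patience = 6, seed = 1L, ...) {
  if (is.null(data))
    data <- build_dataset(mixed_manifest(channels = max(channels),
                                         seed = seed, ...))
  rows <- list()
  for (ch in sort(channels)) {
    ds <- channel_subset(data, ch)
    fit <- evac_cnn(ds, epochs = epochs, patience = patience,
                    seed = derive_seed(seed, paste0("frames", ch)))
    m <- evaluate_model(fit, ds, "test")
    rows[[length(rows) + 1]] <- data.frame(
      channels = ch, test_mse = m$mse, test_mae = m$mae, test_r2 = m$r2)
  }
  new_report("frame_sweep", table = do.call(rbind, rows), seed = seed,
             manifest = data$manifest)
}

#' Per-density evaluation
#'
#' Trains one model per initial density on single-density datasets, plus a
#' smaller mixed-density model, mirroring the per-density accuracy table:
#' single-density models are expected to beat the mixed one.
#'
#' @param rho0 Densities, one model each.
#' @param alpha_n Alpha grid size.
#' @param windows Windows per run for the single-density sets.
#' @param mixed_windows Windows per run for the mixed comparison set (the
#'   default keeps the mixed set the same total size as one single-density
#'   set).
#' @param ... Further arguments to [evac_cnn()].
#' @inheritParams exp_frame_sweep
#' @return An `evac_report`; its table has one row per density plus
#'   `"mixed"`, and the fitted models are attached.
#' @export
exp_per_density <- function(rho0 = seq(0.1, 0.5, by = 0.1), alpha_n = 100,
                            windows = 20, mixed_windows = NULL,
                            epochs = 40, patience = 6, seed = 1L, ...) {
  if (is.null(mixed_windows))
    mixed_windows <- max(1L, round(windows / length(rho0)))
  rows <- list()
  models <- list()
  for (r in rho0) {
    ds <- build_dataset(mixed_manifest(alpha_n = alpha_n, windows = windows,
                                       rho0 = r, seed = seed))
    fit <- evac_cnn(ds, epochs = epochs, patience = patience,
                    seed = derive_seed(seed, paste0("dens", r)), ...)
    m <- evaluate_model(fit, ds, "test")
    rows[[length(rows) + 1]] <- data.frame(
      rho0 = as.character(r), n = length(ds$y), test_mse = m$mse,
      test_mae = m$mae, test_r2 = m$r2)
    models[[as.character(r)]] <- fit
  }
  ds <- build_dataset(mixed_manifest(alpha_n = alpha_n,
                                     windows = mixed_windows, seed = seed))
  fit <- evac_cnn(ds, epochs = epochs, patience = patience,
                  seed = derive_seed(seed, "densmixed"), ...)
  ## few windows per cell can leave the test stratum empty; fall back to
  ## the validation split as the held-out set
  m <- evaluate_model(fit, ds,
                      if (any(ds$split == "test")) "test" else "val")
  rows[[length(rows) + 1]] <- data.frame(
    rho0 = "mixed", n = length(ds$y), test_mse = m$mse, test_mae = m$mae,
    test_r2 = m$r2)
  models[["mixed"]] <- fit
  new_report("per_density", table = do.call(rbind, rows), models = models,
             seed = seed)
}

#' Crop robustness
#'
#' Retrains the standard model on square sub-images of varying side length,
#' anchored either at the top-left corner or over the exit at the right
#' wall's centre.  Accuracy should improve with side length, and
#' exit-anchored crops should beat top-left crops of the same size.
#'
#' @param sides Crop side lengths.
#' @param anchors Anchor keywords (see [crop_anchor()]).
#' @param data Optional pre-built uncropped mixed dataset.
#' @inheritParams exp_frame_sweep
#' @return An `evac_report` with metrics per (side, anchor).
#' @export
exp_crop <- function(sides = c(8, 12, 16, 20, 24),
                     anchors = c("topleft", "exit"), data = NULL,
                     epochs = 40, patience = 6, seed = 1L, ...) {
  if (is.null(data)) data <- build_dataset(mixed_manifest(seed = seed, ...))
  L <- dim(data$x)[3]
  rows <- list()
  for (anchor in anchors) {
    for (side in sides) {
      ds <- if (side == L) data else crop_dataset(data, side, anchor)
      fit <- evac_cnn(ds, epochs = epochs, patience = patience,
                      seed = derive_seed(seed, paste0("crop", anchor, side)))
      m <- evaluate_model(fit, ds, "test")
      rows[[length(rows) + 1]] <- data.frame(
        anchor = anchor, side = side, test_mse = m$mse, test_mae = m$mae,
        test_r2 = m$r2)
      if (side == L) break   # full image: anchors coincide
    }
  }
  new_report("crop", table = do.call(rbind, rows), seed = seed,
             manifest = data$manifest)
}

#' Density regression
#'
#' Regresses the initial density rho0 from frame stacks simulated at a
#' fixed rational parameter (alpha = 5), using independent replicate runs
#' per density so the sample count matches the alpha task.
#'
#' @param rho0 Density labels.
#' @param alpha Fixed rational parameter of all simulations.
#' @param reps Replicate runs per density.
#' @param windows Windows per run.
#' @param ... Further arguments to [evac_cnn()].
#' @inheritParams exp_frame_sweep
#' @return An `evac_report` with the test metrics and the fitted model.
#' @export
exp_density_regression <- function(rho0 = seq(0.1, 0.5, by = 0.1),
                                   alpha = 5, reps = 100, windows = 20,
                                   epochs = 40, patience = 6, seed = 1L,
                                   ...) {
  man <- dataset_manifest(rho0 = rho0, alpha = alpha, windows = windows,
                          reps = reps, label = "rho0", seed = seed)
  ds <- build_dataset(man)
  fit <- evac_cnn(ds, epochs = epochs, patience = patience,
                  seed = derive_seed(seed, "densreg"), ...)
  m <- evaluate_model(fit, ds, "test")
  new_report("density_regression",
             table = data.frame(n = length(ds$y), test_mse = m$mse,
                                test_mae = m$mae, test_r2 = m$r2),
             model = fit, manifest = man, seed = seed)
}

#' Double-exit robustness
#'
#' Repeats the alpha regression on simulations with two symmetric exits on
#' the right wall at fixed density, and compares escape times against the
#' single-exit geometry as a sanity check (two exits drain faster).
#'
#' @param rho0 Density of the double-exit simulations.
#' @param alpha_n,windows Dataset size.
#' @param escape_reps Replicates for the escape-time comparison (0 skips).
#' @param ... Further arguments to [evac_cnn()].
#' @inheritParams exp_frame_sweep
#' @return An `evac_report` with test metrics, the prediction table and the
#'   escape-time comparison.
#' @export
exp_double_exit <- function(rho0 = 0.5, alpha_n = 100, windows = 20,
                            escape_reps = 10, epochs = 40, patience = 6,
                            seed = 1L, ...) {
  man <- mixed_manifest(alpha_n = alpha_n, windows = windows, rho0 = rho0,
                        exits = "double", seed = seed)
  ds <- build_dataset(man)
  fit <- evac_cnn(ds, epochs = epochs, patience = patience,
                  seed = derive_seed(seed, "double"), ...)
  m <- evaluate_model(fit, ds, "test")
  idx <- which(ds$split == "test")
  preds <- data.frame(alpha = ds$y[idx],
                      alpha_hat = predict(fit, ds, split = "test"))
  esc <- NULL
  if (escape_reps > 0) {
    base <- list(L = man$L, alpha = 2, rho0 = rho0, max_steps = 500,
                 seed = derive_seed(seed, "esc"))
    single <- mean_escape_time(do.call(sim_config, c(base, exits = "single")),
                               n_reps = escape_reps)
    double <- mean_escape_time(do.call(sim_config, c(base, exits = "double")),
                               n_reps = escape_reps)
    esc <- data.frame(exits = c("single", "double"),
                      mean_escape = c(single$mean, double$mean))
  }
  new_report("double_exit",
             table = data.frame(n = length(ds$y), test_mse = m$mse,
                                test_mae = m$mae, test_r2 = m$r2),
             predictions = preds, escape_times = esc, model = fit,
             manifest = man, seed = seed)
}

#' Crowd-rule transfer: deviation from the optimal strategy
#'
#' Takes a model trained on rational-rule data and applies it, unchanged,
#' to simulations run under the crowd rule, over the full alpha grid at
#' each density.  The mean prediction per density is compared against the
#' alpha-grid mean (2.475 for the standard grid): the difference
#' delta_alpha quantifies how strongly crowd-following biases the apparent
#' rationality of the crowd.
#'
#' @param model A fitted `evac_cnn` trained on rational-rule data; trained
#'   from scratch on the standard mixed dataset when omitted.
#' @param rho0 Densities at which to measure the deviation.
#' @param alpha_n,windows Crowd dataset size per density.
#' @param self_control Also predict on rational-rule data generated the
#'   same way (a self-transfer control whose deviation should be near 0).
#' @inheritParams exp_frame_sweep
#' @return An `evac_report`; `table` has one row per density with the mean
#'   prediction `alpha_hat` and `delta_alpha`.
#' @export
exp_crowd_transfer <- function(model = NULL, rho0 = seq(0.1, 0.5, by = 0.1),
                               alpha_n = 100, windows = 20,
                               self_control = FALSE, epochs = 40,
                               patience = 6, seed = 1L) {
  if (is.null(model)) {
    ds <- build_dataset(mixed_manifest(alpha_n = alpha_n, windows = windows,
                                       seed = seed))
    model <- evac_cnn(ds, epochs = epochs, patience = patience,
                      seed = derive_seed(seed, "transferbase"))
  }
  grid <- alpha_grid(alpha_n)
  baseline <- mean(grid)
  rows <- list()
  for (r in rho0) {
    man <- mixed_manifest(alpha_n = alpha_n, windows = windows, rho0 = r,
                          rule = "crowd", seed = derive_seed(seed, "crowd"))
    ds <- build_dataset(man)
    p <- predict(model, ds)
    row <- data.frame(rho0 = r, n = length(p), alpha_hat = mean(p),
                      delta_alpha = mean(p) - baseline)
    if (self_control) {
      man_r <- mixed_manifest(alpha_n = alpha_n, windows = windows,
                              rho0 = r, rule = "rational",
                              seed = derive_seed(seed, "selfctrl"))
      ds_r <- build_dataset(man_r)
      pr <- predict(model, ds_r)
      row$self_alpha_hat <- mean(pr)
      row$self_delta <- mean(pr) - baseline
    }
    rows[[length(rows) + 1]] <- row
  }
  tab <- do.call(rbind, rows)
  new_report("crowd_transfer", table = tab, baseline = baseline,
             model = model, seed = seed,
             notes = sprintf("baseline alpha = %.3f (grid mean)", baseline))
}
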