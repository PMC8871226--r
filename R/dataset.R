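## Turning simulated frame stacks into labelled multi-channel samples.

#' The standard grid of rational-parameter labels
#'
#' `n` evenly spaced values covering `[0, upper)`: with the defaults,
#' 0.00, 0.05, ..., 4.95, whose mean 2.475 is the baseline used for the
#' crowd-rule transfer deviation.
#'
#' @param n Number of grid values.
#' @param upper Open upper end of the range.
#' @return Numeric vector of length `n`.
#' @export
alpha_grid <- function(n = 100, upper = 5) {
  seq(0, upper, length.out = n + 1)[seq_len(n)]
}

#' Extract a multi-frame window from a run
#'
#' Channels are the consecutive occupancy frames at times
#' `start, start + 1, ..., start + channels - 1`.  Frames beyond the end of
#' the run (everyone escaped) are all-zero: the room really is empty then.
#'
#' @param run An `evac_run`.
#' @param start Time step of the first channel.
#' @param channels Number of consecutive frames.
#' @return An `L x L x channels` integer array of 0/1 values.
#' @export
extract_window <- function(run, start = 36, channels = 8) {
  n_frames <- dim(run$frames)[3]
  if (start < 0 || start >= run$config$max_steps + 1L)
    stop("window start outside the simulation horizon", call. = FALSE)
  L <- run$config$L
  out <- array(0L, dim = c(L, L, channels))
  for (k in seq_len(channels)) {
    idx <- start + k               # frame at time start + k - 1 is slot start + k
    if (idx <= n_frames) out[, , k] <- run$frames[, , idx]
  }
  out
}

#' Crop anchor helpers
#'
#' Upper-left corners for the two monitored regions: the top-left corner of
#' the room, and a window centred on the exit at the middle of the right
#' wall.
#'
#' @param L Full image side length.
#' @param side Crop side length.
#' @param where `"topleft"` or `"exit"`.
#' @return Length-2 integer vector (row, col) of the upper-left corner.
#' @export
crop_anchor <- function(L, side, where = c("topleft", "exit")) {
  where <- match.arg(where)
  if (where == "topleft") return(c(1L, 1L))
  r0 <- ceiling(L / 2) - floor(side / 2) + 1L
  r0 <- max(1L, min(L - side + 1L, r0))
  c(as.integer(r0), as.integer(L - side + 1L))
}

crop_window <- function(x, side, anchor) {
  d <- dim(x)
  if (side < 1 || anchor[1] < 1 || anchor[2] < 1 ||
      anchor[1] + side - 1 > d[1] || anchor[2] + side - 1 > d[2])
    stop("crop does not lie fully inside the image", call. = FALSE)
  x[anchor[1]:(anchor[1] + side - 1), anchor[2]:(anchor[2] + side - 1), ,
    drop = FALSE]
}

#' Describe a dataset of labelled evacuation windows
#'
#' A manifest fixes everything needed to rebuild a dataset bit-for-bit:
#' the density and alpha grids, windows per (rho0, alpha) cell, window
#' geometry, behaviour rule, exit layout, label kind, split fractions and
#' the root seed.
#'
#' With `replicates = "shared"` (default) one simulation is run per
#' (rho0, alpha) cell and the windows are cut at consecutive starts
#' `window_start, window_start + 1, ...` from that run; with
#' `"independent"` each window comes from its own replicate, all cut at
#' `window_start`.
#'
#' @param rho0 Initial densities.
#' @param alpha Rational-parameter labels (ignored label-side when
#'   `label = "rho0"`, but still the simulated value).
#' @param windows Windows per simulation run.
#' @param reps Independent simulation runs per (rho0, alpha) cell (shared
#'   mode only); each contributes `windows` windows, so a cell yields
#'   `reps * windows` samples.
#' @param channels Frames per window.
#' @param window_start Time step of the first window's first frame.
#' @param L,max_steps,epsilon,exits,exit_sep,rule Passed to [sim_config()].
#' @param label `"alpha"` or `"rho0"`: the regression target.
#' @param crop Optional list with `side` and `anchor` (or `where` keyword).
#' @param split Train/validation/test fractions (sum to 1), applied within
#'   every (rho0, alpha) cell.
#' @param replicates `"shared"` or `"independent"`, see above.
#' @param seed Root seed; every cell's simulation seed is derived from it.
#' @return An object of class `evac_manifest`.
#' @export
dataset_manifest <- function(rho0 = seq(0.1, 0.5, by = 0.1),
                             alpha = alpha_grid(100),
                             windows = 20, reps = 1, channels = 8,
                             window_start = 36,
                             L = 24, max_steps = 100, epsilon = 0.1,
                             exits = "single", exit_sep = 6,
                             rule = c("rational", "crowd"),
                             label = c("alpha", "rho0"),
                             crop = NULL,
                             split = c(train = 0.8, val = 0.1, test = 0.1),
                             replicates = c("shared", "independent"),
                             seed = 1L) {
  rule <- match.arg(rule)
  label <- match.arg(label)
  replicates <- match.arg(replicates)
  if (abs(sum(split) - 1) > 1e-8 || length(split) != 3)
    stop("`split` must be three fractions summing to 1", call. = FALSE)
  split <- stats::setNames(as.numeric(split), c("train", "val", "test"))
  if (!is.null(crop)) {
    if (is.null(crop$side)) stop("`crop` needs a `side`", call. = FALSE)
    if (is.null(crop$anchor))
      crop$anchor <- crop_anchor(L, crop$side,
                                 if (is.null(crop$where)) "topleft" else crop$where)
  }
  structure(list(
    rho0 = rho0, alpha = alpha, windows = as.integer(windows),
    reps = as.integer(reps),
    channels = as.integer(channels), window_start = as.integer(window_start),
    L = as.integer(L), max_steps = as.integer(max_steps), epsilon = epsilon,
    exits = exits, exit_sep = exit_sep, rule = rule, label = label,
    crop = crop, split = split, replicates = replicates, seed = as.integer(seed)
  ), class = "evac_manifest")
}

#' Build a labelled dataset of evacuation windows
#'
#' Simulates every (rho0, alpha) cell of the manifest, cuts `windows`
#' multi-frame windows per cell, optionally crops them, labels each sample
#' with alpha or rho0 and assigns a stratified train/validation/test split.
#' Rebuilding from the same manifest reproduces the arrays and split
#' membership exactly.
#'
#' @param manifest An [dataset_manifest()] object.
#' @param progress Print a dot per density while simulating.
#' @return An object of class `evac_dataset`: `x`, an
#'   `N x channels x H x W` integer array; `y`, the numeric labels; `meta`,
#'   a data frame (rho0, alpha, window start, replicate seed); `split`, a
#'   factor with levels train/val/test; and the `manifest`.
#' @export
build_dataset <- function(manifest, progress = FALSE) {
  m <- manifest
  side_r <- if (is.null(m$crop)) m$L else m$crop$side
  cells <- expand.grid(alpha = m$alpha, rho0 = m$rho0,
                       KEEP.OUT.ATTRS = FALSE)
  n_cell <- nrow(cells)
  reps <- if (m$replicates == "shared") m$reps else m$windows
  wins_per_rep <- if (m$replicates == "shared") m$windows else 1L
  per_cell <- reps * wins_per_rep
  N <- n_cell * per_cell
  x <- array(0L, dim = c(N, m$channels, side_r, side_r))
  y <- numeric(N)
  meta_rho <- numeric(N); meta_alpha <- numeric(N)
  meta_start <- integer(N); meta_seed <- integer(N); meta_rep <- integer(N)
  split <- character(N)
  i <- 0L
  for (cell in seq_len(n_cell)) {
    a <- cells$alpha[cell]; rho <- cells$rho0[cell]
    cell_tag <- sprintf("cell/%s/%.6f/%.6f", m$rule, rho, a)
    ## stratified split over the cell's samples, seeded from the manifest
    sp <- cell_split(per_cell, m$split,
                     derive_seed(m$seed, paste0(cell_tag, "/split")))
    j <- 0L
    for (rep in seq_len(reps)) {
      sdr <- derive_seed(m$seed, paste0(cell_tag, "/rep", rep))
      run <- run_simulation(sim_config(
        L = m$L, alpha = a, epsilon = m$epsilon, rho0 = rho, exits = m$exits,
        exit_sep = m$exit_sep, rule = m$rule, max_steps = m$max_steps,
        seed = sdr))
      for (w in seq_len(wins_per_rep)) {
        start <- if (m$replicates == "shared") m$window_start + w - 1L else m$window_start
        img <- extract_window(run, start, m$channels)
        if (!is.null(m$crop)) img <- crop_window(img, m$crop$side, m$crop$anchor)
        i <- i + 1L; j <- j + 1L
        ## img is H x W x C; store as (C, H, W)
        x[i, , , ] <- aperm(img, c(3, 1, 2))
        y[i] <- if (m$label == "alpha") a else rho
        meta_rho[i] <- rho; meta_alpha[i] <- a
        meta_start[i] <- start; meta_seed[i] <- sdr; meta_rep[i] <- rep
        split[i] <- sp[j]
      }
    }
    if (progress && cell %% length(m$alpha) == 0L) cat(".")
  }
  if (progress) cat("\n")
  structure(list(
    x = x, y = y,
    meta = data.frame(rho0 = meta_rho, alpha = meta_alpha,
                      start = meta_start, rep = meta_rep,
                      sim_seed = meta_seed),
    split = factor(split, levels = c("train", "val", "test")),
    manifest = m
  ), class = "evac_dataset")
}

## Deterministic within-cell split: largest-remainder apportionment of the
## fractions, then a seeded shuffle of the slot order.
cell_split <- function(n, fractions, seed) {
  exact <- fractions * n
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  slots <- rep(c("train", "val", "test"), times = base)
  prev <- get_rng_state()
  on.exit(set_rng_state(prev), add = TRUE)
  set.seed(seed)
  sample(slots)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Crop every sample of an existing dataset
#'
#' Applies one crop specification to all channels of all samples; labels,
#' metadata and split membership are unchanged.
#'
#' @param dataset An `evac_dataset`.
#' @param side Crop side length.
#' @param where Anchor keyword for [crop_anchor()], or ignored when
#'   `anchor` is given.
#' @param anchor Optional explicit (row, col) upper-left corner.
#' @return A new `evac_dataset` with cropped images.
#' @export
crop_dataset <- function(dataset, side, where = c("topleft", "exit"),
                         anchor = NULL) {
  d <- dim(dataset$x)
  H <- d[3]
  if (is.null(anchor)) anchor <- crop_anchor(H, side, match.arg(where))
  if (side < 1 || anchor[1] < 1 || anchor[2] < 1 ||
      anchor[1] + side - 1 > d[3] || anchor[2] + side - 1 > d[4])
    stop("crop does not lie fully inside the image", call. = FALSE)
  out <- dataset
  out$x <- dataset$x[, , anchor[1]:(anchor[1] + side - 1),
                     anchor[2]:(anchor[2] + side - 1), drop = FALSE]
  out$manifest$crop <- list(side = side, anchor = anchor)
  out
}

#' Keep only the first `channels` frames of every sample
#'
#' Because windows are cut forward from their start frame, the first `c`
#' channels of a longer window equal the `c`-frame window at the same
#' start, so one wide dataset can serve a whole frame-count sweep on
#' identical simulations.
#'
#' @param dataset An `evac_dataset`.
#' @param channels Number of leading channels to keep.
#' @return A new `evac_dataset`.
#' @export
channel_subset <- function(dataset, channels) {
  if (channels < 1 || channels > dim(dataset$x)[2])
    stop("`channels` outside the available range", call. = FALSE)
  out <- dataset
  out$x <- dataset$x[, seq_len(channels), , , drop = FALSE]
  out$manifest$channels <- as.integer(channels)
  out
}

#' Restrict a dataset to a subset of samples
#'
#' @param dataset An `evac_dataset`.
#' @param keep Logical or integer index over samples.
#' @return The reduced `evac_dataset`.
#' @export
subset_dataset <- function(dataset, keep) {
  out <- dataset
  out$x <- dataset$x[keep, , , , drop = FALSE]
  out$y <- dataset$y[keep]
  out$meta <- dataset$meta[keep, , drop = FALSE]
  out$split <- dataset$split[keep]
  out
}

#' @export
print.evac_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("Evacuation dataset: %d samples of %d x %d x %d (C x H x W)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  label: %s, rule: %s, replicates: %s\n",
              x$manifest$label, x$manifest$rule, x$manifest$replicates))
  cat(sprintf("  densities: %s | alpha values: %d | windows/cell: %d\n",
              paste(x$manifest$rho0, collapse = ", "),
              length(x$manifest$alpha), x$manifest$windows))
  cat("  split: ", paste(sprintf("%s=%d", levels(x$split), table(x$split)),
                         collapse = " "), "\n", sep = "")
  invisible(x)
}
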