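#' Configure an evacuation simulation
#'
#' Builds the full parameterization of one cellular-automaton evacuation run:
#' an `L x L` lattice whose boundary ring is wall except for one or two exit
#' cells, an initial crowd placed uniformly at random on the interior at
#' density `rho0`, and the replicator-dynamics transition rule controlled by
#' the rational parameter `alpha` (attraction of the exit direction) and the
#' floor weight `epsilon` (minimal weight of unattractive or blocked
#' directions).
#'
#' @param L Lattice side length in cells (including the wall ring); `L >= 3`.
#' @param alpha Rational parameter, the weight of the exit direction in the
#'   transition stencil; dimensionless, `alpha >= 0`. Large `alpha` means
#'   pedestrians press stubbornly towards the exit even when it is blocked;
#'   small `alpha` means they wander when blocked.
#' @param epsilon Floor weight given to occupied/blocked/unfavoured
#'   directions, `0 < epsilon << 1`. Keeps every transition stencil
#'   normalizable.
#' @param rho0 Initial density: fraction of interior cells occupied at t = 0,
#'   in `[0, 1]`. The pedestrian count is `round(rho0 * (L-2)^2)`.
#' @param exits Either `"single"` (one exit cell at the vertical midpoint of
#'   the right wall, row `ceiling(L/2)`), `"double"` (two exit cells on the
#'   right wall at rows `ceiling(L/2) - exit_sep` and `ceiling(L/2) +
#'   exit_sep`), or a two-column matrix of (row, col) boundary coordinates.
#' @param exit_sep Half-separation (cells) of the symmetric double exit;
#'   only used when `exits = "double"`.
#' @param rule Behaviour rule: `"rational"` (bounded-rational weight B = 1
#'   everywhere) or `"crowd"` (B equals the mean-field fraction of other
#'   pedestrians in each 45-degree azimuthal sector).
#' @param max_steps Simulation horizon (time steps).
#' @param seed Integer seed; one run consumes a single R RNG stream seeded
#'   with this value (placement, move sampling and tie-breaks, in that
#'   per-step order).
#'
#' @return An object of class `evac_config`.
#' @examples
#' cfg <- sim_config(L = 24, alpha = 10, rho0 = 0.37, seed = 1)
#' cfg
#' @export
sim_config <- function(L = 24, alpha = 2, epsilon = 0.1, rho0 = 0.3,
                       exits = "single", exit_sep = 6,
                       rule = c("rational", "crowd"),
                       max_steps = 100, seed = 1L) {
  rule <- match.arg(rule)
  if (!is.numeric(L) || length(L) != 1 || L < 3 || L != round(L))
    stop("`L` must be a single integer >= 3", call. = FALSE)
  L <- as.integer(L)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0)
    stop("`alpha` must be a single number >= 0", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0 || epsilon >= 1)
    stop("`epsilon` must be in (0, 1)", call. = FALSE)
  if (!is.numeric(rho0) || length(rho0) != 1 || rho0 < 0 || rho0 > 1)
    stop("`rho0` must be in [0, 1]", call. = FALSE)
  if (!is.numeric(max_steps) || length(max_steps) != 1 || max_steps < 1)
    stop("`max_steps` must be a positive integer", call. = FALSE)
  exit_mat <- resolve_exits(exits, L, exit_sep)
  cfg <- structure(list(
    L = L, alpha = as.numeric(alpha), epsilon = as.numeric(epsilon),
    rho0 = as.numeric(rho0), exits = exit_mat, rule = rule,
    max_steps = as.integer(max_steps), seed = as.integer(seed)
  ), class = "evac_config")
  cfg
}

## Exit coordinates sorted by (row, col): the first entry is the canonical
## tie-break winner when a pedestrian is equidistant from several exits.
resolve_exits <- function(exits, L, exit_sep = 6) {
  mid <- ceiling(L / 2)
  if (is.character(exits) && length(exits) == 1) {
    exit_mat <- switch(exits,
      single = cbind(row = mid, col = L),
      double = {
        lo <- mid - exit_sep
        hi <- mid + exit_sep
        if (lo < 2 || hi > L - 1)
          stop("double exit separation does not fit on the wall", call. = FALSE)
        cbind(row = c(lo, hi), col = L)
      },
      stop("`exits` keyword must be 'single' or 'double'", call. = FALSE)
    )
  } else {
    exit_mat <- as.matrix(exits)
    if (ncol(exit_mat) != 2 || nrow(exit_mat) < 1)
      stop("`exits` must be a non-empty two-column (row, col) matrix", call. = FALSE)
    colnames(exit_mat) <- c("row", "col")
  }
  on_boundary <- exit_mat[, 1] == 1 | exit_mat[, 1] == L |
    exit_mat[, 2] == 1 | exit_mat[, 2] == L
  in_range <- exit_mat[, 1] >= 1 & exit_mat[, 1] <= L &
    exit_mat[, 2] >= 1 & exit_mat[, 2] <= L
  if (!all(on_boundary & in_range))
    stop("all exits must lie on the lattice boundary", call. = FALSE)
  exit_mat <- exit_mat[order(exit_mat[, 1], exit_mat[, 2]), , drop = FALSE]
  storage.mode(exit_mat) <- "integer"
  exit_mat
}

#' @export
print.evac_config <- function(x, ...) {
  cat("Evacuation CA configuration\n")
  cat(sprintf("  lattice      : %d x %d (interior %d x %d)\n",
              x$L, x$L, x$L - 2L, x$L - 2L))
  cat(sprintf("  alpha        : %g   epsilon: %g\n", x$alpha, x$epsilon))
  cat(sprintf("  rho0         : %g  (%d pedestrians)\n", x$rho0,
              round(x$rho0 * (x$L - 2L)^2)))
  cat(sprintf("  exits        : %s\n",
              paste(sprintf("(%d,%d)", x$exits[, 1], x$exits[, 2]),
                    collapse = " ")))
  cat(sprintf("  rule         : %s\n", x$rule))
  cat(sprintf("  max_steps    : %d   seed: %d\n", x$max_steps, x$seed))
  invisible(x)
}
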