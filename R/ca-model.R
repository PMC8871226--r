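## Cellular-automaton evacuation dynamics.
##
## Stencil convention: every per-pedestrian quantity is a 3x3 matrix indexed
## (m, n) over the Moore neighbourhood; m is the row offset (1 = up), n the
## column offset (1 = left), (2, 2) the centre ("stay").  The transition
## stencil is P = B * O * E / sum(B * O * E) with
##   O: 1 for empty-or-exit neighbour cells, epsilon for occupied/wall cells,
##      1 at the centre (staying is always possible);
##   E: alpha in the single Moore direction of smallest azimuth to the
##      nearest exit, epsilon elsewhere (centre included);
##   B: 1 everywhere under the rational rule; under the crowd rule the
##      mean-field fraction of other pedestrians per 45-degree sector,
##      epsilon at the centre, all-ones fallback for a lone pedestrian.

## Moore offsets in column-major (m, n) order; index 5 is the centre.
DIR_DR <- c(-1L, 0L, 1L, -1L, 0L, 1L, -1L, 0L, 1L)
DIR_DC <- c(-1L, -1L, -1L, 0L, 0L, 0L, 1L, 1L, 1L)
## Off-centre directions in lexicographic (m, n) order, the documented
## tie-break order for azimuth arg-mins.
LEX_OFF <- c(1L, 4L, 7L, 2L, 8L, 3L, 6L, 9L)
LEX_ANG <- atan2(DIR_DC[LEX_OFF], DIR_DR[LEX_OFF])

#' Initialise the lattice state
#'
#' Places `round(rho0 * (L-2)^2)` pedestrians uniformly at random (without
#' replacement) on the interior cells, builds the wall ring with exit
#' openings, and sets `t = 0`.  Consumes the current R RNG stream; seed it
#' (or use [run_simulation()], which seeds from the config) for
#' reproducibility.
#'
#' @param config An [sim_config()] object.
#' @return An object of class `evac_state`: occupancy matrix, wall mask,
#'   exit cells, pedestrian registry, time `t` and count `N`.
#' @export
init_state <- function(config) {
  L <- config$L
  walls <- matrix(FALSE, L, L)
  walls[c(1L, L), ] <- TRUE
  walls[, c(1L, L)] <- TRUE
  exit_lin <- (config$exits[, 2] - 1L) * L + config$exits[, 1]
  walls[exit_lin] <- FALSE
  is_exit <- rep(FALSE, L * L)
  is_exit[exit_lin] <- TRUE

  interior <- which(!walls & !matrix(is_exit, L, L) &
                    row(walls) > 1 & row(walls) < L &
                    col(walls) > 1 & col(walls) < L)
  n_ped <- round(config$rho0 * (L - 2L)^2)
  if (n_ped > length(interior))
    stop("rho0 demands more pedestrians than free interior cells", call. = FALSE)
  occ <- matrix(0L, L, L)
  ped_pos <- integer(0)
  if (n_ped > 0) {
    ped_pos <- interior[sample.int(length(interior), n_ped)]
    occ[ped_pos] <- 1L
    names(ped_pos) <- seq_len(n_ped)
  }
  structure(list(
    occ = occ, walls = walls, exit_lin = exit_lin, is_exit = is_exit,
    ped_pos = ped_pos, t = 0L, N = n_ped, L = L
  ), class = "evac_state")
}

#' @export
print.evac_state <- function(x, ...) {
  cat(sprintf("Evacuation state: %d x %d lattice, t = %d, N = %d pedestrians\n",
              x$L, x$L, x$t, x$N))
  invisible(x)
}

ped_coords <- function(state, ids = NULL) {
  pos <- state$ped_pos
  if (!is.null(ids)) pos <- pos[as.character(ids)]
  cbind(row = (pos - 1L) %% state$L + 1L, col = (pos - 1L) %/% state$L + 1L)
}

#' Occupancy stencil O for one pedestrian
#'
#' 3x3 matrix over the Moore directions: 1 where the neighbouring cell is
#' empty or an exit opening, `epsilon` where it is occupied by a pedestrian
#' or a wall.  The centre is 1 (staying put is always possible).
#'
#' @param state An `evac_state`.
#' @param ped Pedestrian id.
#' @param epsilon Floor weight.
#' @return 3x3 numeric matrix.
#' @export
occupancy_stencil <- function(state, ped, epsilon = 0.1) {
  pos <- state$ped_pos[as.character(ped)]
  if (is.na(pos)) stop("unknown pedestrian id", call. = FALSE)
  L <- state$L
  r <- (pos - 1L) %% L + 1L
  c <- (pos - 1L) %/% L + 1L
  O <- matrix(epsilon, 3, 3)
  for (m in 1:3) for (n in 1:3) {
    rr <- r + m - 2L
    cc <- c + n - 2L
    open <- state$is_exit[(cc - 1L) * L + rr] ||
      (!state$walls[rr, cc] && state$occ[rr, cc] == 0L)
    O[m, n] <- if (open) 1 else epsilon
  }
  O[2, 2] <- 1
  O
}

#' Exit-attraction stencil E for one pedestrian
#'
#' Exactly one off-centre entry equals `alpha`: the Moore direction whose
#' unit vector has the smallest angular distance to the vector from the
#' pedestrian to its nearest exit (Euclidean; distance ties go to the exit
#' with the smallest (row, col)).  Azimuth ties are broken towards the
#' lexicographically smallest (m, n).  All other entries, centre included,
#' are `epsilon`.
#'
#' @inheritParams occupancy_stencil
#' @param alpha Rational parameter.
#' @return 3x3 numeric matrix.
#' @export
exit_stencil <- function(state, ped, alpha, epsilon = 0.1) {
  pos <- state$ped_pos[as.character(ped)]
  if (is.na(pos)) stop("unknown pedestrian id", call. = FALSE)
  if (pos %in% state$exit_lin)
    stop("pedestrian is standing on an exit cell; exit direction undefined",
         call. = FALSE)
  L <- state$L
  r <- (pos - 1L) %% L + 1L
  c <- (pos - 1L) %/% L + 1L
  er <- (state$exit_lin - 1L) %% L + 1L
  ec <- (state$exit_lin - 1L) %/% L + 1L
  d2 <- (er - r)^2 + (ec - c)^2
  k <- which.min(d2)                      # exits pre-sorted by (row, col)
  ang <- atan2(ec[k] - c, er[k] - r)
  diffs <- round(abs(((LEX_ANG - ang + pi) %% (2 * pi)) - pi), 9)
  best <- LEX_OFF[which.min(diffs)]
  E <- matrix(epsilon, 3, 3)
  E[best] <- alpha
  E
}

#' Crowd (bounded-rationality) stencil B for one pedestrian
#'
#' Under the rational rule B is all ones.  Under the crowd rule the
#' off-centre entry (m, n) is the fraction of all other pedestrians whose
#' azimuth from this pedestrian falls in the 45-degree sector centred on
#' direction (m, n); the centre entry and empty sectors carry the floor
#' weight `epsilon` (the perceived mean field is never exactly zero --
#' without the floor an empty exit-side sector would make escape
#' impossible), and a lone pedestrian falls back to the all-ones rational
#' stencil.
#'
#' @inheritParams occupancy_stencil
#' @param rule `"rational"` or `"crowd"`.
#' @return 3x3 numeric matrix.
#' @export
crowd_stencil <- function(state, ped, rule = c("rational", "crowd"),
                          epsilon = 0.1) {
  rule <- match.arg(rule)
  pos <- state$ped_pos[as.character(ped)]
  if (is.na(pos)) stop("unknown pedestrian id", call. = FALSE)
  if (rule == "rational" || state$N <= 1L) return(matrix(1, 3, 3))
  L <- state$L
  r <- (pos - 1L) %% L + 1L
  c <- (pos - 1L) %/% L + 1L
  others <- state$ped_pos[state$ped_pos != pos]
  orow <- (others - 1L) %% L + 1L
  ocol <- (others - 1L) %/% L + 1L
  sec <- azimuth_sector(orow - r, ocol - c)
  B <- matrix(0, 3, 3)
  cnt <- tabulate(sec, nbins = 9L)
  B[seq_len(9)] <- cnt / length(others)
  B[B == 0] <- epsilon
  B[2, 2] <- epsilon
  B
}

## Map displacement vectors to the stencil index (column-major, 3x3) of the
## Moore direction whose azimuth is nearest.  Sector boundaries (odd
## multiples of 22.5 degrees) are unreachable for integer displacements.
azimuth_sector <- function(dr, dc) {
  s <- round(atan2(dc, dr) / (pi / 4))
  s[s == -4L] <- 4L
  ## s counts 45-degree steps from direction (dr=1, dc=0), i.e. (m,n)=(3,2).
  lut <- integer(9)
  lut[(-3:4) + 4L] <- c(1L, 2L, 3L, 6L, 9L, 8L, 7L, 4L)
  lut[s + 4L]
}

#' Replicator-dynamics transition stencil
#'
#' Combines the occupancy, exit and crowd stencils into the move
#' distribution `P = B * O * E / sum(B * O * E)` (elementwise products).
#'
#' @param O,E,B 3x3 stencil matrices with non-negative entries.
#' @return 3x3 matrix of probabilities summing to one.
#' @export
transition_stencil <- function(O, E, B) {
  W <- B * O * E
  s <- sum(W)
  if (!is.finite(s) || s <= 0)
    stop("degenerate transition stencil: all weights zero", call. = FALSE)
  W / s
}

## Vectorized transition matrix for all pedestrians: N x 9 probabilities in
## column-major (m, n) order plus the linear index of each direction's
## target cell.  This is the hot path used by propose_moves(); it must agree
## with the per-pedestrian stencil functions (tested).
transition_matrix <- function(state, config) {
  pos <- state$ped_pos
  N <- length(pos)
  L <- state$L
  eps <- config$epsilon
  r <- (pos - 1L) %% L + 1L
  c <- (pos - 1L) %/% L + 1L
  nbr_r <- outer(r, DIR_DR, "+")
  nbr_c <- outer(c, DIR_DC, "+")
  lin <- (nbr_c - 1L) * L + nbr_r

  open <- matrix(state$is_exit[lin], N, 9) |
    (!state$walls[lin] & state$occ[lin] == 0L)
  O <- ifelse(open, 1, eps)
  O[, 5] <- 1

  ## nearest exit (Euclidean; ties -> first exit in (row, col) order)
  er <- (state$exit_lin - 1L) %% L + 1L
  ec <- (state$exit_lin - 1L) %/% L + 1L
  if (length(er) == 1L) {
    tr <- er - r
    tc <- ec - c
  } else {
    d2 <- outer(r, er, function(a, b) (b - a)^2) +
      outer(c, ec, function(a, b) (b - a)^2)
    k <- max.col(-d2, ties.method = "first")
    tr <- er[k] - r
    tc <- ec[k] - c
  }
  ang <- atan2(tc, tr)
  diffs <- round(abs(outer(ang, LEX_ANG, function(a, b) ((b - a + pi) %% (2 * pi)) - pi)), 9)
  best <- LEX_OFF[max.col(-diffs, ties.method = "first")]
  E <- matrix(eps, N, 9)
  E[cbind(seq_len(N), best)] <- config$alpha

  if (config$rule == "rational" || N <= 1L) {
    B <- matrix(1, N, 9)
  } else {
    drm <- outer(r, r, function(a, b) b - a)
    dcm <- outer(c, c, function(a, b) b - a)
    sec <- matrix(azimuth_sector(as.vector(drm), as.vector(dcm)), N, N)
    B <- matrix(0, N, 9)
    for (d in seq_len(9)) B[, d] <- rowSums(sec == d)
    B[, 6] <- B[, 6] - 1     # self: zero displacement has azimuth 0 -> slot 6
    B <- B / (N - 1L)
    B[B == 0] <- eps         # floor: the perceived mean field is never zero
    B[, 5] <- eps
  }

  W <- B * O * E
  P <- W / rowSums(W)
  list(P = P, targets = lin, ids = names(pos))
}

#' Sample proposed moves for every pedestrian
#'
#' Draws one of the nine Moore cells for each pedestrian from its transition
#' stencil and records the probability of the sampled entry (used for
#' conflict resolution).  A sampled wall cell resolves to "stay".
#'
#' @param state An `evac_state` with `N > 0`.
#' @param config The generating `evac_config`.
#' @return A data frame with one row per pedestrian: `id`, `from`, `target`
#'   (linear cell indices) and `prob`.
#' @export
propose_moves <- function(state, config) {
  tm <- transition_matrix(state, config)
  N <- nrow(tm$P)
  cum <- tm$P
  for (j in 2:9) cum[, j] <- cum[, j] + cum[, j - 1]
  u <- stats::runif(N)
  choice <- rowSums(cum < u) + 1L
  choice[choice > 9L] <- 9L              # guard against fp round-off
  target <- tm$targets[cbind(seq_len(N), choice)]
  prob <- tm$P[cbind(seq_len(N), choice)]
  from <- unname(state$ped_pos)
  wall_hit <- state$walls[target]
  target[wall_hit | choice == 5L] <- from[wall_hit | choice == 5L]
  data.frame(id = as.integer(tm$ids), from = from, target = target,
             prob = prob)
}

#' Resolve same-target conflicts between proposed moves
#'
#' A move is admissible only if its target cell was empty (or an exit
#' opening) before the step; among pedestrians contesting one ordinary cell
#' the one with the largest recorded transition probability moves and the
#' rest stay, with exact ties broken uniformly at random.  Winners of
#' distinct cells move simultaneously.  Exit openings are absorbing: every
#' pedestrian whose destination is an exit escapes in that step, without
#' competing for the cell (the opening is a hole in the wall, not a cell
#' that fills up).
#'
#' @param proposals Output of [propose_moves()].
#' @param state The `evac_state` the proposals were drawn from.
#' @return `proposals` with an added logical column `moved` and `final`, the
#'   resolved cell of each pedestrian.
#' @export
resolve_conflicts <- function(proposals, state) {
  target <- proposals$target
  wants <- target != proposals$from &
    !state$walls[target] & state$occ[target] == 0L
  exiting <- wants & state$is_exit[target]
  final <- proposals$from
  moved <- rep(FALSE, nrow(proposals))
  final[exiting] <- target[exiting]
  moved[exiting] <- TRUE
  contesting <- wants & !exiting
  if (any(contesting)) {
    idx <- which(contesting)
    tie <- stats::runif(length(idx))
    ord <- idx[order(target[idx], -proposals$prob[idx], tie)]
    win <- ord[!duplicated(target[ord])]
    final[win] <- target[win]
    moved[win] <- TRUE
  }
  proposals$final <- final
  proposals$moved <- moved
  proposals
}

#' Advance the simulation by one synchronous step
#'
#' Samples proposals, resolves conflicts, moves the winners, removes
#' pedestrians whose resolved cell is an exit opening (they escape at time
#' `t + 1`) and increments `t`.  A state with `N = 0` is returned unchanged
#' apart from the time counter.
#'
#' @inheritParams propose_moves
#' @return The updated `evac_state`, with an `escaped` attribute holding the
#'   ids removed during this step.
#' @export
ca_step <- function(state, config) {
  if (state$N == 0L) {
    state$t <- state$t + 1L
    attr(state, "escaped") <- integer(0)
    return(state)
  }
  res <- resolve_conflicts(propose_moves(state, config), state)
  movers <- which(res$moved)
  state$occ[res$from[movers]] <- 0L
  escaped_rows <- movers[state$is_exit[res$final[movers]]]
  landed <- setdiff(movers, escaped_rows)
  state$occ[res$final[landed]] <- 1L
  pos <- state$ped_pos
  pos[as.character(res$id[landed])] <- res$final[landed]
  if (length(escaped_rows)) pos <- pos[!names(pos) %in% as.character(res$id[escaped_rows])]
  state$ped_pos <- pos
  state$N <- length(pos)
  state$t <- state$t + 1L
  attr(state, "escaped") <- as.integer(res$id[escaped_rows])
  state
}

#' Run a full evacuation simulation
#'
#' Seeds the RNG from the config, initialises the lattice and iterates
#' [ca_step()] until everyone has escaped or `max_steps` is reached.  One
#' binary occupancy frame is recorded per time step (the state *before* that
#' step's moves, i.e. the states at t = 0, 1, ...).
#'
#' @param config An [sim_config()] object.
#' @return An object of class `evac_run` (a frame stack): `frames`, an
#'   `L x L x n_frames` binary array with time attribute `times`;
#'   `escape_log`, a data frame of (id, time); and the generating `config`.
#' @examples
#' run <- run_simulation(sim_config(L = 12, alpha = 5, rho0 = 0.2, seed = 1))
#' run
#' @export
run_simulation <- function(config) {
  set.seed(config$seed)
  state <- init_state(config)
  frames <- vector("list", config$max_steps + 1L)
  frames[[1L]] <- state$occ
  esc_id <- integer(0)
  esc_t <- integer(0)
  while (state$N > 0L && state$t < config$max_steps) {
    state <- ca_step(state, config)
    out <- attr(state, "escaped")
    if (length(out)) {
      esc_id <- c(esc_id, out)
      esc_t <- c(esc_t, rep(state$t, length(out)))
    }
    frames[[state$t + 1L]] <- state$occ
  }
  frames <- frames[seq_len(state$t + 1L)]
  arr <- array(unlist(frames, use.names = FALSE),
               dim = c(config$L, config$L, length(frames)))
  storage.mode(arr) <- "integer"
  structure(list(
    frames = arr, times = 0:(length(frames) - 1L),
    escape_log = data.frame(id = esc_id, time = esc_t),
    config = config, remaining = state$N
  ), class = "evac_run")
}

#' @export
print.evac_run <- function(x, ...) {
  n0 <- round(x$config$rho0 * (x$config$L - 2L)^2)
  cat(sprintf("Evacuation run: %d frames (t = 0..%d), %d/%d escaped",
              dim(x$frames)[3], max(x$times), nrow(x$escape_log), n0))
  if (x$remaining > 0L)
    cat(sprintf(" (%d remaining at the horizon)", x$remaining))
  cat("\n")
  cat(sprintf("  alpha = %g, rho0 = %g, rule = %s, seed = %d\n",
              x$config$alpha, x$config$rho0, x$config$rule, x$config$seed))
  invisible(x)
}

#' Plot snapshots of an evacuation run
#'
#' Renders occupancy frames as lattice images (pedestrians dark, walls
#' grey), mirroring the usual room-evacuation snapshot figures.
#'
#' @param x An `evac_run`.
#' @param times Time steps to show (defaults to up to four spread over the
#'   run).
#' @param ... Unused.
#' @export
plot.evac_run <- function(x, times = NULL, ...) {
  if (is.null(times)) {
    tmax <- max(x$times)
    times <- unique(round(seq(0, tmax, length.out = min(4, tmax + 1))))
  }
  op <- graphics::par(mfrow = c(1, length(times)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  L <- x$config$L
  walls <- matrix(0L, L, L)
  walls[c(1, L), ] <- 1L
  walls[, c(1, L)] <- 1L
  walls[(x$config$exits[, 2] - 1L) * L + x$config$exits[, 1]] <- 0L
  for (tt in times) {
    img <- x$frames[, , tt + 1L] * 2L + walls
    graphics::image(t(img[L:1, ]), col = c("white", "grey60", "grey10"),
                    axes = FALSE, main = sprintf("t = %d", tt), asp = 1,
                    zlim = c(0, 2))
  }
  invisible(x)
}

#' Mean escape time over independent replicates
#'
#' Runs the simulation `n_reps` times with seeds `config$seed + 0:(n_reps-1)`
#' and averages the time of the final escape; runs in which pedestrians
#' remain at the horizon are censored at `max_steps`.
#'
#' @param config An [sim_config()] object.
#' @param n_reps Number of replicates (>= 1).
#' @return A list with `mean`, `sd` (`NA` for a single replicate), the raw
#'   `times` and the number of censored runs.
#' @export
mean_escape_time <- function(config, n_reps = 50) {
  stopifnot(n_reps >= 1)
  times <- numeric(n_reps)
  censored <- 0L
  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    run <- run_simulation(cfg)
    if (run$remaining > 0L) {
      times[i] <- config$max_steps
      censored <- censored + 1L
    } else {
      times[i] <- if (nrow(run$escape_log)) max(run$escape_log$time) else 0
    }
  }
  list(mean = mean(times), sd = if (n_reps > 1) stats::sd(times) else NA_real_,
       times = times, censored = censored)
}
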