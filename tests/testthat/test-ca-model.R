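test_that("initial placement follows the rounding rule and the geometry", {
  cfg <- sim_config(L = 24, alpha = 10, rho0 = 0.37, seed = 1)
  set.seed(1)
  st <- init_state(cfg)
  expect_equal(st$N, 179)                    # round(0.37 * 22^2)
  expect_equal(sum(st$occ), 179)
  expect_equal(length(st$ped_pos), 179)
  ## walls on the full ring except the exit opening at (12, 24)
  expect_true(all(st$walls[1, ]) && all(st$walls[24, ]) && all(st$walls[, 1]))
  expect_false(st$walls[12, 24])
  expect_true(all(st$walls[setdiff(1:24, 12), 24]))
  ## nobody on a wall, nobody outside the interior
  expect_true(all(st$occ[st$walls] == 0))
  expect_true(all(st$occ[c(1, 24), ] == 0) && all(st$occ[, c(1, 24)] == 0))

  ## empty room
  set.seed(1)
  st0 <- init_state(sim_config(L = 24, rho0 = 0, seed = 1))
  expect_equal(st0$N, 0)
  expect_equal(sum(st0$occ), 0)

  ## determinism under a fixed seed
  set.seed(7); a <- init_state(cfg)
  set.seed(7); b <- init_state(cfg)
  expect_identical(a$occ, b$occ)
})

test_that("double exits sit symmetrically on the right wall", {
  cfg <- sim_config(L = 24, exits = "double", exit_sep = 6)
  expect_equal(unname(cfg$exits[, 1]), c(6, 18))
  expect_equal(unname(cfg$exits[, 2]), c(24, 24))
  expect_error(sim_config(L = 24, exits = "triple"), "single")
  expect_error(sim_config(L = 24, exits = cbind(5, 5)), "boundary")
})

test_that("configuration validation rejects bad parameters", {
  expect_error(sim_config(alpha = -1), "alpha")
  expect_error(sim_config(epsilon = 0), "epsilon")
  expect_error(sim_config(rho0 = 1.2), "rho0")
  expect_error(sim_config(L = 2), "L")
})

test_that("occupancy stencil marks empty, occupied, wall and exit cells", {
  ## lone pedestrian mid-room: all neighbours empty
  st <- place_state(L = 8, peds = c(4, 4))
  O <- occupancy_stencil(st, 1, epsilon = 0.1)
  expect_equal(O, matrix(1, 3, 3))

  ## interior corner: five wall-adjacent entries at epsilon
  st <- place_state(L = 8, peds = c(2, 2))
  O <- occupancy_stencil(st, 1, epsilon = 0.1)
  expect_equal(sum(O == 0.1), 5)
  expect_equal(O[1, 1], 0.1)   # towards the corner
  expect_equal(O[3, 3], 1)     # into the room
  expect_equal(O[2, 2], 1)     # staying is always possible

  ## a neighbouring occupied cell and a neighbouring exit opening
  L <- 8; mid <- ceiling(L / 2)             # exit at (4, 8)
  st <- place_state(L = L, peds = rbind(c(mid, L - 1), c(mid - 1, L - 1)))
  O <- occupancy_stencil(st, 1, epsilon = 0.1)
  expect_equal(O[2, 3], 1)     # the exit cell counts as enterable
  expect_equal(O[1, 2], 0.1)   # the other pedestrian
})

test_that("exit stencil puts alpha on the azimuth arg-min direction", {
  L <- 24; mid <- 12                         # single exit at (12, 24)
  ## due east
  st <- place_state(L = L, peds = c(mid, 5))
  E <- exit_stencil(st, 1, alpha = 3, epsilon = 0.1)
  expect_equal(E[2, 3], 3)
  expect_equal(sum(E == 3), 1)
  expect_equal(E[1, 1], 0.1)

  ## exactly 45 degrees north-west of the exit: direction (3, 3)
  st <- place_state(L = L, peds = c(mid - 4, 20))
  E <- exit_stencil(st, 1, alpha = 3)
  expect_equal(E[3, 3], 3)

  ## straight north of the exit: direction (3, 2)
  st <- place_state(L = L, peds = c(mid - 5, 24 - 1))
  ## (col 23 so the pedestrian is interior; vector is (5, 1): closest to SE?
  ## no -- atan2(1, 5) ~ 11 degrees from straight south, so (3, 2))
  E <- exit_stencil(st, 1, alpha = 3)
  expect_equal(E[3, 2], 3)

  ## standing on the exit cell is an error
  st <- place_state(L = L)
  st$ped_pos <- c("1" = (24L - 1L) * 24L + 12L)
  st$N <- 1L
  expect_error(exit_stencil(st, 1, alpha = 3), "exit")
})

test_that("nearest-exit selection and symmetric ties are deterministic", {
  L <- 24
  ## double exits at (6, 24) and (18, 24); pedestrian on the symmetry axis
  st <- place_state(L = L, peds = c(12, 10), exits = "double", exit_sep = 6)
  E1 <- exit_stencil(st, 1, alpha = 3)
  E2 <- exit_stencil(st, 1, alpha = 3)
  expect_identical(E1, E2)
  ## ties resolve to the first exit in (row, col) order: (6, 24), north-east
  expect_equal(E1[1, 3], 3)
  ## nearer the southern exit: that one wins
  st <- place_state(L = L, peds = c(17, 20), exits = "double", exit_sep = 6)
  E <- exit_stencil(st, 1, alpha = 3)
  expect_equal(sum(E == 3), 1)
  expect_true(E[2, 3] == 3 || E[3, 3] == 3)
})

test_that("crowd stencil is the sector histogram of the other pedestrians", {
  ## rational rule: all ones
  st <- place_state(L = 10, peds = rbind(c(5, 5), c(4, 5)))
  expect_equal(crowd_stencil(st, 1, "rational"), matrix(1, 3, 3))

  ## four other pedestrians all due north: their sector takes all the mass,
  ## every empty sector keeps the epsilon floor
  st <- place_state(L = 12, peds = rbind(c(8, 5), c(7, 5), c(6, 5),
                                         c(5, 5), c(4, 5)))
  B <- crowd_stencil(st, 1, "crowd", epsilon = 0.1)
  expect_equal(B[1, 2], 1)
  expect_equal(B[2, 2], 0.1)                 # centre floor
  off <- B; off[1, 2] <- NA
  expect_true(all(off == 0.1, na.rm = TRUE))

  ## mixed sectors: populated sectors carry the exact fractions
  st <- place_state(L = 12, peds = rbind(c(6, 6), c(6, 9), c(3, 6),
                                         c(9, 9), c(6, 3)))
  B <- crowd_stencil(st, 1, "crowd", epsilon = 0.01)
  expect_equal(B[2, 3] , 0.25)               # east
  expect_equal(sum(B[B != 0.01]), 1)

  ## the last pedestrian falls back to the rational stencil
  st <- place_state(L = 10, peds = c(5, 5))
  expect_equal(crowd_stencil(st, 1, "crowd"), matrix(1, 3, 3))
})

test_that("transition stencil is the normalized product B * O * E", {
  eps <- 1e-6
  ## free exit direction, seven blocked directions, alpha = 2:
  ## P(exit) = 2 / (2 + 7 eps^2 + eps) ~ 1
  O <- matrix(eps, 3, 3); O[2, 2] <- 1; O[2, 3] <- 1
  E <- matrix(eps, 3, 3); E[2, 3] <- 2
  B <- matrix(1, 3, 3)
  P <- transition_stencil(O, E, B)
  expect_equal(sum(P), 1, tolerance = 1e-12)
  expect_equal(P[2, 3], 1, tolerance = 1e-5)

  ## alpha = 0 with everything empty: no move towards the exit at all,
  ## the mass spreads uniformly over the epsilon-weighted directions
  O <- matrix(1, 3, 3)
  E <- matrix(eps, 3, 3); E[2, 3] <- 0
  P <- transition_stencil(O, E, B)
  expect_equal(P[2, 3], 0)
  others <- P[-c(5, 8)]                      # drop centre and exit entries
  expect_equal(max(others) - min(others), 0, tolerance = 1e-15)
  expect_equal(sum(P), 1, tolerance = 1e-12)

  expect_error(transition_stencil(matrix(0, 3, 3), E, B), "degenerate")
})

test_that("vectorized transition probabilities match per-pedestrian stencils", {
  for (rule in c("rational", "crowd")) {
    cfg <- sim_config(L = 14, alpha = 1.7, rho0 = 0.3, rule = rule, seed = 42)
    set.seed(42)
    st <- init_state(cfg)
    tm <- evacnn:::transition_matrix(st, cfg)
    for (ped in as.integer(sample(names(st$ped_pos), 12))) {
      P_ref <- transition_stencil(
        occupancy_stencil(st, ped, cfg$epsilon),
        exit_stencil(st, ped, cfg$alpha, cfg$epsilon),
        crowd_stencil(st, ped, rule, cfg$epsilon))
      row <- which(tm$ids == as.character(ped))
      expect_equal(unname(tm$P[row, ]), as.vector(P_ref), tolerance = 1e-12)
    }
  }
})

test_that("proposals are sampled from the stencil and are seed-deterministic", {
  cfg <- sim_config(L = 10, alpha = 50, rho0 = 0, seed = 1)
  st <- place_state(L = 10, peds = c(5, 5))
  ## alpha = 50 concentrates the stencil on the exit direction
  set.seed(3)
  hits <- replicate(2000, {
    p <- propose_moves(st, cfg)
    p$target
  })
  east <- (5 + 1 - 1) * 10 + 5               # cell (5, 6)
  expect_gt(mean(hits == east), 0.95)

  set.seed(9); p1 <- propose_moves(st, cfg)
  set.seed(9); p2 <- propose_moves(st, cfg)
  expect_identical(p1, p2)
})

test_that("conflicts go to the larger transition probability, ties uniform", {
  st <- place_state(L = 10, peds = rbind(c(5, 5), c(5, 7), c(3, 6)))
  target <- (6 - 1) * 10 + 5                 # everyone wants (5, 6)
  mk <- function(probs) data.frame(id = 1:3, from = unname(st$ped_pos),
                                   target = target, prob = probs)
  res <- resolve_conflicts(mk(c(0.6, 0.3, 0.2)), st)
  expect_equal(res$final[1], target)
  expect_equal(res$moved, c(TRUE, FALSE, FALSE))
  expect_equal(res$final[2:3], unname(st$ped_pos[2:3]))

  ## exact tie between two pedestrians: each wins about half the time
  two <- place_state(L = 10, peds = rbind(c(5, 5), c(5, 7)))
  props <- data.frame(id = 1:2, from = unname(two$ped_pos),
                      target = target, prob = c(0.5, 0.5))
  set.seed(123)
  wins <- replicate(10000, resolve_conflicts(props, two)$moved[1])
  expect_equal(mean(wins), 0.5, tolerance = 3 * 0.5 / sqrt(10000))

  ## a target occupied before the step is not enterable
  occ_target <- place_state(L = 10, peds = rbind(c(5, 5), c(5, 6)))
  props <- data.frame(id = 1:2, from = unname(occ_target$ped_pos),
                      target = c((6 - 1) * 10 + 5, (6 - 1) * 10 + 5),
                      prob = c(0.9, 0.1))
  ## pedestrian 2 "stays" (its own cell is the contested target)
  res <- resolve_conflicts(props, occ_target)
  expect_false(res$moved[1])
})

test_that("a step moves, removes escapees and preserves the invariants", {
  cfg <- sim_config(L = 8, alpha = 1000, rho0 = 0, seed = 1)
  ## pedestrian right next to the exit (4, 8): escapes almost surely
  st <- place_state(L = 8, peds = c(4, 7))
  set.seed(2)
  st2 <- ca_step(st, cfg)
  expect_equal(st2$N, 0)
  expect_equal(attr(st2, "escaped"), 1L)
  expect_equal(sum(st2$occ), 0)
  expect_equal(st2$t, 1L)

  ## empty room: no-op apart from the clock
  st0 <- place_state(L = 8)
  st1 <- ca_step(st0, cfg)
  expect_equal(st1$N, 0)
  expect_equal(st1$t, 1L)

  ## conservation and exclusion along a crowded run
  cfg <- sim_config(L = 12, alpha = 2, rho0 = 0.4, seed = 5)
  set.seed(5)
  st <- init_state(cfg)
  for (i in 1:15) {
    prevN <- st$N
    st <- ca_step(st, cfg)
    expect_equal(sum(st$occ), st$N)
    expect_lte(st$N, prevN)
    expect_true(all(st$occ %in% c(0L, 1L)))
    expect_true(all(st$occ[st$walls] == 0))
    expect_equal(unname(st$occ[st$ped_pos]), rep(1L, st$N))
  }
})

test_that("a full run records one frame per step and reproduces bitwise", {
  cfg <- sim_config(L = 24, alpha = 4, rho0 = 0.2, max_steps = 100, seed = 21)
  run <- run_simulation(cfg)
  expect_lte(dim(run$frames)[3], 101)
  expect_equal(dim(run$frames)[1:2], c(24, 24))
  expect_true(all(run$frames %in% c(0L, 1L)))
  ## pedestrian count per frame never increases
  counts <- apply(run$frames, 3, sum)
  expect_true(all(diff(counts) <= 0))
  ## escapes + remaining = initial population
  expect_equal(nrow(run$escape_log) + run$remaining, round(0.2 * 22^2))

  run2 <- run_simulation(cfg)
  expect_identical(run$frames, run2$frames)
  expect_identical(run$escape_log, run2$escape_log)

  empty <- run_simulation(sim_config(L = 24, rho0 = 0, seed = 3))
  expect_equal(sum(empty$frames), 0)
  expect_equal(nrow(empty$escape_log), 0)
})

test_that("a lone pedestrian follows the greedy azimuth path to the exit", {
  ## Independent oracle: a deterministic walker that always takes the
  ## azimuth arg-min direction (the limit alpha -> Inf of the stencil).
  ## When that path is wall-free it has exactly the Chebyshev length; when
  ## it presses into the wall ring next to the exit the walker stalls and
  ## the stochastic dynamics can only be slower.
  greedy_path <- function(r, c, er = 12, ec = 24, L = 24, max_iter = 200) {
    dirs <- expand.grid(m = 1:3, n = 1:3)
    dirs <- dirs[!(dirs$m == 2 & dirs$n == 2), ]
    dirs <- dirs[order(dirs$m, dirs$n), ]
    ang <- atan2(dirs$n - 2, dirs$m - 2)
    for (step in seq_len(max_iter)) {
      if (r == er && c == ec) return(list(len = step - 1, clean = TRUE))
      a <- atan2(ec - c, er - r)
      d <- round(abs(((ang - a + pi) %% (2 * pi)) - pi), 9)
      k <- which.min(d)
      rr <- r + dirs$m[k] - 2; cc <- c + dirs$n[k] - 2
      wall <- (rr == 1 || rr == L || cc == 1 || cc == L) &&
        !(rr == er && cc == ec)
      if (wall) return(list(len = Inf, clean = FALSE))
      r <- rr; c <- cc
    }
    list(len = Inf, clean = FALSE)
  }
  ## rho0 chosen so exactly one pedestrian is placed
  expect_equal(round(0.002 * 22^2), 1)
  cfg <- sim_config(L = 24, alpha = 1000, rho0 = 0.002, max_steps = 100,
                    seed = 0)
  clean_checked <- 0
  for (s in 31:40) {
    cfg$seed <- s
    run <- run_simulation(cfg)
    pos <- which(run$frames[, , 1] == 1)
    r <- (pos - 1) %% 24 + 1; c <- (pos - 1) %/% 24 + 1
    oracle <- greedy_path(r, c)
    cheb <- max(abs(r - 12), abs(c - 24))
    if (oracle$clean) {
      expect_equal(oracle$len, cheb)         # greedy = Chebyshev when clean
      expect_equal(max(run$escape_log$time), cheb)
      clean_checked <- clean_checked + 1
    } else if (nrow(run$escape_log)) {
      expect_gte(max(run$escape_log$time), cheb)
    }
  }
  expect_gte(clean_checked, 3)               # the oracle actually fired
})

test_that("mean escape time aggregates replicates and censors at the horizon", {
  cfg <- sim_config(L = 12, alpha = 5, rho0 = 0.1, max_steps = 200, seed = 50)
  met <- mean_escape_time(cfg, n_reps = 5)
  expect_length(met$times, 5)
  expect_equal(met$mean, mean(met$times))
  expect_true(met$sd >= 0)
  one <- mean_escape_time(cfg, n_reps = 1)
  expect_true(is.na(one$sd))
  ## a horizon too short to finish censors every replicate
  cfg$max_steps <- 3L
  met3 <- mean_escape_time(cfg, n_reps = 3)
  expect_equal(met3$censored, 3L)
  expect_equal(met3$mean, 3)
})
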