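# evacnn

Cellular-automaton evacuation simulation and convolutional inference of
behavioural rationality.

## The problem

How strongly people weight exit information against everything else is a
key driver of how a crowd evacuates a room — and it is not directly
observable.  `evacnn` addresses the simulation-based-inference version of
this question for R users: it simulates room evacuation with a
replicator-dynamics cellular automaton in which a single *rational
parameter* α sets the attraction of the exit direction, turns stacks of
binary occupancy snapshots into labelled samples, and fits a small
convolutional regression network that reads α (or the initial crowd
density ρ₀) back off the images.  Transferring a model trained on
optimal-strategy (rational-rule) simulations to bounded-rational
(crowd-rule) simulations measures the apparent deviation from optimality,
δα, induced by herding.

It is aimed at researchers in pedestrian dynamics / collective behaviour
who want a self-contained, fully reproducible lattice testbed for
parameter-from-snapshot inference.

## The model

Pedestrians occupy an `L × L` lattice (walls on the ring, one or two exit
openings on the right wall) and update synchronously.  Pedestrian *i*
moves over the Moore directions (m, n) with probability

    P(m,n) = B(m,n) O(m,n) E(m,n) / Σ B O E

where `O` marks free cells (1 empty/exit, ε occupied/wall), `E` carries
the exit attraction (α in the azimuth-arg-min direction towards the
nearest exit, ε elsewhere) and `B` is 1 under the rational rule or the
mean-field fraction of other pedestrians per 45° sector under the crowd
rule.  Same-target conflicts go to the larger sampled probability (ties
uniform); exits are absorbing.  The regressor is an `n_conv`-layer 3×3
convolutional network (max-pool after the first layer, dropout, one dense
layer, linear scalar output) trained with Adam on MSE + L2, implemented
from scratch in RcppArmadillo and gradient-checked against finite
differences.

## Worked example

```r
library(evacnn)

## one simulation
run <- run_simulation(sim_config(L = 24, alpha = 3, rho0 = 0.3, seed = 42))
run
#> Evacuation run: 101 frames (t = 0..100), 126/145 escaped (19 remaining at the horizon)
#>   alpha = 3, rho0 = 0.3, rule = rational, seed = 42

## escape time falls as alpha grows
mean_escape_time(sim_config(alpha = 0.5, rho0 = 0.3, max_steps = 900, seed = 1), n_reps = 10)$mean
#> [1] 195.8
mean_escape_time(sim_config(alpha = 4,   rho0 = 0.3, max_steps = 900, seed = 1), n_reps = 10)$mean
#> [1] 117.8

## a labelled dataset of 8-frame windows and a fitted regressor
ds <- build_dataset(dataset_manifest(rho0 = c(0.2, 0.4),
                                     alpha = alpha_grid(20),
                                     windows = 10, seed = 7))
fit <- evac_cnn(ds, epochs = 15, seed = 1)
unlist(evaluate_model(fit, ds, "test"))
#>        mse        mae         r2          n 
#>  0.3392296  0.4043757  0.8367617 40.0000000
```

The first run shows the congestion regime: 145 pedestrians funnel through
a single opening, and 19 are still inside at the 100-step horizon.  The
escape-time pair shows the monotone effect of rationality (196 → 118
steps).  The fitted network recovers α on held-out windows with R² ≈ 0.84
at this small dataset size; `plot(fit)` draws the loss history, and
`exp_per_density()`, `exp_crop()`, `exp_crowd_transfer()` etc. run the
full experiment suite.

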