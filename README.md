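# myovasim

Mechanistic simulation and analysis of myosin Va ensemble cargo transport
on suspended 3D actin networks.

## The problem

Myosin Va motors carry membrane-bound vesicles through the cell's cortical
actin network. Because the motors are anchored in a fluid lipid membrane,
they diffuse over the cargo surface and assemble into small working teams
wherever the cargo touches a filament. At a filament–filament
intersection, the crossing filament is simultaneously a steric obstacle
and an alternative track, and the outcome — continue straight, turn, or
terminate — is decided by a tug-of-war between the motor ensembles engaged
with the two filaments.

`myovasim` is for biophysicists who want to simulate this system and to
run the corresponding measurement procedures on either simulated or
experimental 3D tracking data.

## The model in brief

* A rigid spherical cargo (diameter 350 nm) carries `n` motors (default
  10) whose anchors diffuse on the sphere (fast-diffusion limit).
* Each motor is a slack-capable elastic linkage (stiffness
  `k_ext = 1 pN/nm` beyond its 50 nm rest length; torsion
  `k_tor = 0.25 pN nm/rad`) with Bell-law kinetics: detachment
  `0.35 s⁻¹ · exp(F δ_d / kBT)`, forward stepping
  `12 s⁻¹ · exp(−F δ_s / kBT)` on the actin lattice (13-subunit 36 nm
  steps, occasionally 11-subunit short steps whose −27.65° azimuth change
  drives a left-handed spiral), and backstepping calibrated so the net
  velocity vanishes exactly at the 1.9 pN stall force.
* Ensemble binding runs at ~2.4 s⁻¹ for a resting cargo and is limited by
  a packing rule: the membrane band within motor reach of a filament
  holds three anchor footprints, which caps working ensembles at three
  motors for the default geometry.
* Between stochastic events the cargo pose is quasi-static: the centre
  relaxes to the elastic-energy minimum subject to sphere–cylinder
  excluded volume (the "re-centring" that lets a blocked cargo reposition
  and slip past an intersecting filament).
* Events are sampled exactly (Gillespie); identical seeds give identical
  event logs.

The analysis toolkit implements: the interaction-geometry bound
`d_int(α) = (R+L)(1+cos α)` (450 nm head-on, 225 nm at 90°), sinusoidal
helix fits `G(t) = c0 + A sin(2πft + φ)` under amplitude/frequency
constraints with handedness from the X–Z phase shift, the 10-frame
approach angle, filament separation from localization clouds,
directional-outcome classification with the compass convention (East =
right turn), Kaplan–Meier run lengths, 250 ms / ±50 nm/s sliding-window
stall-peak detection, BIC-selected Gaussian stall-force mixtures, and
photobleaching motor counting from the binomial variance relation
`σ²_I = v I₀ p (1−p)`.

## Worked example

```r
library(myovasim)

## one intersection encounter: separation d = 100 nm, seeded
cfg <- sim_config("intersection", separation_nm = 100, seed = 7, max_time = 40)
sim <- run_intersection(cfg)
sim
#> <myova_sim> intersection run, 5.8 s, 242 events, outcome: turn_right
sim$outcome_record
#>      alpha   d    outcome  dwell_s interacting
#> 1 38.31298 100 turn_right 2.929705        TRUE
```

The cargo approached the crossing at a measured angle α = 38.3° (same side
as the intersecting filament), hesitated 2.9 s in the interaction zone,
and a second motor ensemble won the tug-of-war: it exited East along the
intersecting filament, a right turn. Batches of such encounters
(`batch_outcomes()`) reproduce the study system's aggregate fractions —
about 61% straight, 33% turning, 6% terminating over interacting
geometries.

```r
## helix fitting on a noisy synthetic spiral (defaults mirror experiment)
fit_helix(gen_helical_trajectory(seed = 1))
#> <helix_fit> left-handed, pitch 2160 nm, velocity 423 nm/s, f 0.196 1/s, A(x,z) = (215, 219) nm
```

A thin command-line surface over the same functions lives in
`inst/scripts/myovasim-cli.R` (subcommands `simulate-run`,
`simulate-intersections`, `simulate-trap`, `analyze-trajectory`,
`classify-outcomes`, `heatmap`, `count-motors`, `detect-stalls`,
`fit-stall-mixture`, `make-fixtures`).

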