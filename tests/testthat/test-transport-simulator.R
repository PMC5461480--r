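# Event-driven engine: determinism, degenerate kinetics, ensemble census,
# trap behaviour and the toy tug-of-war mechanism check.

test_that("a cargo with no motors terminates immediately", {
  s <- simulate_run(sim_config("single_filament", n_motors = 0L, seed = 1))
  expect_equal(s$outcome, "detached")
  expect_equal(nrow(s$events), 0L)
})

test_that("identical seeds give identical event logs", {
  cfg <- sim_config("single_filament", max_time = 4, seed = 33)
  s1 <- simulate_run(cfg)
  s2 <- simulate_run(cfg)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$trajectory, s2$trajectory)
  s3 <- simulate_run(cfg, seed = 34)
  expect_false(identical(s1$events, s3$events))
})

test_that("degenerate kinetics give a uniform forward march", {
  # one motor, detachment and short/back steps disabled: pure 35.75 nm
  # steps at k_step0, i.e. ~429 nm/s to the filament end
  p <- motor_params(k_detach0 = 0, p_short0 = 0, p_short_stall = 0,
                    k_back0 = 0, k_attach_max = 0)
  vs <- vapply(3:5, function(sd) {
    s <- simulate_run(sim_config("single_filament", n_motors = 1L,
                                 motor = p, max_time = 10, seed = sd))
    expect_true(all(s$events$type == "step_long"))
    unname(coef(lm(y_nm ~ t_s, s$trajectory))[2L])
  }, numeric(1))
  # ~ 12 steps/s x 35.75 nm, within Poisson counting noise
  expect_equal(mean(vs), 12 * 35.75, tolerance = 0.12)
})

test_that("trajectory frames are well-formed and the engine is fast enough", {
  s <- simulate_run(sim_config("single_filament", max_time = 6, seed = 5))
  tr <- s$trajectory
  expect_true(all(diff(tr$t_s) > 0))
  expect_true(all(is.finite(as.matrix(tr[, c("x_nm", "y_nm", "z_nm")]))))
  # engaged ensembles never exceed the reach-band packing capacity
  expect_lte(max(tr$engaged_orig), 3L)
})

test_that("engaged census is time-weighted and conserved", {
  s <- simulate_run(sim_config("single_filament", max_time = 6, seed = 5))
  cen <- engaged_motor_census(s)
  expect_true(all(cen$time_s >= 0))
  att <- sum(cen$time_s[cen$count >= 1L])
  expect_equal(sum(cen$fraction[cen$count >= 1L]), 1, tolerance = 1e-9)
  expect_lte(att, max(s$trajectory$t_s, s$events$t) + 1e-9)
  # single-motor cargo can only show counts 0 and 1
  s1 <- simulate_run(sim_config("single_filament", n_motors = 1L,
                                max_time = 6, seed = 8))
  expect_true(all(engaged_motor_census(s1)$count %in% 0:1))
})

test_that("trap runs produce saw-tooth force traces; no motors give zero force", {
  s0 <- simulate_run(sim_config("trap", n_motors = 0L, max_time = 1,
                                frame_interval = 0.01, seed = 1))
  expect_equal(s0$outcome, "detached")
  s <- run_trap(sim_config("trap", max_time = 25, frame_interval = 0.005,
                           seed = 11))
  expect_true(all(s$force$force_pN >= 0))
  expect_gt(max(s$force$force_pN), 1)       # develops pN-scale force
  # force rises and collapses (saw-teeth): large negative excursions exist
  expect_lt(min(diff(s$force$force_pN)), -0.5)
})

test_that("the larger motor team wins the toy tug-of-war", {
  wins <- vapply(1:20, function(sd) tug_of_war_toy(3, 1, seed = sd),
                 character(1))
  expect_gt(mean(wins == "A"), 0.9)
  # symmetric teams are not strongly biased
  wins11 <- vapply(1:20, function(sd) tug_of_war_toy(1, 1, seed = 100 + sd),
                   character(1))
  expect_gt(mean(wins11 == "A"), 0.2)
  expect_lt(mean(wins11 == "A"), 0.8)
})

test_that("intersection runs resolve to a directional outcome with metadata", {
  cfg <- sim_config("intersection", separation_nm = 100, max_time = 30,
                    seed = 103)
  s <- run_intersection(cfg)
  rec <- s$outcome_record
  expect_true(rec$outcome %in% c("straight", "turn_left", "turn_right",
                                 "terminate", "no_reach"))
  if (rec$outcome != "no_reach") {
    expect_true(is.finite(rec$alpha) && rec$alpha >= 0 && rec$alpha < 360)
    expect_gte(rec$dwell_s, 0)
  }
  expect_equal(rec$d, 100)
})
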