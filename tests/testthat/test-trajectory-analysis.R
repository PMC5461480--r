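# Measurement procedures: helix fitting, approach angles, filament
# separation, outcome classification, Kaplan-Meier run lengths, regime map.

test_that("helix fit recovers a noiseless generator exactly", {
  tr <- gen_helical_trajectory(pitch = 2000, radius = 180, velocity = 400,
                               handedness = "left", duration = 20,
                               noise = noise_model(0, 0, 0), seed = 1)
  f <- fit_helix(tr)
  expect_equal(f$handedness, "left")
  expect_equal(f$pitch, 2000, tolerance = 1e-3)
  expect_equal(f$velocity, 400, tolerance = 1e-3)
  expect_equal(f$amplitude_x, 180, tolerance = 1e-2)
  # flipping the generator handedness flips the call
  tr_r <- gen_helical_trajectory(pitch = 2000, radius = 180, velocity = 400,
                                 handedness = "right", duration = 20,
                                 noise = noise_model(0, 0, 0), seed = 1)
  expect_equal(fit_helix(tr_r)$handedness, "right")
})

test_that("helix fit tolerates experimental localization noise", {
  tr <- gen_helical_trajectory(pitch = 2160, radius = 225, velocity = 423,
                               handedness = "left", duration = 30,
                               noise = noise_model(17, 18, 30), seed = 4)
  f <- fit_helix(tr)
  expect_equal(f$handedness, "left")
  expect_lt(abs(f$pitch - 2160) / 2160, 0.10)
})

test_that("non-helical trajectories are recognised", {
  set.seed(9)
  n <- 200
  tr <- data.frame(t_s = seq(0, 19.9, by = 0.1),
                   x_nm = rnorm(n, 0, 20), y_nm = 400 * seq(0, 19.9, by = 0.1),
                   z_nm = rnorm(n, 0, 20))
  expect_equal(fit_helix(tr)$handedness, "non_helical")
  expect_error(fit_helix(tr[1:5, ]), "10 frames")
})

test_that("approach angle matches its compass definition", {
  geom <- intersection_geometry(150)
  t <- seq(0, 2, by = 0.1)
  mk <- function(xoff, zoff) data.frame(
    t_s = t, x_nm = xoff, y_nm = -1200 + 500 * t, z_nm = zoff)
  # vertically above the original filament, intersecting side: 0 degrees
  expect_equal(approach_angle(mk(0, 200), geom), 0, tolerance = 1e-6)
  # vertically below, opposite side: 180 degrees
  expect_equal(approach_angle(mk(0, -200), geom), 180, tolerance = 1e-6)
  # horizontally East: 90 degrees; West: 270
  expect_equal(approach_angle(mk(200, 0), geom), 90, tolerance = 1e-6)
  expect_equal(approach_angle(mk(-200, 0), geom), 270, tolerance = 1e-6)
  # mirror reflection maps alpha to 360 - alpha
  tr <- data.frame(t_s = t, x_nm = 120, y_nm = -1200 + 500 * t, z_nm = 90)
  a1 <- approach_angle(tr, geom)
  tr_m <- tr; tr_m$x_nm <- -tr_m$x_nm
  expect_equal(approach_angle(tr_m, geom), 360 - a1, tolerance = 1e-6)
  expect_error(approach_angle(mk(0, 200)[1:8, ], geom), "10")
})

test_that("filament separation is the Z difference of the clouds", {
  ca <- gen_filament_cloud(100, sigma_z = 0, n_points = 50, seed = 1)
  cb <- gen_filament_cloud(30, sigma_z = 0, n_points = 50, seed = 2)
  r <- filament_separation(ca, cb)
  expect_equal(r$separation_nm, 70)
  expect_false(r$excluded)
  expect_equal(filament_separation(ca, ca)$separation_nm, 0)
  # noisy clouds: within standard-error expectations
  ca <- gen_filament_cloud(120, sigma_z = 5, n_points = 200, seed = 3)
  cb <- gen_filament_cloud(40, sigma_z = 5, n_points = 200, seed = 4)
  expect_lt(abs(filament_separation(ca, cb)$separation_nm - 80), 1.5)
  # beyond the calibrated range: flagged
  cc <- gen_filament_cloud(400, sigma_z = 0, n_points = 50, seed = 5)
  expect_true(filament_separation(ca, cc)$excluded)
  expect_error(filament_separation(ca[1:5, ], cb), "10 points")
})

test_that("outcome classification follows the exit-filament compass rule", {
  geom <- intersection_geometry(100)
  t <- seq(0, 4, by = 0.1)
  # straight: passes the crossing on the original filament
  P <- cbind(0, -1000 + 500 * t, 180)
  expect_equal(classify_outcome(traj_from_points(P), geom), "straight")
  # turn right: exits East along the intersecting filament
  n1 <- sum(-1000 + 500 * t < 0)
  P <- rbind(cbind(0, seq(-1000, 0, length.out = n1), 180),
             cbind(seq(30, 700, length.out = length(t) - n1), 0, 280))
  expect_equal(classify_outcome(traj_from_points(P), geom), "turn_right")
  P[, 1] <- -P[, 1]
  expect_equal(classify_outcome(traj_from_points(P), geom), "turn_left")
  # track ends at the crossing: terminate
  P <- cbind(0, seq(-1000, -50, length.out = length(t)), 180)
  expect_equal(classify_outcome(traj_from_points(P), geom), "terminate")
  # never reaches the intersection region
  P <- cbind(0, seq(-3000, -2000, length.out = length(t)), 180)
  expect_equal(classify_outcome(traj_from_points(P), geom), "not_applicable")
})

test_that("classification agrees with the simulator's own outcome records", {
  agree <- 0L; n <- 0L
  for (sd in c(301, 302, 304, 305, 307, 309)) {
    cfg <- sim_config("intersection", separation_nm = 60 + 20 * (sd %% 7),
                      max_time = 30, seed = sd)
    s <- run_intersection(cfg)
    if (s$outcome == "no_reach") next
    n <- n + 1L
    cls <- classify_outcome(s$trajectory, s$geometry)
    if (cls == s$outcome) agree <- agree + 1L
  }
  expect_gte(agree / n, 0.95)
})

test_that("Kaplan-Meier run lengths match hand-computed product limits", {
  # no censoring: restricted mean reduces to the sample mean
  r <- km_run_length(data.frame(run_length = c(1000, 2000, 3000),
                                censored = FALSE))
  expect_equal(r$mean, 2000)
  expect_equal(r$median, 2000)
  # one observed, one censored beyond it: S(1000) = 0.5, unresolved after
  r <- km_run_length(data.frame(run_length = c(1000, 2000),
                                censored = c(FALSE, TRUE)))
  s <- summary(r$survival, times = c(1000, 1999))
  expect_equal(s$surv, c(0.5, 0.5))
  # survival is monotone non-increasing
  set.seed(2)
  rr <- data.frame(run_length = rexp(40, 1 / 2000),
                   censored = runif(40) < 0.4)
  r <- km_run_length(rr)
  expect_true(all(diff(r$survival$surv) <= 1e-12))
  expect_warning(km_run_length(data.frame(run_length = c(1, 2),
                                          censored = TRUE)), "censored")
})

test_that("straight-to-turn map reports ratios with counts and markers", {
  o <- data.frame(
    alpha = c(rep(30, 15), rep(100, 4)),
    d = c(rep(50, 15), rep(150, 4)),
    outcome = c(rep("straight", 10), rep("turn_left", 3),
                rep("turn_right", 2), rep("straight", 4)))
  h <- straight_turn_heatmap(o)
  low <- h[h$regime == "low_alpha_low_d", ]
  expect_equal(low$ratio, 2)
  expect_equal(low$n_straight, 10); expect_equal(low$n_turn, 5)
  hi <- h[h$regime == "high_alpha_high_d", ]
  expect_true(is.infinite(hi$ratio))  # straights but no turns
  expect_true(is.na(h$ratio[h$regime == "high_alpha_low_d"]))  # empty
})
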