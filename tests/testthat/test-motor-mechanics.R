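# Single-motor elastic linkage, load-dependent kinetics and the quasi-static
# pose relaxation (checked against a brute-force grid oracle).

test_that("linkage force is linear beyond rest length and slack below", {
  p <- motor_params()
  # anchor-head separation 50 nm: at rest length, zero force
  expect_equal(linkage_force(c(0, 0, 50), c(0, 0, 0), p), c(0, 0, 0))
  # 52 nm: 2 pN tension pointing from head toward anchor
  f <- linkage_force(c(0, 0, 52), c(0, 0, 0), p)
  expect_equal(f, c(0, 0, 2))
  # 30 nm: slack, no compression force
  expect_equal(linkage_force(c(0, 0, 30), c(0, 0, 0), p), c(0, 0, 0))
})

test_that("torsion energy is quadratic and even", {
  p <- motor_params()
  expect_equal(torsion_energy(0, p), 0)
  expect_equal(torsion_energy(1, p), 0.125)
  expect_equal(torsion_energy(-1.3, p), torsion_energy(1.3, p))
})

test_that("detachment rate follows Bell's law", {
  p <- motor_params()
  expect_equal(detachment_rate(0, p), 0.35)
  # doubling force
  F2 <- p$kBT * log(2) / p$detach_distance
  expect_equal(detachment_rate(F2, p), 0.70, tolerance = 1e-10)
  expect_equal(detachment_rate(10, p),
               0.35 * exp(10 * p$detach_distance / p$kBT))
  F <- seq(0, 15, by = 0.5)
  expect_true(all(diff(detachment_rate(F, p)) > 0))
  expect_error(detachment_rate(-1, p))
})

test_that("net stepping velocity is anchored at the unloaded and stall points", {
  p <- motor_params()
  # unloaded: 12/s forward split 80/20 long/short minus calibrated backsteps
  v0 <- 12 * (0.8 * 35.75 + 0.2 * 30.25) - p$k_back0 * 35.75
  expect_equal(net_velocity(0, p), v0)
  expect_gt(v0, 395); expect_lt(v0, 425)
  # stall is the zero of v(F), by construction of k_back0
  expect_equal(net_velocity(p$stall_force, p), 0, tolerance = 1e-9)
  root <- uniroot(function(F) net_velocity(F, p), c(0.1, 10), tol = 1e-10)
  expect_equal(root$root, 1.9, tolerance = 1e-6)
  # strictly decreasing; super-stall loads give net retreat
  F <- seq(0, 6, by = 0.1)
  expect_true(all(diff(net_velocity(F, p)) < 0))
  expect_lt(net_velocity(3, p), 0)
})

test_that("forward stepping slows and backstepping accelerates under load", {
  p <- motor_params()
  r0 <- step_rates(0, p); r2 <- step_rates(2, p)
  expect_lt(r2$k_fwd_long + r2$k_fwd_short, r0$k_fwd_long + r0$k_fwd_short)
  expect_gt(r2$k_back, r0$k_back)
  # short-step probability ramps from 0.20 to 0.50 at stall
  expect_equal(r0$k_fwd_short / (r0$k_fwd_long + r0$k_fwd_short), 0.20)
  rs <- step_rates(p$stall_force, p)
  expect_equal(rs$k_fwd_short / (rs$k_fwd_long + rs$k_fwd_short), 0.50)
})

test_that("pose relaxation matches a brute-force grid minimisation", {
  p <- motor_params()
  fil <- fil_y()
  set.seed(7)
  for (rep in 1:4) {
    n <- sample(1:2, 1)
    sites <- sort(sample(800:1000, n))
    motors <- data.frame(filament = 1L, site = sites,
                         phi_ref = runif(n, -0.5, 0.5))
    start <- site_position(fil, sites[1L]) + c(runif(1, -50, 50), 0, 220)
    eq <- equilibrate_pose(start, motors, list(fil), p)
    bf <- brute_force_pose(start, motors, list(fil), p)
    expect_lte(eq$objective, bf$objective * 1.01 + 1e-6)
  }
})

test_that("relaxation never increases the objective and handles slack sets", {
  p <- motor_params()
  fil <- fil_y()
  motors <- data.frame(filament = 1L, site = c(900L, 905L),
                       phi_ref = c(0, 0))
  start <- site_position(fil, 902L) + c(0, 0, 200)
  E0 <- pose_energy(start, motors, list(fil), p, total = TRUE)
  eq <- equilibrate_pose(start, motors, list(fil), p)
  expect_lte(eq$objective, E0 + 1e-9)
  # slack configuration: springs transmit no force; the residual elastic
  # energy is the (tiny) torsional term from the arbitrary reference azimuth
  expect_lt(eq$energy, 0.5)
  mid <- colMeans(rbind(site_position(fil, 900L), site_position(fil, 905L)))
  expect_lt(abs(eq$centre[2] - mid[2]), 5)
  expect_error(equilibrate_pose(start, motors[0, ], list(fil), p),
               "no bound motors")
})

test_that("two symmetric motors centre the cargo between them", {
  p <- motor_params()
  fil <- fil_y(az0 = 0)
  # same-azimuth sites equidistant from the midpoint (26 subunits apart,
  # twist 26 * -166.15 = -4320.9 ~ -0.9 deg: nearly the same azimuth)
  motors <- data.frame(filament = 1L, site = c(887L, 913L), phi_ref = c(0, 0))
  start <- site_position(fil, 900L) + c(0, 0, 190)
  eq <- equilibrate_pose(start, motors, list(fil), p)
  d1 <- sqrt(sum((eq$centre - site_position(fil, 887L))^2))
  d2 <- sqrt(sum((eq$centre - site_position(fil, 913L))^2))
  expect_equal(d1, d2, tolerance = 0.02)
})

test_that("attachment propensity honours calibration, pool size and packing", {
  p <- motor_params()
  band <- myovasim:::make_band_table(175, 50, 4)
  rho0 <- 179
  # resting cargo, all 10 motors free: ensemble rate equals k_attach_max
  expect_equal(attachment_propensity(10, 10, rho0, band, p), 2.4)
  # shrinks with the free pool and with distance from the filament
  expect_lt(attachment_propensity(7, 10, rho0, band, p), 2.4)
  expect_lt(attachment_propensity(10, 10, 205, band, p),
            attachment_propensity(10, 10, rho0, band, p))
  expect_equal(attachment_propensity(10, 10, 240, band, p), 0)
  expect_equal(attachment_propensity(0, 10, rho0, band, p), 0)
  # reach-band packing: 3 anchor footprints fill the band
  expect_equal(band_capacity(rho0, band), 3)
  expect_equal(attachment_propensity(7, 10, rho0, band, p, n_blocking = 3L), 0)
  expect_gt(attachment_propensity(7, 10, rho0, band, p, n_blocking = 2L), 0.3)
  # with three motors bound the propensity toward a second filament is
  # strictly lower than with one bound (smaller free pool, and lower still
  # when the working anchors overlap the second filament's band)
  expect_lt(attachment_propensity(7, 10, 190, band, p, n_blocking = 0L),
            attachment_propensity(9, 10, 190, band, p, n_blocking = 0L))
  expect_lt(attachment_propensity(7, 10, 190, band, p, n_blocking = 2L),
            attachment_propensity(7, 10, 190, band, p, n_blocking = 0L))
})
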