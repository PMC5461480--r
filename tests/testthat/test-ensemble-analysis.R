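# Photobleaching motor counting and stall-force analysis.

test_that("intensity per fluorophore is recovered from binomial bleaching", {
  tr <- gen_bleach_traces(n_fluorophores = 20, v = 100, tau = 10,
                          n_traces = 200, seed = 3)
  est <- intensity_per_fluorophore(tr)
  expect_lt(abs(est$v - 100) / 100, 0.10)
  expect_lt(abs(est$tau_s - 10) / 10, 0.10)
})

test_that("single-trace fallback reads v off the bleaching step", {
  tr <- data.frame(trace = 1, t_s = seq(0, 10, 0.5),
                   intensity = c(rep(120, 11), rep(0, 10)))
  expect_equal(intensity_per_fluorophore(tr)$v, 120)
  flat <- data.frame(trace = 1, t_s = seq(0, 10, 0.5), intensity = 50)
  expect_error(intensity_per_fluorophore(flat), "degenerate")
})

test_that("motor count follows the two-fluorophores-per-motor conversion", {
  tr <- data.frame(trace = 1, t_s = c(0, 1), intensity = c(500, 400))
  mc <- motor_count(tr, v = 100)
  expect_equal(mc$per_trace$n_fluorophores, 5)
  expect_equal(mc$per_trace$n_motors, 2.5)
  # sensitivity contract: doubling v halves the count
  expect_equal(motor_count(tr, v = 200)$per_trace$n_motors, 1.25)
})

test_that("a 20-fluorophore preparation reads out as ~10 motors", {
  tr <- gen_bleach_traces(n_fluorophores = 20, v = 100, tau = 10,
                          n_traces = 200, seed = 6)
  mc <- motor_count(tr)
  expect_lt(abs(mc$mean_motors - 10) / 10, 0.10)
})

test_that("motor count is invariant under intensity rescaling", {
  tr <- gen_bleach_traces(n_fluorophores = 12, v = 80, tau = 8,
                          n_traces = 150, seed = 9)
  m1 <- motor_count(tr)
  tr2 <- tr; tr2$intensity <- tr2$intensity * 3.7
  m2 <- motor_count(tr2)
  expect_equal(m1$mean_motors, m2$mean_motors, tolerance = 1e-6)
})

test_that("stall-peak detector recovers constructed saw-teeth", {
  g <- gen_trap_trace(stall_mean = 3, stall_sd = 0.4, n_events = 15,
                      ramp_v = 100, noise_sd = 0, seed = 2)
  ev <- detect_peak_forces(g$trace, trap_stiffness = 0.019)
  expect_equal(nrow(ev), 15)
  expect_equal(sort(ev$peak_force_pN), sort(g$true_peaks), tolerance = 0.02)
  # with moderate noise the recovered peak mean stays within 5%
  gn <- gen_trap_trace(stall_mean = 3, stall_sd = 0.4, n_events = 20,
                       ramp_v = 100, noise_sd = 0.1, seed = 5)
  evn <- detect_peak_forces(gn$trace, trap_stiffness = 0.019)
  expect_gt(nrow(evn), 15)
  expect_lt(abs(mean(evn$peak_force_pN) - mean(gn$true_peaks)) /
              mean(gn$true_peaks), 0.05)
})

test_that("peak detector respects its velocity thresholds and offsets", {
  t <- seq(0, 10, by = 0.005)
  # monotone rise: second half never retreats, no events
  mono <- data.frame(t_s = t, force_pN = 0.019 * 100 * t)
  expect_equal(nrow(detect_peak_forces(mono, trap_stiffness = 0.019)), 0L)
  # slow ramp (30 nm/s) then drop: below the first-half threshold
  slow <- gen_trap_trace(stall_mean = 3, stall_sd = 1e-6, n_events = 3,
                         ramp_v = 30, noise_sd = 0, seed = 1)
  expect_equal(nrow(detect_peak_forces(slow$trace, trap_stiffness = 0.019)),
               0L)
  # constant force offset shifts peaks but not the event count
  g <- gen_trap_trace(stall_mean = 3, stall_sd = 0.4, n_events = 10,
                      ramp_v = 100, noise_sd = 0, seed = 7)
  e0 <- detect_peak_forces(g$trace, trap_stiffness = 0.019)
  go <- g$trace; go$force_pN <- go$force_pN + 2
  e2 <- detect_peak_forces(go, trap_stiffness = 0.019)
  expect_equal(nrow(e2), nrow(e0))
  expect_equal(e2$peak_force_pN, e0$peak_force_pN + 2, tolerance = 1e-9)
  # raising the threshold never yields more events
  eh <- detect_peak_forces(g$trace, v_threshold = 90, trap_stiffness = 0.019)
  expect_lte(nrow(eh), nrow(e0))
  expect_error(detect_peak_forces(g$trace[1:10, ], trap_stiffness = 0.019),
               "shorter")
})

test_that("mixture decomposition recovers the three stall populations", {
  set.seed(10)
  x <- c(rnorm(140, 1.9, 0.7), rnorm(140, 4.1, 0.6), rnorm(120, 5.9, 0.4))
  m <- stall_mixture(x)
  expect_equal(m$k, 3)
  expect_lt(abs(m$means[1] - 1.9), 0.3)
  expect_lt(abs(m$means[2] - 4.1), 0.3)
  expect_lt(abs(m$means[3] - 5.9), 0.3)
  # a single Gaussian selects one component
  set.seed(11)
  m1 <- stall_mixture(rnorm(300, 3, 0.5))
  expect_equal(m1$k, 1)
  expect_error(stall_mixture(rnorm(10)), "too few")
})

test_that("mixture component means are recovered with small bias", {
  bias <- matrix(NA_real_, 20, 3)
  for (r in 1:20) {
    set.seed(100 + r)
    x <- c(rnorm(133, 1.9, 0.7), rnorm(133, 4.1, 0.6), rnorm(134, 5.9, 0.4))
    m <- stall_mixture(x)
    if (m$k == 3) bias[r, ] <- m$means - c(1.9, 4.1, 5.9)
  }
  expect_gt(mean(!is.na(bias[, 1])), 0.7)   # k = 3 selected in most reps
  expect_lt(max(abs(colMeans(bias, na.rm = TRUE))), 0.2)
})
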