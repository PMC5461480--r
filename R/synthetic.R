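# Seeded generators for every input the analysis operations consume, with
# the statistical structure of the experimental data: helical trajectories
# with per-axis localization noise, binomial photobleaching traces,
# saw-tooth trap traces and STORM-like filament localization clouds.

#' Localization noise model
#'
#' @param sigma_x,sigma_y,sigma_z per-axis localization s.d., nm (defaults:
#'   the measured 17/18/30 nm precision of 3D liposome tracking).
#' @param frame_interval camera frame interval, s.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(sigma_x = 17, sigma_y = 18, sigma_z = 30,
                        frame_interval = 0.1) {
  stopifnot(sigma_x >= 0, sigma_y >= 0, sigma_z >= 0, frame_interval > 0)
  structure(list(sigma_x = sigma_x, sigma_y = sigma_y, sigma_z = sigma_z,
                 frame_interval = frame_interval), class = "noise_model")
}

#' Generate a noisy helical trajectory
#'
#' A deterministic helix of given pitch, radius and axial velocity along
#' +y, plus independent Gaussian localization noise per axis.  With
#' right-handed axes, a right-handed helix has Z leading X by a quarter
#' turn along the direction of travel.
#'
#' @param pitch helix pitch, nm (default: the measured 2160 nm left-handed
#'   spiral of cargo transport).
#' @param radius helix radius, nm (cargo radius + motor reach).
#' @param velocity axial velocity, nm/s.
#' @param handedness `"left"` or `"right"`.
#' @param duration s.
#' @param noise a [noise_model()].
#' @param seed RNG seed.
#' @param phase0 initial phase, radians.
#' @return trajectory data frame `t_s`, `x_nm`, `y_nm`, `z_nm`.
#' @export
gen_helical_trajectory <- function(pitch = 2160, radius = 225,
                                   velocity = 423, handedness = "left",
                                   duration = 30,
                                   noise = noise_model(), seed = 1,
                                   phase0 = 0) {
  stopifnot(pitch > 0, velocity > 0, handedness %in% c("left", "right"))
  set.seed(as.integer(seed))
  t <- seq(0, duration, by = noise$frame_interval)
  hs <- if (handedness == "right") 1 else -1
  psi <- phase0 + hs * 2 * pi * velocity / pitch * t
  n <- length(t)
  data.frame(
    t_s = t,
    x_nm = radius * sin(psi) + stats::rnorm(n, 0, noise$sigma_x),
    y_nm = velocity * t + stats::rnorm(n, 0, noise$sigma_y),
    z_nm = radius * cos(psi) + stats::rnorm(n, 0, noise$sigma_z))
}

#' Generate binomial photobleaching traces
#'
#' Each of `n_fluorophores` fluorophores on each liposome survives to time
#' t with probability `exp(-t/tau)` independently; the trace intensity is
#' `v` per surviving fluorophore plus Gaussian shot noise.
#'
#' @param n_fluorophores fluorophores per liposome.
#' @param v intensity per fluorophore, a.u.
#' @param tau bleaching time constant, s.
#' @param n_traces number of liposomes.
#' @param duration,dt trace length and sampling, s.
#' @param shot_noise_sd additive Gaussian noise s.d., a.u.
#' @param seed RNG seed.
#' @return data frame `trace`, `t_s`, `intensity`.
#' @export
gen_bleach_traces <- function(n_fluorophores = 20, v = 100, tau = 10,
                              n_traces = 200, duration = 40, dt = 0.5,
                              shot_noise_sd = 0, seed = 1) {
  stopifnot(n_fluorophores >= 1, v > 0, tau > 0, n_traces >= 1)
  set.seed(as.integer(seed))
  t <- seq(0, duration, by = dt)
  out <- lapply(seq_len(n_traces), function(i) {
    bleach_t <- stats::rexp(n_fluorophores, rate = 1 / tau)
    surv <- vapply(t, function(tt) sum(bleach_t > tt), numeric(1))
    data.frame(trace = i, t_s = t,
               intensity = v * surv +
                 stats::rnorm(length(t), 0, shot_noise_sd))
  })
  do.call(rbind, out)
}

#' Generate a saw-tooth optical-trap force trace
#'
#' Repeated cycles: force ramps at `ramp_v * k_trap` pN/s to a peak drawn
#' from `N(stall_mean, stall_sd)`, holds briefly, then drops to baseline on
#' motor release, with additive Gaussian noise.
#'
#' @param stall_mean,stall_sd peak-force distribution, pN.
#' @param k_trap trap stiffness, pN/nm.
#' @param n_events number of saw-teeth.
#' @param ramp_v bead velocity during the ramp, nm/s.
#' @param plateau_s hold time at peak, s.
#' @param rest_s baseline time between events, s.
#' @param noise_sd additive force noise s.d., pN.
#' @param dt sampling interval, s.
#' @param seed RNG seed.
#' @return list with `trace` (`t_s`, `force_pN`) and `true_peaks` (pN).
#' @export
gen_trap_trace <- function(stall_mean = 1.9, stall_sd = 0.3,
                           k_trap = 0.019, n_events = 20, ramp_v = 100,
                           plateau_s = 0.05, rest_s = 1, noise_sd = 0,
                           dt = 0.005, seed = 1) {
  stopifnot(k_trap > 0, n_events >= 0, ramp_v > 0)
  set.seed(as.integer(seed))
  peaks <- if (n_events > 0) {
    pmax(stats::rnorm(n_events, stall_mean, stall_sd), 0.2)
  } else numeric(0)
  segs <- list(data.frame(t_s = seq(0, rest_s, by = dt), force_pN = 0))
  t0 <- rest_s
  for (pk in peaks) {
    ramp_T <- pk / (k_trap * ramp_v)
    tt <- seq(dt, ramp_T, by = dt)
    ramp <- data.frame(t_s = t0 + tt, force_pN = k_trap * ramp_v * tt)
    t0 <- t0 + ramp_T
    tt <- seq(dt, plateau_s, by = dt)
    plat <- data.frame(t_s = t0 + tt, force_pN = pk)
    t0 <- t0 + plateau_s
    tt <- seq(dt, rest_s, by = dt)
    rest <- data.frame(t_s = t0 + tt, force_pN = 0)
    t0 <- t0 + rest_s
    segs <- c(segs, list(ramp, plat, rest))
  }
  trace <- do.call(rbind, segs)
  trace$force_pN <- trace$force_pN +
    stats::rnorm(nrow(trace), 0, noise_sd)
  list(trace = trace, true_peaks = peaks)
}

#' Generate a STORM-like filament localization cloud
#'
#' Gaussian scatter about a line at height `z_true` (5 nm default axial
#' precision).
#'
#' @param z_true filament height, nm.
#' @param sigma_z localization precision, nm.
#' @param n_points localizations.
#' @param length_nm span of the filament segment, nm.
#' @param sigma_xy lateral scatter, nm.
#' @param seed RNG seed.
#' @return data frame `x_nm`, `y_nm`, `z_nm`.
#' @export
gen_filament_cloud <- function(z_true, sigma_z = 5, n_points = 200,
                               length_nm = 2000, sigma_xy = 10, seed = 1) {
  stopifnot(n_points >= 1, sigma_z >= 0)
  set.seed(as.integer(seed))
  data.frame(
    x_nm = stats::runif(n_points, 0, length_nm),
    y_nm = stats::rnorm(n_points, 0, sigma_xy),
    z_nm = stats::rnorm(n_points, z_true, sigma_z))
}
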