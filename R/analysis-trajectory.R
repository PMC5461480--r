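# Measurement procedures applied to 3D cargo trajectories: sinusoidal helix
# fitting with handedness calls, approach angles, filament separations,
# directional outcome classification, Kaplan-Meier run lengths and the
# straight-to-turn regime map.

## rotate a trajectory so its net direction of motion lies along +y
align_to_y <- function(traj) {
  P <- as.matrix(traj[, c("x_nm", "y_nm", "z_nm")])
  d <- P[nrow(P), ] - P[1L, ]
  v <- vec_unit(d)
  yhat <- c(0, 1, 0)
  cth <- sum(v * yhat)
  if (cth > 1 - 1e-12) return(traj)
  axis <- vec_cross(v, yhat)
  s <- vec_norm(axis)
  if (s < 1e-12) axis <- c(1, 0, 0) else axis <- axis / s
  th <- atan2(s, cth)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3L, 3L, byrow = TRUE)
  Rm <- diag(3) + sin(th) * t(K) + (1 - cos(th)) * (t(K) %*% t(K))
  P2 <- P %*% Rm
  out <- traj
  out$x_nm <- P2[, 1L]; out$y_nm <- P2[, 2L]; out$z_nm <- P2[, 3L]
  out
}

## bounded sinusoid fit G(t) = c0 + A*sin(2*pi*f*t + phi) for one axis
fit_axis_sinusoid <- function(t, g, amp_limits, freq_limits) {
  gd <- g - mean(g)
  n <- length(t)
  dt <- stats::median(diff(t))
  ## frequency init from the periodogram, restricted to the allowed window
  sp <- stats::spec.pgram(stats::ts(gd, deltat = dt), plot = FALSE,
                          detrend = TRUE, taper = 0)
  ok <- sp$freq >= freq_limits[1L] & sp$freq <= freq_limits[2L]
  f0 <- if (any(ok)) sp$freq[ok][which.max(sp$spec[ok])] else
    mean(freq_limits)
  ## amplitude/phase init by linear regression at f0
  X <- cbind(sin(2 * pi * f0 * t), cos(2 * pi * f0 * t))
  cf <- stats::coef(stats::lm(gd ~ X))
  A0 <- unname(min(max(sqrt(cf[2L]^2 + cf[3L]^2), amp_limits[1L]),
                   amp_limits[2L]))
  phi0 <- unname(atan2(cf[3L], cf[2L]))
  dat <- data.frame(t = t, g = g)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ c0 + A * sin(2 * pi * f * t + phi), data = dat,
      start = list(c0 = mean(g), A = A0, f = unname(f0), phi = phi0),
      lower = c(-Inf, amp_limits[1L], freq_limits[1L], -2 * pi),
      upper = c(Inf, amp_limits[2L], freq_limits[2L], 2 * pi),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  tss <- sum(gd^2)
  list(c0 = unname(cf["c0"]), amplitude = unname(cf["A"]),
       frequency = unname(cf["f"]), phase = unname(cf["phi"]),
       rmsd = sqrt(mean(res^2)),
       r2 = if (tss > 0) 1 - sum(res^2) / tss else 0)
}

#' Fit a helical model to a 3D trajectory
#'
#' The trajectory is rotated so its net motion lies along +y, then the X(t)
#' and Z(t) excursions are fit to `G(t) = c0 + A sin(2 pi f t + phi)` under
#' the constraint window (amplitude 50-500 nm, frequency 0.001-10 1/s).
#' Velocity comes from a linear fit of Y versus t, pitch = velocity /
#' frequency, and handedness from the X-Z phase shift: with right-handed
#' axes and travel along +y, Z leading X by a quarter period is a
#' right-handed spiral.  Trajectories whose sinusoid fits fail to converge
#' inside the constraints (or explain less than `min_r2` of the detrended
#' variance) are called non-helical.
#'
#' @param traj data frame with `t_s`, `x_nm`, `y_nm`, `z_nm`.
#' @param amp_limits,freq_limits constraint windows (nm; 1/s).
#' @param min_r2 minimum variance fraction the sinusoid must explain.
#' @param align rotate the trajectory onto +y first?
#' @return list of class `helix_fit`: amplitudes, frequencies, phases,
#'   `handedness` (`"left"`, `"right"`, `"non_helical"`), `pitch` (nm),
#'   `velocity` (nm/s), `rmsd` (nm).
#' @export
fit_helix <- function(traj, amp_limits = c(50, 500),
                      freq_limits = c(0.001, 10), min_r2 = 0.3,
                      align = TRUE) {
  if (nrow(traj) < 10L) stop("need at least 10 frames to fit a helix")
  traj <- traj[stats::complete.cases(traj[, c("t_s", "x_nm", "y_nm", "z_nm")]), ]
  if (nrow(traj) < 10L) stop("need at least 10 complete frames")
  if (align) traj <- align_to_y(traj)
  t <- traj$t_s
  vfit <- stats::lm(y_nm ~ t_s, data = traj)
  velocity <- unname(stats::coef(vfit)[2L])
  fx <- fit_axis_sinusoid(t, traj$x_nm, amp_limits, freq_limits)
  fz <- fit_axis_sinusoid(t, traj$z_nm, amp_limits, freq_limits)
  bad <- function(f) is.null(f) || !all(is.finite(c(f$amplitude, f$frequency,
                                                    f$phase, f$r2)))
  non_helical <- bad(fx) || bad(fz) || fx$r2 < min_r2 || fz$r2 < min_r2
  if (non_helical) {
    return(structure(list(handedness = "non_helical", velocity = velocity,
                          pitch = NA_real_, amplitude_x = NA_real_,
                          amplitude_z = NA_real_, frequency = NA_real_,
                          phase_x = NA_real_, phase_z = NA_real_,
                          rmsd = NA_real_),
                     class = "helix_fit"))
  }
  tmid <- mean(range(t))
  dphi <- wrap_angle((2 * pi * fz$frequency * tmid + fz$phase) -
                     (2 * pi * fx$frequency * tmid + fx$phase))
  handedness <- if (sin(dphi) > 0) "right" else "left"
  frequency <- fz$frequency
  structure(list(
    handedness = handedness, velocity = velocity,
    pitch = abs(velocity) / frequency,
    amplitude_x = fx$amplitude, amplitude_z = fz$amplitude,
    frequency = frequency, phase_x = fx$phase, phase_z = fz$phase,
    rmsd = sqrt((fx$rmsd^2 + fz$rmsd^2) / 2)
  ), class = "helix_fit")
}

#' @export
print.helix_fit <- function(x, ...) {
  if (x$handedness == "non_helical") {
    cat(sprintf("<helix_fit> non-helical; velocity %.0f nm/s\n", x$velocity))
  } else {
    cat(sprintf(
      "<helix_fit> %s-handed, pitch %.0f nm, velocity %.0f nm/s, f %.3f 1/s, A(x,z) = (%.0f, %.0f) nm\n",
      x$handedness, x$pitch, x$velocity, x$frequency, x$amplitude_x,
      x$amplitude_z))
  }
  invisible(x)
}

#' Approach angle of a cargo at an intersection
#'
#' Mean angular position of the cargo centre around the original filament
#' over the 10 frames immediately before it reaches the crossing centre
#' (circular mean).  0 degrees is the side of the intersecting filament,
#' 180 the opposite side; angles grow toward East (a right turn) so that
#' mirror-reflected trajectories map to 360 minus the original angle.
#'
#' @param traj trajectory data frame (`t_s`, `x_nm`, `y_nm`, `z_nm`).
#' @param intersection an [intersection_geometry()].
#' @param n_frames number of pre-crossing frames to average (10).
#' @return angle in degrees, [0, 360).
#' @export
approach_angle <- function(traj, intersection, n_frames = 10L) {
  orig <- intersection$original
  u <- orig$direction * orig$polarity
  cp <- axis_closest_point(orig, intersection$crossing_point)
  nref <- intersection$crossing_point - cp$point
  if (vec_norm(nref) < 1e-9) nref <- c(0, 0, 1) else nref <- vec_unit(nref)
  e_east <- vec_cross(u, nref)
  P <- as.matrix(traj[, c("x_nm", "y_nm", "z_nm")])
  axial <- as.numeric((P - matrix(cp$point, nrow(P), 3L, byrow = TRUE)) %*% u)
  arrive <- which(axial >= 0)
  arrive <- if (length(arrive)) arrive[1L] else which.max(axial)
  if (arrive <= n_frames) stop("fewer than 10 frames before the crossing")
  idx <- (arrive - n_frames):(arrive - 1L)
  W <- P[idx, , drop = FALSE] -
    matrix(cp$point, length(idx), 3L, byrow = TRUE)
  W <- W - outer(as.numeric(W %*% u), u)
  ang <- atan2(W %*% e_east, W %*% nref)
  (atan2(mean(sin(ang)), mean(cos(ang))) / DEG2RAD) %% 360
}

#' Filament separation from localization point clouds
#'
#' The separation of two crossing filaments is the absolute difference of
#' the mean Z positions of their localization clouds; separations above the
#' 250 nm calibration cutoff are flagged for exclusion from outcome
#' statistics.
#'
#' @param cloud_a,cloud_b data frames with columns `x_nm`, `y_nm`, `z_nm`
#'   (>= 10 points each).
#' @param cutoff exclusion cutoff, nm.
#' @return list with `separation_nm` and logical `excluded`.
#' @export
filament_separation <- function(cloud_a, cloud_b, cutoff = 250) {
  if (nrow(cloud_a) < 10L || nrow(cloud_b) < 10L) {
    stop("each localization cloud needs at least 10 points")
  }
  sep <- abs(mean(cloud_a$z_nm) - mean(cloud_b$z_nm))
  list(separation_nm = sep, excluded = sep > cutoff)
}

#' Classify the directional outcome of an intersection transit
#'
#' Straight: the cargo exits past the crossing on the originally bound
#' filament.  Turn: it exits along the intersecting filament, right toward
#' East and left toward West (compass rule, travel South to North).
#' Terminate: the track ends while the cargo is still within interaction
#' range of the crossing.
#'
#' @param traj trajectory data frame.
#' @param intersection an [intersection_geometry()].
#' @param exit_margin axial distance past the crossing that counts as an
#'   exit, nm (kept below the simulator's 500 nm exit threshold so that
#'   frame sampling cannot strand an exiting cargo short of the margin).
#' @return one of `"straight"`, `"turn_left"`, `"turn_right"`,
#'   `"terminate"`, or `"not_applicable"` if the trajectory never comes
#'   within interaction range of the crossing.
#' @export
classify_outcome <- function(traj, intersection, exit_margin = 400) {
  X <- intersection$crossing_point
  orig <- intersection$original
  u <- orig$direction * orig$polarity
  v <- intersection$intersecting$direction
  cp <- axis_closest_point(orig, X)
  nref <- X - cp$point
  nref <- if (vec_norm(nref) < 1e-9) c(0, 0, 1) else vec_unit(nref)
  e_east <- vec_cross(u, nref)
  P <- as.matrix(traj[, c("x_nm", "y_nm", "z_nm")])
  P <- P[stats::complete.cases(P), , drop = FALSE]
  rel <- P - matrix(X, nrow(P), 3L, byrow = TRUE)
  axial <- as.numeric(rel %*% u)
  if (max(axial) < -exit_margin) return("not_applicable")
  fin <- rel[nrow(rel), ]
  a_fin <- sum(fin * u)
  l_fin <- sum(fin * v)
  d_orig <- vec_norm((P[nrow(P), ] - cp$point) -
                       sum((P[nrow(P), ] - cp$point) * u) * u)
  w2 <- P[nrow(P), ] - intersection$intersecting$origin
  d_inter <- vec_norm(w2 - sum(w2 * v) * v)
  if (a_fin >= exit_margin && d_orig <= d_inter) return("straight")
  if (abs(l_fin) >= exit_margin && d_inter < d_orig) {
    return(if (sum(fin * e_east) > 0) "turn_right" else "turn_left")
  }
  "terminate"
}

#' Kaplan-Meier run-length estimate
#'
#' Product-limit survival estimate of run lengths with right-censoring for
#' runs that ended at a filament end or support bead.  When the longest
#' record is censored the mean is restricted to the largest observed length.
#'
#' @param runs data frame with `run_length` (nm) and logical `censored`.
#' @return list with `survival` (a `survfit` object), `mean`, `se_mean`,
#'   `median` (nm) and `all_censored`.
#' @export
km_run_length <- function(runs) {
  stopifnot(all(runs$run_length >= 0))
  event <- !runs$censored
  if (!any(event)) {
    warning("all runs censored: only a lower bound on run length")
    return(list(survival = NULL, mean = NA_real_, se_mean = NA_real_,
                median = NA_real_, all_censored = TRUE,
                lower_bound = max(runs$run_length)))
  }
  fit <- survival::survfit(survival::Surv(runs$run_length, event) ~ 1)
  tab <- summary(fit, rmean = max(runs$run_length))$table
  list(survival = fit, mean = unname(tab["rmean"]),
       se_mean = unname(tab["se(rmean)"]), median = unname(tab["median"]),
       all_censored = FALSE)
}

#' Straight-to-turn ratio per spatial regime
#'
#' Events are binned by (mirrored) approach angle and separation into the
#' four interaction regimes (boundaries 60 degrees and 125 nm) plus the
#' non-interaction regime, and the ratio of straight to turning events is
#' reported per regime with its event counts.  Regimes with turns absent
#' but straights present get an infinite ratio; empty regimes NA.
#'
#' @param outcomes data frame with `alpha` (deg), `d` (nm), `outcome`.
#' @param params [interaction_params()].
#' @return data frame: `regime`, `n_straight`, `n_turn`, `n_terminate`,
#'   `n_total`, `ratio`.
#' @export
straight_turn_heatmap <- function(outcomes, params = interaction_params()) {
  reg <- regime_bin(outcomes$alpha, outcomes$d, params)
  lv <- levels(reg)
  res <- lapply(lv, function(r) {
    o <- outcomes$outcome[reg == r]
    ns <- sum(o == "straight")
    nt <- sum(o %in% c("turn_left", "turn_right"))
    nx <- sum(o == "terminate")
    ratio <- if (ns + nt == 0L) NA_real_ else if (nt == 0L) Inf else ns / nt
    data.frame(regime = r, n_straight = ns, n_turn = nt, n_terminate = nx,
               n_total = length(o), ratio = ratio)
  })
  do.call(rbind, res)
}
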