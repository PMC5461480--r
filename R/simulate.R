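# Event-driven stochastic engine for motor-cargo transport.
#
# Hybrid quasi-static scheme: the cargo pose is relaxed to its elastic
# minimum after every discrete event, and the discrete events (bind, unbind,
# long/short/back step) are sampled exactly (Gillespie) from propensities
# that are constant between events.  Free membrane anchors are treated in
# the well-mixed fast-diffusion limit, so binding propensities reduce to the
# reach-band fraction of the sphere surface (see attachment_propensity).

#' Simulation configuration
#'
#' @param geometry one of `"single_filament"`, `"intersection"`, `"trap"`.
#' @param cargo_diameter cargo sphere diameter, nm.
#' @param n_motors total motors on the cargo surface.
#' @param membrane_D membrane diffusion coefficient of a motor anchor,
#'   um^2/s.  Documents the fast-diffusion regime under which anchors are
#'   treated as well mixed; it does not enter the propensities directly.
#' @param motor [motor_params()].
#' @param motor_reach motor linkage reach, nm.
#' @param separation_nm filament separation `d` for intersection runs, nm.
#' @param inter_polarity polarity of the intersecting filament (+1 East).
#' @param trap_stiffness harmonic trap stiffness, pN/nm.
#' @param seed integer RNG seed (required at simulation time).
#' @param frame_interval trajectory sampling interval, s.
#' @param max_time simulation horizon, s.
#' @param intersection_dwell_limit dwell time at the intersection after
#'   which a run is scored as terminated, s.
#' @param filament_length single-filament track length, nm (`NULL`: sized
#'   from `max_time` at ~450 nm/s).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(geometry = c("single_filament", "intersection", "trap"),
                       cargo_diameter = 350, n_motors = 10L,
                       membrane_D = 0.92, motor = motor_params(),
                       motor_reach = motor$rest_length,
                       separation_nm = 100, inter_polarity = 1L,
                       trap_stiffness = 0.019, seed = NULL,
                       frame_interval = 0.1, max_time = 30,
                       intersection_dwell_limit = 10,
                       filament_length = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(n_motors >= 0, frame_interval > 0, max_time > 0,
            cargo_diameter > 0, trap_stiffness > 0, membrane_D > 0,
            intersection_dwell_limit > 0)
  if (geometry == "intersection" &&
      (separation_nm < 0 || separation_nm > 250)) {
    stop("separation_nm must lie in [0, 250]")
  }
  structure(list(
    geometry = geometry, cargo_diameter = cargo_diameter,
    n_motors = as.integer(n_motors), membrane_D = membrane_D,
    motor = motor, motor_reach = motor_reach,
    separation_nm = separation_nm, inter_polarity = as.integer(inter_polarity),
    trap_stiffness = trap_stiffness, seed = seed,
    frame_interval = frame_interval, max_time = max_time,
    intersection_dwell_limit = intersection_dwell_limit,
    filament_length = filament_length
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s, cargo %.0f nm, %d motors, seed %s\n",
              x$geometry, x$cargo_diameter, x$n_motors,
              if (is.null(x$seed)) "unset" else format(x$seed)))
  invisible(x)
}

## ---- core event loop --------------------------------------------------------

## grow-able event buffer
new_event_log <- function(n = 4096L) {
  env <- new.env(parent = emptyenv())
  env$t <- numeric(n); env$type <- character(n)
  env$filament <- integer(n); env$site <- integer(n); env$n <- 0L
  env
}
log_event <- function(log, t, type, filament = NA_integer_,
                      site = NA_integer_) {
  n <- log$n + 1L
  if (n > length(log$t)) {
    log$t <- c(log$t, numeric(length(log$t)))
    log$type <- c(log$type, character(length(log$type)))
    log$filament <- c(log$filament, integer(length(log$filament)))
    log$site <- c(log$site, integer(length(log$site)))
  }
  log$t[n] <- t; log$type[n] <- type
  log$filament[n] <- filament; log$site[n] <- site
  log$n <- n
}
event_df <- function(log) {
  i <- seq_len(log$n)
  data.frame(t = log$t[i], type = log$type[i],
             filament = log$filament[i], site = log$site[i])
}

## accessible, unoccupied, near-side sites of `fil` from cargo centre
accessible_sites <- function(fil, centre, reach_tot, occupied) {
  w <- centre - fil$origin
  s0 <- sum(w * fil$direction)
  cperp <- w - s0 * fil$direction
  rho <- vec_norm(cperp)
  half <- (rho - fil$radius)
  if (half >= reach_tot) return(integer(0))
  win <- sqrt(reach_tot^2 - max(half, 0)^2)
  lo <- max(0, ceiling((s0 - win) / fil$monomer_rise))
  hi <- min(fil$n_sites, floor((s0 + win) / fil$monomer_rise))
  if (hi < lo) return(integer(0))
  idx <- lo:hi
  idx <- idx[!(idx %in% occupied)]
  if (!length(idx)) return(integer(0))
  pos <- site_position(fil, idx)
  dvec <- matrix(centre, length(idx), 3L, byrow = TRUE) - pos
  within <- sqrt(rowSums(dvec^2)) <= reach_tot
  idx <- idx[within]
  if (!length(idx) || rho < 1e-9) return(idx)
  ## near-side filter: site's radial direction must face the cargo centre
  az <- (fil$azimuth0 + idx * fil$monomer_twist) * DEG2RAD
  rad_dot <- cos(az) * sum(fil$e1 * cperp) + sin(az) * sum(fil$e2 * cperp)
  idx[rad_dot > 0]
}

## fast scalar site position (hot path)
site_pos_fast <- function(fil, i) {
  az <- (fil$azimuth0 + i * fil$monomer_twist) * DEG2RAD
  fil$origin + (i * fil$monomer_rise) * fil$direction +
    fil$radius * (cos(az) * fil$e1 + sin(az) * fil$e2)
}

sim_core <- function(filaments, params, cargo_radius, n_motors, band,
                     init_motors, init_centre, max_time, frame_interval,
                     mode = "transport", trap = NULL, crossing = NULL,
                     dwell_limit = 10, exit_margin = 500, zone_radius = 500) {
  reach_tot <- cargo_radius + params$rest_length
  nf <- length(filaments)
  occupied <- lapply(seq_len(nf), function(i)
    init_motors$site[init_motors$filament == i])

  k_ext <- params$k_ext; k_tor <- params$k_tor
  L0 <- params$rest_length; Rp <- cargo_radius + L0
  kBT <- params$kBT; dd <- params$detach_distance
  ds <- params$step_distance_param; Fs <- params$stall_force
  p0 <- params$p_short0; pst <- params$p_short_stall

  ## per-motor state as plain vectors, updated incrementally
  m_fil <- init_motors$filament
  m_site <- init_motors$site
  m_phi <- init_motors$phi_ref
  nb <- length(m_fil)
  hx <- hy <- hz <- numeric(0)       # head positions
  e1x <- e1y <- e1z <- e2x <- e2y <- e2z <- numeric(0)  # filament frames
  plx <- ply <- plz <- numeric(0)    # plus-end directions
  push_motor_geom <- function(i) {
    f <- filaments[[m_fil[i]]]
    h <- site_pos_fast(f, m_site[i])
    hx[i] <<- h[1L]; hy[i] <<- h[2L]; hz[i] <<- h[3L]
    e1x[i] <<- f$e1[1L]; e1y[i] <<- f$e1[2L]; e1z[i] <<- f$e1[3L]
    e2x[i] <<- f$e2[1L]; e2y[i] <<- f$e2[2L]; e2z[i] <<- f$e2[3L]
    p <- f$direction * f$polarity
    plx[i] <<- p[1L]; ply[i] <<- p[2L]; plz[i] <<- p[3L]
  }
  for (i in seq_len(nb)) push_motor_geom(i)
  drop_motor <- function(i) {
    keep <- setdiff(seq_len(nb), i)
    m_fil <<- m_fil[keep]; m_site <<- m_site[keep]; m_phi <<- m_phi[keep]
    hx <<- hx[keep]; hy <<- hy[keep]; hz <<- hz[keep]
    e1x <<- e1x[keep]; e1y <<- e1y[keep]; e1z <<- e1z[keep]
    e2x <<- e2x[keep]; e2y <<- e2y[keep]; e2z <<- e2z[keep]
    plx <<- plx[keep]; ply <<- ply[keep]; plz <<- plz[keep]
    nb <<- nb - 1L
  }

  ## filament penalty data
  fo <- lapply(filaments, `[[`, "origin")
  fd <- lapply(filaments, `[[`, "direction")
  flen <- vapply(filaments, `[[`, numeric(1), "length")
  fexcl <- vapply(filaments, function(f) cargo_radius + f$radius, numeric(1))
  trap_c <- if (!is.null(trap)) trap$centre else NULL
  trap_k <- if (!is.null(trap)) trap$stiffness else 0

  eval_both <- function(x) {
    E <- 0; g1 <- 0; g2 <- 0; g3 <- 0
    if (nb > 0L) {
      wx <- x[1L] - hx; wy <- x[2L] - hy; wz <- x[3L] - hz
      len2 <- wx * wx + wy * wy + wz * wz
      len <- sqrt(len2)
      ext <- len - Rp
      taut <- ext > 0
      if (any(taut)) {
        E <- E + 0.5 * k_ext * sum(ext[taut]^2)
        cf <- k_ext * ext[taut] / len[taut]
        g1 <- g1 + sum(cf * wx[taut])
        g2 <- g2 + sum(cf * wy[taut])
        g3 <- g3 + sum(cf * wz[taut])
      }
      a1 <- wx * e1x + wy * e1y + wz * e1z
      a2 <- wx * e2x + wy * e2y + wz * e2z
      r2 <- a1 * a1 + a2 * a2
      th <- ((atan2(a2, a1) - m_phi + pi) %% (2 * pi)) - pi
      ok <- r2 > 1e-12
      if (any(ok)) {
        E <- E + 0.5 * k_tor * sum(th[ok]^2)
        cf <- k_tor * th[ok] / r2[ok]
        g1 <- g1 + sum(cf * (-a2[ok] * e1x[ok] + a1[ok] * e2x[ok]))
        g2 <- g2 + sum(cf * (-a2[ok] * e1y[ok] + a1[ok] * e2y[ok]))
        g3 <- g3 + sum(cf * (-a2[ok] * e1z[ok] + a1[ok] * e2z[ok]))
      }
      E <- E + TIEBREAK_K * sum(len2)
      g1 <- g1 + 2 * TIEBREAK_K * sum(wx)
      g2 <- g2 + 2 * TIEBREAK_K * sum(wy)
      g3 <- g3 + 2 * TIEBREAK_K * sum(wz)
    }
    for (j in seq_len(nf)) {
      o <- fo[[j]]; d <- fd[[j]]
      w1 <- x[1L] - o[1L]; w2 <- x[2L] - o[2L]; w3 <- x[3L] - o[3L]
      s <- w1 * d[1L] + w2 * d[2L] + w3 * d[3L]
      s <- min(max(s, 0), flen[j])
      r1 <- w1 - s * d[1L]; r2v <- w2 - s * d[2L]; r3 <- w3 - s * d[3L]
      rho <- sqrt(r1 * r1 + r2v * r2v + r3 * r3)
      pen <- fexcl[j] - rho
      if (pen > 0 && rho > 1e-9) {
        E <- E + 0.5 * PENALTY_K * pen * pen
        cf <- PENALTY_K * pen / rho
        g1 <- g1 - cf * r1; g2 <- g2 - cf * r2v; g3 <- g3 - cf * r3
      }
    }
    if (trap_k > 0) {
      d1 <- x[1L] - trap_c[1L]; d2 <- x[2L] - trap_c[2L]
      d3 <- x[3L] - trap_c[3L]
      E <- E + 0.5 * trap_k * (d1 * d1 + d2 * d2 + d3 * d3)
      g1 <- g1 + trap_k * d1; g2 <- g2 + trap_k * d2; g3 <- g3 + trap_k * d3
    }
    list(E = E, g = c(g1, g2, g3))
  }
  last_x <- NULL; last_v <- NULL
  obj_fn <- function(x) {
    if (is.null(last_x) || x[1L] != last_x[1L] || x[2L] != last_x[2L] ||
        x[3L] != last_x[3L]) {
      last_v <<- eval_both(x); last_x <<- x
    }
    last_v$E
  }
  obj_gr <- function(x) {
    if (is.null(last_x) || x[1L] != last_x[1L] || x[2L] != last_x[2L] ||
        x[3L] != last_x[3L]) {
      last_v <<- eval_both(x); last_x <<- x
    }
    last_v$g
  }
  relax_maxit <- getOption("myovasim.relax_maxit", 150L)
  relax <- function(centre) {
    last_x <<- NULL
    stats::optim(centre, obj_fn, obj_gr, method = "BFGS",
                 control = list(maxit = relax_maxit, reltol = 1e-11))$par
  }
  centre <- relax(init_centre)

  ft <- seq(0, max_time, by = frame_interval)
  n_ft <- length(ft)
  FX <- matrix(NA_real_, n_ft, 3L)
  ENG <- matrix(NA_integer_, n_ft, nf)
  fi <- 1L
  flush_frames <- function(t_new) {
    while (fi <= n_ft && ft[fi] <= t_new + 1e-12) {
      FX[fi, ] <<- centre
      for (j in seq_len(nf)) ENG[fi, j] <<- sum(m_fil == j)
      fi <<- fi + 1L
    }
  }

  log <- new_event_log()
  t <- 0
  entered <- FALSE; t_enter <- NA_real_
  outcome <- NA_character_
  rise <- params$monomer_rise
  flush_frames(0)

  repeat {
    ## --- propensities ---
    prop <- numeric(0); kind <- integer(0); who <- integer(0)
    if (nb > 0) {
      wx <- centre[1L] - hx; wy <- centre[2L] - hy; wz <- centre[3L] - hz
      len <- sqrt(wx * wx + wy * wy + wz * wz)
      Tn <- k_ext * pmax(len - Rp, 0)
      F_par <- pmax(0, -Tn * (wx * plx + wy * ply + wz * plz) /
                      pmax(len, 1e-9))
      k_det <- params$k_detach0 * exp(pmin(Tn * dd / kBT, 50))
      xb <- F_par * ds / kBT
      k_fwd <- params$k_step0 * exp(-xb)
      psf <- p0 + (pst - p0) * pmin(F_par / Fs, 1)
      k_long <- k_fwd * (1 - psf)
      k_short <- k_fwd * psf
      k_back <- params$k_back0 * exp(pmin(xb, 50))
      for (i in seq_len(nb)) {
        f <- filaments[[m_fil[i]]]
        tl <- m_site[i] + STEP_SUBUNITS_LONG * f$polarity
        ts <- m_site[i] + STEP_SUBUNITS_SHORT * f$polarity
        tb <- m_site[i] + STEP_SUBUNITS_BACK * f$polarity
        occ <- occupied[[m_fil[i]]]
        if (tl < 0 || tl > f$n_sites || tl %in% occ) k_long[i] <- 0
        if (ts < 0 || ts > f$n_sites || ts %in% occ) k_short[i] <- 0
        if (tb < 0 || tb > f$n_sites || tb %in% occ) k_back[i] <- 0
      }
      prop <- c(rbind(k_det, k_long, k_short, k_back))
      kind <- rep(1:4, times = nb)
      who <- rep(seq_len(nb), each = 4L)
    }
    n_free <- n_motors - nb
    att <- numeric(nf)
    if (n_free > 0) {
      ## bound-motor anchor positions (sphere point nearest each head)
      if (nb > 0) {
        wxa <- hx - centre[1L]; wya <- hy - centre[2L]; wza <- hz - centre[3L]
        la <- sqrt(wxa * wxa + wya * wya + wza * wza)
        ax <- centre[1L] + cargo_radius * wxa / la
        ay <- centre[2L] + cargo_radius * wya / la
        az <- centre[3L] + cargo_radius * wza / la
      }
      for (j in seq_len(nf)) {
        o <- fo[[j]]; d <- fd[[j]]
        w1 <- centre[1L] - o[1L]; w2 <- centre[2L] - o[2L]
        w3 <- centre[3L] - o[3L]
        s <- min(max(w1 * d[1L] + w2 * d[2L] + w3 * d[3L], 0), flen[j])
        r1 <- w1 - s * d[1L]; r2v <- w2 - s * d[2L]; r3 <- w3 - s * d[3L]
        rho <- sqrt(r1 * r1 + r2v * r2v + r3 * r3)
        n_blk <- 0L
        if (nb > 0) {
          ## anchors inside filament j's reach band block membrane area
          sa <- (ax - o[1L]) * d[1L] + (ay - o[2L]) * d[2L] +
            (az - o[3L]) * d[3L]
          sa <- pmin(pmax(sa, 0), flen[j])
          da <- sqrt((ax - o[1L] - sa * d[1L])^2 +
                     (ay - o[2L] - sa * d[2L])^2 +
                     (az - o[3L] - sa * d[3L])^2)
          n_blk <- sum(da <= params$rest_length + filaments[[j]]$radius)
        }
        att[j] <- attachment_propensity(n_free, n_motors, rho, band, params,
                                        n_blocking = n_blk)
      }
    }
    prop <- c(prop, att); kind <- c(kind, rep(5L, nf))
    who <- c(who, seq_len(nf))
    A <- sum(prop)

    if (A <= 0) { flush_frames(max_time); t <- max_time; break }
    tau <- stats::rexp(1L, A)
    if (t + tau > max_time) { flush_frames(max_time); t <- max_time; break }
    flush_frames(t + tau)
    t <- t + tau

    pick <- findInterval(stats::runif(1L) * A, cumsum(prop)) + 1L
    k <- kind[pick]; i <- who[pick]

    if (k == 1L) {                    # detach
      occupied[[m_fil[i]]] <- setdiff(occupied[[m_fil[i]]], m_site[i])
      log_event(log, t, "detach", m_fil[i], m_site[i])
      drop_motor(i)
      if (nb == 0L) {
        if (!is.null(trap)) {
          centre <- relax(centre)
        } else if (mode == "intersection") {
          ## a full release terminates the run only if the cargo is
          ## physically interacting with the intersecting filament
          o <- fo[[2L]]; d <- fd[[2L]]
          w <- centre - o
          s <- min(max(sum(w * d), 0), flen[2L])
          rho2 <- vec_norm(centre - o - s * d)
          reach2 <- cargo_radius + params$rest_length +
            filaments[[2L]]$radius
          outcome <- if (rho2 <= reach2) "terminate" else "no_reach"
          break
        } else {
          outcome <- "detached"
          break
        }
      } else centre <- relax(centre)
    } else if (k %in% c(2L, 3L, 4L)) {  # step
      f <- filaments[[m_fil[i]]]
      dsub <- c(NA, STEP_SUBUNITS_LONG, STEP_SUBUNITS_SHORT,
                STEP_SUBUNITS_BACK)[k]
      new_site <- m_site[i] + dsub * f$polarity
      occupied[[m_fil[i]]] <- c(setdiff(occupied[[m_fil[i]]], m_site[i]),
                                new_site)
      ## the linkage's head-side azimuth rotates with the site: a short
      ## step torques the cargo by the lattice azimuth change
      m_phi[i] <- m_phi[i] +
        wrap_angle((new_site - m_site[i]) * f$monomer_twist * DEG2RAD)
      m_site[i] <- new_site
      h <- site_pos_fast(f, new_site)
      hx[i] <- h[1L]; hy[i] <- h[2L]; hz[i] <- h[3L]
      log_event(log, t, c(NA, "step_long", "step_short", "step_back")[k],
                m_fil[i], new_site)
      centre <- relax(centre)
    } else {                          # attach toward filament i
      f <- filaments[[i]]
      cand <- accessible_sites(f, centre, reach_tot, occupied[[i]])
      if (length(cand)) {
        site <- if (length(cand) == 1L) cand else
          cand[floor(stats::runif(1L) * length(cand)) + 1L]
        h <- site_pos_fast(f, site)
        w <- centre - h
        phi <- atan2(sum(w * f$e2), sum(w * f$e1))
        nb <- nb + 1L
        m_fil[nb] <- i; m_site[nb] <- site; m_phi[nb] <- phi
        push_motor_geom(nb)
        occupied[[i]] <- c(occupied[[i]], site)
        log_event(log, t, "bind", i, site)
        centre <- relax(centre)
      }
      ## no accessible site: thinned (null) event, state unchanged
    }

    ## --- stop conditions ---
    if (mode == "intersection") {
      if (!entered && vec_norm(centre - crossing) <= zone_radius) {
        entered <- TRUE; t_enter <- t
      }
      on_orig <- any(m_fil == 1L); on_inter <- any(m_fil == 2L)
      if (centre[2L] >= exit_margin && !on_inter && nb > 0L) {
        outcome <- "straight"; break
      }
      if (abs(centre[1L]) >= exit_margin && !on_orig && nb > 0L) {
        outcome <- if (centre[1L] > 0) "exit_east" else "exit_west"
        break
      }
      if (entered && t - t_enter > dwell_limit) { outcome <- "terminate"; break }
    }
    if (t >= max_time) break
  }

  if (is.na(outcome)) {
    outcome <- if (mode == "intersection") {
      if (entered) "terminate" else "no_reach"
    } else "end"
  }
  keep <- seq_len(fi - 1L)
  frames <- data.frame(t_s = ft[keep], x_nm = FX[keep, 1L],
                       y_nm = FX[keep, 2L], z_nm = FX[keep, 3L])
  for (j in seq_len(nf)) {
    frames[[c("engaged_orig", "engaged_inter")[j]]] <- ENG[keep, j]
  }
  list(frames = frames, events = event_df(log), end_time = t,
       outcome = outcome, t_enter = t_enter,
       dwell = if (entered) t - t_enter else 0,
       centre = centre,
       motors = data.frame(filament = m_fil, site = m_site, phi_ref = m_phi))
}

## initial state: one motor bound at axial position y0 (nm along the
## filament axis from its origin), lattice phase already randomised via the
## filament's azimuth0; cargo centre placed at contact and relaxed.
init_single_bound <- function(fil, y0, params, cargo_radius) {
  site <- round(y0 / fil$monomer_rise)
  az <- site_azimuth(fil, site) * DEG2RAD
  radial <- cos(az) * fil$e1 + sin(az) * fil$e2
  h <- site_position(fil, site)
  centre <- h + (cargo_radius + params$rest_length / 2) * radial
  w <- centre - h
  phi <- atan2(sum(w * fil$e2), sum(w * fil$e1))
  list(motors = data.frame(filament = 1L, site = site, phi_ref = phi),
       centre = centre)
}

#' Simulate a motor-cargo transport run
#'
#' Runs the event-driven engine for the geometry declared in the config:
#' a single suspended filament (spiralling transport), a 3D filament
#' intersection (tug-of-war directional outcome), or a harmonic trap (stall
#' force saw-teeth).  Identical config and seed give identical event logs.
#'
#' @param config a [sim_config()]; `config$seed` must be set (or passed).
#' @param seed optional seed overriding `config$seed`.
#' @return list of class `myova_sim` with elements `trajectory` (data frame
#'   `t_s`, `x_nm`, `y_nm`, `z_nm`, engaged counts), `events`, `outcome`,
#'   `config`, and for intersection runs an `outcome_record`, for trap runs
#'   a `force` data frame (`t_s`, `force_pN`).
#' @export
simulate_run <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- if (!is.null(seed)) seed else config$seed
  if (is.null(seed)) stop("a seed is required for simulation")
  set.seed(as.integer(seed))
  params <- config$motor
  R <- config$cargo_diameter / 2
  band <- make_band_table(R, params$rest_length, 4)

  if (config$n_motors == 0L) {
    traj <- data.frame(t_s = 0, x_nm = NA_real_, y_nm = NA_real_,
                       z_nm = NA_real_, engaged_orig = 0L)
    return(structure(list(trajectory = traj,
                          events = event_df(new_event_log(1L)),
                          outcome = "detached", config = config,
                          seed = seed),
                     class = "myova_sim"))
  }

  if (config$geometry == "single_filament") {
    len <- if (!is.null(config$filament_length)) config$filament_length else
      config$max_time * 450 + 2000
    fil <- actin_filament(origin = c(0, -500, 0), direction = c(0, 1, 0),
                          length = len, azimuth0 = stats::runif(1L, 0, 360))
    init <- init_single_bound(fil, 500, params, R)
    res <- sim_core(list(fil), params, R, config$n_motors, band,
                    init$motors, init$centre, config$max_time,
                    config$frame_interval, mode = "transport")
    out <- list(trajectory = res$frames, events = res$events,
                outcome = res$outcome, config = config, seed = seed,
                filaments = list(fil))
  } else if (config$geometry == "intersection") {
    geom <- intersection_geometry(
      config$separation_nm, inter_polarity = config$inter_polarity,
      azimuth0_original = stats::runif(1L, 0, 360),
      azimuth0_inter = stats::runif(1L, 0, 360))
    init <- init_single_bound(geom$original, 3000 - 1500, params, R)
    res <- sim_core(list(geom$original, geom$intersecting), params, R,
                    config$n_motors, band, init$motors, init$centre,
                    config$max_time, config$frame_interval,
                    mode = "intersection", crossing = geom$crossing_point,
                    dwell_limit = config$intersection_dwell_limit)
    outcome <- res$outcome
    if (outcome %in% c("exit_east", "exit_west")) {
      outcome <- if (outcome == "exit_east") "turn_right" else "turn_left"
    }
    alpha <- tryCatch(approach_angle(res$frames, geom),
                      error = function(e) NA_real_)
    rec <- data.frame(alpha = alpha, d = config$separation_nm,
                      outcome = outcome, dwell_s = res$dwell,
                      interacting = if (is.na(alpha)) NA else
                        interacts(alpha, config$separation_nm,
                                  interaction_params(config$cargo_diameter,
                                                     config$motor_reach)))
    out <- list(trajectory = res$frames, events = res$events,
                outcome = outcome, outcome_record = rec,
                geometry = geom, config = config, seed = seed,
                filaments = list(geom$original, geom$intersecting))
  } else {  # trap
    fil <- actin_filament(origin = c(0, -1000, 0), direction = c(0, 1, 0),
                          length = 4000, azimuth0 = stats::runif(1L, 0, 360))
    init <- init_single_bound(fil, 1000, params, R)
    c0 <- equilibrate_pose(init$centre, init$motors, list(fil), params,
                           R)$centre
    trap <- list(centre = c0, stiffness = config$trap_stiffness)
    res <- sim_core(list(fil), params, R, config$n_motors, band,
                    init$motors, init$centre, config$max_time,
                    config$frame_interval, mode = "trap", trap = trap)
    force <- data.frame(
      t_s = res$frames$t_s,
      force_pN = config$trap_stiffness * abs(res$frames$y_nm - c0[2L]))
    out <- list(trajectory = res$frames, events = res$events,
                outcome = res$outcome, force = force,
                trap_centre = c0, config = config, seed = seed,
                filaments = list(fil))
  }
  structure(out, class = "myova_sim")
}

#' @export
print.myova_sim <- function(x, ...) {
  cat(sprintf("<myova_sim> %s run, %.1f s, %d events, outcome: %s\n",
              x$config$geometry, max(x$trajectory$t_s), nrow(x$events),
              x$outcome))
  invisible(x)
}

#' Simulate one intersection encounter
#'
#' Initialises the cargo bound to the original filament 1.5 um upstream of
#' the crossing and runs to a directional outcome: `straight` (exit on the
#' original filament past the crossing), `turn_left` / `turn_right`
#' (compass rule: East is right of the South-to-North travel), or
#' `terminate` (all motors release while the cargo interacts with the
#' crossing, or the dwell exceeds the configured limit).  The approach angle
#' alpha is measured from the sampled trajectory with the 10-frame rule.
#'
#' @param config [sim_config()] with `geometry = "intersection"`.
#' @param seed RNG seed.
#' @return `myova_sim` object carrying an `outcome_record` data frame
#'   (`alpha`, `d`, `outcome`, `dwell_s`, `interacting`).
#' @export
run_intersection <- function(config, seed = NULL) {
  stopifnot(config$geometry == "intersection")
  simulate_run(config, seed)
}

#' Simulate an optical-trap force trace
#'
#' @param config [sim_config()] with `geometry = "trap"`; trap traces are
#'   sampled at `frame_interval` (use a few ms to resolve saw-teeth).
#' @param seed RNG seed.
#' @return `myova_sim` object whose `force` element is a `(t_s, force_pN)`
#'   trace.
#' @export
run_trap <- function(config, seed = NULL) {
  stopifnot(config$geometry == "trap")
  simulate_run(config, seed)
}

#' Time-weighted census of simultaneously engaged motors
#'
#' Reconstructs per-filament engaged-motor counts from the event log and
#' weights each count by the time spent there.
#'
#' @param sim a `myova_sim` object.
#' @param filament which filament to census (1 = original).
#' @return data frame with `count`, `time_s` (total time at that count) and
#'   `fraction` (of attached time, i.e. count >= 1).
#' @export
engaged_motor_census <- function(sim, filament = 1L) {
  ev <- sim$events
  end_t <- max(sim$trajectory$t_s[nrow(sim$trajectory)],
               if (nrow(ev)) max(ev$t) else 0)
  ## initial state: reconstruct from first events is fragile; replay forward
  n0 <- sim$trajectory$engaged_orig[1L]
  if (filament == 2L) n0 <- sim$trajectory$engaged_inter[1L]
  times <- c(0, ev$t[ev$type %in% c("bind", "detach") & ev$filament == filament],
             end_t)
  deltas <- ifelse(ev$type[ev$type %in% c("bind", "detach") &
                             ev$filament == filament] == "bind", 1L, -1L)
  counts <- cumsum(c(n0, deltas))
  dt <- diff(times)
  counts <- counts[seq_along(dt)]
  agg <- tapply(dt, counts, sum)
  out <- data.frame(count = as.integer(names(agg)), time_s = as.numeric(agg))
  attached <- sum(out$time_s[out$count >= 1L])
  out$fraction <- ifelse(out$count >= 1L, out$time_s / attached, NA_real_)
  out[order(out$count), ]
}

#' Force-clamp toy tug-of-war between two rigid motor teams
#'
#' Mechanism check for the intersection model: `m` motors walking one way
#' and `n` walking the other are rigidly assigned to two antiparallel 1D
#' tracks (no rebinding).  Motors pull the point cargo through slack-capable
#' linkages, step and detach with the package's load-dependent rates, and
#' the side that still holds the cargo when the other has fully released
#' wins.  With `m > n` the larger team should win the large majority of
#' trials ("the ensemble with the greater number of motors wins").
#'
#' @param m,n team sizes.
#' @param params [motor_params()].
#' @param seed RNG seed.
#' @param max_time horizon, s.
#' @return `"A"` (the m-team), `"B"`, or `"draw"` (horizon reached).
#' @export
tug_of_war_toy <- function(m, n, params = motor_params(), seed = 1,
                           max_time = 60) {
  set.seed(as.integer(seed))
  L0 <- params$rest_length
  rise <- params$monomer_rise
  pos <- c(runif(m, 10, 30), runif(n, -30, -10))  # head positions, nm
  dirn <- c(rep(1, m), rep(-1, n))                # walking direction
  alive <- rep(TRUE, m + n)
  x <- 0; t <- 0
  relax_x <- function() {
    f <- function(x) {
      ext <- pmax(abs(x - pos[alive]) - L0, 0)
      0.5 * params$k_ext * sum(ext^2) + 1e-4 * sum((x - pos[alive])^2)
    }
    stats::optimize(f, range(pos[alive]) + c(-2 * L0, 2 * L0))$minimum
  }
  while (t < max_time) {
    if (!any(alive[1:m])) return("B")
    if (!any(alive[(m + 1):(m + n)])) return("A")
    x <- relax_x()
    ext <- pmax(abs(x - pos) - L0, 0) * alive
    Tn <- params$k_ext * ext
    ## resistive if the linkage pulls the head against its walking direction
    res <- ifelse(sign(x - pos) * dirn < 0, Tn, 0)
    k_det <- detachment_rate(Tn, params) * alive
    sr <- step_rates(res, params)
    k_f <- (sr$k_fwd_long + sr$k_fwd_short) * alive
    k_b <- sr$k_back * alive
    A <- sum(k_det + k_f + k_b)
    t <- t + stats::rexp(1L, A)
    u <- stats::runif(1L) * A
    cs <- cumsum(c(k_det, k_f, k_b))
    pick <- findInterval(u, cs) + 1L
    nm <- m + n
    if (pick <= nm) {
      alive[pick] <- FALSE
    } else if (pick <= 2L * nm) {
      i <- pick - nm
      pos[i] <- pos[i] + dirn[i] * STEP_SUBUNITS_LONG * rise
    } else {
      i <- pick - 2L * nm
      pos[i] <- pos[i] - dirn[i] * STEP_SUBUNITS_LONG * rise
    }
  }
  "draw"
}
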