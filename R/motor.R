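# Single-motor mechanics: elastic linkage to the cargo membrane and
# load-dependent attachment, detachment and stepping kinetics.

## subunit counts realising the 36 / 31 / 36 nm steps on a 2.75 nm lattice
STEP_SUBUNITS_LONG  <- 13L   # 35.75 nm,  azimuth ~ +0.05 deg
STEP_SUBUNITS_SHORT <- 11L   # 30.25 nm,  azimuth ~ -27.65 deg
STEP_SUBUNITS_BACK  <- -13L

## guard for Bell-law exponents
capped_exp <- function(x) exp(pmin(x, 50))

#' Kinetic and elastic parameters of a myosin Va motor
#'
#' Defaults reproduce the measured single-motor anchors: unloaded detachment
#' 0.35 1/s, ensemble attachment 2.4 1/s, 1 pN/nm extensional and
#' 0.25 pN nm/rad torsional linkage stiffness, 36 nm forward steps with
#' occasional short (31 nm) and backward steps, and a 1.9 pN stall.  Load
#' dependence is Bell-law throughout; `k_back0` defaults to the closed-form
#' value that places the zero of the net stepping velocity exactly at
#' `stall_force` (see [stall_consistent_back_rate()]).
#'
#' @param k_ext linkage extensional stiffness, pN/nm.
#' @param k_tor linkage torsional stiffness, pN nm/rad.
#' @param rest_length linkage rest (contour) length, nm; tension develops
#'   only beyond it (a flexible 50 nm HMM cannot push).
#' @param k_detach0 unloaded detachment rate, 1/s.
#' @param detach_distance Bell distance for detachment, nm.
#' @param k_step0 unloaded forward stepping rate, 1/s.
#' @param p_short0 unloaded probability that a forward step is short.
#' @param p_short_stall short-step probability at stall (linear ramp).
#' @param k_back0 unloaded backstep rate, 1/s; `NULL` = stall-consistent.
#' @param step_distance_param Bell distance for stepping, nm.
#' @param stall_force single-motor stall force, pN.
#' @param k_attach_max ensemble-level attachment rate for an unconstrained
#'   cargo resting on a filament with its full motor complement free, 1/s.
#' @param kBT thermal energy, pN nm.
#' @return list of class `motor_params`.
#' @export
motor_params <- function(k_ext = 1, k_tor = 0.25, rest_length = 50,
                         k_detach0 = 0.35, detach_distance = 0.6,
                         k_step0 = 12, p_short0 = 0.20, p_short_stall = 0.5,
                         k_back0 = NULL, step_distance_param = 3.4,
                         stall_force = 1.9, k_attach_max = 2.4, kBT = 4.1) {
  p <- list(k_ext = k_ext, k_tor = k_tor, rest_length = rest_length,
            k_detach0 = k_detach0, detach_distance = detach_distance,
            k_step0 = k_step0, p_short0 = p_short0,
            p_short_stall = p_short_stall,
            step_distance_param = step_distance_param,
            stall_force = stall_force, k_attach_max = k_attach_max,
            kBT = kBT, monomer_rise = 2.75)
  rates <- c(k_detach0, k_step0, k_attach_max)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (p_short0 < 0 || p_short0 > 1) stop("p_short0 must lie in [0, 1]")
  if (stall_force <= 0) stop("stall_force must be > 0")
  if (k_ext < 0 || k_tor < 0 || rest_length <= 0 || kBT <= 0) {
    stop("elastic parameters must be positive")
  }
  p$k_back0 <- if (is.null(k_back0)) stall_consistent_back_rate(p) else k_back0
  structure(p, class = "motor_params")
}

#' Backstep rate that puts the stall exactly at `stall_force`
#'
#' Solves `v(F_s) = 0` in closed form for the Bell-law stepping scheme:
#' `k_back0 = k_step0 * exp(-2 F_s delta / kBT) * s_mean(F_s) / s_back`,
#' where `s_mean(F_s)` is the mean forward step at stall (equal mix of long
#' and short lattice steps) and `s_back` the backstep size.
#'
#' @param params a `motor_params` list (k_back0 not required).
#' @return backstep rate at zero load, 1/s.
#' @export
stall_consistent_back_rate <- function(params) {
  rise <- params$monomer_rise
  s_long <- STEP_SUBUNITS_LONG * rise
  s_short <- STEP_SUBUNITS_SHORT * rise
  s_back <- abs(STEP_SUBUNITS_BACK) * rise
  ps <- params$p_short_stall
  s_mean <- (1 - ps) * s_long + ps * s_short
  params$k_step0 *
    exp(-2 * params$stall_force * params$step_distance_param / params$kBT) *
    s_mean / s_back
}

#' @export
print.motor_params <- function(x, ...) {
  cat(sprintf(
    paste0("<motor_params> k_ext %.2f pN/nm, k_tor %.2f pN nm/rad, L0 %.0f nm\n",
           "  k_detach0 %.2f 1/s (delta %.2f nm), k_step0 %.1f 1/s (delta %.2f nm)\n",
           "  p_short %.2f -> %.2f at stall, k_back0 %.4f 1/s, stall %.2f pN\n"),
    x$k_ext, x$k_tor, x$rest_length, x$k_detach0, x$detach_distance,
    x$k_step0, x$step_distance_param, x$p_short0, x$p_short_stall,
    x$k_back0, x$stall_force))
  invisible(x)
}

#' Elastic linkage force on a bound motor head
#'
#' The linkage behaves as a linear spring beyond its rest length and is slack
#' (zero force) below it.  Returns the force vector exerted on the head,
#' pointing from the head toward its membrane anchor when taut.
#'
#' @param anchor_world anchor position on the cargo surface, nm.
#' @param head_pos head (binding site) position, nm.
#' @param params [motor_params()].
#' @return numeric length-3 force in pN.
#' @export
linkage_force <- function(anchor_world, head_pos, params = motor_params()) {
  r <- anchor_world - head_pos
  len <- vec_norm(r)
  ext <- len - params$rest_length
  if (ext <= 0 || len < .Machine$double.eps) return(c(0, 0, 0))
  params$k_ext * ext * r / len
}

#' Torsional energy of a bound motor linkage
#'
#' `0.5 * k_tor * theta^2` where `theta` is the angular deviation (radians)
#' of the current linkage azimuth about the filament axis from its azimuth at
#' binding.
#'
#' @param theta angular deviation, radians (may be a vector).
#' @param params [motor_params()].
#' @return energy in pN nm.
#' @export
torsion_energy <- function(theta, params = motor_params()) {
  0.5 * params$k_tor * theta^2
}

#' Load-dependent detachment rate (Bell's law)
#'
#' @param F resistive load magnitude(s), pN (>= 0).
#' @param params [motor_params()].
#' @return rate(s), 1/s; `k_detach0` at zero load, monotone increasing.
#' @export
detachment_rate <- function(F, params = motor_params()) {
  if (any(F < 0)) stop("load F must be >= 0")
  params$k_detach0 * capped_exp(F * params$detach_distance / params$kBT)
}

## short-step probability ramps linearly from p_short0 to p_short_stall
p_short <- function(F, params) {
  frac <- pmin(pmax(F, 0) / params$stall_force, 1)
  params$p_short0 + (params$p_short_stall - params$p_short0) * frac
}

#' Load-dependent stepping rates
#'
#' Forward stepping slows and backstepping accelerates under resistive load
#' (Bell's law with a shared step distance parameter); the forward flux
#' splits into long (36 nm) and short (31 nm) lattice steps with a
#' short-step probability that grows under load.  Assisting loads are
#' treated as zero.
#'
#' @param F_parallel resistive load component(s) along the track, pN.
#' @param params [motor_params()].
#' @return list with vectors `k_fwd_long`, `k_fwd_short`, `k_back` (1/s).
#' @export
step_rates <- function(F_parallel, params = motor_params()) {
  F <- pmax(F_parallel, 0)
  x <- F * params$step_distance_param / params$kBT
  k_fwd <- params$k_step0 * exp(-x)
  ps <- p_short(F, params)
  list(k_fwd_long = k_fwd * (1 - ps),
       k_fwd_short = k_fwd * ps,
       k_back = params$k_back0 * capped_exp(x))
}

#' Net single-motor velocity under load
#'
#' Expected axial displacement rate of a bound motor:
#' `k_long*35.75 + k_short*30.25 - k_back*35.75` nm/s.  Strictly decreasing
#' in load with its zero at `stall_force` for the default parameters.
#'
#' @param F resistive load(s), pN.
#' @param params [motor_params()].
#' @return velocity in nm/s.
#' @export
net_velocity <- function(F, params = motor_params()) {
  r <- step_rates(F, params)
  rise <- params$monomer_rise
  r$k_fwd_long * STEP_SUBUNITS_LONG * rise +
    r$k_fwd_short * STEP_SUBUNITS_SHORT * rise +
    r$k_back * STEP_SUBUNITS_BACK * rise
}

# --- membrane reach band -----------------------------------------------------

## Fraction of the cargo sphere surface from which a membrane anchor can
## reach the binding-site shell of a filament whose axis passes at distance
## rho from the cargo centre.  Evaluated on a deterministic Fibonacci sphere
## grid; used in the fast-diffusion (well-mixed) limit of anchor dynamics.
band_fraction_raw <- function(rho, cargo_radius, reach, fil_radius,
                              n_grid = 6000L) {
  i <- seq_len(n_grid) - 0.5
  z <- 1 - 2 * i / n_grid
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  px <- cargo_radius * r * cos(phi)
  py <- cargo_radius * r * sin(phi)
  pz <- cargo_radius * z
  ## filament axis along y at (x = 0, z = -rho) relative to the centre
  vapply(rho, function(rh) {
    d_axis <- sqrt(px^2 + (pz + rh)^2)
    mean(d_axis <= reach + fil_radius)
  }, numeric(1))
}

## Lookup table over rho in [contact, max reach]; linear interpolation.
## footprint_frac is the sphere-area fraction of one bound motor's anchor
## footprint (a spherical cap of radius rest_length around the head's
## nearest surface point): the reach band can only pack
## floor(f(rho)/footprint_frac) bound motors.
make_band_table <- function(cargo_radius, reach, fil_radius) {
  rho_min <- cargo_radius + fil_radius
  rho_max <- cargo_radius + reach + fil_radius
  rho <- seq(rho_min - 2, rho_max, by = 1)
  frac <- band_fraction_raw(rho, cargo_radius, reach, fil_radius)
  list(rho = rho, frac = frac, rho_min = rho_min, rho_max = rho_max,
       f_ref = frac[which.min(abs(rho - rho_min))],
       footprint_frac = (1 - cos(reach / cargo_radius)) / 2)
}

band_fraction <- function(table, rho) {
  if (rho >= table$rho_max) return(0)
  rho <- max(rho, table$rho[1L])
  stats::approx(table$rho, table$frac, xout = rho, rule = 2)$y
}

#' Reach-band packing capacity of a filament
#'
#' Maximum number of motors that can simultaneously engage a filament:
#' the membrane area within motor reach of the filament's binding sites,
#' divided by the anchor footprint (a cap of radius `rest_length`) of one
#' bound motor.  For the default 350 nm cargo and 50 nm motors this is 3
#' for a cargo resting on the filament, falling as the cargo is held away.
#'
#' @param rho distance from the cargo centre to the filament axis, nm.
#' @param band reach-band table (see [attachment_propensity()]).
#' @return integer capacity (>= 0).
#' @export
band_capacity <- function(rho, band) {
  floor(band_fraction(band, rho) / band$footprint_frac)
}

#' Attachment propensity of the free-motor pool toward a filament
#'
#' In the fast membrane-diffusion limit the free anchors are well mixed on
#' the sphere, and the total binding propensity toward a filament is
#' `k_attach_max * (n_free / n_motors) * f(rho) / f_ref`, where `f(rho)` is
#' the fraction of the sphere surface within motor reach of the filament's
#' binding-site shell at the current centre-to-axis distance `rho`, and
#' `f_ref` its value for a cargo resting on the filament.  The calibration
#' makes an unconstrained resting cargo with its full complement free bind
#' at `k_attach_max` (~2.4 1/s); the propensity falls as motors leave the
#' free pool or the cargo is held away from the filament.  Bound motors
#' block membrane area: a new motor needs an unoccupied footprint-sized
#' patch (a cap of radius `rest_length`) inside the band, and the band
#' holds [band_capacity()] such patches (three for the default geometry).
#' Anchors of motors bound to any filament count against a band they sit
#' in, so a second filament whose reach band overlaps the working
#' ensemble's anchors sees its binding propensity suppressed — the
#' geometric restriction that makes a turning ensemble harder to nucleate
#' the more motors already hold the cargo.
#'
#' @param n_free number of free (unbound) motors.
#' @param n_motors total motors on the cargo.
#' @param rho distance from the cargo centre to the filament axis, nm.
#' @param band precomputed reach-band table (internal; built by the
#'   simulator from [interaction_params()]).
#' @param params [motor_params()].
#' @param n_blocking number of bound-motor anchors whose membrane
#'   footprints lie inside this filament's reach band (on any filament).
#' @return propensity in 1/s.
#' @export
attachment_propensity <- function(n_free, n_motors, rho, band,
                                  params = motor_params(), n_blocking = 0L) {
  if (n_free <= 0) return(0)
  f <- band_fraction(band, rho)
  ## packing rule: a new anchor needs a free footprint-sized patch
  if (n_blocking >= floor(f / band$footprint_frac)) return(0)
  params$k_attach_max * (n_free / n_motors) * f / band$f_ref
}
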