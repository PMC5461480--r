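# Quasi-static cargo pose: total elastic energy of the motor linkages plus
# steric exclusion, minimised over the cargo centre after every discrete
# event ("re-centring").
#
# Because membrane anchors equilibrate instantaneously to the sphere point
# nearest each bound head (membrane diffusion is ~100x faster than stepping),
# the sphere's orientation drops out of the energy and the pose reduces to
# the 3 translational degrees of freedom of the centre.  A tiny
# entropic-centring term (TIEBREAK_K per bound motor) resolves the
# degeneracy of fully slack linkages and draws the centre over the attached
# motors, implementing cargo re-centring.

TIEBREAK_K <- 1e-4   # pN/nm, per bound motor
PENALTY_K <- 50      # pN/nm, sphere-cylinder exclusion penalty (rigid-contact limit: sub-0.1 nm penetration at pN-scale contact forces)

## motors: data.frame(filament = index into `filaments`, site = integer,
##                    phi_ref = radians)
## returns list(fn, gr, heads)
make_pose_objective <- function(motors, filaments, params, cargo_radius,
                                trap = NULL) {
  nb <- nrow(motors)
  heads <- matrix(0, nb, 3L)
  U <- E1 <- E2 <- matrix(0, nb, 3L)
  if (nb > 0) {
    for (i in seq_len(nb)) {
      fil <- filaments[[motors$filament[i]]]
      heads[i, ] <- site_position(fil, motors$site[i])
      U[i, ] <- fil$direction; E1[i, ] <- fil$e1; E2[i, ] <- fil$e2
    }
  }
  phi_ref <- motors$phi_ref
  L0 <- params$rest_length; k_ext <- params$k_ext; k_tor <- params$k_tor
  nf <- length(filaments)

  energy_parts <- function(centre) {
    E_spring <- E_tor <- E_tie <- 0
    g <- c(0, 0, 0)
    if (nb > 0) {
      W <- matrix(centre, nb, 3L, byrow = TRUE) - heads
      len <- sqrt(rowSums(W * W))
      ext <- len - cargo_radius - L0
      taut <- ext > 0 & len > 1e-9
      E_spring <- 0.5 * k_ext * sum(ext[taut]^2)
      if (any(taut)) {
        coef <- k_ext * ext[taut] / len[taut]
        g <- g + colSums(coef * W[taut, , drop = FALSE])
      }
      ## torsion about each filament axis relative to the binding azimuth
      a1 <- rowSums(W * E1); a2 <- rowSums(W * E2)
      r2 <- a1^2 + a2^2
      ok <- r2 > 1e-12
      th <- wrap_angle(atan2(a2, a1) - phi_ref)
      E_tor <- 0.5 * k_tor * sum(th[ok]^2)
      if (any(ok)) {
        coef <- k_tor * th[ok] / r2[ok]
        g <- g + colSums(coef * (-a2[ok] * E1[ok, , drop = FALSE] +
                                  a1[ok] * E2[ok, , drop = FALSE]))
      }
      E_tie <- TIEBREAK_K * sum(len^2)
      g <- g + 2 * TIEBREAK_K * colSums(W)
    }
    E_pen <- 0
    for (j in seq_len(nf)) {
      cp <- axis_closest_point(filaments[[j]], centre)
      rv <- centre - cp$point
      rho <- vec_norm(rv)
      pen <- (cargo_radius + filaments[[j]]$radius) - rho
      if (pen > 0 && rho > 1e-9) {
        E_pen <- E_pen + 0.5 * PENALTY_K * pen^2
        g <- g - PENALTY_K * pen * rv / rho
      }
    }
    E_trap <- 0
    if (!is.null(trap)) {
      dv <- centre - trap$centre
      E_trap <- 0.5 * trap$stiffness * sum(dv * dv)
      g <- g + trap$stiffness * dv
    }
    list(E = E_spring + E_tor + E_tie + E_pen + E_trap, g = g,
         E_elastic = E_spring + E_tor)
  }

  list(
    fn = function(centre) energy_parts(centre)$E,
    gr = function(centre) energy_parts(centre)$g,
    parts = energy_parts,
    heads = heads
  )
}

#' Total elastic energy of a cargo pose
#'
#' Extension (slack below rest length) plus torsion energy of all bound
#' motor linkages at a given cargo centre, with steric sphere-cylinder
#' exclusion and optional trap terms available separately.
#'
#' @param centre cargo centre, nm (length 3).
#' @param motors data frame with columns `filament` (index into
#'   `filaments`), `site` (subunit index) and `phi_ref` (linkage azimuth at
#'   binding, radians).
#' @param filaments list of [actin_filament()] objects.
#' @param params [motor_params()].
#' @param cargo_radius cargo sphere radius, nm.
#' @param trap optional `list(centre, stiffness)` harmonic trap.
#' @param total if `TRUE` return the full objective (including the
#'   regularisation, penalty and trap terms used by the minimiser);
#'   otherwise the elastic (spring + torsion) energy only.
#' @return energy in pN nm.
#' @export
pose_energy <- function(centre, motors, filaments, params = motor_params(),
                        cargo_radius = 175, trap = NULL, total = FALSE) {
  obj <- make_pose_objective(motors, filaments, params, cargo_radius, trap)
  p <- obj$parts(centre)
  if (total) p$E else p$E_elastic
}

#' Relax the cargo pose to its elastic-energy minimum
#'
#' Quasi-static re-centring: minimises the total linkage energy over the
#' cargo centre subject to sphere-cylinder exclusion (as a stiff smooth
#' penalty), starting from the current centre.  With at least one bound
#' motor the minimum is well defined; slack configurations are resolved by
#' the entropic-centring regulariser which draws the centre over the bound
#' motors.
#'
#' @inheritParams pose_energy
#' @param centre starting centre (warm start), nm.
#' @return list with `centre`, `energy` (elastic), `objective` (full
#'   minimised objective) and `convergence` (0 = converged).
#' @export
equilibrate_pose <- function(centre, motors, filaments,
                             params = motor_params(), cargo_radius = 175,
                             trap = NULL) {
  if (nrow(motors) == 0 && is.null(trap)) {
    stop("no bound motors: cargo pose is undefined")
  }
  obj <- make_pose_objective(motors, filaments, params, cargo_radius, trap)
  opt <- stats::optim(centre, obj$fn, obj$gr, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  p <- obj$parts(opt$par)
  list(centre = opt$par, energy = p$E_elastic, objective = p$E,
       convergence = opt$convergence)
}
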