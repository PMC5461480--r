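# Actin filament geometry: suspended filaments as rigid 3D lines carrying a
# discrete helical lattice of myosin binding sites, plus the interaction
# geometry of a spherical cargo approaching a filament intersection.

DEG2RAD <- pi / 180

vec_norm <- function(v) sqrt(sum(v * v))

vec_unit <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

vec_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## wrap an angle (radians) to (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y <= -pi, y + 2 * pi, y)
}

#' Construct a suspended actin filament
#'
#' A filament is a rigid cylinder of radius `radius` whose surface carries a
#' discrete helical lattice of binding sites: one site per actin subunit,
#' rising `monomer_rise` nm per subunit and rotating `monomer_twist` degrees
#' per subunit about the axis (negative twist = left-handed genetic helix).
#' Site azimuths are measured by the right-hand rule about `direction` in the
#' filament's own orthonormal frame `(e1, e2, direction)`.
#'
#' @param origin numeric length-3, nm; start of the axis segment.
#' @param direction numeric length-3; axis direction (normalised internally).
#' @param length filament length in nm.
#' @param polarity `+1` if the plus (barbed) end lies along `+direction`,
#'   `-1` if along `-direction`.  Myosin Va walks toward the plus end.
#' @param monomer_rise axial rise per subunit, nm.
#' @param monomer_twist twist per subunit in degrees about `direction`.
#' @param azimuth0 azimuth (degrees) of site 0.
#' @param radius filament excluded-volume radius, nm.
#' @return An object of class `actin_filament`.
#' @examples
#' fil <- actin_filament(c(0, 0, 0), c(0, 1, 0), length = 5000)
#' site_position(fil, 13) - site_position(fil, 0)
#' @export
actin_filament <- function(origin = c(0, 0, 0), direction = c(0, 1, 0),
                           length = 10000, polarity = 1L,
                           monomer_rise = 2.75, monomer_twist = -166.15,
                           azimuth0 = 0, radius = 4) {
  stopifnot(length(origin) == 3L, length(direction) == 3L,
            is.finite(length), length > 0, monomer_rise > 0, radius > 0,
            polarity %in% c(-1L, 1L, -1, 1))
  u <- vec_unit(direction)
  ## deterministic perpendicular frame: cross with the axis least aligned to u
  ref <- diag(3)[, which.min(abs(u))]
  e1 <- vec_unit(vec_cross(ref, u))
  e2 <- vec_cross(u, e1)  # e1 x e2 = u
  structure(list(
    origin = as.numeric(origin), direction = u,
    polarity = as.integer(sign(polarity)),
    length = length, monomer_rise = monomer_rise,
    monomer_twist = monomer_twist, azimuth0 = azimuth0,
    radius = radius, e1 = e1, e2 = e2,
    n_sites = floor(length / monomer_rise)
  ), class = "actin_filament")
}

#' @export
print.actin_filament <- function(x, ...) {
  cat(sprintf(
    "<actin_filament> length %.0f nm, %d sites, rise %.2f nm, twist %.2f deg, plus end %s\n",
    x$length, x$n_sites + 1L, x$monomer_rise, x$monomer_twist,
    if (x$polarity > 0) "+direction" else "-direction"))
  invisible(x)
}

#' Position of a binding site on the helical lattice
#'
#' Site `index` sits `index * monomer_rise` nm along the axis from the origin,
#' displaced radially by the filament radius at azimuth
#' `azimuth0 + index * monomer_twist` (degrees, right-hand rule about the
#' axis direction).
#'
#' @param filament an [actin_filament()].
#' @param index integer subunit index (vectorised); must lie on the filament.
#' @return numeric matrix with one row per index (columns x, y, z in nm), or
#'   a length-3 vector for a single index.
#' @export
site_position <- function(filament, index) {
  s <- index * filament$monomer_rise
  if (any(s < 0 | s > filament$length)) {
    stop("site index outside filament length")
  }
  az <- (filament$azimuth0 + index * filament$monomer_twist) * DEG2RAD
  pos <- outer(s, filament$direction) +
    filament$radius * (outer(cos(az), filament$e1) + outer(sin(az), filament$e2))
  pos <- sweep(pos, 2L, filament$origin, `+`)
  if (length(index) == 1L) as.numeric(pos) else pos
}

## azimuth (degrees, [0, 360)) of site index about the filament axis
site_azimuth <- function(filament, index) {
  (filament$azimuth0 + index * filament$monomer_twist) %% 360
}

## closest point on the filament axis segment to point p, plus axial coord
axis_closest_point <- function(filament, p) {
  w <- p - filament$origin
  s <- sum(w * filament$direction)
  s <- min(max(s, 0), filament$length)
  list(point = filament$origin + s * filament$direction, s = s)
}

#' Interaction parameters of the motor-cargo complex
#'
#' @param cargo_diameter cargo sphere diameter, nm.
#' @param motor_reach contour length of the motor linkage (HMM length), nm.
#' @return list of class `interaction_params`.
#' @export
interaction_params <- function(cargo_diameter = 350, motor_reach = 50) {
  if (cargo_diameter <= 0 || motor_reach <= 0) {
    stop("cargo_diameter and motor_reach must be positive")
  }
  structure(list(cargo_diameter = cargo_diameter, motor_reach = motor_reach),
            class = "interaction_params")
}

#' Mirror an approach angle onto [0, 180] degrees
#'
#' Angles between 180 and 360 degrees are reflected onto 0-180, exploiting
#' the mirror symmetry of the intersection geometry about the plane through
#' both filament axes.
#'
#' @param alpha approach angle(s) in degrees, in [0, 360).
#' @return angle(s) in [0, 180].
#' @export
mirror_angle <- function(alpha) {
  a <- alpha %% 360
  ifelse(a > 180, 360 - a, a)
}

#' Maximum filament separation permitting a cargo-filament interaction
#'
#' For a cargo of radius R whose centre orbits the original filament at
#' approach angle `alpha` (0 degrees = same side as the intersecting
#' filament), motors of reach L can touch the intersecting filament as long
#' as the centre-to-centre separation d does not exceed
#' `d_int(alpha) = (R + L) * (1 + cos(alpha))`: 450 nm head-on for the
#' default 350 nm cargo and 50 nm motors, 225 nm broadside at 90 degrees,
#' and 0 at 180 degrees.
#'
#' @param alpha approach angle(s), degrees (mirrored internally).
#' @param params an [interaction_params()].
#' @return maximum separation(s) in nm.
#' @export
max_interaction_separation <- function(alpha, params = interaction_params()) {
  stopifnot(inherits(params, "interaction_params"))
  a <- mirror_angle(alpha)
  (params$cargo_diameter / 2 + params$motor_reach) * (1 + cos(a * DEG2RAD))
}

#' Does a motor-cargo complex interact with the intersecting filament?
#'
#' Boundary inclusive: `d == d_int(alpha)` counts as an interaction.
#'
#' @param alpha approach angle(s), degrees.
#' @param d filament separation(s), nm (>= 0).
#' @param params an [interaction_params()].
#' @return logical vector.
#' @export
interacts <- function(alpha, d, params = interaction_params()) {
  if (any(d < 0)) stop("separation d must be >= 0")
  d <= max_interaction_separation(alpha, params)
}

#' Bin an intersection geometry into its spatial regime
#'
#' The (alpha, d) plane is split into one non-interaction regime (beyond
#' `d_int`) and four interaction regimes bounded by alpha = 60 degrees and
#' d = 125 nm (boundaries assigned to the high side).
#'
#' @param alpha approach angle(s), degrees (mirrored internally to 0-180).
#' @param d filament separation(s), nm.
#' @param params an [interaction_params()].
#' @return factor with levels `low_alpha_low_d`, `low_alpha_high_d`,
#'   `high_alpha_low_d`, `high_alpha_high_d`, `non_interaction`.
#' @export
regime_bin <- function(alpha, d, params = interaction_params()) {
  a <- mirror_angle(alpha)
  lab <- ifelse(!interacts(a, d, params), "non_interaction",
         ifelse(a < 60,
                ifelse(d < 125, "low_alpha_low_d", "low_alpha_high_d"),
                ifelse(d < 125, "high_alpha_low_d", "high_alpha_high_d")))
  factor(lab, levels = c("low_alpha_low_d", "low_alpha_high_d",
                         "high_alpha_low_d", "high_alpha_high_d",
                         "non_interaction"))
}

#' Construct an intersection of two suspended filaments
#'
#' The original filament runs South to North (+y) through the origin; the
#' intersecting filament crosses it nearly perpendicularly (in the x-y
#' projection) with centre-to-centre separation `separation_d` along +z, the
#' side on which approach angle 0 is defined.  Looking top-down with travel
#' from South to North, East (+x) is a right turn.
#'
#' @param separation_d centre-to-centre separation at the crossing, nm
#'   (0-250, the analysis cutoff).
#' @param inter_polarity polarity of the intersecting filament: `+1` plus end
#'   East (+x), `-1` plus end West.
#' @param half_length half-length of each filament arm, nm.
#' @param azimuth0_original,azimuth0_inter lattice phase (degrees) of each
#'   filament.
#' @param original_polarity polarity of the original filament (+1 = North).
#' @return list of class `intersection_geometry` with elements `original`,
#'   `intersecting`, `separation_d`, `crossing_point`.
#' @export
intersection_geometry <- function(separation_d, inter_polarity = 1L,
                                  half_length = 3000,
                                  azimuth0_original = 0, azimuth0_inter = 0,
                                  original_polarity = 1L) {
  if (separation_d < 0 || separation_d > 250) {
    stop("separation_d must lie in [0, 250] nm (analysis cutoff)")
  }
  original <- actin_filament(
    origin = c(0, -half_length, 0), direction = c(0, 1, 0),
    length = 2 * half_length, polarity = original_polarity,
    azimuth0 = azimuth0_original)
  intersecting <- actin_filament(
    origin = c(-half_length, 0, separation_d), direction = c(1, 0, 0),
    length = 2 * half_length, polarity = inter_polarity,
    azimuth0 = azimuth0_inter)
  structure(list(original = original, intersecting = intersecting,
                 separation_d = separation_d,
                 crossing_point = c(0, 0, separation_d)),
            class = "intersection_geometry")
}

#' @export
print.intersection_geometry <- function(x, ...) {
  cat(sprintf(
    "<intersection_geometry> separation d = %.0f nm, intersecting plus end %s\n",
    x$separation_d, if (x$intersecting$polarity > 0) "East" else "West"))
  invisible(x)
}
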