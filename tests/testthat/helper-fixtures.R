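# Shared fixtures: small deterministic geometries and a brute-force pose
# energy minimiser used as the oracle for equilibrate_pose.

fil_y <- function(len = 5000, az0 = 0, polarity = 1L) {
  actin_filament(origin = c(0, -len / 2, 0), direction = c(0, 1, 0),
                 length = len, polarity = polarity, azimuth0 = az0)
}

## brute-force minimisation of the full pose objective over a 3D grid with
## local refinement; independent of the BFGS path used by equilibrate_pose
brute_force_pose <- function(centre0, motors, filaments, params,
                             cargo_radius = 175, span = 120, n = 13L,
                             levels = 4L) {
  best <- centre0
  for (lv in seq_len(levels)) {
    g <- seq(-span, span, length.out = n)
    pts <- as.matrix(expand.grid(x = best[1] + g, y = best[2] + g,
                                 z = best[3] + g))
    E <- apply(pts, 1L, function(p)
      pose_energy(p, motors, filaments, params, cargo_radius, total = TRUE))
    best <- pts[which.min(E), ]
    span <- span / (n / 2.5)
  }
  list(centre = as.numeric(best),
       objective = pose_energy(as.numeric(best), motors, filaments, params,
                               cargo_radius, total = TRUE))
}

## synthetic intersection trajectory builders (analysis-side tests)
traj_from_points <- function(P, dt = 0.1) {
  data.frame(t_s = (seq_len(nrow(P)) - 1L) * dt,
             x_nm = P[, 1L], y_nm = P[, 2L], z_nm = P[, 3L])
}
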