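# Configuration documents, file formats and batch orchestration.

CONFIG_KEYS <- c("geometry", "cargo_diameter", "n_motors", "membrane_D",
                 "motor", "motor_reach", "separation_nm", "inter_polarity",
                 "trap_stiffness", "seed", "frame_interval", "max_time",
                 "intersection_dwell_limit", "filament_length")

#' Load a simulation configuration from YAML or JSON
#'
#' Missing keys take the [sim_config()] defaults; unknown keys are
#' rejected.  A nested `motor` block overrides [motor_params()] fields.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a validated [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(doc)) doc <- list()
  unknown <- setdiff(names(doc), CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(doc$motor)) {
    bad <- setdiff(names(doc$motor), names(formals(motor_params)))
    if (length(bad)) stop("unknown motor keys: ", paste(bad, collapse = ", "))
    doc$motor <- do.call(motor_params, doc$motor)
  }
  do.call(sim_config, doc)
}

#' Save a simulation configuration
#'
#' @param config a [sim_config()].
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  doc <- unclass(config)
  doc$motor <- unclass(doc$motor)
  doc$motor <- doc$motor[names(doc$motor) %in% names(formals(motor_params))]
  doc <- doc[!vapply(doc, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Write / read a trajectory CSV
#'
#' Columns: `t_s`, `x_nm`, `y_nm`, `z_nm` and any engaged-motor counts.
#'
#' @param traj trajectory data frame.
#' @param path CSV path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path)
}

#' Deterministic child seeds from a master seed
#'
#' Counter-based split: `child_i = (master * 48271 + i * 2654435761) mod
#' (2^31 - 1)`, keeping every seed a valid 32-bit integer, so batches are
#' reproducible and order-independent.
#'
#' @param master master seed (integer).
#' @param n number of children.
#' @return integer vector of `n` seeds.
#' @export
child_seeds <- function(master, n) {
  m <- 2^31 - 1
  x <- (as.numeric(master) %% m) * 48271 %% m
  as.integer((x + seq_len(n) * 2654435761) %% m)
}

#' Run a batch of intersection encounters
#'
#' Samples intersection geometries (separation `d` uniform on
#' `d_range`; the approach angle is uniform on [0, 360) through the random
#' spiral phase at arrival), runs one seeded simulation per geometry, and
#' summarises directional-outcome fractions over the encounters whose
#' measured (alpha, d) predict an interaction.  The intersecting filament's
#' polarity is drawn at random unless fixed.
#'
#' @param config [sim_config()] template (geometry fields are overridden).
#' @param n_runs number of encounters.
#' @param seed master seed; children via [child_seeds()].
#' @param d_range separation range, nm.
#' @param inter_polarity `NULL` to randomise per run, else +1 / -1.
#' @return list of class `outcome_batch` with `outcomes` (one row per run:
#'   `seed`, `alpha`, `d`, `outcome`, `dwell_s`, `interacting`) and
#'   `summary` (fractions with binomial CIs over interacting encounters).
#' @export
batch_outcomes <- function(config, n_runs, seed, d_range = c(50, 250),
                           inter_polarity = NULL) {
  stopifnot(n_runs >= 1)
  seeds <- child_seeds(seed, n_runs)
  set.seed(as.integer(seed))
  dsamp <- stats::runif(n_runs, d_range[1L], d_range[2L])
  pols <- if (is.null(inter_polarity)) {
    sample(c(-1L, 1L), n_runs, replace = TRUE)
  } else rep(as.integer(inter_polarity), n_runs)
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- config
    cfg$geometry <- "intersection"
    cfg$separation_nm <- dsamp[i]
    cfg$inter_polarity <- pols[i]
    sim <- run_intersection(cfg, seed = seeds[i])
    rec <- sim$outcome_record
    rec$seed <- seeds[i]
    rec$inter_polarity <- pols[i]
    rows[[i]] <- rec
  }
  outcomes <- do.call(rbind, rows)
  structure(list(outcomes = outcomes,
                 summary = summarise_outcomes(outcomes),
                 seed = seed),
            class = "outcome_batch")
}

#' Summarise directional-outcome fractions
#'
#' Fractions (with 95 percent binomial confidence intervals) of straight,
#' turning and terminating outcomes over interacting encounters; reaches
#' excluded as `no_reach`.
#'
#' @param outcomes outcome data frame (as in [batch_outcomes()]).
#' @return data frame `outcome`, `n`, `fraction`, `ci_lo`, `ci_hi`.
#' @export
summarise_outcomes <- function(outcomes) {
  keep <- outcomes$outcome != "no_reach" & !is.na(outcomes$interacting) &
    outcomes$interacting
  o <- outcomes$outcome[keep]
  n <- length(o)
  cats <- list(straight = "straight", turn = c("turn_left", "turn_right"),
               turn_left = "turn_left", turn_right = "turn_right",
               terminate = "terminate")
  res <- lapply(names(cats), function(nm) {
    k <- sum(o %in% cats[[nm]])
    ci <- if (n > 0) stats::binom.test(k, n)$conf.int else c(NA, NA)
    data.frame(outcome = nm, n = k,
               fraction = if (n > 0) k / n else NA_real_,
               ci_lo = ci[1L], ci_hi = ci[2L])
  })
  out <- do.call(rbind, res)
  attr(out, "n_interacting") <- n
  out
}

#' @export
print.outcome_batch <- function(x, ...) {
  n <- attr(x$summary, "n_interacting")
  cat(sprintf("<outcome_batch> %d runs, %d interacting encounters\n",
              nrow(x$outcomes), n))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
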