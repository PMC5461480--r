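# Ensemble-level measurements: motor counting from photobleaching intensity
# statistics, and stall-force event detection plus Gaussian-mixture
# decomposition of optical-trap traces.

#' Intensity per fluorophore from photobleaching statistics
#'
#' For an ensemble of liposome bleaching traces whose fluorophores survive
#' independently with probability `p(t) = exp(-t/tau)`, the across-trace
#' intensity variance obeys the binomial relation
#' `var_I(t) = v * I0 * p * (1 - p)` with `v` the intensity of one
#' fluorophore and `I0` the mean initial intensity.  `tau` is fitted first
#' from the mean-intensity decay, then `v` by weighted least squares of the
#' variance against `I0 * p * (1-p)` with weights inverse to the squared
#' prediction, concentrating the fit on the informative mid-bleach window
#' (0.05 < p < 0.97) where binomial variance dominates camera noise.
#'
#' For a single trace, `v` falls back to the median size of the discrete
#' downward bleaching steps.
#'
#' @param traces data frame with columns `trace`, `t_s`, `intensity`.
#' @return list with `v`, `tau_s`, `I0` (mean initial intensity).
#' @export
intensity_per_fluorophore <- function(traces) {
  stopifnot(all(c("trace", "t_s", "intensity") %in% names(traces)))
  ids <- unique(traces$trace)
  if (length(ids) == 1L) {
    g <- traces[order(traces$t_s), ]
    steps <- -diff(g$intensity)
    thr <- 3 * stats::mad(diff(g$intensity)) + 1e-12
    drops <- steps[steps > thr]
    if (!length(drops)) drops <- max(steps)
    if (max(steps) <= 0) stop("degenerate input: trace shows no decay")
    return(list(v = stats::median(drops), tau_s = NA_real_,
                I0 = g$intensity[1L]))
  }
  tg <- sort(unique(traces$t_s))
  M <- tapply(traces$intensity, traces$t_s, mean)[as.character(tg)]
  V <- tapply(traces$intensity, traces$t_s, stats::var)[as.character(tg)]
  if (all(V < 1e-12)) stop("degenerate input: zero variance across traces")
  if (stats::sd(M) < 1e-12) stop("degenerate input: no intensity decay")
  ## decay time from the mean trace
  dat <- data.frame(t = tg, M = as.numeric(M))
  pos <- dat$M > 0
  lmfit <- stats::lm(log(M) ~ t, data = dat[pos, ])
  tau0 <- -1 / stats::coef(lmfit)[2L]
  fit <- tryCatch(
    stats::nls(M ~ I0 * exp(-t / tau), data = dat,
               start = list(I0 = dat$M[1L], tau = max(tau0, 1e-3))),
    error = function(e) NULL)
  if (is.null(fit)) {
    tau <- unname(max(tau0, 1e-3)); I0 <- exp(stats::coef(lmfit)[1L])
  } else {
    cf <- stats::coef(fit); tau <- unname(cf["tau"]); I0 <- unname(cf["I0"])
  }
  p <- exp(-tg / tau)
  x <- I0 * p * (1 - p)
  ## weighted least squares with weights 1/x^2 (the variance of a sample
  ## variance scales with its square), i.e. the mean variance-to-
  ## prediction ratio over the informative part of the bleach
  keep <- is.finite(V) & p > 0.05 & p < 0.97
  if (!any(keep)) stop("trace too short: no informative bleaching window")
  v <- mean(V[keep] / x[keep])
  if (!is.finite(v) || v <= 0) stop("could not estimate a positive v")
  list(v = v, tau_s = tau, I0 = unname(I0))
}

#' Motor count from photobleaching intensity
#'
#' Converts initial intensity to fluorophore and motor numbers:
#' `n_fluorophores = I0 / v` and, with two fluorophores per motor (one per
#' motor domain), `n_motors = I0 / (fluor_per_motor * v)`.  The count is
#' scale-invariant: rescaling a trace rescales `I0` and `v` together.
#'
#' @param traces data frame (`trace`, `t_s`, `intensity`).
#' @param v intensity per fluorophore; estimated from the traces when NULL.
#' @param fluor_per_motor fluorophores per motor (2 for a double-headed
#'   construct tagged on each motor domain).
#' @return list with per-trace data frame `per_trace` (`trace`, `I0`,
#'   `n_fluorophores`, `n_motors`), population `mean_motors`, and `v`.
#' @export
motor_count <- function(traces, v = NULL, fluor_per_motor = 2) {
  est <- if (is.null(v)) intensity_per_fluorophore(traces) else list(v = v)
  if (est$v <= 0) stop("v must be positive")
  ids <- unique(traces$trace)
  I0 <- vapply(ids, function(id) {
    g <- traces[traces$trace == id, ]
    g$intensity[which.min(g$t_s)]
  }, numeric(1))
  nf <- I0 / est$v
  nm <- nf / fluor_per_motor
  list(per_trace = data.frame(trace = ids, I0 = I0, n_fluorophores = nf,
                              n_motors = nm),
       mean_motors = mean(nm), v = est$v)
}

#' Detect stall peaks in an optical-trap force trace
#'
#' A peak is the maximal force within a 250 ms sliding window whose first
#' half shows the bead advancing faster than `v_threshold` and whose second
#' half shows it retreating faster than `-v_threshold` (velocities from the
#' displacement `F / trap_stiffness`).  Overlapping qualifying windows are
#' merged into one event.  The displacement is boxcar-smoothed over a fifth
#' of the window before velocities and peak heights are read off, so that
#' sampling noise neither fakes half-window velocity crossings nor inflates
#' window maxima.
#'
#' @param trace data frame with `t_s`, `force_pN`, uniformly sampled.
#' @param window window width, s.
#' @param v_threshold half-window speed threshold, nm/s.
#' @param trap_stiffness trap stiffness, pN/nm.
#' @return data frame of events: `time_s`, `peak_force_pN`.
#' @export
detect_peak_forces <- function(trace, window = 0.25, v_threshold = 50,
                               trap_stiffness = 0.019) {
  t <- trace$t_s; F <- trace$force_pN
  dt <- stats::median(diff(t))
  h <- max(1L, round(window / 2 / dt))
  if (length(t) <= 2L * h) stop("trace shorter than the sliding window")
  k <- max(1L, round(window / 5 / dt))
  if (k > 1L) {
    Fs <- as.numeric(stats::filter(F, rep(1 / k, k), sides = 2))
    Fs[is.na(Fs)] <- F[is.na(Fs)]
    F <- Fs
  }
  x <- F / trap_stiffness
  n <- length(x)
  i0 <- seq_len(n - 2L * h)
  v1 <- (x[i0 + h] - x[i0]) / (h * dt)
  v2 <- (x[i0 + 2L * h] - x[i0 + h]) / (h * dt)
  qual <- which(v1 > v_threshold & v2 < -v_threshold)
  if (!length(qual)) {
    return(data.frame(time_s = numeric(0), peak_force_pN = numeric(0)))
  }
  ## merge windows that overlap (qualifying starts closer than one window)
  brk <- c(0L, which(diff(qual) > 2L * h), length(qual))
  out <- lapply(seq_len(length(brk) - 1L), function(g) {
    q <- qual[(brk[g] + 1L):brk[g + 1L]]
    span <- min(q):(max(q) + 2L * h)
    j <- span[which.max(F[span])]
    data.frame(time_s = t[j], peak_force_pN = F[j])
  })
  do.call(rbind, out)
}

#' Gaussian-mixture decomposition of stall forces
#'
#' Fits univariate Gaussian mixtures with `k_range` components to detected
#' peak forces and selects the number of components by BIC, reporting the
#' components sorted by ascending mean.
#'
#' @param forces numeric vector of peak forces, pN (>= `min_events`).
#' @param k_range candidate component counts.
#' @param min_events minimum number of events for a stable fit.
#' @importFrom mclust Mclust mclustBIC
#' @return list of class `stall_mixture`: `k`, `means`, `sds`, `weights`,
#'   `bic` (per candidate k), `n`.
#' @export
stall_mixture <- function(forces, k_range = 1:4, min_events = 50L) {
  forces <- forces[is.finite(forces)]
  if (length(forces) < min_events) {
    stop("too few stall events for a stable mixture fit")
  }
  fit <- mclust::Mclust(forces, G = k_range, modelNames = "V",
                        verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  ord <- order(fit$parameters$mean)
  structure(list(
    k = fit$G,
    means = unname(fit$parameters$mean[ord]),
    sds = unname(sqrt(fit$parameters$variance$sigmasq))[
      if (length(fit$parameters$variance$sigmasq) == 1L) rep(1L, fit$G) else ord],
    weights = unname(fit$parameters$pro[ord]),
    bic = fit$BIC, n = length(forces)
  ), class = "stall_mixture")
}

#' @export
print.stall_mixture <- function(x, ...) {
  cat(sprintf("<stall_mixture> %d events, k = %d\n", x$n, x$k))
  for (i in seq_len(x$k)) {
    cat(sprintf("  component %d: %.2f +/- %.2f pN (weight %.2f)\n",
                i, x$means[i], x$sds[i], x$weights[i]))
  }
  invisible(x)
}
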