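#' Relative standard deviation of a time series
#'
#' Sample (n-1) standard deviation divided by the mean; the fluctuation
#' measure used to compare growth speed, wall thickness, and vesicle
#' intensity over time lapses.
#'
#' @param x numeric series, at least 3 samples.
#' @return sd(x) / mean(x).
#' @export
relative_std <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("need at least 3 samples")
  m <- mean(x)
  if (m == 0) stop("relative std undefined for zero mean")
  stats::sd(x) / m
}

#' Normalized time-lagged cross-correlation
#'
#' For each lag `dt`, the mean over the overlap of
#' `(a(t) - mean(a)) (b(t + dt) - mean(b))` divided by the product of the
#' full-series sample standard deviations; with `a = b` the value at zero
#' lag is exactly 1. Positive lags mean `b` follows `a`.
#'
#' @param a,b equal-length, uniformly sampled series.
#' @param max_lag maximum lag in samples; must not exceed `length(a) / 3`.
#' @return data.frame(lag, r).
#' @export
cross_correlation <- function(a, b, max_lag = floor(length(a) / 3)) {
  n <- length(a)
  if (length(b) != n) stop("series must have equal length")
  if (max_lag > n / 3) stop("max_lag must not exceed n/3")
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) stop("zero-variance input")
  ma <- mean(a); mb <- mean(b)
  lags <- seq(-max_lag, max_lag)
  r <- vapply(lags, function(dt) {
    ts <- seq(max(1, 1 - dt), min(n, n - dt))
    sum((a[ts] - ma) * (b[ts + dt] - mb)) / ((length(ts) - 1) * sa * sb)
  }, numeric(1))
  data.frame(lag = lags, r = r)
}

#' Photobleaching correction against a fixed-cell reference
#'
#' Divides a measured trace by a reference trace (same illumination cadence,
#' signal from fixed cells) normalized to its initial value.
#'
#' @param trace measured intensities.
#' @param reference reference intensities, all positive.
#' @return corrected trace.
#' @export
bleach_correct <- function(trace, reference) {
  if (length(reference) != length(trace))
    stop("trace and reference must have equal length")
  if (any(reference <= 0)) stop("reference trace must stay positive")
  trace / (reference / reference[1])
}

#' Drift of a fiducial thickness mark in the lab frame
#'
#' Tracks a local thickness extremum across the frames of a kymograph (wall
#' thickness vs arclength behind the tip) with parabolic subpixel
#' refinement, converts each position to the lab frame using the advancing
#' tip position, and reports the drift speed as the slope of a linear fit.
#' Near-zero drift of a mark laid down in the wall indicates the absence of
#' advective wall flow.
#'
#' @param kymo list with `t_min` (frame times), `s_um` (arclength grid,
#'   distance behind the tip), `h` (matrix frames x positions, nm),
#'   `tip_position_um` (tip position per frame, lab frame).
#' @param prominence_frac minimum extremum prominence relative to the frame
#'   median, below which the mark is considered absent.
#' @return list(drift_um_per_min, track = data.frame(t_min, s_um,
#'   lab_um)).
#' @export
fiducial_drift <- function(kymo, prominence_frac = 0.02) {
  h <- kymo$h; s <- kymo$s_um; tt <- kymo$t_min
  if (!is.matrix(h) || nrow(h) != length(tt) || ncol(h) != length(s))
    stop("kymograph h must be a frames x positions matrix")
  ds <- diff(s[1:2])
  find_peak <- function(v, near = NULL) {
    cand <- which(diff(sign(diff(v))) == -2) + 1
    cand <- cand[v[cand] - stats::median(v) >
                   prominence_frac * stats::median(v)]
    if (length(cand) == 0) return(NULL)
    if (!is.null(near)) cand <- cand[order(abs(s[cand] - near))][1]
    else cand <- cand[which.max(v[cand])]
    # parabolic refinement
    k <- cand
    if (k <= 1 || k >= length(v)) return(s[k])
    d <- 0.5 * (v[k - 1] - v[k + 1]) / (v[k - 1] - 2 * v[k] + v[k + 1])
    s[k] + max(-0.5, min(0.5, d)) * ds
  }
  pos <- rep(NA_real_, length(tt))
  prev <- NULL
  for (i in seq_along(tt)) {
    p <- find_peak(h[i, ], near = prev)
    if (is.null(p)) break
    pos[i] <- p; prev <- p
  }
  okn <- sum(is.finite(pos))
  if (okn < 5) stop("mark lost: fiducial trackable in ", okn, " < 5 frames")
  keep <- is.finite(pos)
  lab <- kymo$tip_position_um[keep] - pos[keep]
  fit <- stats::lm(lab ~ tt[keep])
  list(drift_um_per_min = unname(stats::coef(fit)[2]),
       track = data.frame(t_min = tt[keep], s_um = pos[keep], lab_um = lab))
}

#' Strain rate from tip kinematics
#'
#' The wall strain rate equals the surface growth speed over the squared tip
#' radius of curvature; a hemispherical cap advancing at `tip_speed` creates
#' surface at `2 pi R v`, hence `G = 2 pi v / R`.
#'
#' @param tip_speed_um_min tip elongation speed (um/min).
#' @param R_um tip radius of curvature (um).
#' @return strain rate (1/min).
#' @export
strain_rate_from_kinematics <- function(tip_speed_um_min, R_um) {
  if (R_um <= 0) stop("R must be positive")
  2 * pi * tip_speed_um_min / R_um
}
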