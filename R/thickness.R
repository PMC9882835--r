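#' Wall thickness from a pair of peak fits
#'
#' The local wall thickness is the distance between the outer-face and
#' inner-face peak centres along the contour normal, minus the projection of
#' the calibrated chromatic shift onto the outward normal. A non-positive
#' corrected distance or an unacceptable fit is flagged invalid.
#'
#' @param fit_inner,fit_outer `peak_fit` objects for the membrane (inner) and
#'   lectin (outer) channels, centres in nm along the same normal.
#' @param chromatic_shift_nm 2-vector, calibrated shift of the outer channel.
#' @param normal outward unit normal at the measurement point.
#' @return list(h_nm, valid).
#' @export
compute_thickness <- function(fit_inner, fit_outer,
                              chromatic_shift_nm = c(0, 0),
                              normal = c(1, 0)) {
  if (!isTRUE(fit_inner$ok) || !isTRUE(fit_outer$ok))
    return(list(h_nm = NA_real_, valid = FALSE))
  h <- (fit_outer$center_nm - fit_inner$center_nm) -
    sum(chromatic_shift_nm * normal)
  list(h_nm = h, valid = is.finite(h) && h > 0)
}

# Gaussian smoothing of values sampled on a (possibly circular) arclength grid
.smooth_arclength <- function(s, v, ok, sd_um, circular = TRUE, total_len = NULL) {
  out <- rep(NA_real_, length(s))
  si <- s[ok]; vi <- v[ok]
  if (length(si) < 3) return(v)
  for (i in seq_along(s)) {
    d <- abs(si - s[i])
    if (circular && !is.null(total_len)) d <- pmin(d, total_len - d)
    wgt <- exp(-d^2 / (2 * sd_um^2))
    out[i] <- sum(wgt * vi) / sum(wgt)
  }
  out
}

#' Map wall thickness around a cell
#'
#' Full thickness pipeline on a registered two-channel mid-slice image:
#' contour segmentation on the membrane channel, per-point normal intensity
#' profiles of both channels, Gaussian-plus-step peak fits, chromatic-shift
#' correction, quality gating, and Gaussian smoothing along the arclength at
#' the configured scale (default 500 nm, the along-surface resolution of the
#' method).
#'
#' @param image a `synthetic_image`, or list of two matrices with
#'   `config$pixel_size_nm` set.
#' @param config a `pipeline_config`; see [pipeline_config()].
#' @param contour optionally a precomputed `cell_contour`.
#' @return a `thickness_map` data.frame: s_um, sprime_um, h_nm (smoothed),
#'   h_raw_nm, quality, flag; attributes `tip_index`, `contour`,
#'   `smoothing_scale_nm`.
#' @export
map_thickness <- function(image, config = pipeline_config(), contour = NULL) {
  if (!inherits(image, "synthetic_image") && is.list(image) &&
      is.matrix(image[[1]])) {
    image <- structure(list(channels = image, x0_um = 0, y0_um = 0,
                            pixel_um = config$pixel_size_nm * 1e-3,
                            nx = ncol(image[[1]]), ny = nrow(image[[1]]),
                            spec = NULL),
                       class = "synthetic_image")
  }
  if (is.null(contour))
    contour <- segment_contour(image, channel = 1,
                               smooth_sigma_px = config$segment_sigma_px)
  nrm <- contour_normals(contour)
  n <- nrow(contour)
  half <- max(3 * max(config$psf_sigma_nm), 450)
  h_raw <- qual <- rep(NA_real_, n)
  flag <- rep("ok", n)
  for (i in seq_len(n)) {
    prof <- sample_normal_profile(image, contour, i, half_length_nm = half,
                                  channels = c(1, 2))
    f1 <- fit_peak(prof$position_nm, prof$ch1, config$psf_sigma_nm[1],
                   config$width_range, config$quality_min)
    f2 <- fit_peak(prof$position_nm, prof$ch2, config$psf_sigma_nm[2],
                   config$width_range, config$quality_min)
    th <- compute_thickness(f1, f2, config$chromatic_shift_nm, nrm[i, ])
    h_raw[i] <- th$h_nm
    qual[i] <- min(f1$quality, f2$quality)
    flag[i] <- if (!isTRUE(f1$ok) || !isTRUE(f2$ok)) "low_quality"
      else if (!th$valid) "negative" else "ok"
  }
  ok <- flag == "ok"
  if (mean(!ok) > 0.5)
    warning(sprintf("map_thickness: %.0f%% of contour points flagged",
                    100 * mean(!ok)))
  hs <- .smooth_arclength(contour$s_um, h_raw, ok,
                          sd_um = config$smoothing_scale_nm / 2354.8,
                          circular = isTRUE(attr(contour, "closed")),
                          total_len = attr(contour, "length_um"))
  out <- data.frame(s_um = contour$s_um, sprime_um = contour$sprime_um,
                    h_nm = hs, h_raw_nm = h_raw, quality = qual, flag = flag)
  structure(out, tip_index = attr(contour, "tip_index"), contour = contour,
            smoothing_scale_nm = config$smoothing_scale_nm,
            class = c("thickness_map", "data.frame"))
}

#' Tip and side thickness summaries of a map
#'
#' Tip is the mean over `|s'| <= tip_window_um`; side the mean over
#' `side_window_um[1] <= |s'| <= side_window_um[2]`, accepted points only.
#'
#' @param map a `thickness_map`.
#' @param tip_window_um apical half-window (um).
#' @param side_window_um lateral window (um, length 2).
#' @return list(tip_nm, side_nm, ratio).
#' @export
tip_side_summary <- function(map, tip_window_um = 1,
                             side_window_um = c(5, 10)) {
  ok <- map$flag == "ok" & is.finite(map$h_nm)
  sp <- abs(map$sprime_um)
  tip <- mean(map$h_nm[ok & sp <= tip_window_um])
  side <- mean(map$h_nm[ok & sp >= side_window_um[1] & sp <= side_window_um[2]])
  list(tip_nm = tip, side_nm = side, ratio = tip / side)
}
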