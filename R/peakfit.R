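#' Fit a Gaussian peak on an asymmetric step background
#'
#' Fits `I(x) = b_out + (b_in - b_out) * pnorm((c - x)/w) + A * exp(-(x-c)^2 /
#' (2 w^2))` to an intensity profile sampled across the cell wall. The
#' error-function step is the physical form of the PSF-convolved intensity
#' difference between the cell interior and the medium, and sharing the peak
#' centre and width between the Gaussian and the step removes the centre bias
#' that a plain Gaussian fit incurs when the two plateaus differ.
#'
#' @param position_nm signed positions along the normal (negative inside).
#' @param intensity counts at each position.
#' @param psf_sigma_nm nominal PSF sigma, used to initialize and gate the
#'   fitted width.
#' @param width_range acceptable fitted width as multiples of the PSF sigma;
#'   outside this range the fit is flagged.
#' @param quality_min fits with R-squared below this value are flagged.
#' @return a `peak_fit`: list(center_nm, width_sigma_nm, amplitude,
#'   background_in, background_out, quality, ok).
#' @export
fit_peak <- function(position_nm, intensity, psf_sigma_nm = 200,
                     width_range = c(0.5, 3), quality_min = 0.8) {
  keep <- is.finite(position_nm) & is.finite(intensity)
  x <- position_nm[keep]; y <- intensity[keep]
  if (length(x) < 8) {
    return(structure(list(center_nm = NA_real_, width_sigma_nm = NA_real_,
                          amplitude = NA_real_, background_in = NA_real_,
                          background_out = NA_real_, quality = 0, ok = FALSE),
                     class = "peak_fit"))
  }
  nfl <- max(3L, round(0.15 * length(x)))
  bi0 <- mean(utils::head(y, nfl)); bo0 <- mean(utils::tail(y, nfl))
  c0 <- x[which.max(y)]
  A0 <- max(y) - max(bi0, bo0)
  w0 <- max(psf_sigma_nm, 1)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      y ~ bo + (bi - bo) * pnorm((cc - x) / w) + A * exp(-(x - cc)^2 / (2 * w^2)),
      start = list(A = max(A0, 1e-3), cc = c0, w = w0, bi = bi0, bo = bo0),
      lower = c(A = 0, cc = min(x), w = w0 * width_range[1] / 2, bi = 0, bo = 0),
      upper = c(A = Inf, cc = max(x), w = w0 * width_range[2] * 2,
                bi = Inf, bo = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 80))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # coarse fallback: grid over the centre, remaining parameters linear
    cand <- seq(min(x), max(x), length.out = 81)
    best <- NULL; best_sse <- Inf
    for (cc in cand) {
      M <- cbind(1, pnorm((cc - x) / w0), exp(-(x - cc)^2 / (2 * w0^2)))
      cf <- tryCatch(qr.solve(M, y), error = function(e) NULL)
      if (is.null(cf)) next
      sse <- sum((y - M %*% cf)^2)
      if (sse < best_sse) { best_sse <- sse; best <- list(cc = cc, cf = cf) }
    }
    if (is.null(best)) {
      return(structure(list(center_nm = NA_real_, width_sigma_nm = NA_real_,
                            amplitude = NA_real_, background_in = NA_real_,
                            background_out = NA_real_, quality = 0, ok = FALSE),
                       class = "peak_fit"))
    }
    pars <- c(A = unname(best$cf[3]), cc = best$cc, w = w0,
              bi = unname(best$cf[1] + best$cf[2]), bo = unname(best$cf[1]))
    res <- y - cbind(1, pnorm((pars["cc"] - x) / w0),
                     exp(-(x - pars["cc"])^2 / (2 * w0^2))) %*% best$cf
  } else {
    pars <- stats::coef(fit)
    res <- stats::residuals(fit)
  }
  sst <- sum((y - mean(y))^2)
  quality <- if (sst > 0) max(0, min(1, 1 - sum(res^2) / sst)) else 0
  wr <- pars[["w"]] / psf_sigma_nm
  ok <- quality >= quality_min && wr >= width_range[1] && wr <= width_range[2] &&
    pars[["A"]] > 0
  structure(list(center_nm = pars[["cc"]], width_sigma_nm = pars[["w"]],
                 amplitude = pars[["A"]], background_in = pars[["bi"]],
                 background_out = pars[["bo"]],
                 quality = quality, ok = ok),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("peak: centre %.1f nm, sigma %.1f nm, A %.1f, bg in/out %.1f/%.1f, q %.3f%s\n",
              x$center_nm, x$width_sigma_nm, x$amplitude, x$background_in,
              x$background_out, x$quality, if (x$ok) "" else " [flagged]"))
  invisible(x)
}

#' Full width at mid height of a peaked profile
#'
#' Gaussian fit above a baseline estimated from the profile flanks; the
#' returned width is `2 sqrt(2 log 2) * sigma` (about `2.355 sigma`), in the
#' units of `position`. Used for polarity-domain sizes along the tip
#' arclength.
#'
#' @param position coordinate (e.g. arclength, um).
#' @param intensity profile values.
#' @return width at half maximum, same units as `position`.
#' @export
fwmh <- function(position, intensity) {
  keep <- is.finite(position) & is.finite(intensity)
  x <- position[keep]; y <- intensity[keep]
  nfl <- max(3L, round(0.1 * length(x)))
  fl <- c(utils::head(y, nfl), utils::tail(y, nfl))
  b0 <- mean(fl)
  if (max(y) - b0 <= 3 * stats::sd(fl) + 1e-12)
    stop("no peak above baseline")
  c0 <- x[which.max(y)]
  w0 <- diff(range(x)) / 8
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nlsLM(y ~ b + A * exp(-(x - cc)^2 / (2 * w^2)),
                        start = list(A = max(y) - b0, cc = c0, w = w0, b = b0),
                        lower = c(A = 0, cc = min(x), w = 1e-9, b = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 80))),
    error = function(e) stop("no peak above baseline: Gaussian fit failed"))
  unname(2 * sqrt(2 * log(2)) * stats::coef(fit)[["w"]])
}

#' Background-subtracted apical marker intensity
#'
#' Maximum intensity within an apical window around the contour tip, minus
#' the median background measured outside the cell.
#'
#' @param image `synthetic_image` or matrix.
#' @param contour a `cell_contour`.
#' @param channel marker channel index.
#' @param tip_index contour tip; defaults to the contour attribute.
#' @param window_um radius of the apical window (um).
#' @param bg_margin_um pixels farther than this from the contour, outside the
#'   cell, are used for the background estimate.
#' @param pixel_size_nm required for plain matrices.
#' @return background-subtracted counts, with attributes `background` and
#'   `saturated`.
#' @export
tip_intensity <- function(image, contour, channel = 1, tip_index = NULL,
                          window_um = 1, bg_margin_um = 0.8,
                          pixel_size_nm = NULL) {
  ip <- .as_image_parts(image, channel, pixel_size_nm)
  if (is.null(tip_index)) tip_index <- attr(contour, "tip_index")
  m <- ip$m
  xg <- ip$x0 + (seq_len(ncol(m)) - 1) * ip$px
  yg <- ip$y0 + (seq_len(nrow(m)) - 1) * ip$px
  G <- expand.grid(x = xg, y = yg)
  tipx <- contour$x_um[tip_index]; tipy <- contour$y_um[tip_index]
  dtip <- sqrt((G$x - tipx)^2 + (G$y - tipy)^2)
  v <- as.vector(t(m))   # matches expand.grid order (x fastest)
  win <- v[dtip <= window_um]
  if (length(win) == 0) stop("apical window contains no pixels")
  # background: outside the contour polygon and away from it
  inside <- .point_in_polygon(G$x, G$y, contour$x_um, contour$y_um)
  dmin <- .min_dist_to_points(G$x, G$y, contour$x_um, contour$y_um)
  bgpix <- v[!inside & dmin > bg_margin_um]
  bg <- if (length(bgpix) > 0) stats::median(bgpix) else stats::median(v)
  out <- max(win) - bg
  attr(out, "background") <- bg
  attr(out, "saturated") <- any(win >= 65535)
  out
}

# even-odd rule point-in-polygon, vectorized over query points
.point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.min_dist_to_points <- function(px, py, vx, vy) {
  # coarse but adequate: distance to polygon vertices (vertices are ~1 px apart)
  d <- rep(Inf, length(px))
  for (i in seq_along(vx)) {
    d <- pmin(d, sqrt((px - vx[i])^2 + (py - vy[i])^2))
  }
  d
}
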