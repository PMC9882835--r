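# Bilinear interpolation of a matrix image (rows = y) at physical coordinates.
# Points outside the raster return NA.
.bilinear <- function(m, x0_um, y0_um, pixel_um, x_um, y_um) {
  cx <- (x_um - x0_um) / pixel_um + 1
  cy <- (y_um - y0_um) / pixel_um + 1
  nx <- ncol(m); ny <- nrow(m)
  j0 <- floor(cx); i0 <- floor(cy)
  fx <- cx - j0; fy <- cy - i0
  ok <- j0 >= 1 & j0 <= nx - 1 & i0 >= 1 & i0 <= ny - 1
  out <- rep(NA_real_, length(x_um))
  if (any(ok)) {
    j <- j0[ok]; i <- i0[ok]; u <- fx[ok]; v <- fy[ok]
    out[ok] <- m[cbind(i, j)] * (1 - u) * (1 - v) +
      m[cbind(i, j + 1)] * u * (1 - v) +
      m[cbind(i + 1, j)] * (1 - u) * v +
      m[cbind(i + 1, j + 1)] * u * v
  }
  out
}

.as_image_parts <- function(image, channel, pixel_size_nm = NULL) {
  if (inherits(image, "synthetic_image")) {
    list(m = image$channels[[channel]], x0 = image$x0_um, y0 = image$y0_um,
         px = image$pixel_um)
  } else {
    if (is.null(pixel_size_nm))
      stop("pixel_size_nm is required for a plain matrix image")
    list(m = image, x0 = 0, y0 = 0, px = pixel_size_nm * 1e-3)
  }
}

#' Segment the cell contour from the membrane channel
#'
#' Traces the cell outline on the (smoothed) membrane channel: Otsu threshold,
#' largest connected component, ordered boundary, then subpixel refinement of
#' each boundary point to the membrane ridge by a parabolic fit of the
#' intensity sampled along the local normal. The contour is resampled at
#' uniform arclength (about one pixel) and the tip is located as the point of
#' maximal projection onto the major axis of the contour.
#'
#' @param image a `synthetic_image` or numeric matrix (rows = y).
#' @param channel channel index holding the membrane signal.
#' @param pixel_size_nm pixel pitch, required for plain matrices.
#' @param smooth_sigma_px Gaussian smoothing before thresholding (pixels).
#' @param min_area_px minimum component area regarded as a cell.
#' @param refine_fit re-centre the contour with the Gaussian-plus-step peak
#'   fit on the raw channel (removes the step-induced ridge bias).
#' @param psf_sigma_nm nominal PSF sigma used by the refinement fit.
#' @return a `cell_contour`: data.frame(x_um, y_um, s_um, sprime_um) with
#'   attributes `tip_index`, `closed`, `pixel_um`.
#' @export
segment_contour <- function(image, channel = 1, pixel_size_nm = NULL,
                            smooth_sigma_px = 1.5, min_area_px = 200,
                            refine_fit = TRUE, psf_sigma_nm = 200) {
  ip <- .as_image_parts(image, channel, pixel_size_nm)
  m <- ip$m
  if (max(m) <= min(m)) stop("no contour found: image is constant")
  sm <- as.matrix(EBImage::gblur(m, sigma = smooth_sigma_px))
  rng <- range(sm)
  thr <- EBImage::otsu(EBImage::Image((sm - rng[1]) / diff(rng)),
                       range = c(0, 1))
  mask <- (sm - rng[1]) / diff(rng) > thr
  # a cell must stand out of the background, not just split the noise
  mu_in <- mean(sm[mask]); mu_out <- mean(sm[!mask])
  if (!is.finite(mu_in) || !is.finite(mu_out) ||
      (mu_in - mu_out) < 5 * stats::sd(sm[!mask]))
    stop("no contour found: no feature above the background noise")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  tab <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  if (length(tab) == 0 || max(tab) < min_area_px)
    stop("no contour found: no connected component above ", min_area_px, " px")
  big <- which.max(tab)
  oc <- EBImage::ocontour(EBImage::Image((lab == big) * 1))[[1]]
  if (nrow(oc) < 20) stop("no contour found: boundary too short")
  # ocontour returns 0-based (row, col) pairs of the mask boundary; map to
  # physical coordinates of pixel centres (rows index y in this package)
  bx <- ip$x0 + oc[, 2] * ip$px
  by <- ip$y0 + oc[, 1] * ip$px
  n <- length(bx)
  idx <- function(i) ((i - 1) %% n) + 1
  # subpixel ridge refinement along local normals (two passes: the mask
  # boundary can sit a few pixels off the membrane ridge)
  rx <- bx; ry <- by
  for (pass in 1:2) {
    off_px <- if (pass == 1) seq(-6, 6, by = 0.5) else seq(-2, 2, by = 0.25)
    px0 <- rx; py0 <- ry
    for (i in seq_len(n)) {
      a <- idx(i - 3); b <- idx(i + 3)
      tx <- px0[b] - px0[a]; ty <- py0[b] - py0[a]
      tl <- sqrt(tx^2 + ty^2)
      if (tl < 1e-9) next
      nxv <- -ty / tl; nyv <- tx / tl
      xs <- px0[i] + nxv * off_px * ip$px
      ys <- py0[i] + nyv * off_px * ip$px
      vals <- .bilinear(sm, ip$x0, ip$y0, ip$px, xs, ys)
      if (anyNA(vals)) next
      k <- which.max(vals)
      if (k <= 1 || k >= length(off_px)) next
      # parabolic subpixel peak
      d <- 0.5 * (vals[k - 1] - vals[k + 1]) /
        (vals[k - 1] - 2 * vals[k] + vals[k + 1])
      d <- max(-0.5, min(0.5, d))
      sh <- (off_px[k] + d * diff(off_px[1:2])) * ip$px
      rx[i] <- px0[i] + nxv * sh
      ry[i] <- py0[i] + nyv * sh
    }
  }
  # light smoothing along the contour, then uniform arclength resampling
  ks <- function(z) (z + z[idx(seq_len(n) + 1)] + z[idx(seq_len(n) - 1)]) / 3
  rx <- ks(rx); ry <- ks(ry)
  ct <- .resample_contour(rx, ry, ip$px)
  if (refine_fit) {
    # the smoothed-ridge maximum is biased towards the brighter plateau;
    # re-centre each point with the Gaussian-plus-step fit on the raw channel
    nrm <- contour_normals(ct)
    half <- 3 * psf_sigma_nm
    step <- ip$px * 1e3 / 2
    shifts <- rep(0, nrow(ct))
    for (i in seq_len(nrow(ct))) {
      pos <- seq(-half, half, by = step)
      xs <- ct$x_um[i] + nrm[i, 1] * pos * 1e-3
      ys <- ct$y_um[i] + nrm[i, 2] * pos * 1e-3
      vals <- .bilinear(m, ip$x0, ip$y0, ip$px, xs, ys)
      f <- fit_peak(pos, vals, psf_sigma_nm, quality_min = 0.5)
      if (isTRUE(f$ok) && abs(f$center_nm) < half)
        shifts[i] <- f$center_nm
    }
    sm_sh <- stats::filter(c(utils::tail(shifts, 3), shifts,
                             utils::head(shifts, 3)),
                           rep(1 / 7, 7), sides = 2)[4:(nrow(ct) + 3)]
    ct <- .resample_contour(ct$x_um + nrm[, 1] * sm_sh * 1e-3,
                            ct$y_um + nrm[, 2] * sm_sh * 1e-3, ip$px)
  }
  ct
}

.resample_contour <- function(rx, ry, px_um) {
  n <- length(rx)
  seg <- sqrt(diff(c(rx, rx[1]))^2 + diff(c(ry, ry[1]))^2)
  cs <- c(0, cumsum(seg))
  L <- cs[n + 1]
  s_new <- seq(0, L, by = px_um)
  s_new <- s_new[s_new < L - px_um / 2]
  xs <- stats::approx(cs, c(rx, rx[1]), xout = s_new)$y
  ys <- stats::approx(cs, c(ry, ry[1]), xout = s_new)$y
  pts <- data.frame(x_um = xs, y_um = ys, s_um = s_new)
  # tip: maximal projection on the major axis
  pc <- stats::prcomp(cbind(xs, ys))
  proj <- pc$x[, 1]
  tip <- which.max(proj)
  sp <- s_new - s_new[tip]
  sp <- ifelse(sp > L / 2, sp - L, ifelse(sp < -L / 2, sp + L, sp))
  pts$sprime_um <- sp
  structure(pts, tip_index = tip, closed = TRUE, pixel_um = px_um,
            length_um = L, class = c("cell_contour", "data.frame"))
}

#' Outward unit normals of a contour
#'
#' Normals are computed from a centred tangent over `half_window` contour
#' points on each side and oriented away from the contour centroid.
#'
#' @param contour a `cell_contour`.
#' @param half_window half-width of the tangent window (points).
#' @return matrix n x 2 of unit normals.
#' @export
contour_normals <- function(contour, half_window = 5) {
  x <- contour$x_um; y <- contour$y_um
  n <- length(x)
  idx <- function(i) ((i - 1) %% n) + 1
  a <- idx(seq_len(n) - half_window); b <- idx(seq_len(n) + half_window)
  tx <- x[b] - x[a]; ty <- y[b] - y[a]
  tl <- sqrt(tx^2 + ty^2); tl[tl < 1e-12] <- 1
  nx <- -ty / tl; ny <- tx / tl
  cx <- mean(x); cy <- mean(y)
  flip <- (nx * (x - cx) + ny * (y - cy)) < 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
  cbind(nx, ny)
}

#' Sample intensity profiles along the contour normal
#'
#' Bilinear-interpolated intensity of each requested channel along the
#' outward normal at one contour point. Positions are signed: negative inside
#' the cell, positive outside.
#'
#' @param image `synthetic_image` or matrix.
#' @param contour a `cell_contour`.
#' @param index contour point index.
#' @param half_length_nm profile half-length (nm).
#' @param step_nm sampling step; defaults to half a pixel and must not exceed
#'   one pixel.
#' @param channels channel indices to sample.
#' @param pixel_size_nm required for plain matrices.
#' @return data.frame(position_nm, oob, ch1[, ch2, ...]); `oob` flags samples
#'   outside the raster (returned as NA, not an error).
#' @export
sample_normal_profile <- function(image, contour, index, half_length_nm = 650,
                                  step_nm = NULL, channels = 1,
                                  pixel_size_nm = NULL) {
  ip <- .as_image_parts(image, channels[1], pixel_size_nm)
  px_nm <- ip$px * 1e3
  if (is.null(step_nm)) step_nm <- px_nm / 2
  if (step_nm > px_nm) stop("step_nm must not exceed the pixel size")
  nrm <- contour_normals(contour)
  p <- c(contour$x_um[index], contour$y_um[index])
  nv <- nrm[index, ]
  pos <- seq(-half_length_nm, half_length_nm, by = step_nm)
  xs <- p[1] + nv[1] * pos * 1e-3
  ys <- p[2] + nv[2] * pos * 1e-3
  out <- data.frame(position_nm = pos)
  for (k in channels) {
    ipk <- .as_image_parts(image, k, pixel_size_nm)
    out[[paste0("ch", k)]] <- .bilinear(ipk$m, ipk$x0, ipk$y0, ipk$px, xs, ys)
  }
  out$oob <- rowSums(is.na(out[, -1, drop = FALSE])) > 0
  attr(out, "normal") <- nv
  out
}

#' Summary geometry of a segmented contour
#'
#' Estimates tube radius (median half-width about the major axis over the
#' central part of the cell), length (extent along the major axis), and tip
#' radius of curvature (least-squares circle through the apical arc). Used to
#' recover elastic strains from deflation image pairs.
#'
#' @param contour a `cell_contour`.
#' @return list(R_um, L_um, Rt_um).
#' @export
contour_geometry <- function(contour) {
  x <- contour$x_um; y <- contour$y_um
  pc <- stats::prcomp(cbind(x, y))
  along <- pc$x[, 1]; perp <- pc$x[, 2]
  ext <- diff(range(along))
  mid <- abs(along - stats::median(along)) < 0.3 * ext
  R <- stats::median(abs(perp[mid]))
  sp <- contour$sprime_um
  apical <- abs(sp) <= 1.3 * R
  xa <- x[apical]; ya <- y[apical]
  # Kasa least-squares circle fit
  A <- cbind(2 * xa, 2 * ya, 1)
  b <- xa^2 + ya^2
  sol <- qr.solve(A, b)
  Rt <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  # cylindrical-section length: total extent minus the two end caps
  list(R_um = R, L_um = ext - unname(Rt) - R, Rt_um = unname(Rt))
}
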