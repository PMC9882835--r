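#' Phantom hypha geometry
#'
#' Build the ground-truth geometry of a synthetic hypha: a tube of radius
#' `radius_um` around a midline polyline, closed by a hemispherical cap at the
#' growing end (and at the back). The wall is the region between an inner face
#' (the plasma-membrane line) and an outer face displaced by the local wall
#' thickness `h(s)` along the outward normal, where `s` is the arclength
#' distance from the tip apex in micrometres.
#'
#' @param radius_um tube radius (um), > 0.
#' @param length_um midline length (um), > 0.
#' @param thickness_nm wall thickness: a single positive number (nm) or a
#'   function of arclength `s` (um, >= 0) returning thickness in nm.
#' @param cap_radius_um radius of the apical cap (um); defaults to the tube
#'   radius. Used by deflation pairs with a distinct tip strain.
#' @param bend_deg optional bend of the midline (degrees) applied at its
#'   midpoint; 0 gives a straight tube.
#' @param origin_um 2-vector, position of the midline start (um).
#' @return an object of class `phantom_geometry`.
#' @examples
#' g <- make_phantom(radius_um = 1, length_um = 4, thickness_nm = 80)
#' cv <- phantom_curves(g)
#' range(cv$h_nm)
#' @export
make_phantom <- function(radius_um, length_um, thickness_nm = 80,
                         cap_radius_um = radius_um, bend_deg = 0,
                         origin_um = c(0, 0)) {
  if (!is.numeric(radius_um) || radius_um <= 0)
    stop("radius_um must be positive")
  if (!is.numeric(length_um) || length_um <= 0)
    stop("length_um must be positive")
  if (cap_radius_um <= 0) stop("cap_radius_um must be positive")
  hfun <- if (is.function(thickness_nm)) {
    thickness_nm
  } else {
    if (!is.numeric(thickness_nm) || thickness_nm <= 0)
      stop("thickness_nm must be positive")
    local({ h0 <- thickness_nm; function(s) rep(h0, length(s)) })
  }
  # midline polyline: straight, or two straight halves joined at bend_deg
  if (abs(bend_deg) < 1e-12) {
    mid <- rbind(origin_um, origin_um + c(length_um, 0))
  } else {
    a <- bend_deg * pi / 180
    p0 <- origin_um
    p1 <- origin_um + c(length_um / 2, 0)
    p2 <- p1 + length_um / 2 * c(cos(a), sin(a))
    mid <- rbind(p0, p1, p2)
  }
  seg <- diff(mid)
  seg_len <- sqrt(rowSums(seg^2))
  geom <- structure(list(
    midline_um = mid,
    seg_len_um = seg_len,
    mid_len_um = sum(seg_len),
    radius_um = radius_um,
    cap_radius_um = cap_radius_um,
    thickness_fun = hfun,
    s_max_um = sum(seg_len) + cap_radius_um * pi / 2,
    tip_um = mid[nrow(mid), ] + seg[nrow(seg), ] / seg_len[length(seg_len)] *
      cap_radius_um
  ), class = "phantom_geometry")
  # invariant: thickness positive everywhere on the contour
  ss <- seq(0, geom$s_max_um, length.out = 257)
  if (any(!is.finite(hfun(ss))) || any(hfun(ss) <= 0))
    stop("thickness profile must be positive everywhere")
  geom
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat("phantom hypha: R =", x$radius_um, "um, midline", x$mid_len_um,
      "um, cap", x$cap_radius_um, "um\n")
  cat("  thickness at tip:", x$thickness_fun(0), "nm; at s=2um:",
      x$thickness_fun(2), "nm\n")
  invisible(x)
}

# Signed geometry of query points relative to the phantom wall.
# Returns, per point: di_um (signed distance to the inner face, negative
# inside the cell), s_um (|arclength| of the normal foot from the tip apex),
# region (cap/side/back).
phantom_point_geometry <- function(geom, x_um, y_um) {
  mid <- geom$midline_um
  nseg <- nrow(mid) - 1
  n <- length(x_um)
  best_d2 <- rep(Inf, n)
  best_m <- numeric(n)    # arclength along midline of the foot point
  m0 <- 0
  for (j in seq_len(nseg)) {
    p <- mid[j, ]; q <- mid[j + 1, ]
    vx <- q[1] - p[1]; vy <- q[2] - p[2]
    L2 <- vx * vx + vy * vy
    tt <- ((x_um - p[1]) * vx + (y_um - p[2]) * vy) / L2
    tt <- pmin(1, pmax(0, tt))
    dx <- x_um - (p[1] + tt * vx); dy <- y_um - (p[2] + tt * vy)
    d2 <- dx * dx + dy * dy
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_m[upd] <- m0 + tt[upd] * sqrt(L2)
    m0 <- m0 + sqrt(L2)
  }
  dm <- sqrt(best_d2)
  M <- geom$mid_len_um
  R <- geom$radius_um; Rc <- geom$cap_radius_um
  eps <- 1e-9
  at_end <- best_m >= M - eps
  at_start <- best_m <= eps
  region <- ifelse(at_end, "cap", ifelse(at_start, "back", "side"))
  di <- dm - R
  s <- (M - best_m) + Rc * pi / 2
  # apical cap: distance from cap centre, arclength from apex along the cap
  if (any(at_end)) {
    C <- mid[nrow(mid), ]
    u <- (geom$tip_um - C) / Rc
    px <- x_um[at_end] - C[1]; py <- y_um[at_end] - C[2]
    r <- sqrt(px^2 + py^2)
    cosphi <- pmin(1, pmax(-1, (px * u[1] + py * u[2]) / pmax(r, 1e-12)))
    di[at_end] <- r - Rc
    s[at_end] <- Rc * acos(cosphi)
  }
  if (any(at_start)) {
    C <- mid[1, ]
    r <- sqrt((x_um[at_start] - C[1])^2 + (y_um[at_start] - C[2])^2)
    di[at_start] <- r - R
    s[at_start] <- geom$s_max_um  # thickness continued from the far side
  }
  list(di_um = di, s_um = pmin(s, geom$s_max_um), region = region)
}

#' Sample the ground-truth wall curves
#'
#' Returns the inner and outer wall faces of a phantom, sampled at arclength
#' steps `ds_um` from the tip apex (`s = 0`) to the back of the tube, on the
#' upper side of the midline. The outer point is the inner point displaced by
#' `h(s)` along the outward normal, which is the defining property of the
#' phantom and the reference for all thickness oracles.
#'
#' @param geom a `phantom_geometry`.
#' @param ds_um arclength sampling step (um).
#' @return data.frame with `s_um`, inner face `xi_um, yi_um`, outer face
#'   `xo_um, yo_um`, outward normal `nx, ny`, and `h_nm`.
#' @export
phantom_curves <- function(geom, ds_um = 0.02) {
  stopifnot(inherits(geom, "phantom_geometry"))
  s <- seq(0, geom$s_max_um, by = ds_um)
  mid <- geom$midline_um
  M <- geom$mid_len_um; R <- geom$radius_um; Rc <- geom$cap_radius_um
  cap_arc <- Rc * pi / 2
  C <- mid[nrow(mid), ]
  u <- (geom$tip_um - C) / Rc
  # upper-side normal convention (counter-clockwise rotation of the tangent)
  xi <- yi <- nx <- ny <- numeric(length(s))
  on_cap <- s <= cap_arc
  phi <- s[on_cap] / Rc
  # rotate the apex direction by +phi towards the upper side
  ux <- u[1] * cos(phi) - u[2] * sin(phi)
  uy <- u[1] * sin(phi) + u[2] * cos(phi)
  xi[on_cap] <- C[1] + Rc * ux; yi[on_cap] <- C[2] + Rc * uy
  nx[on_cap] <- ux; ny[on_cap] <- uy
  if (any(!on_cap)) {
    m <- M - (s[!on_cap] - cap_arc)   # arclength position along the midline
    cum <- c(0, cumsum(geom$seg_len_um))
    j <- pmin(findInterval(pmax(m, 0), cum, rightmost.closed = TRUE),
              nrow(mid) - 1)
    p <- mid[j, , drop = FALSE]; q <- mid[j + 1, , drop = FALSE]
    tl <- geom$seg_len_um[j]
    tt <- (pmax(m, 0) - cum[j]) / tl
    tx <- (q[, 1] - p[, 1]) / tl; ty <- (q[, 2] - p[, 2]) / tl
    # upper-side outward normal of a left-to-right midline is (-ty, tx)
    xi[!on_cap] <- p[, 1] + tt * (q[, 1] - p[, 1]) - ty * R
    yi[!on_cap] <- p[, 2] + tt * (q[, 2] - p[, 2]) + tx * R
    nx[!on_cap] <- -ty; ny[!on_cap] <- tx
  }
  h <- geom$thickness_fun(s)
  data.frame(s_um = s, xi_um = xi, yi_um = yi,
             xo_um = xi + nx * h * 1e-3, yo_um = yi + ny * h * 1e-3,
             nx = nx, ny = ny, h_nm = h)
}

#' Imaging model specification
#'
#' Parameters of the synthetic two-channel imaging model. Channel 1 images a
#' line source on the wall inner face plus a cytoplasmic background filling
#' the cell; channel 2 a line source on the outer face plus a medium
#' background outside the cell. Backgrounds are expressed as a fraction of
#' the unit peak radiance so that `photon_scale` scales every expected count
#' linearly. Channel 2 is translated by the chromatic shift before noise.
#'
#' @param pixel_size_nm pixel pitch (nm), > 0.
#' @param psf_sigma_nm Gaussian PSF sigma per channel (nm, length 2); 0 gives
#'   an ideal delta-PSF rendering.
#' @param chromatic_shift_nm 2-vector (x, y) shift applied to channel 2 (nm).
#' @param background_in cytoplasmic background of channel 1 (relative).
#' @param background_out medium background of channel 2 (relative).
#' @param photon_scale expected counts at the line-source peak.
#' @param read_noise_sd Gaussian read-noise sd (counts).
#' @param noise logical; FALSE renders the noise-free expectation image.
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @param margin_um raster margin around the phantom when the raster is sized
#'   automatically.
#' @return an `imaging_spec` object.
#' @export
imaging_spec <- function(pixel_size_nm = 65, psf_sigma_nm = c(200, 200),
                         chromatic_shift_nm = c(30, -20),
                         background_in = 0.5, background_out = 0.3,
                         photon_scale = 200, read_noise_sd = 3,
                         noise = TRUE, seed = 1L, margin_um = 0.8) {
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be positive")
  if (length(psf_sigma_nm) == 1) psf_sigma_nm <- rep(psf_sigma_nm, 2)
  if (any(psf_sigma_nm < 0)) stop("psf_sigma_nm must be >= 0")
  if (length(chromatic_shift_nm) != 2) stop("chromatic_shift_nm must have length 2")
  if (photon_scale <= 0) stop("photon_scale must be positive")
  structure(list(pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
                 chromatic_shift_nm = chromatic_shift_nm,
                 background_in = background_in, background_out = background_out,
                 photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 noise = isTRUE(noise), seed = as.integer(seed),
                 margin_um = margin_um),
            class = "imaging_spec")
}

# expected (noise-free) radiance of one channel over a pixel grid
.render_expectation <- function(geom, spec, xg_um, yg_um, channel) {
  px <- spec$pixel_size_nm
  sig <- spec$psf_sigma_nm[channel]
  shift <- if (channel == 2) spec$chromatic_shift_nm else c(0, 0)
  G <- expand.grid(x = xg_um, y = yg_um)
  # a feature translated by +shift is seen by sampling the field at p - shift
  pg <- phantom_point_geometry(geom, G$x - shift[1] * 1e-3,
                               G$y - shift[2] * 1e-3)
  di_nm <- pg$di_um * 1e3
  if (channel == 1) {
    dline <- di_nm
    bg <- spec$background_in
    step <- if (sig > 0) stats::pnorm(-di_nm / sig) else as.numeric(di_nm < 0)
  } else {
    h_nm <- geom$thickness_fun(pg$s_um)
    dline <- di_nm - h_nm
    bg <- spec$background_out
    step <- if (sig > 0) stats::pnorm(dline / sig) else as.numeric(dline > 0)
  }
  line <- if (sig > 0) exp(-dline^2 / (2 * sig^2)) else
    as.numeric(abs(dline) <= px / 2)
  rad <- spec$photon_scale * (line + bg * step)
  matrix(rad, nrow = length(yg_um), ncol = length(xg_um), byrow = TRUE)
}

#' Render a two-channel synthetic image of a phantom
#'
#' Channel 1 (membrane) is a Gaussian line source on the wall inner face plus
#' a convolved cytoplasmic background step; channel 2 (lectin) a line source
#' on the outer face plus a convolved medium background step, translated by
#' the chromatic shift. Line and step responses are evaluated analytically
#' from the signed distance to the wall faces (the exact PSF convolution for
#' a locally straight wall). Shot noise is Poisson on the expected counts and
#' read noise additive Gaussian; output is bit-identical for a fixed seed.
#'
#' @param geom a `phantom_geometry`.
#' @param spec an `imaging_spec`.
#' @param raster optional list(x0_um, y0_um, nx, ny) fixing the raster; by
#'   default the raster is sized to the phantom plus `spec$margin_um`.
#' @return a `synthetic_image`: list with `channels` (two count matrices,
#'   rows = y), `truth` (the geometry), `spec`, and the raster mapping.
#' @export
render_image <- function(geom, spec = imaging_spec(), raster = NULL) {
  stopifnot(inherits(geom, "phantom_geometry"), inherits(spec, "imaging_spec"))
  px_um <- spec$pixel_size_nm * 1e-3
  cv <- phantom_curves(geom, ds_um = 0.05)
  hmax_um <- max(cv$h_nm) * 1e-3
  R <- max(geom$radius_um, geom$cap_radius_um)
  # bounding box of the outer wall face (curves sample the upper side only;
  # the box is symmetric about the midline for the lower side and back cap)
  gx <- c(min(c(cv$xi_um, geom$midline_um[, 1])) - R,
          max(c(cv$xo_um, geom$tip_um[1] + hmax_um)))
  gy <- c(min(geom$midline_um[, 2]) - R - hmax_um,
          max(c(cv$yo_um, geom$midline_um[, 2] + R + hmax_um)))
  clear <- 3 * max(spec$psf_sigma_nm) * 1e-3 + px_um
  if (is.null(raster)) {
    pad <- max(spec$margin_um, clear)
    x0 <- gx[1] - pad
    y0 <- gy[1] - pad
    nx <- ceiling((gx[2] + pad - x0) / px_um)
    ny <- ceiling((gy[2] + pad - y0) / px_um)
  } else {
    x0 <- raster$x0_um; y0 <- raster$y0_um; nx <- raster$nx; ny <- raster$ny
    over <- c(left = x0 - (gx[1] - clear),
              right = (gx[2] + clear) - (x0 + (nx - 1) * px_um),
              bottom = y0 - (gy[1] - clear),
              top = (gy[2] + clear) - (y0 + (ny - 1) * px_um))
    if (any(over > 0))
      stop("phantom exceeds raster bounds by (um): ",
           paste(sprintf("%s %.2f", names(over)[over > 0], over[over > 0]),
                 collapse = ", "))
  }
  xg <- x0 + (seq_len(nx) - 1) * px_um
  yg <- y0 + (seq_len(ny) - 1) * px_um
  ch <- lapply(1:2, function(k) .render_expectation(geom, spec, xg, yg, k))
  if (spec$noise) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(spec$seed)
    ch <- lapply(ch, function(m) {
      n <- matrix(stats::rpois(length(m), lambda = m), nrow = nrow(m))
      n + matrix(stats::rnorm(length(m), 0, spec$read_noise_sd), nrow = nrow(m))
    })
  }
  structure(list(channels = ch, truth = geom, spec = spec,
                 x0_um = x0, y0_um = y0, pixel_um = px_um,
                 nx = nx, ny = ny),
            class = "synthetic_image")
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat("synthetic image:", x$ny, "x", x$nx, "px,", length(x$channels),
      "channels, pixel", x$spec$pixel_size_nm, "nm, seed", x$spec$seed, "\n")
  invisible(x)
}

#' Render a before/after deflation image pair
#'
#' The "after" geometry shrinks each axis so that the requested elastic
#' strain `(before - after) / after` is recovered exactly: deflated radius
#' `R0 = R1 / (1 + radial)`, length `L0 = L1 / (1 + longitudinal)`, and cap
#' radius `Rt0 = Rt1 / (1 + tip)` (tip defaults to the radial strain).
#' Both images share the raster and imaging spec; the after image uses
#' `seed + 1` so noise realizations are independent.
#'
#' @param geom inflated (`before`) phantom geometry.
#' @param strains list with `radial`, `longitudinal`, optional `tip` (each >= 0).
#' @param spec an `imaging_spec`.
#' @return list(before, after, geometry_before, geometry_after, true_strains).
#' @export
make_deflation_pair <- function(geom, strains, spec = imaging_spec()) {
  st <- list(radial = strains$radial, longitudinal = strains$longitudinal,
             tip = if (is.null(strains$tip)) strains$radial else strains$tip)
  for (nm in names(st)) {
    if (st[[nm]] <= -1) stop("strain ", nm, " must be > -1")
    if (st[[nm]] < 0) stop("deflation strains must be >= 0")
  }
  g0 <- make_phantom(radius_um = geom$radius_um / (1 + st$radial),
                     length_um = geom$mid_len_um / (1 + st$longitudinal),
                     thickness_nm = geom$thickness_fun,
                     cap_radius_um = geom$cap_radius_um / (1 + st$tip),
                     origin_um = geom$midline_um[1, ])
  img1 <- render_image(geom, spec)
  spec0 <- spec; spec0$seed <- spec$seed + 1L
  img0 <- render_image(g0, spec0,
                       raster = list(x0_um = img1$x0_um, y0_um = img1$y0_um,
                                     nx = img1$nx, ny = img1$ny))
  list(before = img1, after = img0,
       geometry_before = geom, geometry_after = g0, true_strains = st)
}

#' Construct a pair of time series with a known lag
#'
#' Series `b` is series `a` delayed by `lag` samples plus Gaussian noise;
#' used to validate the normalized cross-correlation. The shared signal is a
#' unit-variance AR(1) process, reproducible from `seed`.
#'
#' @param n series length; must exceed `3 * abs(lag)`.
#' @param lag integer delay of `b` relative to `a` (samples).
#' @param noise_sd sd of the independent noise added to `b`.
#' @param seed integer seed.
#' @return data.frame(t, a, b).
#' @export
make_trace_pair <- function(n, lag = 0L, noise_sd = 0, seed = 1L) {
  lag <- as.integer(lag)
  if (n <= 3 * abs(lag)) stop("need n > 3 * |lag|")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  off <- abs(lag)
  base <- as.numeric(stats::arima.sim(list(ar = 0.8), n = n + 2 * off))
  base <- (base - mean(base)) / stats::sd(base)
  a <- base[(off + 1):(off + n)]
  b <- base[(off + 1 - lag):(off + n - lag)] + stats::rnorm(n, 0, noise_sd)
  data.frame(t = seq_len(n), a = a, b = b)
}
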