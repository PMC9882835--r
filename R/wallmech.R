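#' Elastic strains from a deflation pair
#'
#' Per-axis elastic strain `(before - after) / after` of a pressurized cell
#' relaxing upon depressurization (laser ablation or hyperosmotic shock):
#' radial from the lateral radius, longitudinal from the length, tip from the
#' tip radius of curvature. Inputs are geometry snapshots as produced by
#' [contour_geometry()] or plain lists with `R_um`, `L_um`, `Rt_um`.
#'
#' @param before,after geometry snapshots (inflated, deflated).
#' @return list(radial, longitudinal, tip) with NA for absent axes.
#' @export
elastic_strain <- function(before, after) {
  one <- function(b, a) {
    if (is.null(b) || is.null(a) || !is.finite(b) || !is.finite(a))
      return(NA_real_)
    if (a <= 0) stop("deflated dimension must be positive")
    (b - a) / a
  }
  list(radial = one(before$R_um, after$R_um),
       longitudinal = one(before$L_um, after$L_um),
       tip = one(before$Rt_um, after$Rt_um))
}

#' Wall modulus-to-pressure ratio on the cell side
#'
#' Thin-shell force balance of the cylindrical part of a pressurized tube:
#' `Y/P = R1 / (h_side * radial_strain)`, dimensionless for consistent units
#' (radius in um, thickness in nm, the factor 1000 converts).
#'
#' @param R1_um lateral radius before deflation (um).
#' @param h_side_nm wall thickness on the side (nm).
#' @param radial_strain elastic strain of the radius.
#' @param P_MPa optional turgor pressure, to also report Y in MPa.
#' @return list(Y_over_P, Y_MPa or NA).
#' @export
modulus_ratio_side <- function(R1_um, h_side_nm, radial_strain, P_MPa = NULL) {
  if (R1_um <= 0 || h_side_nm <= 0) stop("radius and thickness must be positive")
  if (radial_strain == 0) stop("zero strain: modulus undefined")
  yp <- 1000 * R1_um / (h_side_nm * radial_strain)
  list(Y_over_P = yp, Y_MPa = if (is.null(P_MPa)) NA_real_ else yp * P_MPa)
}

#' Wall modulus-to-pressure ratio at the tip
#'
#' Force balance of the hemispherical cap: `Y/P = Rt1 / (2 * h_tip *
#' tip_strain)` - exactly half the cylindrical value for identical inputs.
#'
#' @param Rt1_um tip radius of curvature before deflation (um).
#' @param h_tip_nm tip wall thickness (nm).
#' @param tip_strain elastic strain of the tip radius.
#' @param P_MPa optional turgor pressure.
#' @return list(Y_over_P, Y_MPa or NA).
#' @export
modulus_ratio_tip <- function(Rt1_um, h_tip_nm, tip_strain, P_MPa = NULL) {
  if (Rt1_um <= 0 || h_tip_nm <= 0) stop("radius and thickness must be positive")
  if (tip_strain == 0) stop("zero strain: modulus undefined")
  yp <- 1000 * Rt1_um / (2 * h_tip_nm * tip_strain)
  list(Y_over_P = yp, Y_MPa = if (is.null(P_MPa)) NA_real_ else yp * P_MPa)
}

#' Wall surface modulus
#'
#' Apparent areal stiffness `sigma = h * Y`; with h in nm and Y in MPa the
#' product `1 nm x 1 MPa = 1e-3 N/m`.
#'
#' @param h_nm wall thickness (nm).
#' @param Y_MPa Young's modulus (MPa).
#' @return surface modulus in N/m.
#' @export
surface_modulus <- function(h_nm, Y_MPa) h_nm * Y_MPa * 1e-3

#' Radial-to-longitudinal strain anisotropy ratio
#'
#' For an isotropic thin-walled tube the hoop stress is twice the axial
#' stress, so the radial elastic strain is exactly twice the longitudinal
#' one; a ratio near 2 therefore indicates no major wall anisotropy.
#'
#' @param radial_strain,longitudinal_strain elastic strains.
#' @return the ratio radial / longitudinal.
#' @export
anisotropy_ratio <- function(radial_strain, longitudinal_strain) {
  if (longitudinal_strain <= 0) stop("longitudinal strain must be positive")
  radial_strain / longitudinal_strain
}

#' Iso-ablation external molarity
#'
#' Interpolates the osmotic strain series at the ablation strain: the
#' external molarity at which an osmotic shock shrinks the cell as much as
#' full depressurization, i.e. the molarity balancing turgor. Piecewise
#' linear, no extrapolation.
#'
#' @param molarity_M external osmolyte molarities (M), increasing.
#' @param strain lateral elastic strains measured at each molarity,
#'   non-decreasing in molarity.
#' @param ablation_strain lateral elastic strain upon ablation.
#' @return interpolated molarity (M).
#' @export
iso_ablation_molarity <- function(molarity_M, strain, ablation_strain) {
  o <- order(molarity_M)
  m <- molarity_M[o]; st <- strain[o]
  if (any(diff(st) < -1e-9))
    stop("strain series must be non-decreasing in molarity")
  if (ablation_strain < min(st) || ablation_strain > max(st))
    stop("ablation strain outside the measured series; no extrapolation")
  stats::approx(st, m, xout = ablation_strain, ties = "ordered")$y
}

#' van 't Hoff osmotic pressure of a solute concentration
#'
#' @param molarity_M concentration (mol/L).
#' @param temperature_K temperature (K).
#' @return pressure in MPa (`c * R * T`).
#' @export
vant_hoff_pressure <- function(molarity_M, temperature_K = 298) {
  molarity_M * 1000 * 8.314 * temperature_K / 1e6
}

#' Turgor pressure from the osmotic chain
#'
#' Boyle-van 't Hoff chain: the internal osmolyte concentration at zero
#' turgor is `c0bar = c0tilde + c_media` (iso-ablation molarity plus medium
#' molarity); the effective concentration in the turgid state follows from
#' the ablation volume ratio `V0/V1` and the osmotically inaccessible volume
#' fraction `beta`, `c1bar = c0bar * (V0/V1 - beta) / (1 - beta)`; turgor is
#' `P = (c1bar - c_media) * R * T`.
#'
#' @param c0_tilde_M iso-ablation sorbitol molarity (M).
#' @param c_media_M medium molarity (M).
#' @param volume_ratio V0/V1, deflated over turgid volume, in (0, 1].
#' @param beta_osm inaccessible volume fraction, in [0, 1).
#' @param temperature_K temperature (K).
#' @return a `turgor_estimate`: list(c0_tilde_M, c_media_M, c0_bar_M,
#'   c1_bar_M, volume_ratio, beta_osm, temperature_K, P_MPa).
#' @export
turgor_from_osmotics <- function(c0_tilde_M, c_media_M, volume_ratio,
                                 beta_osm = 0.22, temperature_K = 298) {
  if (beta_osm < 0 || beta_osm >= 1) stop("beta_osm must be in [0, 1)")
  if (volume_ratio <= 0 || volume_ratio > 1)
    stop("volume_ratio must be in (0, 1]")
  if (volume_ratio <= beta_osm)
    stop("volume_ratio <= beta_osm: non-physical negative concentration")
  c0bar <- c0_tilde_M + c_media_M
  c1bar <- c0bar * (volume_ratio - beta_osm) / (1 - beta_osm)
  P <- vant_hoff_pressure(c1bar - c_media_M, temperature_K)
  if (P < 0) {
    warning("negative turgor clipped to zero")
    P <- 0
  }
  structure(list(c0_tilde_M = c0_tilde_M, c_media_M = c_media_M,
                 c0_bar_M = c0bar, c1_bar_M = c1bar,
                 volume_ratio = volume_ratio, beta_osm = beta_osm,
                 temperature_K = temperature_K, P_MPa = P),
            class = "turgor_estimate")
}

#' @export
print.turgor_estimate <- function(x, ...) {
  cat(sprintf("turgor estimate: c0bar %.3f M, c1bar %.3f M (beta %.2f, V0/V1 %.2f) -> P = %.2f MPa\n",
              x$c0_bar_M, x$c1_bar_M, x$beta_osm, x$volume_ratio, x$P_MPa))
  invisible(x)
}
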