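#!/usr/bin/env Rscript
# Wall elasticity and turgor from deflation and osmotic measurements.
#
# A phantom is deflated by known elastic strains, the strains are recovered
# by the imaging pipeline, and the thin-shell balances convert them into
# Young's modulus and surface modulus. The osmotic chain then gives turgor.

library(hyphoshell)

dir.create("results", showWarnings = FALSE)

message("Deflation assay on a rendered phantom pair...")
h_side <- 80; h_tip <- 70
pair <- make_deflation_pair(make_phantom(1.25, 4, h_side),
                            list(radial = 0.10, longitudinal = 0.05),
                            imaging_spec(seed = 17))
g1 <- contour_geometry(segment_contour(pair$before))
g0 <- contour_geometry(segment_contour(pair$after))
st <- elastic_strain(g1, g0)
message(sprintf("strains: radial %.3f, longitudinal %.3f (truth 0.100/0.050)",
                st$radial, st$longitudinal))
message(sprintf("anisotropy ratio %.2f - close to the isotropic value 2",
                anisotropy_ratio(st$radial, st$longitudinal)))

message("\nTurgor from the osmotic chain...")
# a synthetic osmotic-shock series bracketing the ablation strain
series <- data.frame(molarity_M = c(0.4, 0.6, 0.8, 1.0, 1.2),
                     strain = c(0.040, 0.062, 0.080, 0.098, 0.115))
c0t <- iso_ablation_molarity(series$molarity_M, series$strain,
                             ablation_strain = 0.081)
est <- turgor_from_osmotics(c0_tilde_M = c0t, c_media_M = 0.112,
                            volume_ratio = 0.70, beta_osm = 0.22)
print(est)
est_b0 <- turgor_from_osmotics(c0t, 0.112, 0.70, beta_osm = 0)
message(sprintf("with beta = 0 the estimate rises to %.2f MPa", est_b0$P_MPa))

message("\nModuli from the recovered strains at P = 1.1 MPa...")
side <- modulus_ratio_side(g1$R_um, h_side, st$radial, P_MPa = est$P_MPa)
tip <- modulus_ratio_tip(g1$Rt_um, h_tip, st$radial, P_MPa = est$P_MPa)
rep <- list(strains = st,
            turgor = unclass(est), turgor_beta0_MPa = est_b0$P_MPa,
            Y_side_MPa = side$Y_MPa, Y_tip_MPa = tip$Y_MPa,
            sigma_side_N_m = surface_modulus(h_side, side$Y_MPa),
            sigma_tip_N_m = surface_modulus(h_tip, tip$Y_MPa))
jsonlite::write_json(rep, "results/mechanics.json", auto_unbox = TRUE,
                     digits = NA)
message(sprintf("Y side %.0f MPa (sigma %.1f N/m), Y tip %.0f MPa (sigma %.1f N/m)",
                rep$Y_side_MPa, rep$sigma_side_N_m, rep$Y_tip_MPa,
                rep$sigma_tip_N_m))
message("-> results/mechanics.json")
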