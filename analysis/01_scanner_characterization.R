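#!/usr/bin/env Rscript

# Scanner timing/geometry and tracer harmonic response.
#
# Establishes the basic numbers every later step relies on: the Lissajous
# repetition period (21.54 ms -> 46 whole 3D frames/s) and the drive FOV
# (19.2 x 19.2 x 9.6 mm), then contrasts the harmonic spectra of the two
# tracer models. The multicore 32 nm tracer holds its high harmonics far
# better than the bimodal 4/16 nm model — the mechanism behind its better
# image quality at equal dose.

library(mpiangio)

dir.create("results", showWarnings = FALSE)

cfg <- scanner_config()
print(cfg)

scanner_tab <- data.frame(
  quantity = c("lissajous_period_ms", "frame_rate_per_s",
               "fov_x_mm", "fov_y_mm", "fov_z_mm",
               "voxel_dx_mm", "voxel_dy_mm", "voxel_dz_mm"),
  value = c(lissajous_period(cfg) * 1e3, frame_rate(cfg),
            fov_extent(cfg), recon_grid_geometry(cfg)$spacing)
)
write.csv(scanner_tab, "results/scanner_characteristics.csv",
          row.names = FALSE)

hs_m <- harmonic_spectrum(tracer_mcp3(), cfg)
hs_r <- harmonic_spectrum(tracer_resovist(), cfg)
spectra <- rbind(cbind(tracer = "MCP3", hs_m),
                 cbind(tracer = "Resovist", hs_r))
write.csv(spectra, "results/harmonic_spectra.csv", row.names = FALSE)

odd <- function(h) h$harmonic %% 2 == 1
cat(sprintf(
  "harmonic 9/3 amplitude ratio: MCP3 %.3f vs Resovist %.4f (%.0fx)\n",
  hs_m$amplitude[9] / hs_m$amplitude[3],
  hs_r$amplitude[9] / hs_r$amplitude[3],
  (hs_m$amplitude[9] / hs_m$amplitude[3]) /
    (hs_r$amplitude[9] / hs_r$amplitude[3])))
cat("wrote results/scanner_characteristics.csv, results/harmonic_spectra.csv\n")
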