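# Shared fixtures, built lazily and cached for the whole test run.
# The mid-size system matrix (15x15x7, full mixing band) takes ~15 s to
# simulate and is reused by the reconstruction-in-the-loop tests.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# small grid for solver unit tests: 5x5x3 voxels, sub-fundamental band
fx_scanner_small <- function() fixture("sc_small", function() {
  scanner_config(recon_grid = c(5L, 5L, 3L), recon_volume = c(10, 10, 6),
                 samples_per_frame = 512L)
})

fx_sm_small <- function() fixture("sm_small", function() {
  sc <- fx_scanner_small()
  simulate_system_matrix(sc, tracer_mcp3(), recon_grid_geometry(sc),
                         max_frequency_index = 60L)
})

# well-conditioned wide-pitch grid (3.2 / 2.7 mm voxels): columns are
# nearly orthogonal, so consistent systems are solved essentially exactly
fx_sm_wide <- function() fixture("sm_wide", function() {
  sc <- scanner_config(recon_grid = c(5L, 5L, 3L), recon_volume = c(16, 16, 8),
                       samples_per_frame = 512L)
  simulate_system_matrix(sc, tracer_mcp3(), recon_grid_geometry(sc),
                         max_frequency_index = 60L)
})

# mid grid with the full mixing band up to Nyquist (4096 samples)
fx_scanner_mid <- function() fixture("sc_mid", function() {
  scanner_config(recon_grid = c(15L, 15L, 7L),
                 recon_volume = c(13.2, 13.2, 6.6),
                 samples_per_frame = 4096L)
})

fx_sm_mid <- function() fixture("sm_mid", function() {
  sc <- fx_scanner_mid()
  simulate_system_matrix(sc, tracer_mcp3(), recon_grid_geometry(sc))
})

# odd 0.8 mm grid whose voxel centers include the origin, for the
# segmentation / diameter tests
fx_scanner_08 <- function() fixture("sc_08", function() {
  scanner_config(recon_grid = c(25L, 25L, 11L),
                 recon_volume = c(20, 20, 8.8),
                 samples_per_frame = 512L)
})

# fast pipeline configuration for plumbing tests
fx_fast_config <- function() fixture("fast_cfg", function() {
  validate_config(overrides = list(
    scanner = list(recon_grid = c(9L, 9L, 5L),
                   recon_volume_mm = c(10.56, 10.56, 4.8),
                   samples_per_frame = 2048L),
    signal = list(duration_s = 14, frame_stride = 8L,
                  max_components = 150L),
    recon = list(sweeps = 5L)
  ))
})

# 26-neighborhood binary dilation of a 3D mask, used to build vessel
# envelopes (lumen support plus one voxel of partial-volume shell)
dilate_mask_3d <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    out <- out | mask[xs, ys, zs]
  }
  out
}

rel_err <- function(a, b) sqrt(sum((a - b)^2) / max(sum(b^2), 1e-300))
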