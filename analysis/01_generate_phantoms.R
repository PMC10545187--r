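#!/usr/bin/env Rscript
# Generate the three study phantoms (healthy flat, healthy curved, NMDA-like
# thinned) and record their design parameters and exact ground truth.
# Volumes are written to scratch/ (regenerable binary data); the design table
# and truth summaries go to results/.

suppressPackageStartupMessages(library(octlayer))

dir.create("results", showWarnings = FALSE)
dir.create("scratch/phantoms", recursive = TRUE, showWarnings = FALSE)

thin_layers <- default_retina_layers()
thin_layers$thickness_um[1:3] <- thin_layers$thickness_um[1:3] / 1.8

specs <- list(
  healthy_flat   = phantom_spec(seed = 11L),
  healthy_curved = phantom_spec(curvature_um = 50, seed = 12L),
  nmda_like      = phantom_spec(layers = thin_layers, seed = 13L)
)

rows <- lapply(names(specs), function(id) {
  spec <- specs[[id]]
  ph <- generate_phantom(spec)
  out <- file.path("scratch/phantoms", id)
  write_oct_volume(ph$volume, out)
  write_ground_truth(ph$truth, out)
  cat(sprintf("%-15s design URCL %6.2f um, %d x %d x %d voxels -> %s\n",
              id, ph$truth$urcl_design_um,
              dim(ph$volume$intensity)[1], dim(ph$volume$intensity)[2],
              dim(ph$volume$intensity)[3], out))
  data.frame(phantom = id,
             urcl_design_um = ph$truth$urcl_design_um,
             n_medium = spec$n_medium,
             curvature_um = spec$curvature_um,
             speckle_contrast = spec$speckle_contrast,
             n_z = spec$shape[1], n_x = spec$shape[2], n_y = spec$shape[3],
             seed = spec$seed)
})

designs <- do.call(rbind, rows)
write.csv(designs, "results/phantom_designs.csv", row.names = FALSE)
cat("wrote results/phantom_designs.csv\n")
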