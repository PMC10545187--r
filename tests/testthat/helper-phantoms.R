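# Small phantom builders shared across the test files. The four-layer stack
# keeps the URCL design at 120 um (NFL + GCL + IPL) while dropping the outer
# layers so test volumes stay small.

test_layers <- function() {
  data.frame(
    name = c("NFL", "GCL", "IPL", "INL"),
    thickness_um = c(15, 25, 80, 30),
    reflectivity = c(0.50, 0.25, 0.15, 0.45),
    stringsAsFactors = FALSE
  )
}

small_spec <- function(...) {
  args <- utils::modifyList(
    list(layers = test_layers(), shape = c(300L, 60L, 12L),
         spacing = c(z = 1, x = 5, y = 4), speckle_contrast = 0, seed = 42L),
    list(...)
  )
  do.call(phantom_spec, args)
}

# One thick homogeneous slab: convenient for moment and noise checks.
slab_spec <- function(...) {
  args <- utils::modifyList(
    list(layers = data.frame(name = "slab", thickness_um = 120,
                             reflectivity = 0.5, stringsAsFactors = FALSE),
         i2_after_layer = "slab", shape = c(280L, 30L, 25L),
         spacing = c(z = 1, x = 5, y = 4), speckle_contrast = 0.5,
         seed = 42L),
    list(...)
  )
  do.call(phantom_spec, args)
}

# 0-based row range (as 1-based R indices) lying strictly inside the slab
# layer of a slab_spec() phantom, with a safety margin of `pad` voxels.
slab_rows <- function(spec, pad = 3L) {
  z1 <- spec$n_medium * spec$top_depth_um
  z2 <- spec$n_medium * (spec$top_depth_um + sum(spec$layers$thickness_um))
  (ceiling(z1 / spec$spacing[["z"]]) + 1L + pad):
    (floor(z2 / spec$spacing[["z"]]) - pad)
}
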