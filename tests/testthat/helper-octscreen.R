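# Small phantom geometries shared across tests: full production scans are
# 500 x 500 lateral positions, but the generators are resolution-agnostic,
# so most tests run on reduced grids for speed.

small_clean_spec <- function(...) {
  args <- utils::modifyList(
    list(n_alines = 96L, n_bscans = 20L, axial_px = 160L,
         image_size_px = c(240L, 240L),
         speckle_sd = 0, specular_column_rate = 0, reflectance_drift = 0),
    list(...))
  do.call(phantom_spec, args)
}

small_noisy_spec <- function(...) {
  args <- utils::modifyList(
    list(n_alines = 96L, n_bscans = 20L, axial_px = 160L,
         image_size_px = c(240L, 240L)),
    list(...))
  do.call(phantom_spec, args)
}

# thickness map built directly from a matrix of um values
tm_from_matrix <- function(m, dx_um = 12, dy_um = 12) {
  octscreen:::new_thickness_map(m, dx_um = dx_um, dy_um = dy_um)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
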