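# Small phantom used by the unit tests: same anatomy as the default spec,
# scaled down so per-test segmentation stays fast.
small_phantom_spec <- function(s_xy = 1, s_z = 1, noise_sd = 10, seed = 1L,
                               ...) {
  phantom_spec(n_slices = 48L, n_rows = 96L, n_cols = 96L,
               spacing = c(3, 1, 1),
               body_semi_axes = c(42, 45),
               lung_semi_axes = c(60, 26, 15),
               lung_center_x = 22,
               bifurcation_slice = 24L,
               trachea_radius = 5,
               bronchus_radius = 2.5,
               bronchus_offset = 3.5,
               bronchus_length_slices = 6L,
               s_xy = s_xy, s_z = s_z, noise_sd = noise_sd, seed = seed,
               ...)
}

# Body-plus-airway-only volume (no lungs): an elliptic soft-tissue torso with
# one or two straight air tubes, for airway-tracking edge cases.
make_tube_volume <- function(n_slices = 30L, n = 80L, radius = 5,
                             offsets = 0, body_hu = 0, phase = "inspiration") {
  y <- matrix((seq_len(n) - (n + 1) / 2), n, n)
  x <- matrix((seq_len(n) - (n + 1) / 2), n, n, byrow = TRUE)
  body <- (y / (n / 2 - 4))^2 + (x / (n / 2 - 3))^2 <= 1
  sl <- matrix(-1000, n, n)
  sl[body] <- body_hu
  for (off in offsets) sl[y^2 + (x - off)^2 <= radius^2] <- -1000
  vox <- array(0, c(n_slices, n, n))
  for (s in seq_len(n_slices)) vox[s, , ] <- sl
  ct_volume(vox, c(3, 1, 1), phase)
}

# Stack two [slice, row, col] arrays along the slice axis.
abind_slices <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# One tiny uniform-tissue slice.
tissue_slice <- function(n = 64, hu = 0) matrix(hu, n, n)
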