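# Fixtures built in code at test time.

# Compact C-bundle phantom (44^3 grid) for tests that only need geometry,
# not the full default resolution.
small_phantom <- function(fa_anterior = 0.47, fa_rest = 0.47,
                          noiseless = TRUE, snr_b0 = 20, seed = 1L,
                          bundle_radius = 2, n_directions = 24) {
  sp <- phantom_spec(
    grid_shape = c(44, 44, 44), arc_radius = 28,
    bundle_radius = bundle_radius,
    fa_inside = c(anterior = fa_anterior, dorsal = fa_rest,
                  posterior = fa_rest, ventral = fa_rest),
    noiseless = noiseless, snr_b0 = snr_b0, seed = seed
  )
  make_bundle_phantom(sp, make_gradient_scheme(n_directions, 800))
}

# Hand-built scalar_maps object: uniform +x eigenvector field with an
# fa_value slab/tube where `mask_fa` is TRUE (everything else fa = 0).
synthetic_maps <- function(dim, voxel_size = 2, fa_array, e1_array = NULL) {
  if (is.null(e1_array)) {
    e1_array <- array(0, dim = c(dim, 3))
    e1_array[, , , 1] <- 1
  }
  structure(
    list(fa = fa_array, md = fa_array * 0 + 0.8, ad = fa_array * 0 + 1,
         rd = fa_array * 0 + 0.7, e1 = e1_array,
         mask = array(TRUE, dim), negative_eigenvalue = array(FALSE, dim),
         dim = dim, voxel_size = voxel_size),
    class = "scalar_maps"
  )
}

# Minimal bundle from a list of point matrices (mm).
manual_bundle <- function(streamlines, voxel_size = 2, dim = c(64, 64, 64)) {
  structure(
    list(streamlines = streamlines,
         seed_vox = matrix(1L, length(streamlines), 3),
         step = 1, voxel_size = voxel_size, dim = dim),
    class = "tract_bundle"
  )
}

# Simulate noiseless DWI signals for a single tensor (6-vector) under a
# scheme; returns the per-volume signal vector.
signals_for_tensor <- function(tensor6, scheme, S0 = 100) {
  b <- scheme_bvals(scheme)
  g <- scheme_bvecs(scheme)
  A <- tensor_to_matrix(tensor6)
  q <- rowSums((g %*% A) * g)
  S0 * exp(-b * q / 1000)
}

# Wrap per-voxel tensors (rows of `tensors6`) into a dwi_study with
# noiseless signals, voxels laid out along the first axis.
study_from_tensors <- function(tensors6, scheme, S0 = 100) {
  n <- nrow(tensors6)
  nvol <- length(scheme_bvals(scheme))
  dat <- array(0, dim = c(n, 1, 1, nvol))
  for (i in seq_len(n)) {
    dat[i, 1, 1, ] <- signals_for_tensor(tensors6[i, ], scheme, S0)
  }
  structure(list(data = dat, scheme = scheme, voxel_size = 2, S0 = S0),
            class = "dwi_study")
}
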