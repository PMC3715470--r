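# Internal helpers shared across modules.

# Derive a reproducible 32-bit substream seed from a master seed and an index.
# Distinct (master, index) pairs map to distinct seeds with overwhelming
# probability; values stay below 2^31 - 1.
substream_seed <- function(master, index) {
  s <- (as.double(master) %% 2147483647) * 48271 + as.double(index) * 69621 + 12345
  as.integer(s %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# mm coordinates of voxel centers under the package's RAS+ convention:
# 0-based voxel index (i,j,k) maps to (i,j,k) * voxel_size mm.
voxel_to_mm <- function(idx1, voxel_size) (idx1 - 1) * voxel_size

# Nearest 1-based voxel index for mm points (n x 3 matrix). Half-way points
# (exactly on a voxel face) round up, so boundary assignment is consistent
# along a track rather than alternating as round-half-to-even would.
mm_to_voxel <- function(pts, voxel_size) floor(pts / voxel_size + 0.5) + 1

# Linear (1-based) array index from an n x 3 index matrix; NA outside `dim`.
linear_index <- function(vox, dim) {
  ok <- vox[, 1] >= 1 & vox[, 1] <= dim[1] &
    vox[, 2] >= 1 & vox[, 2] <= dim[2] &
    vox[, 3] >= 1 & vox[, 3] <= dim[3]
  out <- rep(NA_integer_, nrow(vox))
  out[ok] <- vox[ok, 1] + (vox[ok, 2] - 1L) * dim[1] +
    (vox[ok, 3] - 1L) * dim[1] * dim[2]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
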