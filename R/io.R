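# File I/O: NIfTI volumes (via RNifti), FSL-style bvec/bval text,
# TrackVis .trk streamline bundles, JSON landmarks/ROIs, cohort CSV.

# RAS+ affine of the package's grid convention: voxel (0,0,0) center at the
# origin, axes scaled by the voxel size.
grid_affine <- function(voxel_size) {
  diag(c(rep(voxel_size, 3), 1))
}

#' Write / read a DWI study as NIfTI + bvec/bval
#'
#' The 4-D volume goes to `<prefix>.nii.gz` with an RAS+ diagonal affine;
#' the gradient scheme to FSL-style `<prefix>.bvec` (3 rows) and
#' `<prefix>.bval` (1 row), b0 volumes first.
#'
#' @param study a `dwi_study`.
#' @param prefix output path prefix.
#' @return `write_dwi`: the prefix, invisibly. `read_dwi`: a `dwi_study`.
#' @export
write_dwi <- function(study, prefix) {
  stopifnot(inherits(study, "dwi_study"))
  img <- RNifti::asNifti(study$data)
  RNifti::pixdim(img) <- c(rep(study$voxel_size, 3), 1)
  aff <- structure(grid_affine(study$voxel_size), code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  bvec <- t(scheme_bvecs(study$scheme))
  writeLines(apply(format(bvec, digits = 10, trim = TRUE), 1, paste,
                   collapse = " "), paste0(prefix, ".bvec"))
  writeLines(paste(format(scheme_bvals(study$scheme), trim = TRUE),
                   collapse = " "), paste0(prefix, ".bval"))
  invisible(prefix)
}

#' @rdname write_dwi
#' @export
read_dwi <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  vs <- abs(RNifti::xform(img)[1, 1])
  bval <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bvec <- matrix(scan(paste0(prefix, ".bvec"), quiet = TRUE),
                 nrow = 3, byrow = TRUE)
  is_b0 <- bval == 0
  dirs <- t(bvec[, !is_b0, drop = FALSE])
  scheme <- structure(
    list(directions = dirs, bvalues = bval[!is_b0], n_b0 = sum(is_b0)),
    class = "gradient_scheme"
  )
  data <- array(as.numeric(img), dim = dim(img))
  # reorder so that b0 volumes come first (the package convention)
  ord <- order(!is_b0)
  if (is.unsorted(ord)) data <- data[, , , ord, drop = FALSE]
  structure(list(data = data, scheme = scheme, voxel_size = vs,
                 S0 = NA_real_),
            class = "dwi_study")
}

#' Write / read scalar maps as NIfTI volumes
#'
#' One file per map (`fa.nii.gz`, `md.nii.gz`, `ad.nii.gz`, `rd.nii.gz`,
#' `e1.nii.gz`) inside `dir`.
#' @param maps a `scalar_maps` object.
#' @param dir output directory (created if needed).
#' @return `write_scalar_maps`: `dir` invisibly; `read_scalar_maps`: a
#'   `scalar_maps` object (mask = finite FA voxels).
#' @export
write_scalar_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aff <- structure(grid_affine(maps$voxel_size), code = 2L)
  wr <- function(arr, name) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(rep(maps$voxel_size, 3),
                             rep(1, length(dim(arr)) - 3))
    RNifti::sform(img) <- aff
    RNifti::qform(img) <- aff
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  for (nm in c("fa", "md", "ad", "rd")) wr(maps[[nm]], nm)
  wr(maps$e1, "e1")
  invisible(dir)
}

#' @rdname write_scalar_maps
#' @export
read_scalar_maps <- function(dir) {
  rd <- function(name) {
    img <- RNifti::readNifti(file.path(dir, paste0(name, ".nii.gz")))
    array(as.numeric(img), dim = dim(img))
  }
  fa <- rd("fa")
  img <- RNifti::readNifti(file.path(dir, "fa.nii.gz"))
  vs <- abs(RNifti::xform(img)[1, 1])
  structure(
    list(fa = fa, md = rd("md"), ad = rd("ad"), rd = rd("rd"), e1 = rd("e1"),
         mask = is.finite(fa), negative_eigenvalue = array(FALSE, dim(fa)),
         dim = dim(fa), voxel_size = vs),
    class = "scalar_maps"
  )
}

#' Write / read a TrackVis .trk streamline file
#'
#' Minimal TrackVis format (version 2, little-endian, 1000-byte header, no
#' per-point scalars or per-track properties). Points are stored in the
#' format's voxel-mm convention, which coincides with this package's mm
#' coordinates under its diagonal RAS+ affine; `voxel_order` is set to RAS.
#' Coordinates survive a round trip to float32 precision.
#'
#' @param bundle a `tract_bundle`.
#' @param path output `.trk` file.
#' @return `write_trk`: `path` invisibly; `read_trk`: a `tract_bundle`.
#' @export
write_trk <- function(bundle, path) {
  stopifnot(inherits(bundle, "tract_bundle"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), raw(1)), con)                # id_string
  writeBin(as.integer(bundle$dim), con, size = 2, endian = "little")
  writeBin(rep(bundle$voxel_size, 3), con, size = 4, endian = "little")
  writeBin(rep(0, 3), con, size = 4, endian = "little")       # origin
  writeBin(0L, con, size = 2, endian = "little")              # n_scalars
  writeBin(raw(200), con)                                     # scalar names
  writeBin(0L, con, size = 2, endian = "little")              # n_properties
  writeBin(raw(200), con)                                     # property names
  aff <- grid_affine(bundle$voxel_size)
  writeBin(as.numeric(t(aff)), con, size = 4, endian = "little") # vox_to_ras
  writeBin(raw(444), con)                                     # reserved
  writeBin(c(charToRaw("RAS"), raw(1)), con)                  # voxel_order
  writeBin(c(charToRaw("RAS"), raw(1)), con)                  # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4, endian = "little")
  writeBin(raw(2), con)                                       # pad1
  writeBin(raw(6), con)                                       # invert/swap
  writeBin(length(bundle$streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")              # version
  writeBin(1000L, con, size = 4, endian = "little")           # hdr_size
  for (p in bundle$streamlines) {
    writeBin(nrow(p), con, size = 4, endian = "little")
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_trk
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, raw(), 6)
  if (!identical(id[1:5], charToRaw("TRACK"))) stop("not a TrackVis .trk file")
  dm <- readBin(con, integer(), 3, size = 2, endian = "little")
  vs <- readBin(con, numeric(), 3, size = 4, endian = "little")
  seek(con, 988)
  n_count <- readBin(con, integer(), 1, size = 4, endian = "little")
  version <- readBin(con, integer(), 1, size = 4, endian = "little")
  hdr <- readBin(con, integer(), 1, size = 4, endian = "little")
  if (hdr != 1000) stop("unsupported .trk header size: ", hdr)
  streamlines <- list()
  repeat {
    np <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (length(np) == 0) break
    xyz <- readBin(con, numeric(), 3 * np, size = 4, endian = "little")
    streamlines[[length(streamlines) + 1]] <- matrix(xyz, ncol = 3, byrow = TRUE)
  }
  if (n_count > 0 && length(streamlines) != n_count) {
    warning("n_count header field disagrees with the number of tracks read")
  }
  structure(
    list(streamlines = streamlines,
         seed_vox = matrix(NA_integer_, length(streamlines), 3),
         step = NA_real_, voxel_size = vs[1], dim = dm),
    class = "tract_bundle"
  )
}

#' Landmarks and ROIs as JSON
#'
#' Landmarks are stored as a list of five 1-based voxel index triples plus
#' the voxel size; ROIs as a list of `{kind, label, voxels}` entries.
#'
#' @param landmarks_vox 5 x 3 matrix of 1-based voxel indices.
#' @param voxel_size voxel edge in mm.
#' @param path JSON file path.
#' @return readers return the stored objects; writers the path, invisibly.
#' @export
write_landmarks <- function(landmarks_vox, voxel_size, path) {
  jsonlite::write_json(
    list(voxel_size = voxel_size,
         landmarks = lapply(seq_len(nrow(landmarks_vox)),
                            function(i) as.integer(landmarks_vox[i, ]))),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  lm <- do.call(rbind, lapply(j$landmarks, unlist))
  j$voxel_size <- j$voxel_size[[1]]
  list(landmarks_vox = lm, voxel_size = j$voxel_size,
       landmarks_mm = voxel_to_mm(lm, j$voxel_size))
}

#' @rdname write_landmarks
#' @param rois list of [roi_spec()] objects.
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(
    lapply(rois, function(r) {
      list(kind = r$kind, label = r$label,
           voxels = lapply(seq_len(nrow(r$voxels)),
                           function(i) as.integer(r$voxels[i, ])))
    }),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_rois <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(j, function(r) {
    roi_spec(r$kind, matrix(unlist(r$voxels), ncol = 3, byrow = TRUE),
             r$label %||% "")
  })
}

#' Write / read a tract profile as CSV
#'
#' Columns: `position`, `mean`, `se`, `n`.
#' @param profile a `tract_profile`.
#' @param path CSV path.
#' @export
write_profile <- function(profile, path) {
  n <- profile$n_subjects %||% profile$n_streamlines
  utils::write.csv(
    data.frame(position = profile$position, mean = profile$mean,
               se = profile$se, n = n),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_profile
#' @param parameter parameter name to attach on read.
#' @export
read_profile <- function(path, parameter = "fa") {
  d <- utils::read.csv(path)
  structure(
    list(position = d$position, mean = d$mean, se = d$se,
         n_subjects = d$n[1], parameter = parameter),
    class = "tract_profile"
  )
}

#' Write / read a cohort table as CSV
#' @param cohort a `cohort_table`.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$group <- factor(d$group, levels = c("control", "patient"))
  class(d) <- c("cohort_table", "data.frame")
  d
}
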