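#' Deterministic FACT-style streamline tractography
#'
#' Seed one streamline at the center of every voxel whose FA meets
#' `fa_threshold` and propagate bidirectionally with Euler steps along the
#' nearest-voxel principal eigenvector (FACT: no direction interpolation),
#' sign-aligned with the previous step. A track terminates when it would
#' enter a voxel with FA below threshold, when it would leave the volume, or
#' when the angle between consecutive step directions exceeds
#' `angle_threshold`. There is no minimum or maximum length criterion;
#' `max_steps` is only a safety cap against closed orbits in synthetic
#' fields (a warning is raised if it is ever hit).
#'
#' Tracking is fully deterministic: identical inputs give bit-identical
#' bundles.
#'
#' @param maps a [scalar_maps()] object.
#' @param fa_threshold FA stopping/seeding threshold (default 0.2).
#' @param angle_threshold maximum angle between consecutive steps, degrees
#'   (default 45).
#' @param step Euler step length in mm; default half the voxel size.
#' @param max_steps safety cap on steps per direction.
#' @return class `tract_bundle`: `streamlines` (list of n x 3 mm matrices,
#'   RAS+), `seed_vox` (matrix of 1-based seed voxel indices), `step`,
#'   `voxel_size`, `dim`.
#' @export
track <- function(maps, fa_threshold = 0.2, angle_threshold = 45,
                  step = NULL, max_steps = 2000) {
  stopifnot(inherits(maps, "scalar_maps"))
  vs <- maps$voxel_size
  dm <- maps$dim
  if (is.null(step)) step <- vs / 2
  stopifnot(step > 0, angle_threshold > 0)
  cosmin <- cos(angle_threshold * pi / 180)

  fa <- as.vector(maps$fa)
  fa[!as.vector(maps$mask)] <- NA_real_
  e1m <- matrix(maps$e1, ncol = 3)

  seed_lin <- which(!is.na(fa) & fa >= fa_threshold)
  if (length(seed_lin) == 0) {
    warning("no voxel reaches the FA seeding threshold: empty bundle")
    return(structure(list(streamlines = list(), seed_vox = matrix(0, 0, 3),
                          step = step, voxel_size = vs, dim = dm),
                     class = "tract_bundle"))
  }
  seed_vox <- arrayInd(seed_lin, dm)
  seed_mm <- voxel_to_mm(seed_vox, vs)
  d0 <- e1m[seed_lin, , drop = FALSE]

  fwd <- fact_propagate(seed_mm, d0, fa, e1m, dm, vs,
                        fa_threshold, cosmin, step, max_steps)
  bwd <- fact_propagate(seed_mm, -d0, fa, e1m, dm, vs,
                        fa_threshold, cosmin, step, max_steps)

  n <- length(seed_lin)
  streamlines <- vector("list", n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    b <- bwd[[i]]
    f <- fwd[[i]]
    pts <- rbind(
      if (nrow(b)) b[rev(seq_len(nrow(b))), , drop = FALSE],
      seed_mm[i, , drop = FALSE],
      f
    )
    if (nrow(pts) >= 2) {
      streamlines[[i]] <- pts
      keep[i] <- TRUE
    }
  }
  structure(
    list(streamlines = streamlines[keep],
         seed_vox = seed_vox[keep, , drop = FALSE],
         step = step, voxel_size = vs, dim = dm),
    class = "tract_bundle"
  )
}

# Propagate all seeds simultaneously in one direction. Returns a list of
# per-seed point matrices (seed excluded), in step order.
fact_propagate <- function(P0, D0, fa, e1m, dim, vs, fa_threshold,
                           cosmin, step, max_steps) {
  n <- nrow(P0)
  active <- seq_len(n)
  P <- P0
  Dprev <- D0
  rec_id <- vector("list", 0L)
  rec_pt <- vector("list", 0L)
  it <- 0L
  while (length(active) > 0 && it < max_steps) {
    it <- it + 1L
    vox <- mm_to_voxel(P, vs)
    lin <- linear_index(vox, dim)
    dir <- e1m[lin, , drop = FALSE]
    dots <- rowSums(dir * Dprev)
    flip <- !is.na(dots) & dots < 0
    dir[flip, ] <- -dir[flip, , drop = FALSE]
    cosang <- abs(dots)
    ok <- is.finite(cosang) & cosang >= cosmin
    newP <- P + step * dir
    nvox <- mm_to_voxel(newP, vs)
    nlin <- linear_index(nvox, dim)
    ok <- ok & !is.na(nlin) & !is.na(fa[nlin]) & fa[nlin] >= fa_threshold
    if (any(ok)) {
      rec_id[[it]] <- active[ok]
      rec_pt[[it]] <- newP[ok, , drop = FALSE]
    }
    active <- active[ok]
    P <- newP[ok, , drop = FALSE]
    Dprev <- dir[ok, , drop = FALSE]
  }
  if (length(active) > 0) {
    warning(sprintf("%d track(s) hit the max_steps safety cap (%d)",
                    length(active), max_steps))
  }
  ids <- unlist(rec_id, use.names = FALSE)
  out <- rep(list(matrix(0, 0, 3)), n)
  if (length(ids)) {
    pts <- do.call(rbind, rec_pt)
    ord <- split(seq_along(ids), ids) # row order within a group is step order
    for (nm in names(ord)) {
      out[[as.integer(nm)]] <- pts[ord[[nm]], , drop = FALSE]
    }
  }
  out
}

#' Streamline lengths of a bundle
#' @param bundle a `tract_bundle`.
#' @return numeric vector of polyline lengths in mm.
#' @export
streamline_lengths <- function(bundle) {
  vapply(bundle$streamlines, function(p) {
    if (nrow(p) < 2) return(0)
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))
}

#' @export
print.tract_bundle <- function(x, ...) {
  len <- streamline_lengths(x)
  cat(sprintf("Bundle: %d streamlines, step %g mm, mean length %.1f mm\n",
              length(x$streamlines), x$step,
              if (length(len)) mean(len) else NA))
  invisible(x)
}

#' Region-of-interest specification
#'
#' A set of voxels used to retain (`include`) or exclude (`exclude`, the
#' "NOT" ROI of manual tractography) streamlines that pass through it.
#'
#' @param kind `"include"` or `"exclude"`.
#' @param voxels n x 3 matrix of 1-based voxel indices.
#' @param label optional name.
#' @return class `roi_spec`.
#' @export
roi_spec <- function(kind = c("include", "exclude"), voxels, label = "") {
  kind <- match.arg(kind)
  voxels <- matrix(as.integer(round(voxels)), ncol = 3)
  if (nrow(voxels) == 0) stop("ROI geometry is empty")
  structure(list(kind = kind, voxels = voxels, label = label), class = "roi_spec")
}

#' @rdname roi_spec
#' @param mask logical 3-D array; `TRUE` voxels form the ROI.
#' @export
roi_from_mask <- function(mask, kind = c("include", "exclude"), label = "") {
  roi_spec(kind, which(mask, arr.ind = TRUE), label)
}

#' @rdname roi_spec
#' @param axis 1, 2 or 3: the axis perpendicular to the plane.
#' @param index slice index along `axis` (1-based).
#' @param dim grid dimensions.
#' @export
roi_plane <- function(axis, index, dim, kind = c("include", "exclude"),
                      label = "") {
  stopifnot(axis %in% 1:3, index >= 1, index <= dim[axis])
  others <- setdiff(1:3, axis)
  g <- expand.grid(seq_len(dim[others[1]]), seq_len(dim[others[2]]))
  vox <- matrix(0L, nrow(g), 3)
  vox[, axis] <- as.integer(index)
  vox[, others[1]] <- g[, 1]
  vox[, others[2]] <- g[, 2]
  roi_spec(kind, vox, label)
}

#' Select streamlines with include / NOT ROIs
#'
#' Keep the streamlines that intersect every `include` ROI (some point falls
#' in a member voxel, nearest-voxel assignment) and intersect no `exclude`
#' ("NOT") ROI. Streamline order is preserved; the output is always a subset
#' of the input.
#'
#' @param bundle a `tract_bundle`.
#' @param rois list of [roi_spec()] objects; at least one must be `include`.
#' @return filtered `tract_bundle`.
#' @export
select_bundle <- function(bundle, rois) {
  stopifnot(inherits(bundle, "tract_bundle"))
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  kinds <- vapply(rois, function(r) r$kind, character(1))
  if (!any(kinds == "include")) stop("at least one include ROI is required")
  dm <- bundle$dim
  nv <- prod(dm)
  lut <- lapply(rois, function(r) {
    ind <- linear_index(r$voxels, dm)
    if (anyNA(ind)) stop("ROI '", r$label, "' has voxels outside the grid")
    v <- logical(nv)
    v[ind] <- TRUE
    v
  })
  keep <- vapply(bundle$streamlines, function(p) {
    lin <- linear_index(mm_to_voxel(p, bundle$voxel_size), dm)
    lin <- lin[!is.na(lin)]
    for (j in seq_along(rois)) {
      hit <- any(lut[[j]][lin])
      if (kinds[j] == "include" && !hit) return(FALSE)
      if (kinds[j] == "exclude" && hit) return(FALSE)
    }
    TRUE
  }, logical(1))
  bundle$streamlines <- bundle$streamlines[keep]
  bundle$seed_vox <- bundle$seed_vox[keep, , drop = FALSE]
  bundle
}
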