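# Landmark-normalized tract profiles ("cross-section" extraction).

#' Project landmarks onto each streamline
#'
#' Map each of the five landmarks to the arc-length coordinate of its
#' nearest point on each streamline. Streamlines are first put in canonical
#' orientation (the end nearer the LM1 projection first); streamlines on
#' which the five projections are not strictly increasing, or for which a
#' landmark lies farther than `capture_radius` from every point, are flagged
#' and excluded from profile averaging.
#'
#' @param bundle a `tract_bundle`.
#' @param landmarks 5 x 3 matrix of landmark positions in mm (LM1..LM5).
#' @param capture_radius maximum landmark-to-streamline distance in mm.
#' @return class `landmark_projection`: `arc` (n_streamlines x 5 arc-length
#'   coordinates, mm, NA where unmapped), `flipped` (logical: streamline was
#'   reversed), `retained` (logical), `n_excluded`, `landmarks`,
#'   `capture_radius`.
#' @export
project_landmarks <- function(bundle, landmarks, capture_radius = 10) {
  stopifnot(inherits(bundle, "tract_bundle"))
  landmarks <- matrix(landmarks, ncol = 3)
  if (nrow(landmarks) != 5) stop("exactly 5 landmarks (LM1..LM5) are required")
  n <- length(bundle$streamlines)
  arc <- matrix(NA_real_, n, 5)
  flipped <- logical(n)
  for (i in seq_len(n)) {
    p <- bundle$streamlines[[i]]
    s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    total <- s[length(s)]
    co <- numeric(5)
    for (l in 1:5) {
      d2 <- (p[, 1] - landmarks[l, 1])^2 + (p[, 2] - landmarks[l, 2])^2 +
        (p[, 3] - landmarks[l, 3])^2
      j <- which.min(d2)
      co[l] <- if (sqrt(d2[j]) <= capture_radius) s[j] else NA_real_
    }
    # canonical orientation: LM1 end first (tie -> smaller first coordinate)
    if (!is.na(co[1]) && !is.na(co[5])) {
      rev_needed <- co[1] > co[5] ||
        (co[1] == co[5] && p[nrow(p), 1] < p[1, 1])
      if (rev_needed) {
        co <- total - co
        flipped[i] <- TRUE
      }
    }
    arc[i, ] <- co
  }
  retained <- apply(arc, 1, function(a) !anyNA(a) && all(diff(a) > 0))
  structure(
    list(arc = arc, flipped = flipped, retained = retained,
         n_excluded = sum(!retained), landmarks = landmarks,
         capture_radius = capture_radius),
    class = "landmark_projection"
  )
}

# Sample a 3-D scalar array at mm points. "nearest" matches FACT's
# nearest-voxel semantics and avoids partial-volume dilution at sharp
# boundaries; "trilinear" interpolates the 8 surrounding voxel centers.
sample_map <- function(vol, pts, voxel_size, interp = c("nearest", "trilinear")) {
  interp <- match.arg(interp)
  dm <- dim(vol)
  if (interp == "nearest") {
    lin <- linear_index(mm_to_voxel(pts, voxel_size), dm)
    out <- rep(NA_real_, nrow(pts))
    out[!is.na(lin)] <- vol[lin[!is.na(lin)]]
    return(out)
  }
  g <- pts / voxel_size + 1 # continuous 1-based voxel coordinate
  f0 <- pmin(pmax(floor(g), 1), matrix(rep(dm - 1, each = nrow(g)), ncol = 3))
  w <- g - f0
  out <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    vox <- cbind(f0[, 1] + dx, f0[, 2] + dy, f0[, 3] + dz)
    lin <- linear_index(vox, dm)
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
      (if (dy) w[, 2] else 1 - w[, 2]) *
      (if (dz) w[, 3] else 1 - w[, 3])
    v <- rep(NA_real_, nrow(pts))
    v[!is.na(lin)] <- vol[lin[!is.na(lin)]]
    out <- out + wt * v
  }
  out
}

#' Landmark-normalized tract profile
#'
#' Warp each retained streamline's arc-length so that landmark LMi maps to
#' normalized position i (piecewise-linear between landmarks), resample each
#' streamline at `k_per_segment` equally spaced positions per segment, sample
#' the chosen scalar map at the resampled points, and average across
#' streamlines per position ("cross section"). Positions outside [LM1, LM5]
#' are discarded.
#'
#' @param bundle a `tract_bundle`.
#' @param proj a [project_landmarks()] result for this bundle.
#' @param maps a [scalar_maps()] object.
#' @param parameter one of `"fa"`, `"md"`, `"ad"`, `"rd"`.
#' @param k_per_segment interior sampling density per landmark segment.
#' @param interp scalar-map sampling: `"nearest"` (default; consistent with
#'   FACT's nearest-voxel lookup and robust to sharp tissue boundaries) or
#'   `"trilinear"`.
#' @return class `tract_profile`: `position` (1 to 5), `mean`, `se`
#'   (dispersion across streamlines), `n_streamlines`, `parameter`.
#' @export
normalize_and_average <- function(bundle, proj, maps, parameter = "fa",
                                  k_per_segment = 20,
                                  interp = c("nearest", "trilinear")) {
  stopifnot(inherits(bundle, "tract_bundle"),
            inherits(proj, "landmark_projection"))
  parameter <- match.arg(parameter, c("fa", "md", "ad", "rd"))
  interp <- match.arg(interp)
  idx <- which(proj$retained)
  if (length(idx) == 0) {
    stop("no streamline retained a strictly increasing landmark projection")
  }
  u <- seq(1, 5, by = 1 / k_per_segment)
  vol <- maps[[parameter]]
  V <- matrix(NA_real_, length(idx), length(u))
  for (k in seq_along(idx)) {
    i <- idx[k]
    p <- bundle$streamlines[[i]]
    if (proj$flipped[i]) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    s_u <- stats::approx(1:5, proj$arc[i, ], xout = u)$y
    xyz <- cbind(
      stats::approx(s, p[, 1], xout = s_u, rule = 2)$y,
      stats::approx(s, p[, 2], xout = s_u, rule = 2)$y,
      stats::approx(s, p[, 3], xout = s_u, rule = 2)$y
    )
    V[k, ] <- sample_map(vol, xyz, maps$voxel_size, interp)
  }
  m <- colMeans(V)
  se <- if (nrow(V) > 1) {
    apply(V, 2, stats::sd) / sqrt(nrow(V))
  } else {
    rep(0, ncol(V))
  }
  structure(
    list(position = u, mean = m, se = se, n_streamlines = nrow(V),
         parameter = parameter),
    class = "tract_profile"
  )
}

#' Mean of a profile between two landmarks
#'
#' Unweighted mean of the per-position means over normalized positions in
#' `[from_lm, to_lm]` (inclusive). `segment_mean(p, 1, 2)` is the LM12
#' segment mean used for subject-level group comparison.
#'
#' @param profile a `tract_profile` (or a group profile).
#' @param from_lm,to_lm landmark numbers, `1 <= from < to <= 5`.
#' @return scalar mean.
#' @export
segment_mean <- function(profile, from_lm = 1, to_lm = 2) {
  stopifnot(from_lm >= 1, to_lm <= 5, from_lm < to_lm)
  sel <- profile$position >= from_lm & profile$position <= to_lm
  if (!any(sel)) stop("no profile positions in the requested landmark range")
  mean(profile$mean[sel])
}

#' Group-average profile across subjects
#'
#' Average per-subject tract profiles position-wise; dispersion is the
#' standard error across subjects (the convention used for group
#' mean +/- 1 SE profile plots).
#'
#' @param profiles list of `tract_profile` objects on a common position grid.
#' @return class `tract_profile` with `n_subjects`.
#' @export
group_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  pos <- profiles[[1]]$position
  for (p in profiles) {
    if (!isTRUE(all.equal(p$position, pos))) {
      stop("profiles are not on a common position grid")
    }
  }
  M <- do.call(rbind, lapply(profiles, function(p) p$mean))
  se <- if (nrow(M) > 1) apply(M, 2, stats::sd) / sqrt(nrow(M)) else rep(0, ncol(M))
  structure(
    list(position = pos, mean = colMeans(M), se = se,
         n_subjects = nrow(M), parameter = profiles[[1]]$parameter),
    class = "tract_profile"
  )
}

#' @export
print.tract_profile <- function(x, ...) {
  n <- x$n_subjects %||% x$n_streamlines
  cat(sprintf("Tract profile (%s): %d positions LM1-LM5, averaged over %d %s\n",
              x$parameter, length(x$position), n,
              if (is.null(x$n_subjects)) "streamlines" else "subjects"))
  cat(sprintf("  LM12 segment mean: %.4f\n", segment_mean(x, 1, 2)))
  invisible(x)
}

#' Snap landmarks to the locally brightest FA voxel
#'
#' Optional helper mimicking manual landmark placement: within the slice
#' through each landmark (perpendicular to `axis`), restricted to a small
#' in-plane window, move the landmark to the voxel with the highest FA.
#'
#' @param landmarks_vox 5 x 3 matrix of 1-based voxel indices.
#' @param maps a [scalar_maps()] object.
#' @param axis slice axis (1, 2 or 3) per landmark; recycled.
#' @param window in-plane half-width of the search window, voxels.
#' @return snapped 5 x 3 voxel index matrix.
#' @export
snap_landmarks_to_fa <- function(landmarks_vox, maps, axis = 3, window = 2) {
  axis <- rep_len(axis, 5)
  out <- landmarks_vox
  for (l in 1:5) {
    others <- setdiff(1:3, axis[l])
    rng1 <- pmax(1, landmarks_vox[l, others[1]] - window):
      pmin(maps$dim[others[1]], landmarks_vox[l, others[1]] + window)
    rng2 <- pmax(1, landmarks_vox[l, others[2]] - window):
      pmin(maps$dim[others[2]], landmarks_vox[l, others[2]] + window)
    best <- c(landmarks_vox[l, ], -Inf)
    for (a in rng1) for (b in rng2) {
      vox <- landmarks_vox[l, ]
      vox[others[1]] <- a
      vox[others[2]] <- b
      v <- maps$fa[vox[1], vox[2], vox[3]]
      if (is.finite(v) && v > best[4]) best <- c(vox, v)
    }
    out[l, ] <- best[1:3]
  }
  out
}
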