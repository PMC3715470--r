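#' Axially symmetric eigenvalues for a target FA and MD
#'
#' Invert the fractional-anisotropy definition under axial symmetry
#' (lambda2 = lambda3): return the eigenvalue triple with the requested FA
#' and mean diffusivity. Vectorized over `fa` and `md`.
#'
#' With d = lambda1 - lambda2, FA = d / sqrt(3 MD^2 + 2 d^2 / 3), so
#' d = sqrt(3) FA MD / sqrt(1 - 2 FA^2 / 3); lambda1 = MD + 2d/3,
#' lambda2 = lambda3 = MD - d/3, which stays positive for all FA < 1.
#'
#' @param fa target fractional anisotropy in `[0, 1)`.
#' @param md target mean diffusivity (10^-3 mm^2/s).
#' @return matrix with columns `lambda1 >= lambda2 = lambda3 > 0`.
#' @examples
#' eigenvalues_for_fa_md(0, 0.7)        # isotropic: (0.7, 0.7, 0.7)
#' eigenvalues_for_fa_md(0.47, 0.81)    # control-like cingulum tensor
#' @export
eigenvalues_for_fa_md <- function(fa, md) {
  if (any(fa < 0 | fa >= 1)) stop("fa must lie in [0, 1)")
  if (any(md <= 0)) stop("md must be positive")
  d <- sqrt(3) * fa * md / sqrt(1 - 2 * fa^2 / 3)
  l1 <- md + 2 * d / 3
  l23 <- md - d / 3
  stopifnot(all(l23 > 0)) # guaranteed for fa < 1 under axial symmetry
  cbind(lambda1 = l1, lambda2 = l23, lambda3 = l23)
}

#' Specification of a curved-bundle DWI phantom
#'
#' Parameters of a C-shaped (half-torus) fiber bundle embedded in an
#' isotropic background, emulating a cingulum-like tract. The arc is split
#' into four named segments whose boundaries coincide with landmark arc
#' fractions (anterior up to LM2 at 0.30, dorsal to 0.55, posterior to 0.80,
#' ventral beyond), so the anterior segment is exactly the LM1-LM2 interval
#' used for group comparison.
#'
#' @param grid_shape integer 3-vector, volume dimensions in voxels.
#' @param voxel_size isotropic voxel edge in mm.
#' @param arc_radius radius of the centerline arc in mm.
#' @param bundle_radius tube radius in voxels.
#' @param fa_inside named numeric: target FA for segments
#'   `anterior`, `dorsal`, `posterior`, `ventral` (each in `[0, 1)`).
#' @param md_inside mean diffusivity inside the tube (10^-3 mm^2/s).
#' @param background isotropic diffusivity outside the tube (10^-3 mm^2/s).
#' @param snr_b0 signal-to-noise ratio of the b = 0 signal (Rician noise);
#'   ignored when `noiseless = TRUE`.
#' @param seed integer seed for the noise stream.
#' @param noiseless if `TRUE`, emit noise-free signals.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_size = 2,
                         arc_radius = 36,
                         bundle_radius = 3,
                         fa_inside = c(anterior = 0.47, dorsal = 0.47,
                                       posterior = 0.47, ventral = 0.47),
                         md_inside = 0.81,
                         background = 0.7,
                         snr_b0 = 20,
                         seed = 1L,
                         noiseless = FALSE) {
  segs <- c("anterior", "dorsal", "posterior", "ventral")
  if (length(fa_inside) == 1 && is.null(names(fa_inside))) {
    fa_inside <- stats::setNames(rep(fa_inside, 4), segs)
  }
  if (!all(segs %in% names(fa_inside))) {
    stop("fa_inside must name all of: ", paste(segs, collapse = ", "))
  }
  fa_inside <- fa_inside[segs]
  if (any(fa_inside < 0 | fa_inside >= 1)) stop("segment FA targets must lie in [0, 1)")
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8), voxel_size > 0,
            arc_radius > 0, bundle_radius > 0, md_inside > 0, background > 0)
  if (!noiseless && !(snr_b0 > 0)) stop("snr_b0 must be positive unless noiseless")
  # the tube (arc radius + tube radius, plus one voxel margin) must fit
  half_xy <- (min(grid_shape[1:2]) - 1) * voxel_size / 2
  if (arc_radius + (bundle_radius + 1) * voxel_size > half_xy) {
    stop("bundle does not fit inside the grid: reduce arc_radius or enlarge grid")
  }
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
         arc_radius = arc_radius, bundle_radius = bundle_radius,
         fa_inside = fa_inside, md_inside = md_inside, background = background,
         snr_b0 = snr_b0, seed = as.integer(seed), noiseless = isTRUE(noiseless)),
    class = "phantom_spec"
  )
}

# Landmark arc fractions along the centerline (LM1..LM5) and the segment
# breaks derived from them.
landmark_fractions <- function() c(0.05, 0.30, 0.55, 0.80, 0.95)
segment_breaks <- function() c(0.30, 0.55, 0.80)

# Centerline point(s) at arc fraction t in [0, 1], in mm.
# Half circle in the xy-plane, opening toward +x ("C" shape).
centerline_point <- function(t, arc_radius, center) {
  th <- pi / 2 + pi * t
  cbind(center[1] + arc_radius * cos(th),
        center[2] + arc_radius * sin(th),
        rep(center[3], length(t)))
}

#' Simulate a DWI study of a C-shaped bundle phantom
#'
#' Generate a 4-D diffusion-weighted volume over a half-torus bundle.
#' Inside the tube, tensors are axially symmetric with the principal axis
#' tangent to the centerline and eigenvalues solving the segment's target FA
#' at the given MD; outside, diffusion is isotropic at the background
#' diffusivity. Signals follow `S = S0 exp(-b g' D g)`; Rician noise is
#' applied by perturbing two quadrature channels with independent
#' `N(0, (S0/snr_b0)^2)` noise and taking the magnitude.
#'
#' @param spec a [phantom_spec()].
#' @param scheme a [make_gradient_scheme()] object.
#' @return list of class `bundle_phantom` with
#' \describe{
#'   \item{study}{class `dwi_study`: `data` (4-D array), `scheme`,
#'     `voxel_size`, `S0`.}
#'   \item{truth}{ground truth: fine `centerline` (mm), `arc_length` (mm),
#'     `landmarks_vox` (5 x 3, 1-based), `landmarks_mm`, `segment_breaks`
#'     (arc fractions), `tube_mask`, `fa_target` and `md_target` arrays,
#'     `tensor_true` (x,y,z,6 array: Dxx,Dyy,Dzz,Dxy,Dxz,Dyz), `tangent`
#'     (x,y,z,3), `arc_fraction` array, and the noise `seed`.}
#' }
#' @export
make_bundle_phantom <- function(spec, scheme = make_gradient_scheme(48, 800)) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(scheme, "gradient_scheme"))
  dm <- spec$grid_shape
  vs <- spec$voxel_size
  center <- (dm - 1) * vs / 2
  R <- spec$arc_radius
  r_mm <- spec$bundle_radius * vs

  # voxel-center coordinates relative to the arc center
  x <- voxel_to_mm(seq_len(dm[1]), vs) - center[1]
  y <- voxel_to_mm(seq_len(dm[2]), vs) - center[2]
  z <- voxel_to_mm(seq_len(dm[3]), vs) - center[3]
  U <- array(rep(x, times = dm[2] * dm[3]), dim = dm)
  V <- array(rep(rep(y, each = dm[1]), times = dm[3]), dim = dm)
  W <- array(rep(z, each = dm[1] * dm[2]), dim = dm)

  rho <- sqrt(U^2 + V^2)
  theta <- atan2(V, U)                     # (-pi, pi]
  tfrac <- ((theta - pi / 2) %% (2 * pi)) / pi  # arc fraction; >1 on the gap side
  on_arc <- tfrac <= 1
  # distance to the arc: radial for voxels facing the arc, else to an endpoint
  d_arc <- sqrt((rho - R)^2 + W^2)
  ep1 <- centerline_point(0, R, c(0, 0, 0))
  ep2 <- centerline_point(1, R, c(0, 0, 0))
  d_end <- pmin(
    sqrt((U - ep1[1])^2 + (V - ep1[2])^2 + W^2),
    sqrt((U - ep2[1])^2 + (V - ep2[2])^2 + W^2)
  )
  dist <- ifelse(on_arc, d_arc, d_end)
  tube <- dist <= r_mm & on_arc            # endpoint caps are cut flat

  brk <- segment_breaks()
  seg_idx <- findInterval(pmin(tfrac, 1), brk) + 1L  # 1..4
  fa_tgt <- array(0, dim = dm)
  fa_tgt[tube] <- spec$fa_inside[seg_idx[tube]]
  md_tgt <- array(spec$background, dim = dm)
  md_tgt[tube] <- spec$md_inside

  # tangent of the centerline at the nearest arc point (azimuthal direction)
  tx <- -sin(theta); ty <- cos(theta)

  # per-voxel tensors: lambda2 I + (lambda1 - lambda2) t t'
  ev <- eigenvalues_for_fa_md(fa_tgt[tube], spec$md_inside)
  l1 <- l23 <- array(spec$background, dim = dm) # background isotropic
  l1[tube] <- ev[, 1]
  l23[tube] <- ev[, 2]
  dl <- l1 - l23
  Txx <- l23 + dl * tx^2
  Tyy <- l23 + dl * ty^2
  Tzz <- l23  # tangent has no z component
  Txy <- dl * tx * ty
  tensor_true <- array(c(Txx, Tyy, Tzz, Txy, array(0, dm), array(0, dm)),
                       dim = c(dm, 6))

  # signals per volume: g' D g = lambda2 + (lambda1 - lambda2) (g . t)^2
  bv <- scheme_bvals(scheme)
  gv <- scheme_bvecs(scheme)
  S0 <- 100
  nvol <- length(bv)
  data <- array(0, dim = c(dm, nvol))
  for (k in seq_len(nvol)) {
    gdotT <- gv[k, 1] * tx + gv[k, 2] * ty
    q <- l23 + dl * gdotT^2
    data[, , , k] <- S0 * exp(-bv[k] * q / 1000) # b s/mm^2 x D 1e-3 mm^2/s
  }
  if (!spec$noiseless) {
    sigma <- S0 / spec$snr_b0
    with_seed(spec$seed, {
      n <- length(data)
      data[] <- sqrt((data + stats::rnorm(n, 0, sigma))^2 +
                       stats::rnorm(n, 0, sigma)^2)
    })
  }

  tt <- seq(0, 1, length.out = 501)
  cl <- centerline_point(tt, R, center)
  lm_mm_exact <- centerline_point(landmark_fractions(), R, center)
  lm_vox <- mm_to_voxel(lm_mm_exact, vs)
  lm_mm <- voxel_to_mm(lm_vox, vs) # landmark = voxel center, like a 1-voxel ROI

  tang <- array(c(tx, ty, array(0, dm)), dim = c(dm, 3))
  structure(
    list(
      study = structure(
        list(data = data, scheme = scheme, voxel_size = vs, S0 = S0),
        class = "dwi_study"
      ),
      truth = list(
        centerline = cl, arc_length = pi * R,
        landmark_fractions = landmark_fractions(),
        landmarks_vox = lm_vox, landmarks_mm = lm_mm,
        segment_breaks = brk, tube_mask = tube,
        fa_target = fa_tgt, md_target = md_tgt,
        tensor_true = tensor_true, tangent = tang,
        arc_fraction = ifelse(tube, tfrac, NA_real_),
        segment = array(ifelse(tube, seg_idx, NA_integer_), dim = dm),
        seed = spec$seed
      ),
      spec = spec
    ),
    class = "bundle_phantom"
  )
}

#' @export
print.bundle_phantom <- function(x, ...) {
  cat(sprintf(
    "C-bundle phantom: %s grid, %g mm voxels, arc radius %g mm, %d tube voxels\n",
    paste(x$spec$grid_shape, collapse = "x"), x$spec$voxel_size,
    x$spec$arc_radius, sum(x$truth$tube_mask)
  ))
  cat(sprintf("  segment FA targets: %s; MD %g; %s\n",
              paste(sprintf("%s=%.2f", names(x$spec$fa_inside), x$spec$fa_inside),
                    collapse = ", "),
              x$spec$md_inside,
              if (x$spec$noiseless) "noiseless" else sprintf("SNR(b0)=%g", x$spec$snr_b0)))
  invisible(x)
}
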