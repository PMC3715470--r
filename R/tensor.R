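#' Log-linear diffusion tensor fit
#'
#' Fit the diffusion tensor per voxel by ordinary least squares on the
#' log-signal: minimize `||ln S - (ln S0 - b g' D g)||` over the 7 parameters
#' (6 tensor elements + ln S0). Noiseless single-tensor signals are recovered
#' exactly. Voxels with any nonpositive or non-finite signal are masked out.
#'
#' @param study a `dwi_study` (see [make_bundle_phantom()] or [read_dwi()]).
#' @return class `tensor_volume`: `tensor` (x,y,z,6 array, order
#'   Dxx,Dyy,Dzz,Dxy,Dxz,Dyz, units 10^-3 mm^2/s), `lnS0` array, logical
#'   `mask` of fitted voxels, `dim`, `voxel_size`.
#' @export
fit_tensor <- function(study) {
  stopifnot(inherits(study, "dwi_study"))
  X <- tensor_design_matrix(study$scheme)
  if (qr(X)$rank < 7) {
    stop("gradient scheme is rank-deficient: need >= 6 non-collinear directions plus b0")
  }
  dm <- dim(study$data)[1:3]
  nvol <- dim(study$data)[4]
  S <- matrix(study$data, ncol = nvol)
  ok <- rowSums(!is.finite(S) | S <= 0) == 0
  beta <- matrix(NA_real_, nrow = 7, ncol = nrow(S))
  if (any(ok)) {
    # (X'X)^-1 X' applied to all voxels at once; b in s/mm^2 against D in
    # 1e-3 mm^2/s, so scale b by 1e-3 in the design (done via /1000 here)
    Xs <- X
    Xs[, 2:7] <- Xs[, 2:7] / 1000
    beta[, ok] <- solve(crossprod(Xs), t(Xs) %*% t(log(S[ok, , drop = FALSE])))
  }
  tensor <- array(t(beta[2:7, , drop = FALSE]), dim = c(dm, 6))
  lnS0 <- array(beta[1, ], dim = dm)
  structure(
    list(tensor = tensor, lnS0 = lnS0, mask = array(ok, dim = dm),
         dim = dm, voxel_size = study$voxel_size),
    class = "tensor_volume"
  )
}

# Closed-form eigenvalues of symmetric 3x3 matrices, vectorized
# (trigonometric / Cardano method). Input: 6 columns Dxx,Dyy,Dzz,Dxy,Dxz,Dyz.
# Returns a 3-column matrix with lambda1 >= lambda2 >= lambda3.
sym3_eigenvalues <- function(Tn) {
  a <- Tn[, 1]; b <- Tn[, 2]; cc <- Tn[, 3]
  d <- Tn[, 4]; e <- Tn[, 5]; f <- Tn[, 6]
  q <- (a + b + cc) / 3
  p1 <- d^2 + e^2 + f^2
  p2 <- (a - q)^2 + (b - q)^2 + (cc - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  iso <- p <= .Machine$double.eps * (abs(q) + 1)
  ps <- ifelse(iso, 1, p)
  # B = (A - q I) / p; r = det(B) / 2
  ba <- (a - q) / ps; bb <- (b - q) / ps; bc <- (cc - q) / ps
  bd <- d / ps; be <- e / ps; bf <- f / ps
  detB <- ba * (bb * bc - bf^2) - bd * (bd * bc - bf * be) + be * (bd * bf - bb * be)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  l1[iso] <- l2[iso] <- l3[iso] <- q[iso]
  cbind(l1, l2, l3)
}

# Principal eigenvector of symmetric 3x3 matrices given their eigenvalues,
# vectorized: columns of M = (A - l2 I)(A - l3 I) span the lambda1 eigenspace.
# Sign convention: first nonzero component positive.
sym3_principal_eigenvector <- function(Tn, ev) {
  a <- Tn[, 1]; b <- Tn[, 2]; cc <- Tn[, 3]
  d <- Tn[, 4]; e <- Tn[, 5]; f <- Tn[, 6]
  s <- ev[, 2] + ev[, 3]
  p <- ev[, 2] * ev[, 3]
  # A^2 (symmetric), then M = A^2 - s A + p I
  m11 <- a^2 + d^2 + e^2 - s * a + p
  m12 <- a * d + d * b + e * f - s * d
  m13 <- a * e + d * f + e * cc - s * e
  m22 <- d^2 + b^2 + f^2 - s * b + p
  m23 <- d * e + b * f + f * cc - s * f
  m33 <- e^2 + f^2 + cc^2 - s * cc + p
  n1 <- m11^2 + m12^2 + m13^2
  n2 <- m12^2 + m22^2 + m23^2
  n3 <- m13^2 + m23^2 + m33^2
  pick <- max.col(cbind(n1, n2, n3), ties.method = "first")
  vx <- ifelse(pick == 1, m11, ifelse(pick == 2, m12, m13))
  vy <- ifelse(pick == 1, m12, ifelse(pick == 2, m22, m23))
  vz <- ifelse(pick == 1, m13, ifelse(pick == 2, m23, m33))
  nrm <- sqrt(vx^2 + vy^2 + vz^2)
  deg <- !is.finite(nrm) | nrm <= 0
  nrm[deg] <- 1
  vx <- vx / nrm; vy <- vy / nrm; vz <- vz / nrm
  # degenerate (lambda1 = lambda2): any unit vector is valid; use +x
  vx[deg] <- 1; vy[deg] <- 0; vz[deg] <- 0
  sgn <- ifelse(vx != 0, sign(vx), ifelse(vy != 0, sign(vy), sign(vz)))
  sgn[sgn == 0] <- 1
  cbind(vx * sgn, vy * sgn, vz * sgn)
}

#' Scalar diffusion maps from a fitted tensor volume
#'
#' Eigen-decompose each voxel's tensor and derive the four scalar parameters
#' and the principal eigenvector field:
#' FA = sqrt(3/2) sqrt(sum (lambda_i - mean)^2) / sqrt(sum lambda_i^2),
#' MD = mean(lambda), aD = lambda1, rD = (lambda2 + lambda3)/2. Eigenvalues
#' are used raw (no clipping); voxels with a negative eigenvalue are flagged
#' in `negative_eigenvalue` so degradation stays visible. The eigenvector
#' sign convention makes the first nonzero component positive.
#'
#' @param tensors a `tensor_volume` from [fit_tensor()].
#' @return class `scalar_maps`: arrays `fa`, `md`, `ad`, `rd`; `e1`
#'   (x,y,z,3); logical `mask` and `negative_eigenvalue`; `dim`, `voxel_size`.
#' @export
scalar_maps <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_volume"))
  dm <- tensors$dim
  Tn <- matrix(tensors$tensor, ncol = 6)
  ok <- as.vector(tensors$mask) & rowSums(!is.finite(Tn)) == 0
  ev <- matrix(NA_real_, nrow(Tn), 3)
  e1 <- matrix(NA_real_, nrow(Tn), 3)
  if (any(ok)) {
    ev[ok, ] <- sym3_eigenvalues(Tn[ok, , drop = FALSE])
    e1[ok, ] <- sym3_principal_eigenvector(Tn[ok, , drop = FALSE],
                                           ev[ok, , drop = FALSE])
  }
  md <- rowMeans(ev)
  num <- (ev[, 1] - md)^2 + (ev[, 2] - md)^2 + (ev[, 3] - md)^2
  den <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  fa <- sqrt(1.5) * sqrt(num) / sqrt(den)
  fa[ok & den == 0] <- 0 # all-zero tensor
  structure(
    list(
      fa = array(fa, dm), md = array(md, dm),
      ad = array(ev[, 1], dm), rd = array((ev[, 2] + ev[, 3]) / 2, dm),
      e1 = array(e1, dim = c(dm, 3)),
      mask = array(ok, dm),
      negative_eigenvalue = array(ok & ev[, 3] < 0, dm),
      dim = dm, voxel_size = tensors$voxel_size
    ),
    class = "scalar_maps"
  )
}

#' @export
print.scalar_maps <- function(x, ...) {
  cat(sprintf("Scalar maps: %s grid, %g mm voxels, %d fitted voxels\n",
              paste(x$dim, collapse = "x"), x$voxel_size, sum(x$mask)))
  cat(sprintf("  FA range %.3f-%.3f, MD median %.3f (1e-3 mm^2/s)\n",
              min(x$fa[x$mask]), max(x$fa[x$mask]),
              stats::median(x$md[x$mask])))
  invisible(x)
}
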