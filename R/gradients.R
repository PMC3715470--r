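#' Diffusion gradient scheme
#'
#' Build a single-shell diffusion encoding scheme: `n_directions` unit
#' gradient directions spread approximately uniformly over the sphere by a
#' spherical-Fibonacci (golden-angle) layout, preceded by `n_b0` unweighted
#' (b = 0) volumes. The layout is deterministic for a fixed `n_directions`.
#'
#' @param n_directions number of diffusion-weighted directions (>= 6; fewer
#'   leaves the tensor under-determined).
#' @param bvalue diffusion weighting in s/mm^2 applied to every direction.
#' @param n_b0 number of unweighted volumes (>= 1).
#' @return An object of class `gradient_scheme`: a list with `directions`
#'   (`n_directions` x 3 matrix of unit vectors), `bvalues` (per-direction
#'   weightings) and `n_b0`. Use [scheme_bvals()] / [scheme_bvecs()] for the
#'   per-volume expansion (b0 volumes first).
#' @examples
#' sch <- make_gradient_scheme(48, 800)
#' length(scheme_bvals(sch))  # 49 volumes
#' @export
make_gradient_scheme <- function(n_directions, bvalue = 800, n_b0 = 1) {
  if (n_directions < 6) {
    stop("n_directions must be >= 6: the diffusion tensor has 6 free elements")
  }
  stopifnot(bvalue > 0, n_b0 >= 1)
  if (n_directions == 6) {
    # the spherical-Fibonacci layout is tensor-degenerate at exactly n = 6;
    # use the classic dual-gradient six-direction scheme instead
    dirs <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
                  c(1, 0, -1), c(0, 1, 1), c(0, 1, -1)) / sqrt(2)
  } else {
    i <- seq_len(n_directions) - 1
    golden <- pi * (3 - sqrt(5))
    z <- 1 - (2 * i + 1) / n_directions
    r <- sqrt(pmax(0, 1 - z^2))
    th <- golden * i
    dirs <- cbind(r * cos(th), r * sin(th), z)
  }
  dirs <- dirs / sqrt(rowSums(dirs^2))
  colnames(dirs) <- c("x", "y", "z")
  structure(
    list(
      directions = dirs,
      bvalues = rep(as.double(bvalue), n_directions),
      n_b0 = as.integer(n_b0)
    ),
    class = "gradient_scheme"
  )
}

#' Per-volume b-values / b-vectors of a scheme
#'
#' Expand a [make_gradient_scheme()] object to per-volume form, b0 volumes
#' first. b0 volumes carry a zero vector.
#' @param scheme a `gradient_scheme`.
#' @return `scheme_bvals`: numeric vector of length `n_b0 + n_directions`;
#'   `scheme_bvecs`: matrix with one row per volume.
#' @export
scheme_bvals <- function(scheme) {
  c(rep(0, scheme$n_b0), scheme$bvalues)
}

#' @rdname scheme_bvals
#' @export
scheme_bvecs <- function(scheme) {
  rbind(matrix(0, scheme$n_b0, 3), scheme$directions)
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf(
    "Gradient scheme: %d directions at b = %g s/mm^2 + %d b0 volume(s)\n",
    nrow(x$directions), x$bvalues[1], x$n_b0
  ))
  invisible(x)
}

# Design matrix of the log-linear tensor fit: one row per volume,
# columns (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
tensor_design_matrix <- function(scheme) {
  b <- scheme_bvals(scheme)
  g <- scheme_bvecs(scheme)
  cbind(
    1,
    -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
    -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3], -2 * b * g[, 2] * g[, 3]
  )
}
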