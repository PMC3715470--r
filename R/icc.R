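#' Intraclass correlation, two-way random, absolute agreement, single measures
#'
#' ICC(2,1) from the two-way random-effects ANOVA decomposition of an
#' `n_targets x k_raters` matrix:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' where MSR, MSC and MSE are the row (target), column (rater) and residual
#' mean squares. Absolute agreement penalizes systematic rater offsets. The
#' confidence interval is the standard F-based interval (McGraw & Wong,
#' case 2A, single measures).
#'
#' @param ratings complete numeric matrix, one row per rated target, one
#'   column per rater; `n >= 2`, `k >= 2`.
#' @param conf_level confidence level for the interval.
#' @return class `icc_result`: `icc`, `lower`, `upper`, mean squares,
#'   `n`, `k`, and `degenerate` (`TRUE` when between-target variance is
#'   zero, in which case `icc` is `NA`).
#' @export
icc_absolute_agreement <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings must be complete (no NA)")
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 targets and 2 raters")
  gm <- mean(ratings)
  rowm <- rowMeans(ratings)
  colm <- colMeans(ratings)
  SSR <- k * sum((rowm - gm)^2)
  SSC <- n * sum((colm - gm)^2)
  SST <- sum((ratings - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (SSR <= .Machine$double.eps * SST) {
    return(structure(list(icc = NA_real_, lower = NA_real_, upper = NA_real_,
                          MSR = MSR, MSC = MSC, MSE = MSE, n = n, k = k,
                          degenerate = TRUE),
                     class = "icc_result"))
  }
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  structure(list(icc = icc, lower = lower, upper = upper,
                 MSR = MSR, MSC = MSC, MSE = MSE, n = n, k = k,
                 degenerate = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$degenerate) {
    cat("ICC(2,1): undefined (zero between-target variance)\n")
  } else {
    cat(sprintf("ICC(2,1) = %.3f (95%% CI %.3f-%.3f), n = %d targets, k = %d raters\n",
                x$icc, x$lower, x$upper, x$n, x$k))
  }
  invisible(x)
}
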