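# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms (brute force, explicit sums,
# Newton iteration) than the code paths they validate.

# AUC by exhaustive pairwise enumeration with half credit for ties.
brute_force_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + (p > q) + 0.5 * (p == q)
  }
  s / (length(pos) * length(neg))
}

# Mann-Whitney U by exhaustive pair counting (x vs y).
brute_force_u <- function(x, y) {
  s <- 0
  for (a in x) for (b in y) s <- s + (a > b) + 0.5 * (a == b)
  s
}

# Youden scan over every candidate threshold (all midpoints plus sentinels),
# higher scores = positive class.
brute_force_youden <- function(pos, neg) {
  uq <- sort(unique(c(pos, neg)))
  cand <- c(min(uq) - 1, (uq[-1] + uq[-length(uq)]) / 2, max(uq) + 1)
  best <- list(J = -Inf)
  for (cu in cand) {
    sens <- mean(pos > cu)
    spec <- mean(neg <= cu)
    J <- sens + spec - 1
    if (J > best$J) best <- list(J = J, cutoff = cu, sens = sens, spec = spec)
  }
  best
}

# Logistic regression by direct Newton maximization of the log-likelihood
# l(beta) = sum[y x'beta - log(1 + exp(x'beta))].
newton_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- crossprod(X, y - p)
    H <- crossprod(X * (p * (1 - p)), X)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.vector(beta)
}

# ICC(2,1) from mean squares obtained via stats::aov on the long-format
# two-way layout (independent of the package's explicit sums of squares).
aov_icc21 <- function(ratings) {
  n <- nrow(ratings)
  k <- ncol(ratings)
  d <- data.frame(
    y = as.vector(ratings),
    target = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ target + rater, data = d))[[1]][, "Mean Sq"]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

# Random symmetric positive-definite 3x3 tensor as (Dxx,Dyy,Dzz,Dxy,Dxz,Dyz),
# eigenvalues in [0.1, 2].
random_pd_tensor <- function() {
  lam <- sort(runif(3, 0.1, 2), decreasing = TRUE)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  A <- Q %*% diag(lam) %*% t(Q)
  c(A[1, 1], A[2, 2], A[3, 3], A[1, 2], A[1, 3], A[2, 3])
}

tensor_to_matrix <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

# Definitional FA from eigenvalues.
fa_from_eigenvalues <- function(lam) {
  lb <- mean(lam)
  sqrt(1.5) * sqrt(sum((lam - lb)^2)) / sqrt(sum(lam^2))
}
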