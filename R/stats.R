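# Group-discrimination statistics battery.

#' Cohen's d with average-SD standardizer
#'
#' Standardized mean difference `|m1 - m2| / ((sd1 + sd2) / 2)`. The
#' denominator is the plain average of the two group SDs (not the pooled
#' SD); this is the convention that reproduces the published effect sizes
#' this package's worked examples are checked against.
#'
#' @param mean1,sd1 mean and SD of group 1.
#' @param mean2,sd2 mean and SD of group 2.
#' @return nonnegative effect size.
#' @examples
#' cohens_d(0.47, 0.034, 0.39, 0.053)  # 1.84
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2) {
  if (any(sd1 + sd2 <= 0)) stop("zero SD: effect size undefined")
  abs(mean1 - mean2) / ((sd1 + sd2) / 2)
}

#' Two-sample pooled-variance Student's t test
#'
#' Classic Student t with pooled variance and `df = n1 + n2 - 2`, two-tailed.
#' Accepts either raw vectors (`x`, `y`) or group summaries
#' (`mean1, sd1, n1, mean2, sd2, n2`). A Bonferroni significance flag is
#' reported at `alpha`.
#'
#' @param x,y raw group samples (omit if using summaries).
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (omit if using raw data).
#' @param alpha family-corrected significance level (default 0.05/6, the
#'   Bonferroni level for a six-parameter family).
#' @return list with `t`, `df`, `p` (two-tailed), `significant`.
#' @export
two_sample_t <- function(x = NULL, y = NULL,
                         mean1 = NULL, sd1 = NULL, n1 = NULL,
                         mean2 = NULL, sd2 = NULL, n2 = NULL,
                         alpha = 0.05 / 6) {
  if (!is.null(x)) {
    stopifnot(!is.null(y))
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 <= 0) stop("zero pooled variance")
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, significant = p < alpha, alpha = alpha)
}

# Mann-Whitney U of x (group 1) versus y, midrank ties, plus the
# tie-corrected normal-approximation two-sided p. Shared by mann_whitney()
# and roc_auc() so that AUC = U / (n1 n2) and both p-values coincide.
u_statistic <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(c(x, y))
  tiecor <- sum(ties^3 - ties) / (N * (N - 1))
  varU <- n1 * n2 / 12 * ((N + 1) - tiecor)
  z <- if (varU > 0) (U - n1 * n2 / 2) / sqrt(varU) else 0
  p <- if (varU > 0) 2 * stats::pnorm(-abs(z)) else 1
  list(U = U, z = z, p = min(p, 1), varU = varU)
}

#' ROC area under the curve
#'
#' AUC by concordant-pair counting with half credit for ties:
#' `AUC = (#concordant + 0.5 #ties) / (n1 n2)`, computed via midranks.
#' Unless `direction` is given, score orientation is fixed from the group
#' means so that the positive (patient) group is expected higher and the
#' reported AUC is `>= 0.5` by construction; the applied flip is recorded.
#' Significance against AUC = 0.5 uses the Mann-Whitney U normal
#' approximation with tie correction.
#'
#' @param scores numeric per-subject values.
#' @param labels group labels; `positive` identifies the patient group.
#' @param positive label of the positive class (default `"patient"`).
#' @param direction `NA` (auto-orient from group means), `1` (higher score =
#'   positive) or `-1`.
#' @return list with `auc`, `p`, `direction`, `flipped`, `n_positive`,
#'   `n_negative`.
#' @export
roc_auc <- function(scores, labels, positive = "patient", direction = NA) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (length(pos) == 0 || length(neg) == 0) stop("both groups must be nonempty")
  if (is.na(direction)) {
    direction <- if (mean(pos) >= mean(neg)) 1 else -1
  }
  u <- u_statistic(direction * pos, direction * neg)
  list(auc = u$U / (length(pos) * length(neg)), p = u$p,
       direction = direction, flipped = direction < 0,
       n_positive = length(pos), n_negative = length(neg))
}

#' Mann-Whitney U test
#'
#' Independent-sample U statistic with midrank ties and tie-corrected
#' normal-approximation two-sided p-value. Consistent with [roc_auc()]
#' through the identity `AUC = U / (n1 n2)`.
#'
#' @param x,y the two samples.
#' @return list with `U`, `z`, `p`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  u <- u_statistic(x, y)
  list(U = u$U, z = u$z, p = u$p)
}

#' Optimal classification cut-off by the Youden index
#'
#' Sweep midpoints between adjacent sorted unique scores (plus outer
#' sentinels) and maximize `J = sensitivity + specificity - 1`; the first
#' maximum is reported on ties. Orientation follows [roc_auc()]: unless
#' `direction` is given, the side on which the positive group lies is chosen
#' from the group means.
#'
#' @inheritParams roc_auc
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden`,
#'   `direction`, and `degenerate` (`TRUE` when scores are constant).
#' @export
youden_cutoff <- function(scores, labels, positive = "patient", direction = NA) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (length(pos) == 0 || length(neg) == 0) stop("both groups must be nonempty")
  if (is.na(direction)) direction <- if (mean(pos) >= mean(neg)) 1 else -1
  sp <- direction * pos
  sn <- direction * neg
  uq <- sort(unique(c(sp, sn)))
  if (length(uq) < 2) {
    return(list(cutoff = uq[1], sensitivity = 1, specificity = 0, youden = 0,
                direction = direction, degenerate = TRUE))
  }
  cuts <- (uq[-1] + uq[-length(uq)]) / 2
  best <- c(J = -Inf, cut = NA, sens = NA, spec = NA)
  for (cu in cuts) {
    sens <- mean(sp > cu)
    spec <- mean(sn <= cu)
    J <- sens + spec - 1
    if (J > best["J"]) best <- c(J = J, cut = cu, sens = sens, spec = spec)
  }
  list(cutoff = unname(best["cut"]), sensitivity = unname(best["sens"]),
       specificity = unname(best["spec"]), youden = unname(best["J"]),
       direction = direction, degenerate = FALSE)
}

#' Covariate-adjusted binary logistic classification (ENTER model)
#'
#' Fit `group ~ parameter + covariates` by maximum likelihood (iteratively
#' reweighted least squares via [stats::glm()], all terms entered at once),
#' report Wald p-values per term, and classify subjects at fitted
#' probability 0.5. The percent correctly classified is reported alongside
#' the majority-class baseline. Complete separation (non-convergence or
#' fitted probabilities collapsing to 0/1) is flagged, not silently
#' returned.
#'
#' @param cohort a data frame with a `group` column (levels
#'   control/patient) plus parameter and covariate columns.
#' @param parameter name of the predictor of interest.
#' @param covariates further predictor names (default age, sex, education).
#' @return list with `coefficients` (B), `p` (Wald, per term),
#'   `percent_correct`, `baseline_percent`, `correct` (per-subject logical),
#'   `separation_flag`, `n`.
#' @export
logistic_enter <- function(cohort, parameter,
                           covariates = c("age", "sex", "education")) {
  vars <- c(parameter, covariates)
  stopifnot(all(vars %in% names(cohort)), "group" %in% names(cohort))
  dat <- cohort[stats::complete.cases(cohort[, c("group", vars)]), , drop = FALSE]
  if (nrow(dat) < 10) stop("need at least 10 complete cases")
  y <- as.integer(dat$group == "patient")
  if (length(unique(y)) < 2) stop("both groups must be present")
  for (v in vars) {
    if (stats::var(as.numeric(dat[[v]])) == 0) stop("constant predictor: ", v)
  }
  fml <- stats::as.formula(paste("y ~", paste(vars, collapse = " + ")))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = cbind(dat, y = y), family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) sep <- TRUE
  pr <- stats::fitted(fit)
  correct <- (pr >= 0.5) == (y == 1)
  # complete separation: every subject classified with extreme confidence
  eta <- stats::predict(fit)
  if (all(correct) && min(abs(eta)) > 10) sep <- TRUE
  sm <- summary(fit)$coefficients
  list(
    coefficients = stats::coef(fit),
    p = sm[, "Pr(>|z|)"],
    percent_correct = 100 * mean(correct),
    baseline_percent = 100 * max(mean(y), 1 - mean(y)),
    correct = correct,
    separation_flag = sep,
    n = nrow(dat)
  )
}

#' Exact McNemar test on paired classification outcomes
#'
#' Compare two classifiers on the same subjects through their discordant
#' pairs: `b` subjects correct under A only, `c` correct under B only. The
#' two-sided exact binomial p-value is
#' `min(1, 2 P(Bin(b + c, 1/2) <= min(b, c)))`.
#'
#' @param correct_a,correct_b logical vectors: per-subject correctness of
#'   the two classifiers.
#' @return list with `b`, `c`, `p`, `degenerate` (`TRUE` when `b + c = 0`,
#'   in which case `p = 1`).
#' @examples
#' mcnemar_exact(rep(TRUE, 6), rep(FALSE, 6))  # p = 0.03125
#' @export
mcnemar_exact <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  if (b + cc == 0) {
    return(list(b = b, c = cc, p = 1, degenerate = TRUE))
  }
  p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
  list(b = b, c = cc, p = p, degenerate = FALSE)
}

#' Pearson correlation with two-tailed p
#'
#' Product-moment correlation; p from the t transform with `n - 2` degrees
#' of freedom (via [stats::cor.test()]).
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
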