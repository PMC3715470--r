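test_that("average-SD Cohen's d reproduces the reference effect sizes", {
  expect_equal(round(cohens_d(0.47, 0.034, 0.39, 0.053), 2), 1.84)
  expect_equal(round(cohens_d(0.39, 0.038, 0.33, 0.047), 2), 1.41)
  expect_equal(round(cohens_d(0.85, 0.036, 0.96, 0.12), 2), 1.41)
  expect_equal(round(cohens_d(1.24, 0.055, 1.32, 0.062), 2), 1.37)
  expect_equal(round(cohens_d(0.81, 0.036, 0.92, 0.070), 1), 2.1)
  expect_equal(cohens_d(0.5, 0.1, 0.5, 0.2), 0)
  expect_error(cohens_d(1, 0, 2, 0), "zero SD")
})

test_that("pooled t-test matches the textbook formula and t.test", {
  same <- two_sample_t(mean1 = 3, sd1 = 1, n1 = 10, mean2 = 3, sd2 = 1, n2 = 10)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # reference MD comparison: strongly significant at the 0.008 level
  md <- two_sample_t(mean1 = 0.81, sd1 = 0.036, n1 = 22,
                     mean2 = 0.92, sd2 = 0.070, n2 = 14)
  expect_lt(md$p, 0.001)
  expect_true(md$significant)
  expect_equal(md$df, 34)
  set.seed(8)
  for (rep in 1:10) {
    x <- rnorm(sample(4:12, 1)); y <- rnorm(sample(4:12, 1), 0.5)
    got <- two_sample_t(x, y)
    # explicit-sums oracle
    n1 <- length(x); n2 <- length(y)
    sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
    t_ref <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    expect_equal(got$t, t_ref, tolerance = 1e-12)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("AUC equals exhaustive pair enumeration, including ties", {
  labels <- rep(c("patient", "control"), c(6, 4))
  scores <- c(5, 3, 3, 8, 7, 6, 3, 2, 1, 5) # ties across groups
  got <- roc_auc(scores, labels, direction = 1)
  expect_equal(got$auc, brute_force_auc(scores[1:6], scores[7:10]))
  # perfect separation
  expect_equal(roc_auc(c(5, 6, 7, 1, 2), rep(c("patient", "control"), c(3, 2)))$auc, 1)
  # orientation flip: lower-in-patients parameter still reports AUC >= 0.5
  fa_like <- c(rnorm(10, 0.4, 0.02), rnorm(10, 0.48, 0.02))
  lab <- rep(c("patient", "control"), each = 10)
  res <- roc_auc(fa_like, lab)
  expect_true(res$flipped)
  expect_gte(res$auc, 0.5)
})

test_that("labels shuffled independently of scores give AUC near 0.5", {
  set.seed(12)
  aucs <- replicate(200, {
    sc <- rnorm(30)
    lab <- sample(rep(c("patient", "control"), c(14, 16)))
    roc_auc(sc, lab, direction = 1)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("U statistic matches brute force and the AUC identity", {
  set.seed(5)
  for (rep in 1:50) {
    x <- sample(1:8, sample(3:10, 1), replace = TRUE)
    y <- sample(1:8, sample(3:10, 1), replace = TRUE)
    mw <- mann_whitney(x, y)
    expect_equal(mw$U, brute_force_u(x, y))
    auc <- roc_auc(c(x, y), rep(c("patient", "control"),
                                c(length(x), length(y))), direction = 1)
    expect_equal(auc$auc * length(x) * length(y), mw$U, tolerance = 1e-12)
    expect_equal(auc$p, mw$p, tolerance = 1e-12)
  }
  # extremes and null
  expect_equal(mann_whitney(4:6, 1:3)$U, 9)
  expect_equal(mann_whitney(1:3, 4:6)$U, 0)
  expect_gt(mann_whitney(1:9, 1:9)$p, 0.95)
  # the tie-corrected U agrees with wilcox.test's W
  set.seed(6)
  x <- rnorm(12); y <- rnorm(15, 0.3)
  expect_equal(mann_whitney(x, y)$U,
               unname(wilcox.test(x, y, exact = FALSE)$statistic))
})

test_that("Youden cut-off matches an exhaustive threshold sweep", {
  # separated groups: perfect classification
  sep <- youden_cutoff(c(1, 2, 3, 7, 8, 9),
                       rep(c("control", "patient"), each = 3))
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  expect_equal(sep$youden, 1)
  set.seed(9)
  for (rep in 1:20) {
    pos <- round(rnorm(5, 1), 1)
    neg <- round(rnorm(5), 1)
    got <- youden_cutoff(c(pos, neg),
                         rep(c("patient", "control"), each = 5), direction = 1)
    oracle <- brute_force_youden(pos, neg)
    expect_equal(got$youden, oracle$J, tolerance = 1e-12)
  }
  const <- youden_cutoff(rep(1, 10), rep(c("patient", "control"), 5))
  expect_true(const$degenerate)
  expect_equal(const$youden, 0)
})

test_that("large-sample Youden operating point approaches the normal-model optimum", {
  # MD-like group distributions; patients higher
  set.seed(31)
  n <- 4000
  pat <- rnorm(n, 0.92, 0.070)
  ctl <- rnorm(n, 0.81, 0.036)
  got <- youden_cutoff(c(pat, ctl), rep(c("patient", "control"), each = n))
  # analytic optimum on a fine grid
  grid <- seq(0.7, 1.1, by = 1e-4)
  J <- (1 - pnorm(grid, 0.92, 0.070)) + pnorm(grid, 0.81, 0.036) - 1
  opt <- grid[which.max(J)]
  expect_equal(got$cutoff, opt, tolerance = 0.02)
  expect_equal(got$sensitivity, 1 - pnorm(opt, 0.92, 0.070), tolerance = 0.05)
  expect_equal(got$specificity, pnorm(opt, 0.81, 0.036), tolerance = 0.05)
})

test_that("logistic ENTER model recovers the 2x2 log odds ratio", {
  # saturated single binary predictor: coefficient = log OR of the table
  d <- data.frame(
    group = factor(rep(c("patient", "control"), c(20, 20)),
                   levels = c("control", "patient")),
    x = c(rep(1, 14), rep(0, 6), rep(1, 5), rep(0, 15))
  )
  fit <- logistic_enter(d, "x", covariates = character(0))
  logor <- log((14 / 6) / (5 / 15))
  expect_equal(unname(fit$coefficients["x"]), logor, tolerance = 1e-6)
})

test_that("logistic fit matches direct Newton maximization to 1e-6", {
  set.seed(13)
  for (rep in 1:20) {
    n <- 40
    d <- data.frame(
      group = factor(sample(rep(c("control", "patient"), each = n / 2)),
                     levels = c("control", "patient")),
      age = rnorm(n, 68, 8), sex = rbinom(n, 1, 0.5),
      education = rnorm(n, 10, 2)
    )
    d$par <- rnorm(n, ifelse(d$group == "patient", 0.5, 0), 1)
    fit <- logistic_enter(d, "par")
    X <- cbind(1, d$par, d$age, d$sex, d$education)
    beta <- newton_logistic(X, as.integer(d$group == "patient"))
    expect_equal(unname(fit$coefficients), beta, tolerance = 1e-6)
  }
})

test_that("null-effect logistic classification falls to the majority baseline", {
  set.seed(17)
  n <- 400
  d <- data.frame(
    group = factor(rep(c("control", "patient"), c(240, 160)),
                   levels = c("control", "patient")),
    age = rnorm(n, 68, 8), sex = rbinom(n, 1, 0.5),
    education = rnorm(n, 10, 2), par = rnorm(n)
  )
  fit <- logistic_enter(d, "par")
  expect_lt(abs(fit$percent_correct - fit$baseline_percent), 5)
  # complete separation is flagged
  d2 <- d[c(1:20, 241:260), ] # 20 controls + 20 patients
  d2$par <- ifelse(d2$group == "patient", 10, -10)
  fit2 <- logistic_enter(d2, "par")
  expect_true(fit2$separation_flag)
})

test_that("exact McNemar p-values follow the discordant-pair binomial", {
  r6 <- mcnemar_exact(c(rep(TRUE, 6), rep(TRUE, 4)),
                      c(rep(FALSE, 6), rep(TRUE, 4)))
  expect_equal(r6$b, 6)
  expect_equal(r6$c, 0)
  expect_equal(r6$p, 0.03125)
  r5 <- mcnemar_exact(rep(c(TRUE, FALSE), c(5, 2)), rep(FALSE, 7))
  expect_equal(r5$p, 0.0625)
  same <- mcnemar_exact(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  # general counts agree with binom.test's two-sided exact p
  set.seed(2)
  for (rep in 1:10) {
    a <- rbinom(30, 1, 0.6) == 1
    b <- rbinom(30, 1, 0.5) == 1
    got <- mcnemar_exact(a, b)
    if (!got$degenerate) {
      ref <- min(1, 2 * pbinom(min(got$b, got$c), got$b + got$c, 0.5))
      expect_equal(got$p, ref)
    }
  }
})

test_that("Pearson correlation matches the explicit-sums formula", {
  expect_equal(pearson_r(1:10, 1:10)$r, 1)
  expect_equal(pearson_r(1:10, -2 * (1:10) + 5)$r, -1)
  set.seed(14)
  x <- rnorm(10); y <- 0.6 * x + rnorm(10)
  got <- pearson_r(x, y)
  sx <- sum((x - mean(x))^2); sy <- sum((y - mean(y))^2)
  r_ref <- sum((x - mean(x)) * (y - mean(y))) / sqrt(sx * sy)
  expect_equal(got$r, r_ref, tolerance = 1e-12)
  t_ref <- r_ref * sqrt(8 / (1 - r_ref^2))
  expect_equal(got$p, 2 * pt(-abs(t_ref), 8), tolerance = 1e-12)
  expect_error(pearson_r(1:2, 1:2), "3")
})
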