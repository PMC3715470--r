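# Subject-level cohort simulation: two groups with per-parameter normal
# distributions matching published group means/SDs.

#' Default per-parameter group distributions
#'
#' Group means and SDs for the twelve imaging parameters of the reference
#' two-group comparison (controls n = 22 vs patients n = 14): anterior
#' cingulate cortical thickness (mm) and VBM gray-matter density per
#' hemisphere, and the four LM12-segment DTI parameters (FA dimensionless;
#' MD/aD/rD in 10^-3 mm^2/s) per hemisphere.
#'
#' @return data frame with columns `name`, `mean_control`, `sd_control`,
#'   `mean_patient`, `sd_patient`.
#' @export
reference_group_parameters <- function() {
  data.frame(
    name = c("thickness_lh", "thickness_rh", "vbm_lh", "vbm_rh",
             "fa_lm12_lh", "fa_lm12_rh", "md_lm12_lh", "md_lm12_rh",
             "ad_lm12_lh", "ad_lm12_rh", "rd_lm12_lh", "rd_lm12_rh"),
    mean_control = c(2.76, 2.72, 0.54, 0.55, 0.47, 0.39, 0.81, 0.85,
                     1.24, 1.21, 0.59, 0.67),
    sd_control   = c(0.21, 0.21, 0.041, 0.042, 0.034, 0.038, 0.036, 0.036,
                     0.055, 0.049, 0.041, 0.047),
    mean_patient = c(2.60, 2.66, 0.44, 0.47, 0.39, 0.33, 0.92, 0.96,
                     1.32, 1.32, 0.73, 0.82),
    sd_patient   = c(0.26, 0.31, 0.091, 0.070, 0.053, 0.047, 0.070, 0.12,
                     0.062, 0.11, 0.071, 0.12),
    stringsAsFactors = FALSE
  )
}

#' Cohort simulation specification
#'
#' Two-group cohort: per-parameter normal distributions per group plus
#' demographic covariates. Defaults reproduce the reference study
#' conditions: 22 controls vs 14 patients and the [reference_group_parameters()]
#' distributions; age ~ Normal(68, 8) truncated to `[38, 82]` years, sex ~
#' Bernoulli(0.5), education ~ Normal(10, 2) years.
#'
#' @param n_control,n_patient group sizes (>= 2).
#' @param parameters data frame as returned by [reference_group_parameters()].
#' @param age_mean,age_sd,age_range age distribution (years).
#' @param education_mean,education_sd education distribution (years).
#' @param seed master seed; each subject draws from its own substream
#'   derived from `(seed, group, subject index)`, so enlarging a group
#'   leaves existing subjects' rows unchanged.
#' @return class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 22, n_patient = 14,
                        parameters = reference_group_parameters(),
                        age_mean = 68, age_sd = 8, age_range = c(38, 82),
                        education_mean = 10, education_sd = 2,
                        seed = 1L) {
  stopifnot(n_control >= 2, n_patient >= 2)
  req <- c("name", "mean_control", "sd_control", "mean_patient", "sd_patient")
  if (!all(req %in% names(parameters))) {
    stop("parameters must have columns: ", paste(req, collapse = ", "))
  }
  if (any(parameters$sd_control <= 0) || any(parameters$sd_patient <= 0)) {
    stop("all parameter SDs must be positive")
  }
  structure(
    list(n_control = as.integer(n_control), n_patient = as.integer(n_patient),
         parameters = parameters, age_mean = age_mean, age_sd = age_sd,
         age_range = age_range, education_mean = education_mean,
         education_sd = education_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    v <- stats::rnorm(1, mean, sd)
    if (v >= lo && v <= hi) return(v)
  }
}

#' Simulate a two-group subject cohort
#'
#' Draw per-subject parameter values independently from the group-specific
#' normal distributions and covariates from their stated distributions.
#' Reproducible for a fixed seed; each subject has its own random substream,
#' so growing a group appends rows without changing existing ones.
#'
#' @param spec a [cohort_spec()].
#' @return class `cohort_table` (a data frame): `subject_id`, `group`
#'   (factor control/patient), `age`, `sex` (0/1), `education`, one column
#'   per parameter.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  pars <- spec$parameters
  draw_subject <- function(group_code, i) {
    sseed <- substream_seed(spec$seed, group_code * 500000L + i)
    with_seed(sseed, {
      age <- rtruncnorm1(spec$age_mean, spec$age_sd,
                         spec$age_range[1], spec$age_range[2])
      sex <- stats::rbinom(1, 1, 0.5)
      edu <- stats::rnorm(1, spec$education_mean, spec$education_sd)
      mu <- if (group_code == 0) pars$mean_control else pars$mean_patient
      sd <- if (group_code == 0) pars$sd_control else pars$sd_patient
      vals <- stats::rnorm(nrow(pars), mu, sd)
      c(age = age, sex = sex, education = edu,
        stats::setNames(vals, pars$name))
    })
  }
  rows_c <- t(vapply(seq_len(spec$n_control), function(i) draw_subject(0L, i),
                     numeric(3 + nrow(pars))))
  rows_p <- t(vapply(seq_len(spec$n_patient), function(i) draw_subject(1L, i),
                     numeric(3 + nrow(pars))))
  out <- data.frame(
    subject_id = c(sprintf("C%03d", seq_len(spec$n_control)),
                   sprintf("P%03d", seq_len(spec$n_patient))),
    group = factor(rep(c("control", "patient"),
                       c(spec$n_control, spec$n_patient)),
                   levels = c("control", "patient")),
    rbind(rows_c, rows_p),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Group summary of a cohort table
#'
#' Mean, SD and n per group for each parameter column.
#'
#' @param cohort a `cohort_table`.
#' @param parameters parameter column names; default: all columns after the
#'   covariates.
#' @return data frame with one row per parameter.
#' @export
group_summary <- function(cohort, parameters = NULL) {
  fixed <- c("subject_id", "group", "age", "sex", "education")
  if (is.null(parameters)) parameters <- setdiff(names(cohort), fixed)
  ctrl <- cohort$group == "control"
  data.frame(
    parameter = parameters,
    mean_control = vapply(parameters, function(p) mean(cohort[[p]][ctrl]), 0),
    sd_control = vapply(parameters, function(p) stats::sd(cohort[[p]][ctrl]), 0),
    n_control = sum(ctrl),
    mean_patient = vapply(parameters, function(p) mean(cohort[[p]][!ctrl]), 0),
    sd_patient = vapply(parameters, function(p) stats::sd(cohort[[p]][!ctrl]), 0),
    n_patient = sum(!ctrl),
    row.names = NULL
  )
}

#' Per-parameter discrimination table
#'
#' For each parameter: group means and SDs, average-SD Cohen's d, pooled
#' Student's t with two-tailed p and Bonferroni flag, and ROC AUC (oriented
#' so the patient group scores higher) with its Mann-Whitney significance.
#' The layout mirrors a published group-comparison table.
#'
#' @param cohort a `cohort_table`.
#' @param parameters parameter column names (default: all).
#' @param alpha_family Bonferroni-corrected significance level for t and
#'   AUC (default 0.05/6).
#' @return data frame, one row per parameter.
#' @export
discrimination_table <- function(cohort, parameters = NULL,
                                 alpha_family = 0.05 / 6) {
  gs <- group_summary(cohort, parameters)
  res <- lapply(seq_len(nrow(gs)), function(i) {
    p <- gs$parameter[i]
    x <- cohort[[p]][cohort$group == "control"]
    y <- cohort[[p]][cohort$group == "patient"]
    tt <- two_sample_t(x, y, alpha = alpha_family)
    rc <- roc_auc(cohort[[p]], cohort$group)
    data.frame(
      parameter = p,
      mean_control = gs$mean_control[i], sd_control = gs$sd_control[i],
      mean_patient = gs$mean_patient[i], sd_patient = gs$sd_patient[i],
      cohens_d = cohens_d(gs$mean_control[i], gs$sd_control[i],
                          gs$mean_patient[i], gs$sd_patient[i]),
      t = tt$t, p = tt$p, significant = tt$significant,
      auc = rc$auc, auc_p = rc$p, auc_significant = rc$p < alpha_family,
      auc_flipped = rc$flipped
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
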