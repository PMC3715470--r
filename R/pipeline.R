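# End-to-end pipeline: simulate -> fit -> track -> select -> profile -> stats.

#' Default pipeline configuration
#'
#' Study conditions of the reference design: 48 directions at b = 800
#' s/mm^2, 2 mm isotropic voxels over a 64^3 grid, FA threshold 0.2 and
#' angular threshold 45 degrees for tracking, 22 controls vs 14 patients,
#' control bundle FA 0.47 with the patients' anterior segment degraded to
#' 0.39 (between-subject SDs 0.034 / 0.053), and the [reference_group_parameters()]
#' cohort distributions.
#'
#' @param seed master seed; every stochastic stage draws from a named
#'   substream derived from it.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    phantom = list(
      grid_shape = c(64, 64, 64), voxel_size = 2, arc_radius = 36,
      bundle_radius = 3, fa_control = 0.47, fa_sd_control = 0.034,
      fa_patient_anterior = 0.39, fa_sd_patient = 0.053,
      md_inside = 0.81, background = 0.7, snr_b0 = 20,
      n_directions = 48, bvalue = 800
    ),
    cohort = list(n_control = 22, n_patient = 14),
    tracking = list(fa_threshold = 0.2, angle_threshold = 45, step = 1),
    profile = list(k_per_segment = 20, capture_radius = 10, parameter = "fa"),
    stats = list(alpha_family = 0.05 / 6,
                 covariates = c("age", "sex", "education"))
  ), class = "run_config")
}

#' Read / write a run configuration (JSON)
#' @param config a `run_config` list.
#' @param path JSON file.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "run_config")
}

# Per-subject imaging arm: phantom with a subject-specific anterior FA,
# tensor fit, tracking, ROI selection, profile, LM12 segment mean.
subject_imaging <- function(cfg, fa_anterior, fa_rest, subj_seed) {
  ph <- cfg$phantom
  sp <- phantom_spec(
    grid_shape = ph$grid_shape, voxel_size = ph$voxel_size,
    arc_radius = ph$arc_radius, bundle_radius = ph$bundle_radius,
    fa_inside = c(anterior = fa_anterior, dorsal = fa_rest,
                  posterior = fa_rest, ventral = fa_rest),
    md_inside = ph$md_inside, background = ph$background,
    snr_b0 = ph$snr_b0, seed = subj_seed
  )
  scheme <- make_gradient_scheme(ph$n_directions, ph$bvalue)
  phantom <- make_bundle_phantom(sp, scheme)
  maps <- scalar_maps(fit_tensor(phantom$study))
  bundle <- track(maps, cfg$tracking$fa_threshold, cfg$tracking$angle_threshold,
                  cfg$tracking$step)
  rois <- list(
    roi_from_mask(phantom$truth$tube_mask, "include", "bundle"),
    # NOT ROI through the gap of the C (midline analogue): excludes tracks
    # crossing the plane facing the opening, which none of the bundle does.
    roi_plane(1, dim(phantom$truth$tube_mask)[1] - 1,
              dim(phantom$truth$tube_mask), "exclude", "gap-plane")
  )
  sel <- select_bundle(bundle, rois)
  proj <- project_landmarks(sel, phantom$truth$landmarks_mm,
                            cfg$profile$capture_radius)
  prof <- normalize_and_average(sel, proj, maps, cfg$profile$parameter,
                                cfg$profile$k_per_segment)
  list(
    profile = prof,
    lm12 = segment_mean(prof, 1, 2),
    n_streamlines = length(bundle$streamlines),
    n_selected = length(sel$streamlines),
    n_retained = sum(proj$retained),
    n_excluded_projection = proj$n_excluded
  )
}

#' Run the full simulation-analysis pipeline
#'
#' Executes, in order: cohort simulation; the discrimination-statistics
#' battery; the per-subject imaging arm (C-bundle phantom with the
#' subject's anterior FA, tensor fit, FACT tracking, ROI selection,
#' landmark-normalized FA profile, LM12 segment mean); and parameter
#' recovery. All outputs are written under `out_dir` together with a
#' manifest (config, seed, package version, per-file MD5 checksums,
#' per-stage counts). A rerun with the same config and seed reproduces
#' identical tables and reports.
#'
#' @param config a [default_run_config()]-style list.
#' @param out_dir output directory (created).
#' @param stages subset of `c("cohort", "stats", "imaging", "recovery")`;
#'   later stages read cached outputs of earlier ones from `out_dir`.
#' @return invisibly, a list with the key results and output paths.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         stages = c("cohort", "stats", "imaging", "recovery")) {
  stopifnot(is.list(config), !is.null(config$seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- match.arg(stages, several.ok = TRUE)
  log <- list()
  res <- list(out_dir = out_dir)

  if ("cohort" %in% stages) {
    pars <- config$cohort$parameters
    pars <- if (is.null(pars)) reference_group_parameters() else as.data.frame(pars)
    cs <- cohort_spec(config$cohort$n_control, config$cohort$n_patient,
                      parameters = pars,
                      seed = substream_seed(config$seed, 1L))
    cohort <- simulate_cohort(cs)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    log$cohort <- list(n_control = cs$n_control, n_patient = cs$n_patient)
  }
  # downstream stages always work from the CSV artifact, so a cached rerun
  # of any later stage reproduces the same numbers bit for bit
  cohort <- read_cohort(file.path(out_dir, "cohort.csv"))
  res$cohort <- cohort

  if ("stats" %in% stages) {
    dti <- c("fa_lm12_lh", "md_lm12_lh", "ad_lm12_lh", "rd_lm12_lh",
             "fa_lm12_rh", "md_lm12_rh", "ad_lm12_rh", "rd_lm12_rh")
    cortical <- c("thickness_lh", "thickness_rh", "vbm_lh", "vbm_rh")
    disc <- discrimination_table(cohort, c(cortical, dti),
                                 config$stats$alpha_family)
    utils::write.csv(disc, file.path(out_dir, "discrimination.csv"),
                     row.names = FALSE)
    lgs <- lapply(c("fa_lm12_lh", "md_lm12_lh", "ad_lm12_lh", "rd_lm12_lh",
                    "vbm_lh", "thickness_lh"), function(p) {
      fit <- logistic_enter(cohort, p, config$stats$covariates)
      list(parameter = p, B = fit$coefficients[[p]],
           p = fit$p[[p]], percent_correct = fit$percent_correct,
           baseline_percent = fit$baseline_percent,
           separation_flag = fit$separation_flag)
    })
    correct <- lapply(c("fa_lm12_lh", "md_lm12_lh", "vbm_lh"), function(p) {
      logistic_enter(cohort, p, config$stats$covariates)$correct
    })
    names(correct) <- c("fa_lm12_lh", "md_lm12_lh", "vbm_lh")
    mcn <- list(
      md_vs_vbm = mcnemar_exact(correct$md_lm12_lh, correct$vbm_lh),
      fa_vs_vbm = mcnemar_exact(correct$fa_lm12_lh, correct$vbm_lh)
    )
    yd <- lapply(c(md = "md_lm12_lh", fa = "fa_lm12_lh"), function(p) {
      youden_cutoff(cohort[[p]], cohort$group)
    })
    cors <- lapply(c("fa_lm12_lh", "md_lm12_lh"), function(p) {
      ct <- pearson_r(cohort[[p]], cohort$vbm_lh)
      list(x = p, y = "vbm_lh", r = ct$r, p = ct$p)
    })
    demog <- list(
      age = mann_whitney(cohort$age[cohort$group == "control"],
                         cohort$age[cohort$group == "patient"])["p"],
      education = mann_whitney(cohort$education[cohort$group == "control"],
                               cohort$education[cohort$group == "patient"])["p"]
    )
    report <- list(
      discrimination = disc, logistic = lgs, mcnemar = mcn,
      youden = yd, correlations = cors, demographics = demog,
      alpha_family = config$stats$alpha_family
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$discrimination <- disc
    res$report <- report
    log$stats <- list(n_parameters = nrow(disc))
  }

  if ("imaging" %in% stages) {
    ph <- config$phantom
    groups <- rep(c("control", "patient"),
                  c(config$cohort$n_control, config$cohort$n_patient))
    n <- length(groups)
    lm12 <- numeric(n)
    fa_target <- numeric(n)
    profiles <- vector("list", n)
    counts <- vector("list", n)
    for (i in seq_len(n)) {
      sseed <- substream_seed(config$seed, 1000L + i)
      fa_target[i] <- with_seed(sseed, {
        if (groups[i] == "control") {
          rtruncnorm1(ph$fa_control, ph$fa_sd_control, 0.05, 0.95)
        } else {
          rtruncnorm1(ph$fa_patient_anterior, ph$fa_sd_patient, 0.05, 0.95)
        }
      })
      s <- subject_imaging(config, fa_target[i], ph$fa_control,
                           substream_seed(config$seed, 2000L + i))
      lm12[i] <- s$lm12
      profiles[[i]] <- s$profile
      counts[[i]] <- s[c("n_streamlines", "n_selected", "n_retained",
                         "n_excluded_projection")]
    }
    imaging <- data.frame(
      subject = seq_len(n), group = groups,
      fa_anterior_target = fa_target, fa_lm12_measured = lm12
    )
    utils::write.csv(imaging, file.path(out_dir, "imaging_lm12.csv"),
                     row.names = FALSE)
    gp_c <- group_profile(profiles[groups == "control"])
    gp_p <- group_profile(profiles[groups == "patient"])
    write_profile(gp_c, file.path(out_dir, "profile_control.csv"))
    write_profile(gp_p, file.path(out_dir, "profile_patient.csv"))
    res$imaging <- imaging
    res$profile_control <- gp_c
    res$profile_patient <- gp_p
    log$imaging <- list(
      n_subjects = n,
      mean_streamlines = mean(vapply(counts, `[[`, 0, "n_streamlines")),
      mean_selected = mean(vapply(counts, `[[`, 0, "n_selected")),
      mean_retained = mean(vapply(counts, `[[`, 0, "n_retained")),
      mean_excluded_projection =
        mean(vapply(counts, `[[`, 0, "n_excluded_projection"))
    )
  } else if ("recovery" %in% stages) {
    imaging <- utils::read.csv(file.path(out_dir, "imaging_lm12.csv"))
    res$imaging <- imaging
    res$profile_control <- read_profile(file.path(out_dir, "profile_control.csv"))
    res$profile_patient <- read_profile(file.path(out_dir, "profile_patient.csv"))
  }

  if ("recovery" %in% stages) {
    img <- res$imaging
    ph <- config$phantom
    rec <- list(
      fa_lm12_control_mean = mean(img$fa_lm12_measured[img$group == "control"]),
      fa_lm12_patient_mean = mean(img$fa_lm12_measured[img$group == "patient"]),
      fa_control_generating = ph$fa_control,
      fa_patient_generating = ph$fa_patient_anterior,
      transition_position = profile_transition(res$profile_patient,
                                               ph$fa_patient_anterior,
                                               ph$fa_control),
      transition_truth = 2.0
    )
    jsonlite::write_json(rec, file.path(out_dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$recovery <- rec
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("alongtract")),
    seed = config$seed,
    config = unclass(config),
    stages = stages,
    counts = log,
    checksums = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                                 pattern = "\\.(csv|json)$")))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

# Position where a group profile crosses the midpoint between the degraded
# (low) and intact (high) targets, searched upward from LM1: linear
# interpolation between the two straddling grid positions.
profile_transition <- function(profile, low, high) {
  mid <- (low + high) / 2
  u <- profile$position
  m <- profile$mean
  for (i in seq_len(length(u) - 1)) {
    if ((m[i] - mid) * (m[i + 1] - mid) <= 0 && m[i + 1] != m[i]) {
      return(u[i] + (mid - m[i]) / (m[i + 1] - m[i]) * (u[i + 1] - u[i]))
    }
  }
  NA_real_
}

#' Render the human-readable run report
#'
#' Produce the group mean +/- 1 SE profile plot (control and patient bands,
#' x-axis spanning landmarks 1 to 5) and return the discrimination table.
#' Requires a completed [run_pipeline()] directory with both group profiles.
#'
#' @param run_dir a [run_pipeline()] output directory.
#' @param plot_file output plot path (PDF; default `profile_plot.pdf` inside
#'   `run_dir`).
#' @return invisibly, a list with the discrimination table and plot path.
#' @export
render_report <- function(run_dir, plot_file = file.path(run_dir, "profile_plot.pdf")) {
  need <- c("discrimination.csv", "profile_control.csv", "profile_patient.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing)) {
    stop("missing stage outputs in ", run_dir, ": ",
         paste(missing, collapse = ", "),
         " (two completed groups are required)")
  }
  disc <- utils::read.csv(file.path(run_dir, "discrimination.csv"))
  pc <- read_profile(file.path(run_dir, "profile_control.csv"))
  pp <- read_profile(file.path(run_dir, "profile_patient.csv"))
  grDevices::pdf(plot_file, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  ylim <- range(pc$mean - pc$se, pc$mean + pc$se,
                pp$mean - pp$se, pp$mean + pp$se)
  plot(NA, xlim = c(1, 5), ylim = ylim, xlab = "landmark position",
       ylab = "FA", main = "Along-tract group profile (mean +/- 1 SE)")
  band <- function(p, col) {
    graphics::polygon(c(p$position, rev(p$position)),
                      c(p$mean - p$se, rev(p$mean + p$se)),
                      col = grDevices::adjustcolor(col, 0.3), border = NA)
    graphics::lines(p$position, p$mean, col = col, lwd = 2)
  }
  band(pc, "blue")
  band(pp, "red")
  graphics::legend("bottomright", c("controls", "patients"),
                   col = c("blue", "red"), lwd = 2, bty = "n")
  invisible(list(discrimination = disc, plot_file = plot_file))
}
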