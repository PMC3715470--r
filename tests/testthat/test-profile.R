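# A single straight streamline along x (0..100 mm), points every 1 mm,
# inside a 56^3-voxel grid of 2 mm voxels.
straight_line_bundle <- function() {
  pts <- cbind(seq(0, 100, by = 1), 40, 40)
  manual_bundle(list(pts), voxel_size = 2, dim = c(56, 56, 56))
}

test_that("landmarks on a straight line project to their arc positions", {
  b <- straight_line_bundle()
  lms <- cbind(c(5, 30, 55, 80, 95), 40, 40)
  proj <- project_landmarks(b, lms, capture_radius = 10)
  expect_true(proj$retained[1])
  expect_equal(proj$arc[1, ], c(5, 30, 55, 80, 95), tolerance = 0.5)

  # reversed streamline: canonical orientation restores the coordinates
  rev_b <- manual_bundle(list(b$streamlines[[1]][101:1, ]),
                         voxel_size = 2, dim = c(56, 56, 56))
  proj_r <- project_landmarks(rev_b, lms, capture_radius = 10)
  expect_true(proj_r$flipped[1])
  expect_equal(proj_r$arc[1, ], proj$arc[1, ], tolerance = 1e-9)

  # landmark beyond the capture radius leaves the streamline unmapped
  far <- lms
  far[3, 2] <- 40 + 30
  proj_f <- project_landmarks(b, far, capture_radius = 10)
  expect_true(is.na(proj_f$arc[1, 3]))
  expect_false(proj_f$retained[1])
})

test_that("the landmark warp anchors LMi exactly at position i", {
  # scalar field = x coordinate of the voxel center; sampling the profile of
  # a straight line must return the landmark x positions at integer grid
  # points and linear interpolation in between
  dim <- c(56, 56, 56)
  xmap <- array(rep((0:55) * 2, times = 56 * 56), dim)
  maps <- synthetic_maps(dim, fa_array = xmap)
  b <- straight_line_bundle()
  lms <- cbind(c(5, 30, 55, 80, 95), 40, 40)
  proj <- project_landmarks(b, lms, 10)
  prof <- normalize_and_average(b, proj, maps, "fa", k_per_segment = 20)
  at <- function(u) prof$mean[abs(prof$position - u) < 1e-9]
  for (i in 1:5) {
    expect_equal(at(i), c(5, 30, 55, 80, 95)[i], tolerance = 2) # one voxel
  }
  # mid-segment position maps near the arc midpoint of the segment
  expect_equal(at(1.5), (5 + 30) / 2, tolerance = 2)
})

test_that("constant fields give flat profiles with zero dispersion", {
  dim <- c(56, 56, 56)
  maps <- synthetic_maps(dim, fa_array = array(0.5, dim))
  b <- straight_line_bundle()
  lms <- cbind(c(5, 30, 55, 80, 95), 40, 40)
  proj <- project_landmarks(b, lms, 10)
  prof <- normalize_and_average(b, proj, maps, "fa", 20)
  expect_equal(prof$mean, rep(0.5, length(prof$position)))
  expect_equal(prof$se, rep(0, length(prof$position)))

  # duplication invariance: two identical streamlines, same profile, SE 0
  b2 <- manual_bundle(rep(b$streamlines, 2), voxel_size = 2, dim = dim)
  proj2 <- project_landmarks(b2, lms, 10)
  prof2 <- normalize_and_average(b2, proj2, maps, "fa", 20)
  expect_equal(prof2$mean, prof$mean)
  expect_equal(prof2$se, rep(0, length(prof2$position)))
})

test_that("profiles are invariant to streamline order and scale with the map", {
  ph <- small_phantom()
  maps <- scalar_maps(fit_tensor(ph$study))
  b <- track(maps, step = 1)
  proj <- project_landmarks(b, ph$truth$landmarks_mm, 10)
  prof <- normalize_and_average(b, proj, maps, "fa", 20)

  set.seed(3)
  perm <- sample(length(b$streamlines))
  bp <- b
  bp$streamlines <- b$streamlines[perm]
  bp$seed_vox <- b$seed_vox[perm, ]
  projp <- project_landmarks(bp, ph$truth$landmarks_mm, 10)
  profp <- normalize_and_average(bp, projp, maps, "fa", 20)
  expect_equal(profp$mean, prof$mean, tolerance = 1e-12)

  maps_scaled <- maps
  maps_scaled$fa <- maps$fa * 3
  prof3 <- normalize_and_average(b, proj, maps_scaled, "fa", 20)
  expect_equal(prof3$mean, 3 * prof$mean, tolerance = 1e-12)
  expect_equal(segment_mean(prof3, 1, 2), 3 * segment_mean(prof, 1, 2),
               tolerance = 1e-12)
})

test_that("segment means follow the per-position arithmetic", {
  p <- structure(list(position = c(1.2, 1.8), mean = c(0.4, 0.5),
                      se = c(0, 0), n_streamlines = 1, parameter = "fa"),
                 class = "tract_profile")
  expect_equal(segment_mean(p, 1, 2), 0.45)
  expect_error(segment_mean(p, 3, 4), "positions")
  expect_error(segment_mean(p, 2, 1))
  # LM12 mean equals the average of per-position means on [1, 2]
  ph <- small_phantom()
  maps <- scalar_maps(fit_tensor(ph$study))
  b <- track(maps, step = 1)
  proj <- project_landmarks(b, ph$truth$landmarks_mm, 10)
  prof <- normalize_and_average(b, proj, maps, "fa", 20)
  sel <- prof$position >= 1 & prof$position <= 2
  expect_equal(segment_mean(prof, 1, 2), mean(prof$mean[sel]),
               tolerance = 1e-12)
})

test_that("a degraded anterior segment appears as a localized profile step", {
  ph <- small_phantom(fa_anterior = 0.39, fa_rest = 0.47)
  maps <- scalar_maps(fit_tensor(ph$study))
  b <- track(maps, step = 1)
  proj <- project_landmarks(b, ph$truth$landmarks_mm, 10)
  expect_gte(mean(proj$retained[streamline_lengths(b) >=
                                  0.8 * ph$truth$arc_length]), 0.9)
  prof <- normalize_and_average(b, proj, maps, "fa", 20)
  inside_low <- prof$position >= 1 & prof$position <= 1.9
  inside_high <- prof$position >= 2.2 & prof$position <= 4.9
  expect_lt(max(abs(prof$mean[inside_low] - 0.39)), 0.01)
  expect_lt(max(abs(prof$mean[inside_high] - 0.47)), 0.01)
  expect_lt(abs(segment_mean(prof, 1, 2) - 0.39), 0.01)
  tr <- alongtract:::profile_transition(prof, 0.39, 0.47)
  expect_lt(abs(tr - 2), 1 / 20 + 1e-9) # within one profile grid step
})

test_that("doubling the sampling density barely moves a smooth segment mean", {
  ph <- small_phantom()
  maps <- scalar_maps(fit_tensor(ph$study))
  b <- track(maps, step = 1)
  proj <- project_landmarks(b, ph$truth$landmarks_mm, 10)
  m20 <- segment_mean(normalize_and_average(b, proj, maps, "fa", 20), 1, 2)
  m40 <- segment_mean(normalize_and_average(b, proj, maps, "fa", 40), 1, 2)
  expect_lt(abs(m40 - m20) / m20, 0.01)
})

test_that("trilinear sampling agrees with nearest-voxel on smooth fields", {
  dim <- c(56, 56, 56)
  maps <- synthetic_maps(dim, fa_array = array(0.5, dim))
  b <- straight_line_bundle()
  lms <- cbind(c(5, 30, 55, 80, 95), 40, 40)
  proj <- project_landmarks(b, lms, 10)
  pn <- normalize_and_average(b, proj, maps, "fa", 20, interp = "nearest")
  pt <- normalize_and_average(b, proj, maps, "fa", 20, interp = "trilinear")
  expect_equal(pn$mean, pt$mean, tolerance = 1e-12)
})

test_that("landmark snapping moves to the brightest in-slice FA voxel", {
  dim <- c(16, 16, 16)
  fa <- array(0, dim)
  fa[8, 8, 8] <- 0.3
  fa[9, 7, 8] <- 0.9 # brighter neighbor in the same z slice
  maps <- synthetic_maps(dim, fa_array = fa)
  lm <- rbind(c(8, 8, 8), c(8, 8, 8), c(8, 8, 8), c(8, 8, 8), c(8, 8, 8))
  snapped <- snap_landmarks_to_fa(lm, maps, axis = 3, window = 2)
  expect_equal(snapped[1, ], c(9, 7, 8))
})
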