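test_that("ulna and radius frames match their landmark definitions", {
  ## hand-computed cross products for a canonical landmark layout
  f <- build_ulna_frame(EL = c(1, 0, 0), EM = c(-1, 0, 0),
                        HU = c(0, 0, 0), US = c(0, -1, 0))
  expect_equal(f$origin, c(0, 0, 0))
  expect_equal(f$R[, 1], c(1, 0, 0))
  expect_equal(f$R[, 2], c(0, 0, -1))
  expect_equal(f$R[, 3], c(0, 1, 0))
  ## radius frame: z points from US toward EL by construction
  fr <- build_radius_frame(EL = c(0, 0, 0), US = c(0, 0, -1),
                           RS = c(0.1, -0.05, -1))
  expect_equal(as.numeric(fr$R[, 3]), c(0, 0, 1))
  expect_equal(fr$origin, c(0, 0, 0))
  ## degenerate input
  expect_error(build_ulna_frame(c(0, 0, 0), c(1, 1, 1), c(0, 0, 0),
                                c(2, 2, 2)), "degenerate|zero")
  ## scapula frame, direct evaluation
  fs <- build_scapula_frame(SN = c(0, 0, 0), AI = c(1, 0, 0),
                            TS = c(0, 1, 0))
  expect_equal(fs$R[, 2], c(0, 0, 1))   # plane normal
  expect_equal(fs$R[, 3], c(-1, 0, 0))
  expect_equal(fs$R[, 1], c(0, -1, 0))
})

test_that("frames are orthonormal and right-handed for random landmarks", {
  set.seed(11)
  for (i in 1:50) {
    pts <- matrix(rnorm(12, sd = 0.2), 4)
    f <- tryCatch(build_ulna_frame(pts[1, ], pts[2, ],
                                   (pts[1, ] + pts[2, ]) / 2, pts[4, ]),
                  error = function(e) NULL)
    if (is.null(f)) next
    expect_lt(max(abs(crossprod(f$R) - diag(3))), 1e-12)
    expect_equal(det(f$R), 1, tolerance = 1e-12)
  }
})

test_that("alignment rotations reproduce the stored model alignment", {
  m <- generic_model()
  R_h <- fk_pose(m, rep(0, 11))$humerus$R
  al <- alignment_rotations(R_h, m$reference$landmarks)
  expect_equal(al$Rf_hu, m$chain$Rf_hu, tolerance = 1e-12)
  expect_equal(al$Rf_ur, m$chain$Rf_ur, tolerance = 1e-12)
})

test_that("elbow rotations follow the hinge structure", {
  m <- generic_model()
  R_h <- fk_pose(m, rep(0, 11))$humerus$R
  r0 <- elbow_rotations(m, 0, 0, R_h)
  ## at zero elbow angles the alignment reproduces the reference frames
  expect_equal(r0$R_u, m$chain$R_ref$ulna, tolerance = 1e-12)
  expect_equal(r0$R_r, m$chain$R_ref$radius, tolerance = 1e-12)
  ## the ulna rotation is independent of pronation
  r1 <- elbow_rotations(m, 0.4, 0.0, R_h)
  r2 <- elbow_rotations(m, 0.4, 1.1, R_h)
  expect_equal(r1$R_u, r2$R_u)
  expect_false(isTRUE(all.equal(r1$R_r, r2$R_r)))
})

test_that("forward elbow map reproduces the reference and rigid lengths", {
  m <- generic_model()
  ref <- m$reference$landmarks
  pose <- fk_pose(m, rep(0, 11))
  fe <- forward_elbow(m, 0, 0, ref$EL, ref$EM, pose$humerus$R)
  expect_equal(fe$US, ref$US, tolerance = 1e-12)
  expect_equal(fe$RS, ref$RS, tolerance = 1e-12)
  ## |US - HU| is a rigid-body invariant over the elbow workspace
  HU <- (ref$EL + ref$EM) / 2
  d0 <- sqrt(sum((ref$US - HU)^2))
  for (q10 in seq(0, 2.2, length.out = 8)) {
    for (q11 in seq(-1.2, 1.2, length.out = 8)) {
      fe <- forward_elbow(m, q10, q11, ref$EL, ref$EM, pose$humerus$R)
      expect_lt(abs(sqrt(sum((fe$US - HU)^2)) - d0), 1e-10)
    }
  }
  ## US is unaffected by pronation
  a <- forward_elbow(m, 0.5, -1, ref$EL, ref$EM, pose$humerus$R)
  b <- forward_elbow(m, 0.5, 1, ref$EL, ref$EM, pose$humerus$R)
  expect_equal(a$US, b$US)
})

test_that("same-segment landmark distances are invariant under any q", {
  m <- generic_model()
  set.seed(5)
  lm0 <- fk_landmarks(m, rep(0, 11))
  pairs <- list(c("SC", "AC"), c("TS", "AI"), c("EL", "EM"),
                c("US", "OL"), c("RS", "RT"))
  for (i in 1:10) {
    q <- random_configuration(m)
    lm <- fk_landmarks(m, q)
    for (p in pairs) {
      d0 <- sqrt(sum((lm0[[p[1]]] - lm0[[p[2]]])^2))
      d <- sqrt(sum((lm[[p[1]]] - lm[[p[2]]])^2))
      expect_lt(abs(d - d0), 1e-9)
    }
  }
})

test_that("ribcage residuals match the closed form", {
  m <- generic_model()
  e <- m$ellipsoids$ts
  resid <- shoulderelbow:::ellipsoid_residual
  expect_equal(resid(e$center + c(e$axes[1], 0, 0), e), 0, tolerance = 1e-12)
  expect_equal(resid(e$center, e), -1)
  expect_equal(resid(e$center + c(2 * e$axes[1], 0, 0), e), 3,
               tolerance = 1e-12)
  ## reference pose is exactly on both surfaces
  expect_lt(max(abs(ribcage_residuals(m, m$reference$q))), 1e-10)
})

test_that("abduction trajectories satisfy the constraints and endpoints", {
  m <- generic_model()
  traj <- abduction_trajectory(m, 30, 120, n_steps = 11, duration = 2)
  phi <- apply(traj$q, 1, function(q) max(abs(ribcage_residuals(m, q))))
  expect_lt(max(phi), 1e-6)
  expect_equal(elevation_angle(m, traj$q[1, ]), 30, tolerance = 1e-6)
  expect_equal(elevation_angle(m, traj$q[11, ]), 120, tolerance = 1e-6)
  ## degenerate request: constant trajectory with zero velocity
  traj0 <- abduction_trajectory(m, 45, 45, n_steps = 5, duration = 1)
  expect_lt(max(abs(diff(traj0$q))), 1e-12)
  expect_lt(max(abs(traj0$qd)), 1e-12)
  expect_error(abduction_trajectory(m, 90, 30), "start")
})

test_that("landmark fitting inverts the forward map on noise-free data", {
  m <- generic_model()
  traj <- abduction_trajectory(m, 25, 110, n_steps = 8, duration = 2)
  markers <- export_marker_motion(m, traj, noise_sd = 0)
  fit <- fit_landmarks(m, markers)
  expect_identical(fit$skipped, integer(0))
  expect_lt(max(abs(fit$trajectory$q - traj$q)), 1e-6)
  expect_lt(max(fit$rms_residual), 1e-7)
  ## empty table -> empty trajectory
  empty <- fit_landmarks(m, markers[0, ])
  expect_length(empty$trajectory$times, 0L)
})

test_that("marker-fit residuals track the injected noise level", {
  m <- generic_model()
  traj <- abduction_trajectory(m, 30, 100, n_steps = 50, duration = 2)
  markers <- export_marker_motion(m, traj, noise_sd = 2e-3, seed = 7)
  fit <- fit_landmarks(m, markers)
  med <- stats::median(fit$rms_residual)
  expect_gt(med, 2e-3 * 0.8)
  expect_lt(med, 2e-3 * 1.2)
})
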