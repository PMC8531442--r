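test_that("BSIP predictive equations reproduce the printed arm masses", {
  male <- scale_bsip(subject_anthropometry("male", 1.86, 85.5, 0.38))
  expect_equal(male$arm_mass, 3.5055, tolerance = 1e-12)
  expect_equal(round(male$arm_mass, 2), 3.51)
  female <- scale_bsip(subject_anthropometry("female", 1.86, 85.5, 0.38))
  expect_equal(female$arm_mass, 2.9925, tolerance = 1e-12)
  expect_equal(round(female$arm_mass, 2), 2.99)
  ## humerus length fraction: 27/177 of stature for males
  expect_equal(male$length[["humerus"]], 27 / 177 * 1.86)
  ## transverse inertia follows (coef * length)^2 * mass
  expect_equal(male$I_t[["humerus"]],
               (0.315 * male$length[["humerus"]])^2 * male$mass[["humerus"]])
  ## forearm split 62/38
  expect_equal(male$mass[["ulna"]] / (male$mass[["ulna"]] + male$mass[["radius"]]),
               0.62)
  ## arm mass strictly increasing in body mass
  masses <- vapply(seq(50, 110, 10), function(w)
    scale_bsip(subject_anthropometry("male", 1.86, w, 0.38))$arm_mass,
    numeric(1))
  expect_true(all(diff(masses) > 0))
})

test_that("arm-mass sensitivity is 100/m_B percent per kilogram", {
  a <- subject_anthropometry("male", 1.86, 85.5, 0.38)
  expect_equal(arm_mass_sensitivity(a), 100 / 85.5, tolerance = 1e-6)
  expect_equal(round(arm_mass_sensitivity(a), 2), 1.17)
  a100 <- subject_anthropometry("male", 1.86, 100, 0.38)
  expect_equal(arm_mass_sensitivity(a100), 1, tolerance = 1e-6)
  f <- subject_anthropometry("female", 1.86, 85.5, 0.38)
  expect_equal(arm_mass_sensitivity(f), arm_mass_sensitivity(a),
               tolerance = 1e-9)
})

test_that("muscle percentage polynomials match the printed values", {
  bmi_generic <- 85.5 / 1.86^2
  male <- muscle_percentage(subject_anthropometry("male", 1.86, 85.5, 0.38))
  expect_equal(male, 1.09 - 0.0149 * bmi_generic + 0.00009 * bmi_generic^2)
  expect_equal(round(100 * male, 2), 77.67)
  female <- muscle_percentage(subject_anthropometry("female", 1.86, 85.5, 0.38))
  expect_equal(round(100 * female, 2), 67.36)
  ## male curve decreases over the physiological BMI range
  rm_vals <- vapply(seq(12, 40, 2), function(b)
    muscle_percentage(list(gender = "male", weight = b * 1.8^2, height = 1.8)),
    numeric(1))
  expect_true(all(diff(rm_vals) < 0))
  expect_warning(muscle_percentage(list(gender = "male", weight = 30,
                                        height = 1.8)), "BMI")
})

test_that("the anisotropic scaling matrix acts as specified", {
  m <- generic_model()
  g <- m$anthropometry_generic
  S <- scaling_matrix(subject_anthropometry("male", g$height, g$mass,
                                            g$shoulder_width), m)
  expect_equal(S, diag(3))
  S2 <- scaling_matrix(subject_anthropometry("male", 2.10, g$mass,
                                             g$shoulder_width), m)
  expect_equal(S2[3, 3], 2.10 / g$height)
  ## scaling maps the AI-AI span exactly to the subject width
  a <- subject_anthropometry("male", 1.70, 70, 0.45)
  S3 <- scaling_matrix(a, m)
  sm <- scale_morphology(m, S3)
  ai_y <- sm$reference$landmarks$AI[2]
  expect_equal(2 * abs(ai_y), 0.45 * 2 * abs(m$reference$landmarks$AI[2]) /
                 g$shoulder_width, tolerance = 1e-12)
})

test_that("ellipsoid dilation solves the 6th-degree polynomial exactly", {
  ## unit sphere, landmark at (2,0,0): the closed-form dilation is 1
  expect_equal(shoulderelbow:::solve_dilation(c(2, 0, 0), c(1, 1, 1)), 1,
               tolerance = 1e-12)
  ## impossible case: landmark inside the base ellipsoid
  expect_error(shoulderelbow:::solve_dilation(c(0.1, 0, 0), c(1, 1, 1)),
               "no positive real root")
  m <- generic_model()
  ## identity scaling reproduces the stored ellipsoids
  d <- dilate_ellipsoids(m, diag(3))
  expect_equal(d$delta_ts, m$ellipsoids$delta_ts, tolerance = 1e-12)
  expect_equal(d$ai$axes, m$ellipsoids$ai$axes, tolerance = 1e-12)
  ## random anisotropic scalings: residual by direct substitution
  set.seed(2)
  for (i in 1:20) {
    S <- diag(runif(3, 0.5, 2))
    dd <- dilate_ellipsoids(m, S)
    for (lm_e in list(c("TS", "ts"), c("AI", "ai"))) {
      p <- as.numeric(S %*% m$reference$landmarks[[lm_e[1]]])
      e <- dd[[lm_e[2]]]
      resid <- sum(((p - e$center) / e$axes)^2) - 1
      expect_lt(abs(resid), 1e-10)
    }
  }
})

test_that("glenoid angles are measured and adapted consistently", {
  m <- generic_model()
  ang <- glenoid_angles(m)
  expect_equal(ang[["alpha_gi"]], 7, tolerance = 1e-6)
  expect_equal(ang[["alpha_gv"]], 0, tolerance = 1e-6)
  ## adapt -> measure round trip
  m2 <- adapt_glenoid(m, alpha_gi = -7, alpha_gv = 3)
  ang2 <- glenoid_angles(m2)
  expect_equal(ang2[["alpha_gi"]], -7, tolerance = 1e-6)
  expect_equal(ang2[["alpha_gv"]], 3, tolerance = 1e-6)
  ## rotation isometry about SN
  d0 <- sqrt(sum((m$reference$landmarks$GC - m$reference$landmarks$SN)^2))
  d2 <- sqrt(sum((m2$reference$landmarks$GC - m2$reference$landmarks$SN)^2))
  expect_equal(d2, d0, tolerance = 1e-12)
  ## the cone axis tilts with the adapted inclination
  c0 <- build_stability_cone(m)
  c15 <- build_stability_cone(adapt_glenoid(m, alpha_gi = 15))
  tilt <- acos(sum(c0$axis * c15$axis)) * 180 / pi
  expect_equal(tilt, 8, tolerance = 0.2)
})

test_that("PCSA scaling applies the muscle-percentage ratio and overrides", {
  m <- generic_model()
  g <- generic_anthro()
  expect_equal(scale_pcsa(m, g)$muscles$deltoid_middle$pcsa,
               m$muscles$deltoid_middle$pcsa)
  ov <- subject_anthropometry("male", 1.86, 85.5,
                              m$anthropometry_generic$shoulder_width,
                              pcsa_overrides = c(supraspinatus = 10.42))
  m2 <- scale_pcsa(m, ov)
  expect_identical(m2$muscles$supraspinatus$pcsa, 10.42)
  ## halving a PCSA halves its maximum force
  expect_equal(max_forces(10.42, 25), max_forces(20.84, 25) / 2)
  expect_error(scale_pcsa(m, subject_anthropometry(
    "male", 1.86, 85.5, 0.38, pcsa_overrides = c(nonexistent = 3))),
    "unknown muscle")
})

test_that("subject scaling composes and preserves the constraints", {
  m <- generic_model()
  ## identity anthropometry leaves the model unchanged field-wise
  idt <- scale_subject(m, generic_anthro())
  expect_true(isTRUE(all.equal(unclass(m), unclass(idt$model),
                               tolerance = 1e-9)))
  ## a different subject: report carries the gender column and every factor
  a <- subject_anthropometry("female", 1.60, 60, 0.33, alpha_gi = 2)
  sc <- scale_subject(m, a)
  expect_s3_class(sc$report, "msm_scaling_report")
  expect_identical(sc$report$gender, "female")
  expect_equal(sc$report$bsip$arm_mass, (2.2 + 1.3) / 100 * 60)
  expect_equal(sc$report$glenoid[["alpha_gi"]], 2, tolerance = 1e-6)
  ## scaled reference pose still sits exactly on both ellipsoids
  expect_lt(max(abs(ribcage_residuals(sc$model, sc$model$reference$q))),
            1e-10)
  expect_identical(nrow(validate_model(sc$model)), 0L)
})
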