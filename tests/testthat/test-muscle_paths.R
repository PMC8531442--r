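test_that("sphere wrapping matches the taut-string closed form", {
  set.seed(21)
  n_wrapped <- 0L
  for (i in 1:100) {
    r <- runif(1, 0.02, 0.05)
    c0 <- rnorm(3, sd = 0.02)
    ## aim the chord near the center so that wrapping is frequent
    dir <- shoulderelbow:::unit3(rnorm(3))
    off <- rnorm(3, sd = r / 2)
    p1 <- c0 + off - dir * runif(1, 0.08, 0.15)
    p2 <- c0 + off + dir * runif(1, 0.08, 0.15)
    if (sqrt(sum((p1 - c0)^2)) <= r || sqrt(sum((p2 - c0)^2)) <= r) next
    w <- wrap_sphere(p1, p2, c0, r)
    chord <- sqrt(sum((p2 - p1)^2))
    if (!w$wrapped) {
      expect_equal(w$length, chord)
      next
    }
    n_wrapped <- n_wrapped + 1L
    d1 <- sqrt(sum((p1 - c0)^2)); d2 <- sqrt(sum((p2 - c0)^2))
    alpha <- acos(sum((p1 - c0) * (p2 - c0)) / (d1 * d2))
    L <- sqrt(d1^2 - r^2) + sqrt(d2^2 - r^2) +
      r * (alpha - acos(r / d1) - acos(r / d2))
    expect_equal(w$length, L, tolerance = 1e-12)
    expect_gte(w$length, chord)
  }
  expect_gt(n_wrapped, 30L)
})

test_that("wrapping engages exactly when the chord meets the obstacle", {
  ## shrinking the radius releases the wrap continuously
  p1 <- c(-0.08, -0.01, 0.02); p2 <- c(0.07, -0.015, -0.03)
  chord_dist <- local({
    dp <- p2 - p1
    tt <- -sum(p1 * dp) / sum(dp * dp)
    sqrt(sum((p1 + tt * dp)^2))
  })
  ls <- vapply(seq(0.035, 1e-4, length.out = 60), function(r) {
    w <- wrap_sphere(p1, p2, c(0, 0, 0), r)
    expect_identical(w$wrapped, r > chord_dist)
    w$length
  }, numeric(1))
  expect_true(all(diff(ls) <= 1e-12))
  expect_equal(ls[60], sqrt(sum((p2 - p1)^2)), tolerance = 1e-9)
})

test_that("cylinder wrapping reduces to the planar circle solution", {
  r <- 0.03
  p1 <- c(-0.08, -0.004, 0); p2 <- c(0.08, -0.004, 0)  # plane normal to axis
  wc <- wrap_cylinder(p1, p2, c(0, 0, 0), c(0, 0, 1), r, "right")
  wl <- wrap_cylinder(p1, p2, c(0, 0, 0), c(0, 0, 1), r, "left")
  expect_true(wc$wrapped && wl$wrapped)
  ## the shorter of the two fixed sides is the planar taut-string solution
  d <- sqrt(sum(p1^2))
  alpha <- acos(sum(p1 * p2) / d^2)
  L <- 2 * sqrt(d^2 - r^2) + r * (alpha - 2 * acos(r / d))
  expect_equal(min(wc$length, wl$length), L, tolerance = 1e-12)
  ## the two traversal senses differ and are both at least the chord
  expect_gt(abs(wl$length - wc$length), 1e-6)
  expect_gt(min(wc$length, wl$length), sqrt(sum((p2 - p1)^2)))
  ## parallel to the axis, clear of the surface: straight
  ws <- wrap_cylinder(c(0.05, 0, -0.1), c(0.05, 0, 0.1), c(0, 0, 0),
                      c(0, 0, 1), r, "right")
  expect_false(ws$wrapped)
  ## arc length grows with radius at fixed endpoints
  lens <- vapply(seq(0.01, 0.035, length.out = 10), function(rr)
    wrap_cylinder(p1, p2, c(0, 0, 0), c(0, 0, 1), rr, "right")$length,
    numeric(1))
  expect_true(all(diff(lens) > 0))
})

test_that("wrap endpoints inside the obstacle fail loudly", {
  expect_error(wrap_sphere(c(0.01, 0, 0), c(1, 0, 0), c(0, 0, 0), 0.05),
               "inside")
  m <- generic_model()
  bad <- m
  bad$wraps$humeral_head$radius <- 0.2   # swallows the deltoid insertion
  expect_error(muscle_path(bad, rep(0, 11), "deltoid_middle"),
               "deltoid_middle")
})

test_that("muscle paths are straight without vias/wraps and Lipschitz in q", {
  m <- generic_model()
  q0 <- rep(0, 11)
  lm <- fk_landmarks(m, q0)
  p <- muscle_path(m, q0, "teres_minor")   # no wrap, no via
  tm <- m$muscles$teres_minor
  pose <- fk_pose(m, q0)
  o <- shoulderelbow:::fk_point(pose, tm$origin$segment, tm$origin$point)
  i <- shoulderelbow:::fk_point(pose, tm$insertion$segment, tm$insertion$point)
  expect_equal(p$length, sqrt(sum((i - o)^2)), tolerance = 1e-12)
  ## length continuity along a dense sweep for every muscle
  traj <- abduction_trajectory(m, 20, 150, n_steps = 80, duration = 3.25)
  for (mn in c("deltoid_middle", "supraspinatus", "subscapularis",
               "triceps_long", "biceps_long")) {
    L <- vapply(seq_len(nrow(traj$q)), function(i)
      muscle_path(m, traj$q[i, ], mn)$length, numeric(1))
    dq <- apply(abs(diff(traj$q)), 1, max)
    expect_true(all(abs(diff(L)) <= 0.4 * dq + 1e-9))
  }
})

test_that("geometric and excursion moment arms agree", {
  m <- generic_model()
  set.seed(13)
  rel <- c()
  for (i in 1:6) {
    q <- random_configuration(m)
    We <- moment_arms(m, q, "excursion")
    Wg <- moment_arms(m, q, "geometric")
    rel <- c(rel, sqrt(sum((We - Wg)^2)) / sqrt(sum(We^2)))
    ## anatomical bound on every arm
    expect_lt(max(abs(We)), 0.15)
    ## non-spanned coordinates are exactly zero
    for (mn in colnames(We)) {
      ns <- setdiff(1:11, m$muscles[[mn]]$spanned)
      expect_identical(max(abs(We[ns, mn])), 0)
    }
  }
  expect_lt(max(rel), 0.01)
})

test_that("a straight muscle across a hinge has moment arm = lever distance", {
  ## brachialis is a straight humerus-to-ulna string: its elbow moment arm
  ## must equal the perpendicular offset of its line from the hinge axis
  m <- generic_model()
  q <- rep(0, 11); q[10] <- 0.7
  pose <- fk_pose(m, q)
  b <- m$muscles$brachialis
  o <- shoulderelbow:::fk_point(pose, "humerus", b$origin$point)
  i <- shoulderelbow:::fk_point(pose, "ulna", b$insertion$point)
  axis <- as.numeric(pose$ulna$R %*% c(1, 0, 0))
  ## unit tension pulls the insertion toward the origin; the elbow moment
  ## arm is axis . ((i - HU) x pull)
  pull <- (o - i) / sqrt(sum((o - i)^2))
  lever <- sum(axis * shoulderelbow:::cross3(i - pose$ulna$o, pull))
  W <- moment_arms(m, q, "excursion", muscles = "brachialis")
  expect_equal(as.numeric(W[10, "brachialis"]), lever, tolerance = 1e-5)
  Wg <- moment_arms(m, q, "geometric", muscles = "brachialis")
  expect_equal(as.numeric(Wg[10, "brachialis"]), lever, tolerance = 1e-9)
})
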