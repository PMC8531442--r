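test_that("forearm centers of mass follow the half-landmark construction", {
  m <- generic_model()
  set.seed(3)
  for (i in 1:5) {
    q <- random_configuration(m)
    lm <- fk_landmarks(m, q)
    cg <- segment_com(m, q)
    HU <- (lm$EL + lm$EM) / 2
    expect_equal(cg[, "ulna"], (HU + lm$US) / 2, tolerance = 1e-12)
  }
})

test_that("angular velocities satisfy the rotation-kinematics identity", {
  ## body-frame angular velocity must equal unskew(R^T dR/dt) for every
  ## segment; dR/dt estimated by central differences along q-dot
  m <- generic_model()
  set.seed(8)
  for (i in 1:4) {
    q <- random_configuration(m)
    qd <- rnorm(11, sd = 0.6)
    W <- angular_velocities(m, q, qd)
    eps <- 1e-7
    pose_p <- fk_pose(m, q + eps * qd)
    pose_m <- fk_pose(m, q - eps * qd)
    pose <- fk_pose(m, q)
    for (sn in colnames(W)) {
      dR <- (pose_p[[sn]]$R - pose_m[[sn]]$R) / (2 * eps)
      S <- t(pose[[sn]]$R) %*% dR
      w_fd <- c(S[3, 2], S[1, 3], S[2, 1])
      expect_equal(W[, sn], w_fd, tolerance = 1e-5)
    }
  }
  ## hinge recursion special cases
  W0 <- angular_velocities(m, rep(0, 11), rep(0, 11))
  expect_equal(max(abs(W0)), 0)
  qd <- rep(0, 11); qd[10] <- 1
  W1 <- angular_velocities(m, rep(0, 11), qd)
  expect_equal(W1[, "ulna"], c(1, 0, 0))
  expect_equal(max(abs(W1[, "humerus"])), 0)
})

test_that("the Lagrangian reduces to minus potential energy at rest", {
  m <- add_hand_inertia(generic_model())
  q <- short_trajectory()$q[4, ]
  L0 <- lagrangian(m, q, rep(0, 11))
  cg <- segment_com(m, q)
  V <- sum(vapply(colnames(cg), function(sn)
    m$segments[[sn]]$mass * m$options$gravity * cg[3, sn], numeric(1)))
  expect_equal(L0, -V, tolerance = 1e-12)
  ## doubling every mass doubles L at a fixed state
  m2 <- m
  for (sn in names(m2$segments)) {
    m2$segments[[sn]]$mass <- 2 * m2$segments[[sn]]$mass
    m2$segments[[sn]]$inertia_diag <- 2 * m2$segments[[sn]]$inertia_diag
  }
  qd <- rep(0.3, 11)
  expect_equal(lagrangian(m2, q, qd), 2 * lagrangian(m, q, qd),
               tolerance = 1e-12)
})

test_that("static inverse dynamics equals the gravity gradient", {
  ## independent oracle: numerical gradient of the potential energy built
  ## from segment masses and center-of-mass heights only
  m <- add_hand_inertia(generic_model())
  q <- short_trajectory()$q[8, ]   # abducted static posture
  n <- 7L
  traj <- shoulderelbow:::new_trajectory(seq(0, 0.6, length.out = n),
                                         matrix(rep(q, each = n), n))
  loads <- inverse_dynamics(m, traj)
  Vfun <- function(qq) {
    cg <- segment_com(m, qq)
    sum(vapply(colnames(cg), function(sn)
      m$segments[[sn]]$mass * m$options$gravity * cg[3, sn], numeric(1)))
  }
  h <- 1e-6
  gradV <- vapply(1:11, function(k) {
    qp <- q; qp[k] <- q[k] + h
    qm <- q; qm[k] <- q[k] - h
    (Vfun(qp) - Vfun(qm)) / (2 * h)
  }, numeric(1))
  i <- 4L  # interior frame
  expect_equal(loads$tau[i, ], gradV, tolerance = 1e-6 * max(1, max(abs(gradV))))
  ## inertial part vanishes for the static pose
  expect_lt(max(abs(loads$inertial[i, ])), 1e-6)
})

test_that("a locked-shoulder elbow swing matches the compound pendulum", {
  ## with q1..q9 frozen at reference, q10 swings the forearm about the
  ## (horizontal) epicondylar axis: tau_10 must equal the closed-form
  ## compound-pendulum torque I_a * acc + g * sum(m_i * r_i) * sin(angle)
  m <- add_hand_inertia(generic_model())
  ref <- m$reference$landmarks
  axis_dir <- (ref$EL - ref$HU); axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  expect_lt(abs(axis_dir[3]), 1e-9)   # horizontal hinge at reference
  n <- 81L
  times <- seq(0, 1.2, length.out = n)
  amp <- 0.6; om <- 2 * pi / 1.2
  th <- amp * (1 - cos(om * times)) / 2
  Q <- matrix(0, n, 11); Q[, 10] <- th
  traj <- shoulderelbow:::new_trajectory(times, Q)
  loads <- inverse_dynamics(m, traj)
  ## closed form from raw model fields
  HU <- ref$HU
  I_a <- 0; mr <- 0
  for (sn in c("ulna", "radius")) {
    seg <- m$segments[[sn]]
    R <- m$chain$R_ref[[sn]]
    pose <- fk_pose(m, rep(0, 11))
    cg <- pose[[sn]]$o + as.numeric(R %*% seg$com_local)
    d <- cg - HU
    d_perp2 <- sum(d^2) - sum(d * axis_dir)^2
    Ib <- R %*% (seg$inertia_diag * t(R))
    I_a <- I_a + as.numeric(t(axis_dir) %*% Ib %*% axis_dir) +
      seg$mass * d_perp2
    ## signed in-plane lever of the weight about the axis at q10 = 0
    mr <- mr + seg$mass * d
  }
  ## closed form: tau = I_a * thetadd + dV/dtheta, with
  ## dV/dtheta = g * (axis x R(theta) mr)_z  (mr = sum m_i d_i)
  for (i in c(21L, 41L, 61L)) {
    theta <- th[i]
    thdd <- amp / 2 * om^2 * cos(om * times[i])
    lever <- as.numeric(shoulderelbow:::rot_axis(axis_dir, theta) %*% mr)
    tau_closed <- I_a * thdd +
      m$options$gravity * shoulderelbow:::cross3(axis_dir, lever)[3]
    expect_equal(loads$tau[i, 10], tau_closed,
                 tolerance = 1e-3 * max(1, abs(tau_closed)))
  }
})

test_that("energy rate equals generalized-load power along a trajectory", {
  m <- add_hand_inertia(generic_model())
  traj <- abduction_trajectory(m, 20, 150, n_steps = 201, duration = 3.25)
  loads <- inverse_dynamics(m, traj)
  n <- length(traj$times)
  E <- vapply(seq_len(n), function(i) {
    q <- traj$q[i, ]; qd <- traj$qd[i, ]
    mv <- shoulderelbow:::mass_matrix(m, q)
    0.5 * sum(qd * (mv$M %*% qd)) + mv$V
  }, numeric(1))
  h <- traj$times[2] - traj$times[1]
  dEdt <- (E[3:n] - E[1:(n - 2)]) / (2 * h)
  P <- rowSums(loads$tau * traj$qd)[2:(n - 1)]
  scale <- max(abs(P), 1)
  expect_lt(max(abs(dEdt - P)) / scale, 1e-4)
})

test_that("generalized loads are stable under time-grid refinement", {
  m <- add_hand_inertia(generic_model())
  t1 <- abduction_trajectory(m, 40, 100, n_steps = 21, duration = 2)
  t2 <- abduction_trajectory(m, 40, 100, n_steps = 41, duration = 2)
  l1 <- inverse_dynamics(m, t1)
  l2 <- inverse_dynamics(m, t2)
  ## matched interior frame (same physical time)
  i1 <- 11L; i2 <- 21L
  expect_equal(t1$times[i1], t2$times[i2])
  expect_equal(l1$tau[i1, ], l2$tau[i2, ],
               tolerance = 2e-2 * max(abs(l2$tau[i2, ])))
})

test_that("hand merging follows the parallel-axis theorem", {
  m <- generic_model()
  ## zero-mass hand leaves the radius untouched
  m0 <- m; m0$hand$mass <- 0
  expect_equal(add_hand_inertia(m0)$segments$radius,
               m$segments$radius)
  ## point mass offset along x adds m d^2 to Iyy/Izz only
  m1 <- m
  m1$segments$radius$com_local <- c(0, 0, 0)
  m1$segments$radius$mass <- 1
  m1$segments$radius$inertia_diag <- c(0.01, 0.01, 0.01)
  m1$hand <- list(mass = 0.5, inertia_diag = c(0, 0, 0),
                  com_local = c(0.2, 0, 0), merged = FALSE)
  merged <- add_hand_inertia(m1)
  r <- merged$segments$radius
  expect_equal(r$mass, 1.5)
  expect_equal(r$com_local, c(0.5 * 0.2 / 1.5, 0, 0))
  ## composite inertia about the new center: both point masses contribute
  d1 <- 0 - r$com_local[1]; d2 <- 0.2 - r$com_local[1]
  expect_equal(r$inertia_diag[2], 0.01 + 1 * d1^2 + 0.5 * d2^2)
  expect_equal(r$inertia_diag[3], r$inertia_diag[2])
  expect_equal(r$inertia_diag[1], 0.01)   # no x-offset contribution
  ## idempotent
  expect_equal(add_hand_inertia(merged)$segments$radius, r)
})
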