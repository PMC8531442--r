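## Lagrangian dynamics of the five-segment chain.  The kinetic energy is
## assembled from exact point/angular Jacobians (instantaneous joint axes),
## so the Lagrangian is an explicit quadratic form in the generalized
## velocities; generalized loads are obtained by central finite differences
## of the Lagrangian in q and of the generalized momenta in time.

#' Merge the hand block into the radius segment
#'
#' Adds the hand point mass and inertia to the radius using the parallel-axis
#' theorem (diagonal form), shifting the combined center of mass to the
#' mass-weighted mean.  Idempotent: a model whose hand is already merged (or
#' has zero mass) is returned unchanged.
#'
#' @param model an `msm_model`
#' @return the model with hand inertia folded into the radius
#' @export
add_hand_inertia <- function(model) {
  h <- model$hand
  if (isTRUE(h$merged) || h$mass == 0) {
    model$hand$merged <- TRUE
    return(model)
  }
  r <- model$segments$radius
  m_tot <- r$mass + h$mass
  com <- (r$mass * r$com_local + h$mass * h$com_local) / m_tot
  shift <- function(I, m, d) I + m * (sum(d * d) - d * d)
  model$segments$radius$inertia_diag <-
    shift(r$inertia_diag, r$mass, r$com_local - com) +
    shift(h$inertia_diag, h$mass, h$com_local - com)
  model$segments$radius$mass <- m_tot
  model$segments$radius$com_local <- com
  model$hand$merged <- TRUE
  model
}

#' Segment centers of mass at a configuration
#'
#' The forearm centers follow the half-landmark construction
#' (`CG_u = R_u u_US/2 + HU`, `CG_r = R_r r_RS/2 + EL`); clavicle, scapula
#' and humerus use their stored local centers.
#'
#' @param model an `msm_model`
#' @param q 11-vector [rad]
#' @param pose optional precomputed [fk_pose()]
#' @return 3x5 matrix of thorax-frame positions (columns named by segment)
#' @export
segment_com <- function(model, q, pose = fk_pose(model, q)) {
  out <- vapply(SEGMENT_NAMES, function(sn)
    fk_point(pose, sn, model$segments[[sn]]$com_local), numeric(3L))
  colnames(out) <- SEGMENT_NAMES
  out
}

#' Body-frame angular velocities of the five segments
#'
#' Clavicle/scapula/humerus angular velocities are assembled from the
#' instantaneous joint axes; the ulna and radius follow the hinge recursions
#' `w_u = Rx(q10)^T Rf_hu^T w_h + [q10', 0, 0]^T` and
#' `w_r = Rz(q11)^T Rf_ur^T w_u + [0, 0, q11']^T`.
#'
#' @param model an `msm_model`
#' @param q,qd configuration and velocity 11-vectors
#' @return 3x5 matrix (columns named by segment), body-fixed frames
#' @export
angular_velocities <- function(model, q, qd) {
  pose <- fk_pose(model, q)
  ja <- joint_axes(model, q, pose)
  w_thorax <- function(coords) {
    w <- c(0, 0, 0)
    for (k in coords) w <- w + qd[k] * ja$axes[, k]
    w
  }
  w_c <- as.numeric(t(pose$clavicle$R) %*% w_thorax(1:3))
  w_s <- as.numeric(t(pose$scapula$R) %*% w_thorax(1:6))
  w_h <- as.numeric(t(pose$humerus$R) %*% w_thorax(1:9))
  w_u <- as.numeric(t(rot_x(q[10])) %*% t(model$chain$Rf_hu) %*% w_h) +
    c(qd[10], 0, 0)
  w_r <- as.numeric(t(rot_z(q[11])) %*% t(model$chain$Rf_ur) %*% w_u) +
    c(0, 0, qd[11])
  out <- cbind(w_c, w_s, w_h, w_u, w_r, deparse.level = 0)
  colnames(out) <- SEGMENT_NAMES
  out
}

#' Mass matrix and potential energy at a configuration
#' @keywords internal
mass_matrix <- function(model, q) {
  pose <- fk_pose(model, q)
  ja <- joint_axes(model, q, pose)
  M <- matrix(0, 11L, 11L)
  V <- 0
  g <- model$options$gravity
  for (sn in SEGMENT_NAMES) {
    seg <- model$segments[[sn]]
    coords <- segment_coords(sn)
    R <- pose[[sn]]$R
    cg <- fk_point(pose, sn, seg$com_local)
    Jv <- matrix(0, 3L, 11L)
    Jw <- matrix(0, 3L, 11L)
    for (k in coords) {
      Jv[, k] <- cross3(ja$axes[, k], cg - ja$centers[, k])
      Jw[, k] <- ja$axes[, k]
    }
    Iw <- R %*% (seg$inertia_diag * t(R))   # R diag(I) R^T
    M <- M + seg$mass * crossprod(Jv) + t(Jw) %*% Iw %*% Jw
    V <- V + seg$mass * g * cg[3L]
  }
  list(M = M, V = V)
}

#' Lagrangian of the full model
#'
#' `L = sum_seg (m CG'^T CG' + w^T I w)/2 - m g [0 0 1] CG`, summed over the
#' five segments (the hand, once merged, is part of the radius).
#'
#' @param model an `msm_model`
#' @param q,qd configuration and velocity 11-vectors
#' @return scalar [J]
#' @export
lagrangian <- function(model, q, qd) {
  mv <- mass_matrix(model, q)
  0.5 * sum(qd * (mv$M %*% qd)) - mv$V
}

#' Gravitational generalized loads (analytic)
#'
#' `dV/dq_k = sum_seg m g z . (a_k x (CG - c_k))`.
#' @keywords internal
gravity_loads <- function(model, q) {
  pose <- fk_pose(model, q)
  ja <- joint_axes(model, q, pose)
  g <- model$options$gravity
  tau <- numeric(11L)
  for (sn in SEGMENT_NAMES) {
    seg <- model$segments[[sn]]
    cg <- fk_point(pose, sn, seg$com_local)
    for (k in segment_coords(sn))
      tau[k] <- tau[k] +
        seg$mass * g * cross3(ja$axes[, k], cg - ja$centers[, k])[3L]
  }
  tau
}

#' Inverse dynamics along a trajectory
#'
#' Generalized loads `tau_k = d/dt(dL/dq'_k) - dL/dq_k` per frame.  The
#' velocity gradient of the Lagrangian is the exact generalized momentum
#' `M(q) q'`; the configuration gradient uses central differences with step
#' `dq`, and the momentum time derivative central differences on the frame
#' grid (one-sided at the ends).  Deterministic for fixed inputs.
#'
#' @param model an `msm_model` (call [add_hand_inertia()] first to include
#'   the hand)
#' @param traj an `msm_trajectory` with at least 3 frames
#' @param dq finite-difference step in q [rad]
#' @return list with matrices `tau`, `gravitational`, `inertial`
#'   (frames x 11) and the frame `times`
#' @export
inverse_dynamics <- function(model, traj, dq = 1e-6) {
  n <- length(traj$times)
  if (n < 3L) stop("trajectory shorter than the finite-difference stencil")
  h <- traj$times[2L] - traj$times[1L]
  P <- matrix(0, n, 11L)   # generalized momenta dL/dq'
  dLdq <- matrix(0, n, 11L)
  grav <- matrix(0, n, 11L)
  for (i in seq_len(n)) {
    q <- traj$q[i, ]; qd <- traj$qd[i, ]
    P[i, ] <- as.numeric(mass_matrix(model, q)$M %*% qd)
    for (k in 1:11) {
      qp <- q; qp[k] <- q[k] + dq
      qm <- q; qm[k] <- q[k] - dq
      dLdq[i, k] <- (lagrangian(model, qp, qd) -
                       lagrangian(model, qm, qd)) / (2 * dq)
    }
    grav[i, ] <- gravity_loads(model, q)
  }
  dPdt <- matrix(0, n, 11L)
  if (n >= 3L) {
    dPdt[2:(n - 1L), ] <- (P[3:n, , drop = FALSE] -
                             P[1:(n - 2L), , drop = FALSE]) / (2 * h)
    dPdt[1L, ] <- (-3 * P[1L, ] + 4 * P[2L, ] - P[3L, ]) / (2 * h)
    dPdt[n, ] <- (3 * P[n, ] - 4 * P[n - 1L, ] + P[n - 2L, ]) / (2 * h)
  }
  tau <- dPdt - dLdq
  list(times = traj$times, tau = tau, gravitational = grav,
       inertial = tau - grav)
}
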