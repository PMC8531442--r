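## Static-optimization load sharing: minimize the sum of squared muscle
## stresses subject to the 11 generalized-load equality constraints (muscle
## moment arms plus the two ribcage-constraint jacobian columns), force
## bounds, and a linearized glenohumeral stability cone on the joint
## reaction force.  Solved as a quadratic program.

#' Maximum muscle-string forces from PCSA and muscle stress
#'
#' Fick's law: `f_max = sigma * pcsa` elementwise.
#'
#' @param pcsa physiological cross-sectional areas [cm^2]
#' @param sigma maximum muscle stress [N/cm^2]
#' @return force bounds [N]
#' @export
max_forces <- function(pcsa, sigma) {
  if (length(pcsa) == 0L) return(numeric(0))
  if (any(pcsa <= 0) || any(sigma <= 0)) stop("pcsa and sigma must be > 0")
  sigma * pcsa
}

#' Build the glenohumeral stability cone
#'
#' Apex at the humeral-head (GH) center, axis toward the (possibly adapted)
#' glenoid center, aperture either configured or derived as the mean angular
#' extent of the four rim points seen from the apex.  The circular cone is
#' linearized into `facets` half-spaces `n_i . JRF <= 0` with
#' `n_i = cos(theta) u_i - sin(theta) d`.
#'
#' @param model an `msm_model`
#' @param q configuration (the cone moves with the scapula)
#' @param pose optional precomputed pose
#' @param facets number of half-spaces (default from model options)
#' @return list with `apex`, `axis`, `half_angle` [deg], `normals` (3 x m)
#' @export
build_stability_cone <- function(model, q = model$reference$q,
                                 pose = fk_pose(model, q),
                                 facets = model$options$cone_facets) {
  gp <- model$glenoid$points_local
  apex <- pose$humerus$o
  gc <- fk_point(pose, "scapula", gp$GC)
  d <- gc - apex
  if (norm3(d) < 1e-9) stop("degenerate glenoid: GC coincides with GH center")
  d <- unit3(d)
  if (!is.null(model$glenoid$cone_half_angle)) {
    theta <- model$glenoid$cone_half_angle * pi / 180
  } else {
    rim <- vapply(c("IG", "SG", "PG", "AG"), function(pn)
      fk_point(pose, "scapula", gp[[pn]]), numeric(3L))
    angs <- apply(rim, 2L, function(p) {
      v <- unit3(p - apex)
      acos(max(-1, min(1, sum(v * d))))
    })
    theta <- max(angs)   # full angular extent of the fossa
  }
  if (theta <= 0 || theta >= pi / 2)
    stop("degenerate stability cone aperture")
  aux <- if (abs(d[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- unit3(aux - sum(aux * d) * d)
  u2 <- cross3(d, u1)
  phis <- 2 * pi * (seq_len(facets) - 1L) / facets
  N <- vapply(phis, function(ph) {
    u <- cos(ph) * u1 + sin(ph) * u2
    cos(theta) * u - sin(theta) * d
  }, numeric(3L))
  list(apex = apex, axis = d, half_angle = theta * 180 / pi, normals = N)
}

## Straight-line ligament length at a configuration
ligament_length <- function(model, q, lig, pose = fk_pose(model, q)) {
  norm3(fk_point(pose, lig$insertion$segment, lig$insertion$point) -
          fk_point(pose, lig$origin$segment, lig$origin$point))
}

## Per-string path system at one configuration: excursion moment-arm matrix
## W (11 x n), JRF basis B (3 x n: unit-tension force on the arm segments),
## string PCSAs and names.  Passive ligaments (tension-only, negligible
## objective weight) are appended after the muscle strings.
muscle_system <- function(model, q, pose = fk_pose(model, q), dq = 1e-5) {
  mus <- model$muscles
  n_str <- vapply(mus, function(m) m$n_strings, integer(1L))
  idx_muscle <- rep(names(mus), n_str)
  n <- sum(n_str)
  arm_segs <- c("humerus", "ulna", "radius")
  Wm <- moment_arms(model, q, "excursion", dq = dq)
  B <- matrix(0, 3L, n)
  W <- matrix(0, 11L, n)
  pcsa_str <- numeric(n)
  j <- 0L
  for (mn in names(mus)) {
    m <- mus[[mn]]
    path <- muscle_path(model, q, mn, pose, detail = TRUE)
    F <- path_node_forces(path$points)
    b <- c(0, 0, 0)
    for (i in seq_len(nrow(path$points)))
      if (path$node_segment[i] %in% arm_segs) b <- b + F[i, ]
    for (s in seq_len(m$n_strings)) {
      j <- j + 1L
      W[, j] <- Wm[, mn] / 1     # identical string geometry
      B[, j] <- b
      pcsa_str[j] <- m$pcsa / m$n_strings
    }
  }
  ligs <- model$ligaments
  n_lig <- length(ligs)
  W_lig <- matrix(0, 11L, n_lig)
  lig_fmax <- numeric(n_lig)
  if (n_lig > 0L) {
    for (li in seq_len(n_lig)) {
      l <- ligs[[li]]
      for (k in l$spanned) {
        qp <- q; qp[k] <- q[k] + dq
        qm <- q; qm[k] <- q[k] - dq
        W_lig[k, li] <- -(ligament_length(model, qp, l) -
                            ligament_length(model, qm, l)) / (2 * dq)
      }
      lig_fmax[li] <- l$f_max
    }
  }
  list(W = cbind(W, W_lig), B = cbind(B, matrix(0, 3L, n_lig)),
       pcsa = pcsa_str, muscle = idx_muscle,
       n_muscle = n, lig_fmax = lig_fmax,
       ligament = names(ligs))
}

#' Solve one load-sharing frame
#'
#' Minimizes `f~^T P f~` (P = diag(1/pcsa^2) on the muscle block, a tiny
#' regularization weight on the two constraint multipliers) subject to
#' `[W  dPhi_TS/dq  dPhi_AI/dq] f~ = tau`, `0 <= f~ <= f~_max`, and the
#' linearized stability constraint on the joint reaction force.
#'
#' @param model an `msm_model`
#' @param tau generalized loads (11-vector) [N m]
#' @param sys muscle system from `muscle_system()` (moment arms, JRF basis)
#' @param Jc 11x2 constraint jacobian
#' @param cone stability cone from [build_stability_cone()]; `NULL` disables
#'   the stability constraint
#' @param jrf_const constant part of the JRF (gravity/inertia of the arm) [N]
#' @return list of class `msm_loadsharing`: `f` (string forces), `lambda_ts`,
#'   `lambda_ai`, `objective`, `eq_residual`, `status`, `active` bound flags,
#'   `jrf` (3-vector) and `P`, plus the assembled QP blocks for diagnostics
#' @export
solve_frame <- function(model, tau, sys, Jc, cone = NULL,
                        jrf_const = c(0, 0, 0)) {
  nf <- ncol(sys$W)           # muscle strings + passive ligaments
  nm <- sys$n_muscle
  n_lig <- nf - nm
  Aeq <- cbind(sys$W, Jc)
  nv <- nf + 2L
  Pd <- c(1 / sys$pcsa^2, rep(model$options$lambda_p, n_lig + 2L))
  lb <- rep(0, nv)
  ub <- c(max_forces(sys$pcsa, model$options$sigma), sys$lig_fmax,
          rep(model$options$lambda_ub, 2L))
  G <- NULL; h <- NULL
  if (!is.null(cone)) {
    G <- cbind(t(cone$normals) %*% sys$B, matrix(0, ncol(cone$normals), 2L))
    h <- as.numeric(-t(cone$normals) %*% jrf_const)
  }
  res <- tryCatch(
    pracma::quadprog(diag(2 * Pd), rep(0, nv), A = G, b = h,
                     Aeq = Aeq, beq = tau, lb = lb, ub = ub),
    error = function(e) list(xmin = rep(NA_real_, nv), eflag = -99L,
                             msg = conditionMessage(e)))
  x <- res$xmin
  status <- if (identical(res$eflag, 1) || identical(res$eflag, 1L))
    "optimal" else paste0("failed(", res$eflag, ")")
  worst <- NA_character_
  if (!startsWith(status, "optimal") && !anyNA(x)) {
    viol <- c(eq = max(abs(Aeq %*% x - tau)),
              cone = if (is.null(G)) 0 else max(G %*% x - h),
              bounds = max(c(lb - x, x - ub)))
    worst <- names(which.max(viol))
  }
  f <- x[seq_len(nm)]
  names(f) <- sys$muscle
  f_lig <- if (n_lig > 0L) x[nm + seq_len(n_lig)] else numeric(0)
  names(f_lig) <- sys$ligament
  jrf <- as.numeric(sys$B %*% x[seq_len(nf)] + jrf_const)
  structure(list(
    f = f, f_lig = f_lig,
    lambda_ts = x[nf + 1L], lambda_ai = x[nf + 2L],
    objective = sum(Pd * x^2),
    eq_residual = if (anyNA(x)) NA_real_ else max(abs(Aeq %*% x - tau)),
    status = status, most_violated = worst,
    active = list(lower = !anyNA(x) & x < lb + 1e-7,
                  upper = !anyNA(x) & x > ub - 1e-7),
    jrf = jrf,
    qp = list(P = Pd, Aeq = Aeq, beq = tau, G = G, h = h, lb = lb, ub = ub,
              x = x)), class = "msm_loadsharing")
}

#' Stationarity (KKT) residual of a load-sharing solution
#'
#' Reconstructs nonnegative multipliers for the active inequality/bound set
#' and free multipliers for the equalities by nonnegative least squares; the
#' returned value is the norm of the best-achievable stationarity residual,
#' scaled by the gradient norm.
#'
#' @param sol an `msm_loadsharing` solution
#' @param tol activity tolerance
#' @return relative stationarity residual
#' @export
kkt_residual <- function(sol, tol = 1e-6) {
  qp <- sol$qp
  x <- qp$x
  g <- 2 * qp$P * x                       # objective gradient
  cols <- t(qp$Aeq)                       # free multipliers: +/- columns
  A <- cbind(cols, -cols)
  if (!is.null(qp$G)) {
    act <- which(qp$G %*% x > qp$h - tol * (1 + abs(qp$h)))
    if (length(act) > 0L) A <- cbind(A, t(qp$G[act, , drop = FALSE]))
  }
  lo_act <- which(x < qp$lb + tol * (1 + qp$ub * 0 + 1))
  up_act <- which(x > qp$ub - tol * (1 + qp$ub))
  n <- length(x)
  if (length(lo_act) > 0L)
    A <- cbind(A, -diag(n)[, lo_act, drop = FALSE])
  if (length(up_act) > 0L)
    A <- cbind(A, diag(n)[, up_act, drop = FALSE])
  fit <- pracma::lsqnonneg(A, -g)
  sqrt(sum((A %*% fit$x + g)^2)) / max(1, sqrt(sum(g^2)))
}

#' Joint reaction force at the glenohumeral joint
#'
#' Force balance of the humerus+forearm subsystem: the JRF transmitted to
#' the glenoid is the sum of all muscle point loads applied to the arm
#' segments plus the arm's weight, minus its inertial loads.
#'
#' @param model an `msm_model`
#' @param q configuration
#' @param solution an `msm_loadsharing` solution (string forces)
#' @param accel optional 3x3 matrix of arm-segment center-of-mass
#'   accelerations (columns humerus, ulna, radius) [m/s^2]
#' @return JRF 3-vector [N] (thorax frame, force on the glenoid)
#' @export
joint_reaction_force <- function(model, q, solution, accel = NULL) {
  sys <- muscle_system(model, q)
  as.numeric(sys$B[, seq_along(solution$f), drop = FALSE] %*% solution$f +
               jrf_constant(model, q, accel))
}

#' Gravity/inertia part of the JRF
#' @keywords internal
jrf_constant <- function(model, q, accel = NULL) {
  g <- model$options$gravity
  arm <- c("humerus", "ulna", "radius")
  out <- c(0, 0, 0)
  for (i in seq_along(arm)) {
    m <- model$segments[[arm[i]]]$mass
    out <- out + m * c(0, 0, -g)
    if (!is.null(accel)) out <- out - m * accel[, i]
  }
  out
}

#' Simulate muscle forces and JRF along a trajectory
#'
#' Full pipeline per frame: inverse dynamics, excursion moment arms,
#' constraint jacobians, stability cone, load-sharing QP, and joint reaction
#' force (including the arm's linear inertial loads).
#'
#' @param model an `msm_model` (hand merged automatically)
#' @param traj an `msm_trajectory` (e.g. from [abduction_trajectory()])
#' @param use_cone enable the stability constraint (default TRUE)
#' @return list with `frames` (a data.frame: time, elevation [deg], per-frame
#'   QP status, |JRF| [N] and %BW, JRF components, lambda multipliers,
#'   objective) and `solutions` (list of `msm_loadsharing`)
#' @export
simulate_abduction <- function(model, traj, use_cone = TRUE) {
  model <- add_hand_inertia(model)
  n <- length(traj$times)
  loads <- inverse_dynamics(model, traj)
  ## arm-segment CG accelerations by central differences
  cg <- array(0, c(3L, 5L, n))
  for (i in seq_len(n)) cg[, , i] <- segment_com(model, traj$q[i, ])
  acc <- array(0, c(3L, 5L, n))
  if (n >= 3L) {
    h <- traj$times[2L] - traj$times[1L]
    acc[, , 2:(n - 1L)] <- (cg[, , 3:n] - 2 * cg[, , 2:(n - 1L)] +
                              cg[, , 1:(n - 2L)]) / h^2
    acc[, , 1L] <- acc[, , 2L]; acc[, , n] <- acc[, , n - 1L]
  }
  bw <- model$anthropometry_generic$mass * model$options$gravity
  sols <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    q <- traj$q[i, ]
    pose <- fk_pose(model, q)
    sys <- muscle_system(model, q, pose)
    Jc <- constraint_jacobian(model, q)
    cone <- if (use_cone) build_stability_cone(model, q, pose) else NULL
    c0 <- jrf_constant(model, q, acc[, 3:5, i])
    sol <- solve_frame(model, loads$tau[i, ], sys, Jc, cone, c0)
    if (!startsWith(sol$status, "optimal"))
      warning("load sharing not optimal at frame ", i, " (", sol$status,
              "; most violated: ", sol$most_violated, ")")
    sols[[i]] <- sol
    rows[[i]] <- data.frame(
      time = traj$times[i],
      elevation = elevation_angle(model, q),
      status = sol$status,
      jrf_x = sol$jrf[1L], jrf_y = sol$jrf[2L], jrf_z = sol$jrf[3L],
      jrf = norm3(sol$jrf), jrf_pct_bw = norm3(sol$jrf) / bw * 100,
      lambda_ts = sol$lambda_ts, lambda_ai = sol$lambda_ai,
      objective = sol$objective, eq_residual = sol$eq_residual,
      stringsAsFactors = FALSE)
  }
  list(frames = do.call(rbind, rows), solutions = sols, loads = loads)
}
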