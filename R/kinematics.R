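## Kinematics of the 11-coordinate thorax-clavicle-scapula-humerus-ulna-radius
## chain.  Coordinates:
##   q1..q3   sternoclavicular ball joint (intrinsic Euler, default z-y-x)
##   q4..q6   acromioclavicular ball joint
##   q7..q9   glenohumeral ball joint
##   q10      elbow flexion/extension (hinge about the ulna x axis)
##   q11      forearm pronation/supination (hinge about the radius z axis)
## All q are zero in the stored reference pose; fixed alignment rotations make
## the reference pose exact (a deliberate deviation from strict ISB frame
## alignment, which would force non-physiological forearm configurations).

#' Build the ulna bone-fixed frame from elbow/wrist landmarks
#'
#' Origin HU (midpoint of the epicondyles); x toward the lateral epicondyle;
#' y normal to the plane of US, EL, EM; z completes the right-handed triad.
#'
#' @param EL,EM,HU,US landmark positions (3-vectors, thorax frame) [m]
#' @return a frame: list with `origin` (3-vector) and `R` (3x3 rotation whose
#'   columns are the frame axes)
#' @export
build_ulna_frame <- function(EL, EM, HU, US) {
  x <- EL - HU
  if (norm3(x) < 1e-9) stop("degenerate geometry: EL coincides with HU")
  x <- x / norm3(x)
  yraw <- cross3(US - EL, EM - EL)
  if (norm3(yraw) < 1e-12)
    stop("degenerate geometry: US, EL, EM are collinear")
  y <- yraw / norm3(yraw)
  z <- cross3(x, y)
  list(origin = HU, R = cbind(x, y, z, deparse.level = 0))
}

#' Build the radius bone-fixed frame
#'
#' Origin EL; z from the ulnar styloid toward the lateral epicondyle; y normal
#' to the plane of EL, RS, US; x completes the triad.
#'
#' @param EL,US,RS landmark positions (3-vectors, thorax frame) [m]
#' @return a frame (list `origin`, `R`)
#' @export
build_radius_frame <- function(EL, US, RS) {
  z <- EL - US
  if (norm3(z) < 1e-9) stop("degenerate geometry: EL coincides with US")
  z <- z / norm3(z)
  yraw <- cross3(EL - RS, RS - US)
  if (norm3(yraw) < 1e-12)
    stop("degenerate geometry: EL, RS, US are collinear")
  y <- yraw / norm3(yraw)
  x <- cross3(y, z)
  list(origin = EL, R = cbind(x, y, z, deparse.level = 0))
}

#' Build the scapula bone-fixed frame
#'
#' Origin at the spino-glenoid notch SN; y normal to the scapula plane
#' (through SN, AI, TS); z in the scapula plane, perpendicular to SN-TS;
#' x completes the triad.  This frame defines the planes in which glenoid
#' inclination and version are measured.
#'
#' @param SN,AI,TS landmark positions (3-vectors, thorax frame) [m]
#' @return a frame (list `origin`, `R`)
#' @export
build_scapula_frame <- function(SN, AI, TS) {
  yraw <- cross3(SN - AI, SN - TS)
  if (norm3(yraw) < 1e-12)
    stop("degenerate geometry: SN, AI, TS are collinear")
  y <- yraw / norm3(yraw)
  z <- cross3(SN - TS, y)
  z <- z / norm3(z)
  x <- cross3(y, z)
  list(origin = SN, R = cbind(x, y, z, deparse.level = 0))
}

#' Elementary elbow rotations and their composition
#'
#' Returns the thorax rotations of the ulna and radius for given elbow
#' coordinates and a humerus rotation:
#' `R_u = R_h Rf_hu Rx(q10)`, `R_r = R_u Rf_ur Rz(q11)`.
#'
#' @param model an `msm_model` (provides the fixed alignment rotations)
#' @param q10,q11 elbow flexion and pronation angles [rad]
#' @param R_h 3x3 thorax rotation of the humerus
#' @return list with `R_u`, `R_r`
#' @export
elbow_rotations <- function(model, q10, q11, R_h) {
  R_u <- R_h %*% model$chain$Rf_hu %*% rot_x(q10)
  R_r <- R_u %*% model$chain$Rf_ur %*% rot_z(q11)
  list(R_u = R_u, R_r = R_r)
}

#' Fixed alignment rotations from reference-pose frames
#'
#' Computes `Rf_hu = (tR_h)^T tR_u` and `Rf_ur = (tR_u)^T tR_r` from the
#' landmark positions of a reference pose.  Once computed they remain fixed,
#' so the elbow coordinates are measured relative to that pose (the fixed
#' carrying angle is absorbed here).
#'
#' @param R_h thorax rotation of the humerus at the reference pose
#' @param landmarks named list with thorax-frame `EL`, `EM`, `HU`, `US`, `RS`
#' @return list with `Rf_hu`, `Rf_ur`
#' @export
alignment_rotations <- function(R_h, landmarks) {
  fu <- build_ulna_frame(landmarks$EL, landmarks$EM, landmarks$HU, landmarks$US)
  fr <- build_radius_frame(landmarks$EL, landmarks$US, landmarks$RS)
  list(Rf_hu = t(R_h) %*% fu$R, Rf_ur = t(fu$R) %*% fr$R)
}

## ---------------------------------------------------------------------------
## Chain forward kinematics

#' Segment poses for a joint configuration
#'
#' @param model an `msm_model`
#' @param q numeric 11-vector [rad]
#' @return list with per-segment `R` (3x3) and `o` (origin, 3-vector), plus
#'   the joint centers and the elbow landmarks `EL`, `EM`, `HU`
#' @export
fk_pose <- function(model, q) {
  ch <- model$chain
  eu <- ch$euler
  Rc <- ch$R_ref$clavicle %*% rot_seq(eu$sc, q[1:3])
  Rs <- Rc %*% ch$C_cs %*% rot_seq(eu$ac, q[4:6])
  Rh <- Rs %*% ch$C_sh %*% rot_seq(eu$gh, q[7:9])
  o_c <- ch$sc_pos
  o_s <- o_c + as.numeric(Rc %*% ch$ac_local)       # AC joint center
  o_h <- o_s + as.numeric(Rs %*% ch$gh_local)       # GH joint center
  hl <- model$segments$humerus$landmarks_local
  EL <- o_h + as.numeric(Rh %*% hl$EL)
  EM <- o_h + as.numeric(Rh %*% hl$EM)
  HU <- (EL + EM) / 2
  Ru <- Rh %*% ch$Rf_hu %*% rot_x(q[10])
  Rr <- Ru %*% ch$Rf_ur %*% rot_z(q[11])
  list(clavicle = list(R = Rc, o = o_c),
       scapula = list(R = Rs, o = o_s),
       humerus = list(R = Rh, o = o_h),
       ulna = list(R = Ru, o = HU),
       radius = list(R = Rr, o = EL),
       EL = EL, EM = EM, HU = HU)
}

#' Thorax-frame position of a point fixed on a segment
#' @param pose result of [fk_pose()]
#' @param segment segment name or "thorax"
#' @param x_local local coordinates (3-vector) [m]
#' @keywords internal
fk_point <- function(pose, segment, x_local) {
  if (segment == "thorax") return(as.numeric(x_local))
  p <- pose[[segment]]
  p$o + as.numeric(p$R %*% x_local)
}

#' All landmark positions at a configuration
#'
#' @param model an `msm_model`
#' @param q 11-vector [rad]
#' @return named list of thorax-frame 3-vectors (segment landmarks followed by
#'   thorax landmarks)
#' @export
fk_landmarks <- function(model, q) {
  pose <- fk_pose(model, q)
  out <- list()
  for (sn in SEGMENT_NAMES) {
    lms <- model$segments[[sn]]$landmarks_local
    for (ln in names(lms)) out[[ln]] <- fk_point(pose, sn, lms[[ln]])
  }
  c(out, model$thorax$landmarks)
}

#' Instantaneous joint axes and centers of the 11 coordinates
#'
#' For each generalized coordinate returns its instantaneous rotation axis in
#' the thorax frame and a point on that axis, giving the exact point Jacobian
#' `dp/dq_k = a_k x (p - c_k)` for points on segments distal to coordinate k.
#'
#' @param model an `msm_model`
#' @param q 11-vector [rad]
#' @param pose optional precomputed [fk_pose()] result
#' @return list with `axes` (3x11), `centers` (3x11), and `first_coord`,
#'   a named vector giving the first coordinate each segment depends on
#' @export
joint_axes <- function(model, q, pose = fk_pose(model, q)) {
  ch <- model$chain
  eu <- ch$euler
  euler_axes <- function(pre, seq, angles) {
    letters_ <- strsplit(seq, "")[[1L]]
    A <- matrix(0, 3L, 3L)
    R <- pre
    for (i in 1:3) {
      A[, i] <- R %*% switch(letters_[i], x = c(1, 0, 0), y = c(0, 1, 0),
                             z = c(0, 0, 1))
      R <- R %*% switch(letters_[i], x = rot_x(angles[i]),
                        y = rot_y(angles[i]), z = rot_z(angles[i]))
    }
    A
  }
  axes <- matrix(0, 3L, 11L)
  centers <- matrix(0, 3L, 11L)
  axes[, 1:3] <- euler_axes(ch$R_ref$clavicle, eu$sc, q[1:3])
  centers[, 1:3] <- ch$sc_pos
  axes[, 4:6] <- euler_axes(pose$clavicle$R %*% ch$C_cs, eu$ac, q[4:6])
  centers[, 4:6] <- pose$scapula$o
  axes[, 7:9] <- euler_axes(pose$scapula$R %*% ch$C_sh, eu$gh, q[7:9])
  centers[, 7:9] <- pose$humerus$o
  axes[, 10] <- pose$ulna$R %*% c(1, 0, 0)
  centers[, 10] <- pose$ulna$o
  axes[, 11] <- pose$radius$R %*% c(0, 0, 1)
  centers[, 11] <- pose$radius$o
  list(axes = axes, centers = centers,
       first_coord = c(clavicle = 1L, scapula = 4L, humerus = 7L,
                       ulna = 10L, radius = 11L))
}

#' Coordinates a segment depends on
#' @keywords internal
segment_coords <- function(segment) {
  switch(segment,
         clavicle = 1:3, scapula = 1:6, humerus = 1:9, ulna = 1:10,
         radius = 1:11, thorax = integer(0))
}

#' Elbow forward kinematics map
#'
#' Positions of the ulnar and radial styloid processes for given elbow angles
#' and humerus placement: `US = R_u u_US + HU`, `RS = R_r r_RS + EL` with
#' `HU = (EL + EM)/2`.
#'
#' @param model an `msm_model`
#' @param q10,q11 elbow angles [rad]
#' @param EL,EM epicondyle positions (thorax frame) [m]
#' @param R_h thorax rotation of the humerus
#' @return list with `US`, `RS` (3-vectors)
#' @export
forward_elbow <- function(model, q10, q11, EL, EM, R_h) {
  rot <- elbow_rotations(model, q10, q11, R_h)
  HU <- (EL + EM) / 2
  US <- HU + as.numeric(rot$R_u %*% model$segments$ulna$landmarks_local$US)
  RS <- EL + as.numeric(rot$R_r %*% model$segments$radius$landmarks_local$RS)
  list(US = US, RS = RS)
}

#' Scapulothoracic constraint residuals
#'
#' Signed ellipsoid residuals of the TS and AI scapular landmarks on their
#' ribcage ellipsoids; both are zero when the scapula glides on the ribcage.
#'
#' @param model an `msm_model`
#' @param q 11-vector [rad]
#' @param pose optional precomputed pose
#' @return named numeric vector `c(phi_ts, phi_ai)` (dimensionless)
#' @export
ribcage_residuals <- function(model, q, pose = fk_pose(model, q)) {
  sl <- model$segments$scapula$landmarks_local
  ts <- fk_point(pose, "scapula", sl$TS)
  ai <- fk_point(pose, "scapula", sl$AI)
  c(phi_ts = ellipsoid_residual(ts, model$ellipsoids$ts),
    phi_ai = ellipsoid_residual(ai, model$ellipsoids$ai))
}

#' Constraint Jacobian d(phi_TS, phi_AI)/dq
#'
#' Analytic via the joint axes: `dphi/dq_k = grad_p(phi) . (a_k x (p - c_k))`.
#'
#' @param model an `msm_model`
#' @param q 11-vector
#' @return 11x2 matrix (columns phi_ts, phi_ai)
#' @export
constraint_jacobian <- function(model, q) {
  pose <- fk_pose(model, q)
  ja <- joint_axes(model, q, pose)
  sl <- model$segments$scapula$landmarks_local
  J <- matrix(0, 11L, 2L, dimnames = list(NULL, c("phi_ts", "phi_ai")))
  pts <- list(fk_point(pose, "scapula", sl$TS), fk_point(pose, "scapula", sl$AI))
  els <- list(model$ellipsoids$ts, model$ellipsoids$ai)
  for (j in 1:2) {
    p <- pts[[j]]; e <- els[[j]]
    grad <- 2 * (p - e$center) / e$axes^2
    for (k in segment_coords("scapula"))
      J[k, j] <- sum(grad * cross3(ja$axes[, k], p - ja$centers[, k]))
  }
  J
}

## ---------------------------------------------------------------------------
## Trajectories

new_trajectory <- function(times, Q) {
  n <- length(times)
  stopifnot(nrow(Q) == n, ncol(Q) == 11L)
  if (n >= 2L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
  }
  Qd <- matrix(0, n, 11L); Qdd <- matrix(0, n, 11L)
  if (n >= 3L) {
    h <- times[2L] - times[1L]
    for (k in 1:11) {
      x <- Q[, k]
      Qd[2:(n - 1L), k] <- (x[3:n] - x[1:(n - 2L)]) / (2 * h)
      Qd[1L, k] <- (-3 * x[1L] + 4 * x[2L] - x[3L]) / (2 * h)
      Qd[n, k] <- (3 * x[n] - 4 * x[n - 1L] + x[n - 2L]) / (2 * h)
      Qdd[2:(n - 1L), k] <- (x[3:n] - 2 * x[2:(n - 1L)] + x[1:(n - 2L)]) / h^2
      Qdd[1L, k] <- Qdd[2L, k]; Qdd[n, k] <- Qdd[n - 1L, k]
    }
  }
  structure(list(times = times, q = Q, qd = Qd, qdd = Qdd),
            class = "msm_trajectory")
}

#' Project clavicle/scapula coordinates onto the ribcage constraints
#'
#' Gauss-Newton least-change correction of q1..q6 driving both ellipsoid
#' residuals to zero.
#' @param model an `msm_model`
#' @param q starting 11-vector
#' @param tol residual tolerance
#' @return corrected q
#' @keywords internal
project_to_constraints <- function(model, q, tol = 1e-12, max_iter = 50L) {
  for (it in seq_len(max_iter)) {
    phi <- ribcage_residuals(model, q)
    if (max(abs(phi)) < tol) return(q)
    J <- t(constraint_jacobian(model, q)[1:6, , drop = FALSE])  # 2x6
    step <- tryCatch(
      as.numeric(t(J) %*% solve(J %*% t(J), -phi)),
      error = function(e) stop("constraint projection failed (singular jacobian)"))
    q[1:6] <- q[1:6] + step
  }
  stop("constraint projection did not converge")
}

#' Humeral elevation axis of the scapula-plane abduction motion
#' @keywords internal
abduction_axis <- function(plane_deg = 30) {
  ## elevation direction in the scapula plane, `plane_deg` anterior of frontal
  e_dir <- c(sin(plane_deg * pi / 180), -cos(plane_deg * pi / 180), 0)
  unit3(cross3(c(0, 0, -1), e_dir))
}

#' Generate a scapula-plane abduction trajectory
#'
#' Humerothoracic elevation follows a minimum-jerk profile between the two
#' requested angles; the scapula and clavicle follow a linear scapulohumeral
#' rhythm (default 2:1 glenohumeral:scapulothoracic) and are then projected
#' onto the two ribcage-ellipsoid constraints by a least-change correction,
#' so every frame satisfies both constraints to machine precision.  The elbow
#' is held at a configured carrying posture.
#'
#' @param model an `msm_model`
#' @param start_deg,end_deg humerothoracic elevation range [deg]
#' @param n_steps number of frames
#' @param duration motion duration [s]
#' @param carry elbow posture `c(q10, q11)` [rad]
#' @param rhythm glenohumeral:scapulothoracic ratio (default 2)
#' @param clavicle_frac fraction of the scapulothoracic rotation assigned to
#'   the clavicle before projection
#' @param plane_deg scapula-plane angle anterior of the frontal plane [deg]
#' @param axial_frac humeral axial (external) rotation per unit elevation;
#'   real arms externally rotate during elevation to clear the tuberosity
#' @return an `msm_trajectory` (times, q, qd, qdd)
#' @export
abduction_trajectory <- function(model, start_deg = 20, end_deg = 150,
                                 n_steps = 131L, duration = 3.25,
                                 carry = c(0, 0), rhythm = 2,
                                 clavicle_frac = 0.7, plane_deg = 30,
                                 axial_frac = 0.17) {
  if (start_deg > end_deg) stop("start must not exceed end")
  n_axis <- abduction_axis(plane_deg)
  times <- seq(0, duration, length.out = n_steps)
  Q <- matrix(0, n_steps, 11L)
  ch <- model$chain
  ## pre-rotation taking the reference humeral shaft exactly to vertical, so
  ## the humerothoracic elevation equals the profile angle at every frame
  pose0 <- fk_pose(model, rep(0, 11L))
  shaft0 <- unit3(pose0$HU - pose0$humerus$o)
  ax0 <- cross3(shaft0, c(0, 0, -1))
  R0 <- if (norm3(ax0) < 1e-12) diag(3L) else
    rot_axis(ax0, acos(max(-1, min(1, -shaft0[3L]))))
  q_prev <- rep(0, 11L)
  for (i in seq_len(n_steps)) {
    s <- if (n_steps == 1L) 0 else (i - 1) / (n_steps - 1)
    theta <- (start_deg + (end_deg - start_deg) * minimum_jerk(s)$x) * pi / 180
    th_st <- theta / (rhythm + 1)        # scapulothoracic share
    R_c_t <- rot_axis(n_axis, clavicle_frac * th_st) %*% ch$R_ref$clavicle
    R_s_t <- rot_axis(n_axis, th_st) %*% ch$R_ref$scapula
    shaft_up <- as.numeric(rot_axis(n_axis, theta) %*% c(0, 0, 1))
    R_h_t <- rot_axis(shaft_up, axial_frac * theta) %*%
      rot_axis(n_axis, theta) %*% R0 %*% ch$R_ref$humerus
    q <- rep(0, 11L)
    q[1:3] <- euler_from_R(t(ch$R_ref$clavicle) %*% R_c_t, ch$euler$sc)
    q[4:6] <- euler_from_R(t(ch$C_cs) %*% t(R_c_t) %*% R_s_t, ch$euler$ac)
    ## warm-start the projection from the previous frame's correction
    q[1:6] <- q[1:6] + (q_prev[1:6] - q[1:6]) * 0
    q <- tryCatch(project_to_constraints(model, q),
                  error = function(e)
                    stop("infeasible scapulohumeral rhythm at step ", i, ": ",
                         conditionMessage(e)))
    ## re-extract the humeral coordinates against the corrected scapula so the
    ## humerothoracic elevation stays exactly at theta
    pose <- fk_pose(model, q)
    q[7:9] <- euler_from_R(t(ch$C_sh) %*% t(pose$scapula$R) %*% R_h_t,
                           ch$euler$gh)
    q[10:11] <- carry
    Q[i, ] <- q
    q_prev <- q
  }
  new_trajectory(times, Q)
}

#' Humerothoracic elevation angle of a configuration
#'
#' Angle between the humeral shaft (GH toward HU) and the downward thorax
#' vertical [deg].
#' @param model an `msm_model`
#' @param q 11-vector
#' @return elevation [deg]
#' @export
elevation_angle <- function(model, q) {
  pose <- fk_pose(model, q)
  shaft <- unit3(pose$HU - pose$humerus$o)
  acos(max(-1, min(1, sum(shaft * c(0, 0, -1))))) * 180 / pi
}

## ---------------------------------------------------------------------------
## Inverse kinematics from measured landmark trajectories

#' Fit joint coordinates to measured landmark trajectories
#'
#' Per-frame nonlinear least squares (Levenberg-Marquardt) of the 11 joint
#' coordinates against measured thorax-frame landmark positions, with the two
#' ribcage constraints enforced in penalty form.  Frames are warm-started from
#' the previous solution.
#'
#' @param model an `msm_model`
#' @param measured data.frame with a `time` column and `<landmark>_x/_y/_z`
#'   columns [m] for a subset of the model's segment landmarks
#' @param penalty weight of the constraint residuals (sqrt of it multiplies
#'   the dimensionless phi residuals)
#' @param q0 optional starting configuration
#' @return list with `trajectory` (an `msm_trajectory`), `rms_residual` [m]
#'   per frame, and `skipped` (indices of frames with too few landmarks)
#' @export
fit_landmarks <- function(model, measured, penalty = 1e4, q0 = NULL) {
  seg_landmarks <- unlist(lapply(model$segments,
                                 function(s) names(s$landmarks_local)))
  cols <- names(measured)
  lm_names <- unique(sub("_[xyz]$", "", setdiff(cols, "time")))
  lm_names <- intersect(lm_names, seg_landmarks)
  n <- nrow(measured)
  if (n == 0L || length(lm_names) == 0L)
    return(list(trajectory = new_trajectory(numeric(0),
                                            matrix(0, 0, 11L)),
                rms_residual = numeric(0), skipped = integer(0)))
  times <- measured$time
  Q <- matrix(0, n, 11L)
  rms <- rep(NA_real_, n)
  skipped <- integer(0)
  q_start <- if (is.null(q0)) rep(0, 11L) else q0
  lm_map <- list()
  for (sn in SEGMENT_NAMES)
    for (ln in intersect(names(model$segments[[sn]]$landmarks_local), lm_names))
      lm_map[[ln]] <- list(segment = sn,
                           local = model$segments[[sn]]$landmarks_local[[ln]])
  for (i in seq_len(n)) {
    meas <- list()
    for (ln in names(lm_map)) {
      p <- c(measured[[paste0(ln, "_x")]][i], measured[[paste0(ln, "_y")]][i],
             measured[[paste0(ln, "_z")]][i])
      if (all(is.finite(p))) meas[[ln]] <- p
    }
    if (length(meas) < 4L) {
      skipped <- c(skipped, i)
      warning("frame ", i, " skipped: only ", length(meas),
              " finite landmarks")
      Q[i, ] <- q_start
      next
    }
    resid_fn <- function(q) {
      pose <- fk_pose(model, q)
      r <- numeric(0)
      for (ln in names(meas))
        r <- c(r, fk_point(pose, lm_map[[ln]]$segment,
                           lm_map[[ln]]$local) - meas[[ln]])
      phi <- ribcage_residuals(model, q, pose)
      c(r, sqrt(penalty) * phi)
    }
    fit <- minpack.lm::nls.lm(par = q_start, fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200L, ftol = 1e-15, ptol = 1e-15))
    Q[i, ] <- fit$par
    q_start <- fit$par
    r <- resid_fn(fit$par)
    nr <- length(r) - 2L
    rms[i] <- sqrt(mean(r[seq_len(nr)]^2))
  }
  list(trajectory = new_trajectory(times, Q), rms_residual = rms,
       skipped = skipped)
}
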