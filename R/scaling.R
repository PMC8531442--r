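## Subject-specific adaptation of the generic model: body-segment inertial
## parameters (BSIP) from gender/weight/height predictive equations,
## anisotropic morphology scaling, ribcage-ellipsoid dilation, glenoid
## inclination/version adaptation, and BMI-based PCSA scaling.

#' Subject anthropometry
#'
#' @param gender "male" or "female"
#' @param height stature [m]
#' @param weight body mass [kg]
#' @param shoulder_width distance between the two angulus acromialis
#'   landmarks [m]
#' @param alpha_gi,alpha_gv optional target glenoid inclination/version [deg]
#' @param pcsa_overrides optional named vector of subject-specific PCSAs
#'   [cm^2] that replace the scaled values
#' @return an object of class `msm_anthropometry`
#' @export
subject_anthropometry <- function(gender, height, weight, shoulder_width,
                                  alpha_gi = NULL, alpha_gv = NULL,
                                  pcsa_overrides = NULL) {
  gender <- match.arg(gender, c("male", "female"))
  if (!is.finite(height) || height < 1.2 || height > 2.3)
    stop("height must lie in [1.2, 2.3] m")
  if (!is.finite(weight) || weight < 30 || weight > 200)
    stop("weight must lie in [30, 200] kg")
  if (!is.finite(shoulder_width) || shoulder_width <= 0 ||
      shoulder_width >= height)
    stop("shoulder width must be positive and smaller than height")
  if (!is.null(pcsa_overrides) && any(pcsa_overrides <= 0))
    stop("PCSA overrides must be > 0")
  structure(list(gender = gender, height = height, weight = weight,
                 shoulder_width = shoulder_width, alpha_gi = alpha_gi,
                 alpha_gv = alpha_gv, pcsa_overrides = pcsa_overrides),
            class = "msm_anthropometry")
}

## Gender-specific predictive coefficients: masses as percent of body mass,
## lengths as fractions of stature, inertias from gyration-radius coefficients
## (transverse t, lateral/longitudinal l) applied to segment length.
bsip_coefficients <- function(gender) {
  if (gender == "male")
    list(mass_pct = c(clavicle = 0.18, scapula = 0.82, humerus = 2.4,
                      forearm = 1.7),
         len_frac = c(humerus = 27 / 177, forearm = 28.3 / 177),
         gyr = list(humerus = c(t = 0.315, l = 0.14),
                    ulna = c(t = 0.275, l = 0.11),
                    radius = c(t = 0.275, l = 0.11)))
  else
    list(mass_pct = c(clavicle = 0.18, scapula = 0.82, humerus = 2.2,
                      forearm = 1.3),
         len_frac = c(humerus = 24.3 / 161, forearm = 24.7 / 161),
         gyr = list(humerus = c(t = 0.33, l = 0.17),
                    ulna = c(t = 0.255, l = 0.14),
                    radius = c(t = 0.255, l = 0.14)))
}

## forearm mass split between ulna and radius
FOREARM_SPLIT <- c(ulna = 0.62, radius = 0.38)

#' Scale body-segment inertial parameters to a subject
#'
#' Predictive equations: segment masses are gender-specific percentages of
#' body mass, segment lengths fractions of stature, and the transverse/
#' lateral moments of inertia follow (gyration coefficient x length)^2 x mass.
#' The forearm mass is split 62%/38% between ulna and radius.
#'
#' @param anthro an `msm_anthropometry`
#' @return list of class `msm_bsip` with per-segment `mass` [kg], `length`
#'   [m], `I_t`, `I_l` [kg m^2], plus `arm_mass` (humerus + ulna + radius)
#' @export
scale_bsip <- function(anthro) {
  co <- bsip_coefficients(anthro$gender)
  mB <- anthro$weight; lH <- anthro$height
  mass <- c(clavicle = co$mass_pct[["clavicle"]] / 100 * mB,
            scapula = co$mass_pct[["scapula"]] / 100 * mB,
            humerus = co$mass_pct[["humerus"]] / 100 * mB,
            ulna = FOREARM_SPLIT[["ulna"]] * co$mass_pct[["forearm"]] / 100 * mB,
            radius = FOREARM_SPLIT[["radius"]] * co$mass_pct[["forearm"]] / 100 * mB)
  len <- c(humerus = co$len_frac[["humerus"]] * lH,
           ulna = co$len_frac[["forearm"]] * lH,
           radius = co$len_frac[["forearm"]] * lH)
  I_t <- c(humerus = (co$gyr$humerus[["t"]] * len[["humerus"]])^2 * mass[["humerus"]],
           ulna = (co$gyr$ulna[["t"]] * len[["ulna"]])^2 * mass[["ulna"]],
           radius = (co$gyr$radius[["t"]] * len[["radius"]])^2 * mass[["radius"]])
  I_l <- c(humerus = (co$gyr$humerus[["l"]] * len[["humerus"]])^2 * mass[["humerus"]],
           ulna = (co$gyr$ulna[["l"]] * len[["ulna"]])^2 * mass[["ulna"]],
           radius = (co$gyr$radius[["l"]] * len[["radius"]])^2 * mass[["radius"]])
  structure(list(mass = mass, length = len, I_t = I_t, I_l = I_l,
                 arm_mass = mass[["humerus"]] + mass[["ulna"]] + mass[["radius"]]),
            class = "msm_bsip")
}

#' Relative sensitivity of the arm mass to body mass
#'
#' For proportional mass scaling the arm mass grows by `100 / m_B` percent per
#' added kilogram, independent of gender.
#'
#' @param anthro an `msm_anthropometry`
#' @return sensitivity [% per kg]
#' @export
arm_mass_sensitivity <- function(anthro) {
  bs <- scale_bsip(anthro)
  h <- 1e-4
  a2 <- anthro; a2$weight <- anthro$weight + h
  d <- (scale_bsip(a2)$arm_mass - bs$arm_mass) / h
  d / bs$arm_mass * 100
}

#' Anisotropic morphology scaling matrix
#'
#' `S = diag(l_W/l_Wg, l_W/l_Wg, l_H/l_Hg)`: the in-plane (transverse)
#' directions scale with shoulder width, the vertical with stature.
#'
#' @param anthro an `msm_anthropometry`
#' @param model an `msm_model` (provides the generic height/width)
#' @return 3x3 diagonal matrix
#' @export
scaling_matrix <- function(anthro, model) {
  g <- model$anthropometry_generic
  diag(c(anthro$shoulder_width / g$shoulder_width,
         anthro$shoulder_width / g$shoulder_width,
         anthro$height / g$height))
}

## ---------------------------------------------------------------------------
## Ribcage ellipsoid dilation (6th-degree polynomial)

poly_mul <- function(a, b) {
  ## coefficient vectors, ascending powers
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <-
      out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

#' Isotropic dilation factor putting a landmark on a dilated ellipsoid
#'
#' Solves `(v_x^2)/(a+d)^2 + (v_y^2)/(b+d)^2 + (v_z^2)/(c+d)^2 = 1` for `d`
#' by assembling the equivalent 6th-degree polynomial and filtering its roots:
#' real roots only, positive, all dilated semi-axes positive, smallest such
#' root.  The returned root is verified by direct substitution.
#'
#' @param v landmark position relative to the (scaled) ellipsoid center
#' @param axes base semi-axes (3-vector)
#' @return dilation factor `d` [m]
#' @keywords internal
solve_dilation <- function(v, axes) {
  A <- c(axes[1L]^2, 2 * axes[1L], 1)  # (a + d)^2, ascending
  B <- c(axes[2L]^2, 2 * axes[2L], 1)
  C <- c(axes[3L]^2, 2 * axes[3L], 1)
  pad <- function(p, n) c(p, numeric(n - length(p)))
  poly <- pad(v[1L]^2 * poly_mul(B, C), 7L) +
    pad(v[2L]^2 * poly_mul(A, C), 7L) +
    pad(v[3L]^2 * poly_mul(A, B), 7L) - poly_mul(A, poly_mul(B, C))
  rts <- polyroot(poly)
  re <- Re(rts)[abs(Im(rts)) < 1e-9 * (1 + abs(Re(rts)))]
  re <- re[re > 0 & re > -min(axes)]
  if (length(re) == 0L)
    stop("ellipsoid dilation failed: no positive real root ",
         "(geometrically impossible scaling)")
  d <- min(re)
  resid <- sum((v / (axes + d))^2) - 1
  if (abs(resid) > 1e-8)
    stop("ellipsoid dilation root did not verify (residual ", resid, ")")
  d
}

#' Dilate the ribcage ellipsoids for a scaled subject
#'
#' The centers of the TS and AI ellipsoids are the scaled base center `S e0`;
#' their semi-axes are the base semi-axes isotropically dilated so that the
#' scaled TS and AI landmarks lie exactly on their respective surfaces.
#'
#' @param model an `msm_model` (base ellipsoid and reference TS/AI positions)
#' @param S 3x3 scaling matrix
#' @return list with `delta_ts`, `delta_ai` [m] and the two dilated
#'   ellipsoids `ts`, `ai`
#' @export
dilate_ellipsoids <- function(model, S) {
  base <- model$ellipsoids$base
  ts <- model$reference$landmarks$TS
  ai <- model$reference$landmarks$AI
  ctr <- as.numeric(S %*% base$center)
  d_ts <- solve_dilation(as.numeric(S %*% ts) - ctr, base$axes)
  d_ai <- solve_dilation(as.numeric(S %*% ai) - ctr, base$axes)
  list(delta_ts = d_ts, delta_ai = d_ai,
       ts = new_ellipsoid(ctr, base$axes + d_ts),
       ai = new_ellipsoid(ctr, base$axes + d_ai))
}

## ---------------------------------------------------------------------------
## Glenoid orientation

#' Measure glenoid inclination and version
#'
#' Inclination: signed angle in the scapular x-z plane between the scapula z
#' axis and the projected inferior-to-superior glenoid rim vector.  Version:
#' signed angle in the x-y plane between the y axis and the projected
#' posterior-to-anterior rim vector.
#'
#' @param model an `msm_model`
#' @return named numeric vector `c(alpha_gi, alpha_gv)` [deg]
#' @export
glenoid_angles <- function(model) {
  lm <- model$reference$landmarks
  fr <- build_scapula_frame(lm$SN, lm$AI, lm$TS)
  xs <- fr$R[, 1L]; ys <- fr$R[, 2L]; zs <- fr$R[, 3L]
  v_i <- lm$SG - lm$IG
  v_v <- lm$AG - lm$PG
  pr_i <- c(sum(v_i * xs), sum(v_i * zs))
  pr_v <- c(sum(v_v * xs), sum(v_v * ys))
  if (norm3(c(pr_i, 0)) < 1e-12 || norm3(c(pr_v, 0)) < 1e-12)
    stop("degenerate glenoid rim: zero-length projection")
  ## signs chosen so the Rodrigues adaptation operators about +y_s / +z_s
  ## increase the respective measured angle
  c(alpha_gi = atan2(pr_i[1L], pr_i[2L]) * 180 / pi,
    alpha_gv = atan2(-pr_v[1L], pr_v[2L]) * 180 / pi)
}

#' Rodrigues rotation operators for glenoid adaptation
#' @keywords internal
glenoid_rotation <- function(axis, delta_rad) {
  axis %o% axis + cos(delta_rad) * (diag(3L) - axis %o% axis) +
    sin(delta_rad) * skew3(axis)
}

#' Adapt the glenoid inclination/version to target angles
#'
#' Rotates the glenoid center and rim points about the scapular y axis (for
#' inclination) and z axis (for version) with Rodrigues operators, iterating
#' the pair of rotations until the measured angles match the targets (the two
#' plane projections interact, so a single pass is not exact).
#'
#' @param model an `msm_model`
#' @param alpha_gi,alpha_gv target angles [deg]; `NULL` keeps the current value
#' @return the adapted model
#' @export
adapt_glenoid <- function(model, alpha_gi = NULL, alpha_gv = NULL) {
  cur <- glenoid_angles(model)
  if (is.null(alpha_gi)) alpha_gi <- cur[["alpha_gi"]]
  if (is.null(alpha_gv)) alpha_gv <- cur[["alpha_gv"]]
  lm <- model$reference$landmarks
  fr <- build_scapula_frame(lm$SN, lm$AI, lm$TS)
  ys <- fr$R[, 2L]; zs <- fr$R[, 3L]; SN <- fr$origin
  pts <- c("IG", "SG", "PG", "AG", "GC")
  for (it in 1:8) {
    cur <- glenoid_angles(model)
    d_gi <- (alpha_gi - cur[["alpha_gi"]]) * pi / 180
    d_gv <- (alpha_gv - cur[["alpha_gv"]]) * pi / 180
    if (max(abs(c(d_gi, d_gv))) < 1e-12) break
    R <- glenoid_rotation(ys, d_gi) %*% glenoid_rotation(zs, d_gv)
    for (pn in pts)
      model$reference$landmarks[[pn]] <-
        SN + as.numeric(R %*% (model$reference$landmarks[[pn]] - SN))
  }
  ## refresh the scapula-local glenoid points and stored angles
  pose <- fk_pose(model, model$reference$q)
  for (pn in pts)
    model$glenoid$points_local[[pn]] <-
      as.numeric(t(pose$scapula$R) %*%
                   (model$reference$landmarks[[pn]] - pose$scapula$o))
  ang <- glenoid_angles(model)
  model$glenoid$alpha_gi <- ang[["alpha_gi"]]
  model$glenoid$alpha_gv <- ang[["alpha_gv"]]
  model
}

## ---------------------------------------------------------------------------
## Muscle architecture

#' Body muscle percentage from BMI
#'
#' Gender-specific predictive polynomials in BMI = m / l^2:
#' male `1.09 - 0.0149 BMI + 0.00009 BMI^2`,
#' female `1.08 - 0.0203 BMI + 0.000156 BMI^2`.
#' BMI outside [12, 60] is clamped with a warning.
#'
#' @param anthro an `msm_anthropometry` (or a list with gender, height, weight)
#' @return muscle fraction of body composition (0..1 scale)
#' @export
muscle_percentage <- function(anthro) {
  bmi <- anthro$weight / anthro$height^2
  if (bmi < 12 || bmi > 60) {
    warning("BMI ", round(bmi, 1), " outside [12, 60]; clamped")
    bmi <- max(12, min(60, bmi))
  }
  if (anthro$gender == "male")
    1.09 - 0.0149 * bmi + 0.00009 * bmi^2
  else
    1.08 - 0.0203 * bmi + 0.000156 * bmi^2
}

#' Scale muscle PCSAs to a subject
#'
#' Multiplies every PCSA by the ratio of the subject's muscle percentage to
#' the generic model's; any subject-specific override then replaces the
#' scaled value for that muscle.
#'
#' @param model an `msm_model`
#' @param anthro an `msm_anthropometry`
#' @return the model with updated PCSAs
#' @export
scale_pcsa <- function(model, anthro) {
  r_m <- muscle_percentage(anthro)
  fac <- r_m / model$r_m_generic
  for (mn in names(model$muscles))
    model$muscles[[mn]]$pcsa <- model$muscles[[mn]]$pcsa * fac
  ov <- anthro$pcsa_overrides
  if (!is.null(ov)) {
    bad <- setdiff(names(ov), names(model$muscles))
    if (length(bad) > 0L) stop("PCSA override for unknown muscle: ",
                               paste(bad, collapse = ", "))
    for (mn in names(ov)) {
      if (ov[[mn]] <= 0) stop("PCSA override must be > 0 for ", mn)
      model$muscles[[mn]]$pcsa <- as.numeric(ov[[mn]])
    }
  }
  model
}

#' Scale the skeletal morphology (and muscle geometry) of a model
#'
#' Applies the scaling matrix to every thorax-frame reference position
#' (bony landmarks, muscle origins/insertions/via points, wrapping-object
#' centers, ellipsoid center, glenoid points) and rebuilds the model from the
#' scaled geometry.  Wrapping radii are scaled by the mean in-plane factor
#' `(S11 + S22)/2`.  The ribcage ellipsoids are re-dilated so that the scaled
#' reference pose still satisfies both constraints exactly.
#'
#' @param model an `msm_model`
#' @param S 3x3 scaling matrix (or per-segment named list of matrices for
#'   marker-based scaling)
#' @return the scaled model
#' @export
scale_morphology <- function(model, S) {
  geom <- model_geometry(model)
  seg_S <- function(segment) {
    if (is.list(S)) {
      if (is.null(S[[segment]])) stop("no scaling matrix for segment ", segment)
      S[[segment]]
    } else S
  }
  mapp <- function(p, segment) as.numeric(seg_S(segment) %*% p)
  for (sn in names(geom$landmarks))
    for (ln in names(geom$landmarks[[sn]]))
      geom$landmarks[[sn]][[ln]] <- mapp(geom$landmarks[[sn]][[ln]], sn)
  for (mn in names(geom$muscles)) {
    m <- geom$muscles[[mn]]
    geom$muscles[[mn]]$origin$point <- mapp(m$origin$point, m$origin$segment)
    geom$muscles[[mn]]$insertion$point <-
      mapp(m$insertion$point, m$insertion$segment)
    if (length(m$via) > 0L)
      for (i in seq_along(m$via))
        geom$muscles[[mn]]$via[[i]]$point <-
          mapp(m$via[[i]]$point, m$via[[i]]$segment)
  }
  geom$joint_centers$SC <- mapp(geom$joint_centers$SC, "clavicle")
  geom$joint_centers$AC <- mapp(geom$joint_centers$AC, "clavicle")
  geom$joint_centers$GH <- mapp(geom$joint_centers$GH, "scapula")
  for (ln in names(geom$ligaments)) {
    l <- geom$ligaments[[ln]]
    geom$ligaments[[ln]]$origin$point <- mapp(l$origin$point, l$origin$segment)
    geom$ligaments[[ln]]$insertion$point <-
      mapp(l$insertion$point, l$insertion$segment)
  }
  for (wn in names(geom$wraps)) {
    w <- geom$wraps[[wn]]
    Sw <- seg_S(w$attached_segment)
    geom$wraps[[wn]]$center <- as.numeric(Sw %*% w$center)
    if (!is.null(w$axis))
      geom$wraps[[wn]]$axis <- unit3(as.numeric(Sw %*% w$axis))
    geom$wraps[[wn]]$radius <- w$radius * (Sw[1L, 1L] + Sw[2L, 2L]) / 2
  }
  S0 <- if (is.list(S)) seg_S("scapula") else S  # thorax points: global S
  if (is.list(S)) {
    for (ln in names(geom$thorax_landmarks))
      geom$thorax_landmarks[[ln]] <-
        as.numeric(S0 %*% geom$thorax_landmarks[[ln]])
    geom$base_center <- as.numeric(S0 %*% geom$base_center)
  } else {
    for (ln in names(geom$thorax_landmarks))
      geom$thorax_landmarks[[ln]] <- as.numeric(S %*% geom$thorax_landmarks[[ln]])
    geom$base_center <- as.numeric(S %*% geom$base_center)
  }
  for (pn in names(geom$glenoid_points))
    geom$glenoid_points[[pn]] <- mapp(geom$glenoid_points[[pn]], "scapula")
  assemble_model(geom)
}

#' Scale the generic model to a subject
#'
#' Full composition: BSIP scaling, anisotropic morphology scaling with
#' ribcage-ellipsoid dilation, optional glenoid inclination/version
#' adaptation, and BMI-based PCSA scaling.
#'
#' @param model the generic `msm_model`
#' @param anthro an `msm_anthropometry`
#' @return list with the scaled `model` and a `report` (class
#'   `msm_scaling_report`) listing every factor applied
#' @export
scale_subject <- function(model, anthro) {
  S <- scaling_matrix(anthro, model)
  bsip <- scale_bsip(anthro)
  scaled <- scale_morphology(model, S)
  dil <- scaled$ellipsoids  # re-dilated inside assemble_model
  ## apply BSIP: predictive masses/lengths for arm segments, geometric
  ## lengths with schema gyration defaults for clavicle and scapula
  scaled <- apply_bsip(scaled, bsip, anthro)
  if (!is.null(anthro$alpha_gi) || !is.null(anthro$alpha_gv))
    scaled <- adapt_glenoid(scaled, anthro$alpha_gi, anthro$alpha_gv)
  r_m_subject <- muscle_percentage(anthro)
  scaled <- scale_pcsa(scaled, anthro)
  ## the scaled model's reference anthropometry is the subject itself
  scaled$anthropometry_generic <- list(gender = anthro$gender,
                                       height = anthro$height,
                                       mass = anthro$weight,
                                       shoulder_width = anthro$shoulder_width)
  scaled$r_m_generic <- r_m_subject
  report <- structure(list(
    gender = anthro$gender,
    S = S,
    bsip = bsip,
    delta_ts = dil$delta_ts, delta_ai = dil$delta_ai,
    r_m_generic = model$r_m_generic,
    r_m_subject = r_m_subject,
    pcsa_factor = r_m_subject / model$r_m_generic,
    pcsa_overrides = anthro$pcsa_overrides,
    glenoid = c(alpha_gi = scaled$glenoid$alpha_gi,
                alpha_gv = scaled$glenoid$alpha_gv),
    hand_mass = scaled$hand$mass), class = "msm_scaling_report")
  list(model = scaled, report = report)
}

#' Apply a BSIP set to a model
#' @keywords internal
apply_bsip <- function(model, bsip, anthro) {
  gyr_default <- list(clavicle = c(0.12, 0.28, 0.28),   # long axis x
                      scapula = c(0.22, 0.30, 0.22))    # plate normal y
  for (sn in SEGMENT_NAMES) {
    if (sn %in% c("clavicle", "scapula")) {
      m <- bsip$mass[[sn]]
      len <- model$segments[[sn]]$length
      model$segments[[sn]]$mass <- m
      model$segments[[sn]]$inertia_diag <- (gyr_default[[sn]] * len)^2 * m
    } else {
      m <- bsip$mass[[sn]]
      It <- bsip$I_t[[sn]]; Il <- bsip$I_l[[sn]]
      model$segments[[sn]]$mass <- m
      model$segments[[sn]]$length <- bsip$length[[sn]]
      model$segments[[sn]]$inertia_diag <- switch(sn,
        humerus = c(It, It, Il),   # shaft along local z
        ulna = c(Il, It, It),      # hinge/long axis along local x
        radius = c(It, It, Il))    # shaft along local z
    }
  }
  model$hand$mass <- model$options$hand_mass_frac * anthro$weight
  model
}

#' @export
print.msm_scaling_report <- function(x, ...) {
  cat("Subject scaling report\n")
  cat(sprintf("  gender: %s;  S = diag(%.4f, %.4f, %.4f)\n", x$gender,
              x$S[1, 1], x$S[2, 2], x$S[3, 3]))
  cat(sprintf("  arm mass: %.4f kg;  ellipsoid dilations: TS %.4f m, AI %.4f m\n",
              x$bsip$arm_mass, x$delta_ts, x$delta_ai))
  cat(sprintf("  r_m: generic %.4f -> subject %.4f (PCSA factor %.4f)\n",
              x$r_m_generic, x$r_m_subject, x$pcsa_factor))
  cat(sprintf("  glenoid: inclination %.2f deg, version %.2f deg\n",
              x$glenoid[["alpha_gi"]], x$glenoid[["alpha_gv"]]))
  invisible(x)
}
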