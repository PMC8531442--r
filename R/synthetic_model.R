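## Deterministic synthetic right-upper-limb anatomy.
##
## The generator emits a complete generic model -- skeleton landmarks, ribcage
## ellipsoids, 42 muscle groups (14 spanning the elbow), wrapping obstacles,
## and a glenoid built at an exact inclination -- proportioned from standard
## anthropometric ratios at the generic subject's stature.  It is a fixture
## for exercising the modeling stack, not a reproduction of any individual's
## MRI anatomy.  Geometry is expressed in a thorax frame with x anterior,
## y to the subject's left, z superior (gravity acts along -z); the modeled
## side is the right (y < 0).

#' Generator parameters
#'
#' Defaults reproduce the generic subject's metadata: stature 1.86 m, body
#' mass 85.5 kg, glenoid inclination 7 degrees.
#'
#' @param seed integer seed (stored in the model; the anatomy itself is
#'   deterministic, the seed drives marker-noise export)
#' @param stature subject height [m]
#' @param mass body mass [kg]
#' @param glenoid_inclination [deg]
#' @param n_muscles number of muscle groups (42 expected; smaller values drop
#'   trailing shoulder groups and are only useful to probe the validator)
#' @param marker_noise default marker-export noise s.d. [m]
#' @return list of class `msm_generator_params`
#' @export
generator_params <- function(seed = 1L, stature = 1.86, mass = 85.5,
                             glenoid_inclination = 7, n_muscles = 42L,
                             marker_noise = 0) {
  structure(list(seed = as.integer(seed), stature = stature, mass = mass,
                 glenoid_inclination = glenoid_inclination,
                 n_muscles = as.integer(n_muscles),
                 marker_noise = marker_noise),
            class = "msm_generator_params")
}

## Reference skeleton at stature 1.86 m (thorax frame, meters).
skeleton_table <- function() {
  list(
    clavicle = list(SC = c(0.005, -0.015, -0.005),
                    AC = c(-0.010, -0.170, 0.025),
                    CM = c(0.010, -0.095, 0.030)),
    scapula = list(TS = c(-0.095, -0.075, -0.005),
                   AI = c(-0.055, -0.190, 0.020),
                   SN = c(-0.055, -0.155, 0.005),
                   CP = c(0.015, -0.160, 0.010),
                   IA = c(-0.080, -0.100, -0.120),
                   SA = c(-0.085, -0.070, 0.020)),
    humerus = list(EL = c(0.000, -0.210, -0.325),
                   EM = c(0.000, -0.160, -0.325),
                   HU = c(0.000, -0.185, -0.325),
                   DT = c(0.000, -0.205, -0.135),
                   GT = c(0.000, -0.212, 0.000),
                   LT = c(0.020, -0.200, -0.010),
                   BG = c(0.020, -0.190, -0.020)),
    ulna = list(US = c(0.010, -0.160, -0.620),
                OL = c(-0.030, -0.185, -0.315)),
    radius = list(RS = c(0.010, -0.210, -0.615),
                  RT = c(0.010, -0.200, -0.360)))
}

thorax_table <- function() {
  list(IJ = c(0, 0, 0), C7 = c(-0.055, 0, 0.020), T3 = c(-0.070, 0, -0.050),
       T8 = c(-0.090, 0, -0.150), PX = c(0.020, 0, -0.150))
}

## joint centers (GH = humeral head / glenohumeral rotation center)
joint_table <- function() {
  list(SC = c(0.005, -0.015, -0.005), AC = c(-0.010, -0.170, 0.025),
       GH = c(-0.010, -0.185, -0.005))
}

wrap_table <- function() {
  list(
    humeral_head = list(kind = "sphere", center = c(-0.010, -0.185, -0.005),
                        axis = NULL, radius = 0.027,
                        attached_segment = "humerus", wrap_side = "left"),
    elbow_condyle = list(kind = "cylinder", center = c(0.000, -0.185, -0.325),
                         axis = c(0, -1, 0), radius = 0.022,
                         attached_segment = "humerus", wrap_side = "right"))
}

## Passive ligaments included as tension-only strings in the load sharing
## (negligible objective weight): the coracoclavicular complex and the AC
## capsule stabilize the acromioclavicular torques at extreme elevation.
ligament_table <- function() {
  L <- function(o_seg, o, i_seg, i, f_max)
    list(origin = list(segment = o_seg, point = o),
         insertion = list(segment = i_seg, point = i), f_max = f_max)
  list(
    coracoclavicular = L("clavicle", c(-0.008, -0.125, 0.015),
                         "scapula", c(0.015, -0.160, 0.010), 1500),
    acromioclavicular = L("clavicle", c(-0.008, -0.162, 0.025),
                          "scapula", c(-0.030, -0.178, 0.022), 800),
    costoclavicular = L("thorax", c(0.025, -0.030, -0.025),
                        "clavicle", c(0.000, -0.045, -0.002), 1000))
}

## Muscle table: origin/insertion/(via) as (segment, point-at-reference),
## wrap references with the polyline gap they act on, PCSA [cm^2].
## The rotator-cuff PCSAs are deliberately set at twice the degenerated
## values exercised by the 50%-reduction scenario.
muscle_table <- function() {
  M <- function(o_seg, o, i_seg, i, pcsa, via = list(), wraps = list())
    list(origin = list(segment = o_seg, point = o),
         insertion = list(segment = i_seg, point = i),
         via = via, wraps = wraps, n_strings = 1L, pcsa = pcsa)
  ## side_dir: preferred bulge direction in the attached segment's frame
  ## (humerus local axes: x lateral, y anterior, z up the shaft)
  W <- function(name, gap, side_dir = NULL)
    list(list(name = name, gap = gap, side_dir = side_dir))
  list(
    ## --- scapulothoracic / claviculothoracic groups -----------------------
    trapezius_upper = M("thorax", c(-0.055, 0, 0.020),
                        "clavicle", c(-0.005, -0.140, 0.024), 7),
    trapezius_middle = M("thorax", c(-0.070, 0, -0.050),
                         "scapula", c(-0.060, -0.180, 0.015), 6),
    trapezius_lower = M("thorax", c(-0.090, 0, -0.150),
                        "scapula", c(-0.092, -0.085, -0.008), 5),
    rhomboid_major = M("thorax", c(-0.085, 0, -0.095),
                       "scapula", c(-0.090, -0.088, -0.060), 5),
    rhomboid_minor = M("thorax", c(-0.075, 0, -0.035),
                       "scapula", c(-0.094, -0.078, -0.012), 2),
    levator_scapulae = M("thorax", c(-0.040, -0.010, 0.075),
                         "scapula", c(-0.085, -0.070, 0.020), 3),
    serratus_superior = M("thorax", c(0.020, -0.100, -0.040),
                          "scapula", c(-0.083, -0.075, 0.008), 3),
    serratus_middle = M("thorax", c(0.030, -0.115, -0.100),
                        "scapula", c(-0.090, -0.086, -0.055), 4),
    serratus_inferior = M("thorax", c(0.025, -0.110, -0.170),
                          "scapula", c(-0.078, -0.095, -0.105), 6),
    pectoralis_minor = M("thorax", c(0.045, -0.055, -0.090),
                         "scapula", c(0.015, -0.160, 0.010), 4),
    subclavius = M("thorax", c(0.030, -0.020, -0.020),
                   "clavicle", c(0.000, -0.090, 0.012), 1.5),
    omohyoid = M("thorax", c(0.020, -0.005, 0.060),
                 "scapula", c(-0.070, -0.080, 0.012), 0.8),
    sternocleidomastoid = M("thorax", c(0.020, 0.000, 0.100),
                            "clavicle", c(0.000, -0.045, 0.006), 2.5),
    ## --- glenohumeral groups ---------------------------------------------
    deltoid_anterior = M("clavicle", c(0.010, -0.100, 0.018),
                         "humerus", c(0.000, -0.205, -0.135), 12),
    deltoid_middle = M("scapula", c(-0.010, -0.196, 0.028),
                       "humerus", c(0.000, -0.205, -0.135), 16,
                       wraps = W("humeral_head", 1L, c(1, 0, 0))),
    deltoid_posterior = M("scapula", c(-0.075, -0.130, 0.010),
                          "humerus", c(0.000, -0.205, -0.135), 10),
    supraspinatus = M("scapula", c(-0.085, -0.090, 0.005),
                      "humerus", c(0.006, -0.212, -0.002), 20.84,
                      wraps = W("humeral_head", 1L, c(0.3, 0, 1))),
    infraspinatus = M("scapula", c(-0.090, -0.090, -0.040),
                      "humerus", c(-0.012, -0.212, -0.022), 33.32,
                      wraps = W("humeral_head", 1L, c(0.3, -1, 0))),
    subscapularis = M("scapula", c(-0.075, -0.085, -0.040),
                      "humerus", c(0.022, -0.198, -0.025), 35.68,
                      wraps = W("humeral_head", 1L, c(0.3, 1, 0))),
    teres_minor = M("scapula", c(-0.080, -0.110, -0.070),
                    "humerus", c(-0.008, -0.210, -0.035), 6.80),
    teres_major = M("scapula", c(-0.080, -0.100, -0.110),
                    "humerus", c(0.005, -0.175, -0.080), 8),
    pectoralis_major_clavicular = M("clavicle", c(0.005, -0.060, 0.000),
                                    "humerus", c(0.010, -0.190, -0.090), 9),
    pectoralis_major_sternal = M("thorax", c(0.025, -0.020, -0.050),
                                 "humerus", c(0.010, -0.190, -0.090), 10),
    pectoralis_major_abdominal = M("thorax", c(0.025, -0.010, -0.120),
                                   "humerus", c(0.010, -0.190, -0.090), 6),
    latissimus_dorsi_thoracic = M("thorax", c(-0.080, -0.010, -0.150),
                                  "humerus", c(0.006, -0.178, -0.055), 8),
    latissimus_dorsi_lumbar = M("thorax", c(-0.085, -0.030, -0.185),
                                "humerus", c(0.006, -0.178, -0.055), 6),
    latissimus_dorsi_iliac = M("thorax", c(-0.088, -0.050, -0.215),
                               "humerus", c(0.006, -0.178, -0.055), 4),
    coracobrachialis = M("scapula", c(0.015, -0.160, 0.010),
                         "humerus", c(0.008, -0.185, -0.150), 5),
    ## --- elbow-spanning groups -------------------------------------------
    triceps_long = M("scapula", c(-0.040, -0.170, -0.025),
                     "ulna", c(-0.030, -0.185, -0.315), 12,
                     wraps = W("elbow_condyle", 1L)),
    triceps_medial = M("humerus", c(-0.018, -0.185, -0.180),
                       "ulna", c(-0.030, -0.185, -0.315), 8,
                       wraps = W("elbow_condyle", 1L)),
    triceps_lateral = M("humerus", c(-0.015, -0.195, -0.120),
                        "ulna", c(-0.030, -0.185, -0.315), 8,
                        wraps = W("elbow_condyle", 1L)),
    biceps_short = M("scapula", c(0.015, -0.160, 0.010),
                     "radius", c(0.010, -0.200, -0.360), 5),
    biceps_long = M("scapula", c(-0.030, -0.164, 0.010),
                    "radius", c(0.010, -0.200, -0.360), 5,
                    via = list(list(segment = "humerus",
                                    point = c(0.020, -0.190, -0.020)))),
    brachialis = M("humerus", c(0.012, -0.182, -0.200),
                   "ulna", c(0.022, -0.168, -0.355), 10),
    brachioradialis = M("humerus", c(0.002, -0.208, -0.280),
                        "radius", c(0.010, -0.210, -0.615), 3),
    supinator = M("ulna", c(0.000, -0.175, -0.360),
                  "radius", c(0.018, -0.208, -0.385), 3),
    pronator_teres = M("humerus", c(0.008, -0.162, -0.318),
                       "radius", c(0.015, -0.208, -0.430), 5),
    flexor_carpi_radialis = M("humerus", c(0.010, -0.163, -0.320),
                              "radius", c(0.022, -0.198, -0.600), 3),
    flexor_carpi_ulnaris = M("humerus", c(0.005, -0.158, -0.322),
                             "ulna", c(0.016, -0.162, -0.610), 4),
    extensor_carpi_radialis_longus = M("humerus", c(0.000, -0.213, -0.295),
                                       "radius", c(-0.002, -0.206, -0.600), 3),
    extensor_carpi_radialis_brevis = M("humerus", c(-0.002, -0.212, -0.315),
                                       "radius", c(-0.004, -0.203, -0.590), 3),
    extensor_carpi_ulnaris = M("humerus", c(-0.006, -0.210, -0.318),
                               "ulna", c(-0.008, -0.168, -0.612), 3))
}

## ---------------------------------------------------------------------------
## Assembly: reference geometry (thorax frame) -> msm_model

segment_depth <- c(thorax = 0L, clavicle = 1L, scapula = 2L, humerus = 3L,
                   ulna = 4L, radius = 5L)
joint_coords <- list(`1` = 1:3, `2` = 4:6, `3` = 7:9, `4` = 10L, `5` = 11L)

#' Assemble a model from reference geometry
#'
#' Builds all bone-fixed frames, local coordinates, alignment rotations and
#' ribcage ellipsoids from a reference geometry expressed in the thorax
#' frame.  Both the synthetic generator and the morphology scaler funnel
#' through this routine, which guarantees the reference pose satisfies the
#' scapulothoracic constraints exactly (ellipsoid dilation through TS/AI).
#'
#' @param geom reference geometry (see [model_geometry()])
#' @return an `msm_model`
#' @export
assemble_model <- function(geom) {
  lm <- geom$landmarks
  jc <- geom$joint_centers
  HU <- (lm$humerus$EL + lm$humerus$EM) / 2
  lm$humerus$HU <- HU
  ## bone-fixed chain frames
  x_c <- unit3(jc$AC - jc$SC)
  y_c <- unit3(cross3(c(0, 0, 1), x_c))
  R_c <- cbind(x_c, y_c, cross3(x_c, y_c), deparse.level = 0)
  R_s <- build_scapula_frame(lm$scapula$SN, lm$scapula$AI, lm$scapula$TS)$R
  z_h <- unit3(jc$GH - HU)
  y_h <- unit3(cross3(z_h, lm$humerus$EL - lm$humerus$EM))
  R_h <- cbind(cross3(y_h, z_h), y_h, z_h, deparse.level = 0)
  fu <- build_ulna_frame(lm$humerus$EL, lm$humerus$EM, HU, lm$ulna$US)
  fr <- build_radius_frame(lm$humerus$EL, lm$ulna$US, lm$radius$RS)
  R_ref <- list(clavicle = R_c, scapula = R_s, humerus = R_h,
                ulna = fu$R, radius = fr$R)
  origins <- list(clavicle = jc$SC, scapula = jc$AC, humerus = jc$GH,
                  ulna = HU, radius = lm$humerus$EL)
  to_local <- function(p, segment) {
    if (segment == "thorax") return(as.numeric(p))
    as.numeric(t(R_ref[[segment]]) %*% (p - origins[[segment]]))
  }

  segments <- list()
  for (sn in SEGMENT_NAMES) {
    lml <- lapply(lm[[sn]], to_local, segment = sn)
    seg <- geom$inertial[[sn]]
    seg$landmarks_local <- lml
    segments[[sn]] <- seg
  }
  ## geometric lengths and centers of mass
  segments$clavicle$length <- norm3(jc$AC - jc$SC)
  segments$scapula$length <- norm3(lm$scapula$AI - lm$scapula$TS)
  segments$humerus$length <- norm3(jc$GH - HU)
  segments$ulna$length <- norm3(HU - lm$ulna$US)
  segments$radius$length <- norm3(lm$humerus$EL - lm$radius$RS)
  segments$clavicle$com_local <- to_local((jc$SC + jc$AC) / 2, "clavicle")
  segments$scapula$com_local <-
    to_local((lm$scapula$SN + lm$scapula$TS + lm$scapula$AI) / 3, "scapula")
  segments$humerus$com_local <- to_local(jc$GH + 0.45 * (HU - jc$GH), "humerus")
  segments$ulna$com_local <- 0.5 * to_local(lm$ulna$US, "ulna")
  segments$radius$com_local <- 0.5 * to_local(lm$radius$RS, "radius")

  muscles <- list()
  for (mn in names(geom$muscles)) {
    m <- geom$muscles[[mn]]
    att_segs <- c(m$origin$segment, m$insertion$segment,
                  vapply(m$via, function(v) v$segment, character(1)))
    dep <- range(segment_depth[att_segs])
    spanned <- integer(0)
    if (dep[2L] > dep[1L])
      for (j in (dep[1L] + 1L):dep[2L])
        spanned <- c(spanned, joint_coords[[as.character(j)]])
    muscles[[mn]] <- list(
      name = mn,
      origin = list(segment = m$origin$segment,
                    point = to_local(m$origin$point, m$origin$segment)),
      insertion = list(segment = m$insertion$segment,
                       point = to_local(m$insertion$point, m$insertion$segment)),
      via = lapply(m$via, function(v)
        list(segment = v$segment, point = to_local(v$point, v$segment))),
      wraps = m$wraps, n_strings = m$n_strings, pcsa = m$pcsa,
      spanned = spanned,
      elbow_spanning = any(spanned >= 10L))
  }

  ligaments <- list()
  for (ln in names(geom$ligaments)) {
    l <- geom$ligaments[[ln]]
    att_segs <- c(l$origin$segment, l$insertion$segment)
    dep <- range(segment_depth[att_segs])
    spanned <- integer(0)
    if (dep[2L] > dep[1L])
      for (j in (dep[1L] + 1L):dep[2L])
        spanned <- c(spanned, joint_coords[[as.character(j)]])
    ligaments[[ln]] <- list(
      name = ln,
      origin = list(segment = l$origin$segment,
                    point = to_local(l$origin$point, l$origin$segment)),
      insertion = list(segment = l$insertion$segment,
                       point = to_local(l$insertion$point, l$insertion$segment)),
      via = list(), wraps = list(), n_strings = 1L,
      f_max = l$f_max, spanned = spanned)
  }

  wraps <- list()
  for (wn in names(geom$wraps)) {
    w <- geom$wraps[[wn]]
    wraps[[wn]] <- list(
      kind = w$kind,
      center = to_local(w$center, w$attached_segment),
      axis = if (is.null(w$axis)) NULL else
        as.numeric(t(R_ref[[w$attached_segment]]) %*% w$axis),
      radius = w$radius, attached_segment = w$attached_segment,
      wrap_side = w$wrap_side)
  }

  base <- new_ellipsoid(geom$base_center, geom$base_axes)
  d_ts <- solve_dilation(lm$scapula$TS - base$center, base$axes)
  d_ai <- solve_dilation(lm$scapula$AI - base$center, base$axes)

  ## flattened reference landmark map (all thorax positions)
  ref_lm <- list()
  for (sn in SEGMENT_NAMES)
    for (ln in names(lm[[sn]])) ref_lm[[ln]] <- as.numeric(lm[[sn]][[ln]])
  for (pn in names(geom$glenoid_points))
    ref_lm[[pn]] <- as.numeric(geom$glenoid_points[[pn]])
  for (ln in names(geom$thorax_landmarks))
    ref_lm[[ln]] <- as.numeric(geom$thorax_landmarks[[ln]])

  glenoid_local <- lapply(geom$glenoid_points, to_local, segment = "scapula")

  model <- list(
    segments = segments,
    hand = geom$hand,
    chain = precompute_chain(list(
      sc_pos = jc$SC,
      ac_local = to_local(jc$AC, "clavicle"),
      gh_local = to_local(jc$GH, "scapula"),
      R_ref = R_ref,
      Rf_hu = t(R_h) %*% fu$R,
      Rf_ur = t(fu$R) %*% fr$R,
      euler = geom$options$euler)),
    thorax = list(landmarks = geom$thorax_landmarks),
    ellipsoids = list(base = base,
                      ts = new_ellipsoid(base$center, base$axes + d_ts),
                      ai = new_ellipsoid(base$center, base$axes + d_ai),
                      delta_ts = d_ts, delta_ai = d_ai),
    wraps = wraps,
    muscles = muscles,
    ligaments = ligaments,
    glenoid = list(points_local = glenoid_local,
                   alpha_gi = NA_real_, alpha_gv = NA_real_,
                   cone_half_angle = geom$cone_half_angle),
    anthropometry_generic = geom$anthropometry,
    reference = list(q = rep(0, 11L), landmarks = ref_lm),
    options = geom$options,
    r_m_generic = geom$r_m_generic,
    seed = geom$seed)
  class(model) <- "msm_model"
  ang <- glenoid_angles(model)
  model$glenoid$alpha_gi <- ang[["alpha_gi"]]
  model$glenoid$alpha_gv <- ang[["alpha_gv"]]
  model
}

#' Recover the reference geometry of a model
#'
#' Inverse of [assemble_model()]: thorax-frame positions of every landmark,
#' muscle point, wrapping obstacle and glenoid point at the reference pose,
#' plus the inertial, anthropometric and option blocks.
#'
#' @param model an `msm_model`
#' @return a geometry list consumable by [assemble_model()]
#' @export
model_geometry <- function(model) {
  pose <- fk_pose(model, model$reference$q)
  from_local <- function(p, segment) fk_point(pose, segment, p)
  landmarks <- list()
  for (sn in SEGMENT_NAMES)
    landmarks[[sn]] <- lapply(model$segments[[sn]]$landmarks_local,
                              from_local, segment = sn)
  muscles <- list()
  for (mn in names(model$muscles)) {
    m <- model$muscles[[mn]]
    muscles[[mn]] <- list(
      origin = list(segment = m$origin$segment,
                    point = from_local(m$origin$point, m$origin$segment)),
      insertion = list(segment = m$insertion$segment,
                       point = from_local(m$insertion$point,
                                          m$insertion$segment)),
      via = lapply(m$via, function(v)
        list(segment = v$segment, point = from_local(v$point, v$segment))),
      wraps = m$wraps, n_strings = m$n_strings, pcsa = m$pcsa)
  }
  ligaments <- list()
  for (ln in names(model$ligaments)) {
    l <- model$ligaments[[ln]]
    ligaments[[ln]] <- list(
      origin = list(segment = l$origin$segment,
                    point = from_local(l$origin$point, l$origin$segment)),
      insertion = list(segment = l$insertion$segment,
                       point = from_local(l$insertion$point,
                                          l$insertion$segment)),
      f_max = l$f_max)
  }
  wraps <- list()
  for (wn in names(model$wraps)) {
    w <- model$wraps[[wn]]
    wraps[[wn]] <- list(
      kind = w$kind,
      center = from_local(w$center, w$attached_segment),
      axis = if (is.null(w$axis)) NULL else
        as.numeric(pose[[w$attached_segment]]$R %*% w$axis),
      radius = w$radius, attached_segment = w$attached_segment,
      wrap_side = w$wrap_side)
  }
  inertial <- lapply(model$segments, function(s)
    list(mass = s$mass, inertia_diag = s$inertia_diag,
         com_local = s$com_local, length = s$length))
  list(landmarks = landmarks,
       joint_centers = list(SC = model$chain$sc_pos,
                            AC = pose$scapula$o, GH = pose$humerus$o),
       muscles = muscles, ligaments = ligaments, wraps = wraps,
       glenoid_points = lapply(model$glenoid$points_local, from_local,
                               segment = "scapula"),
       thorax_landmarks = model$thorax$landmarks,
       base_center = model$ellipsoids$base$center,
       base_axes = model$ellipsoids$base$axes,
       inertial = inertial,
       hand = model$hand,
       cone_half_angle = model$glenoid$cone_half_angle,
       anthropometry = model$anthropometry_generic,
       options = model$options,
       r_m_generic = model$r_m_generic,
       seed = model$seed)
}

#' Generate the synthetic generic model
#'
#' Deterministic for fixed parameters.  The skeleton is proportioned from the
#' reference tables scaled by stature; the glenoid is built at exactly the
#' requested inclination (version 0); BSIP come from the gender/weight/height
#' predictive equations at the generic anthropometry; the ribcage ellipsoids
#' are dilated through the reference TS/AI so the reference pose satisfies
#' both constraints exactly.
#'
#' @param params a [generator_params()] list
#' @return an `msm_model`
#' @export
generate_generic_model <- function(params = generator_params()) {
  k <- params$stature / 1.86
  scale_pts <- function(lst) lapply(lst, function(p) {
    if (is.list(p)) scale_pts(p) else p * k
  })
  lm <- scale_pts(skeleton_table())
  jc <- scale_pts(joint_table())
  thx <- scale_pts(thorax_table())
  wraps <- wrap_table()
  for (wn in names(wraps)) {
    wraps[[wn]]$center <- wraps[[wn]]$center * k
    wraps[[wn]]$radius <- wraps[[wn]]$radius * k
  }
  ligaments <- ligament_table()
  for (ln in names(ligaments)) {
    ligaments[[ln]]$origin$point <- ligaments[[ln]]$origin$point * k
    ligaments[[ln]]$insertion$point <- ligaments[[ln]]$insertion$point * k
  }
  muscles <- muscle_table()
  for (mn in names(muscles)) {
    muscles[[mn]]$origin$point <- muscles[[mn]]$origin$point * k
    muscles[[mn]]$insertion$point <- muscles[[mn]]$insertion$point * k
    if (length(muscles[[mn]]$via) > 0L)
      for (i in seq_along(muscles[[mn]]$via))
        muscles[[mn]]$via[[i]]$point <- muscles[[mn]]$via[[i]]$point * k
  }
  if (params$n_muscles < length(muscles)) {
    keep_elbow <- ELBOW_MUSCLES
    shoulder <- setdiff(names(muscles), keep_elbow)
    drop_n <- length(muscles) - params$n_muscles
    muscles <- muscles[setdiff(names(muscles), rev(shoulder)[seq_len(drop_n)])]
  }

  ## glenoid rim at exact inclination (version 0) in the scapula frame
  fr_s <- build_scapula_frame(lm$scapula$SN, lm$scapula$AI, lm$scapula$TS)
  xs <- fr_s$R[, 1L]; ys <- fr_s$R[, 2L]; zs <- fr_s$R[, 3L]
  GC <- c(-0.032, -0.168, -0.003) * k
  r_rim <- 0.018 * k   # includes the labrum's effective deepening
  agi <- params$glenoid_inclination * pi / 180
  v_i <- cos(agi) * zs + sin(agi) * xs
  glenoid_points <- list(IG = GC - r_rim * v_i, SG = GC + r_rim * v_i,
                         PG = GC - r_rim * ys, AG = GC + r_rim * ys, GC = GC)

  anthro_g <- list(gender = "male", height = params$stature,
                   mass = params$mass,
                   shoulder_width = 2 * abs(lm$scapula$AI[2L]))
  opts <- default_options()
  inertial <- lapply(SEGMENT_NAMES, function(sn)
    list(mass = 1, inertia_diag = c(1, 1, 1) * 1e-3, com_local = c(0, 0, 0),
         length = 1))
  names(inertial) <- SEGMENT_NAMES
  hand_com <- c(0.01, -0.185, -0.70) * k   # thorax frame, converted below

  geom <- list(landmarks = lm, joint_centers = jc, muscles = muscles,
               ligaments = ligaments,
               wraps = wraps, glenoid_points = glenoid_points,
               thorax_landmarks = thx,
               ## deep thoracic-core ellipsoid: well inside the TS/AI shells so
               ## the dilation factors stay positive over scalings down to 0.5
               base_center = c(-0.015, 0, -0.140) * k,
               base_axes = c(0.045, 0.080, 0.130) * k,
               inertial = inertial,
               hand = list(mass = 0, inertia_diag = c(0, 0, 0),
                           com_local = c(0, 0, 0), merged = FALSE),
               cone_half_angle = NULL,
               anthropometry = anthro_g, options = opts,
               r_m_generic = NA_real_, seed = params$seed)
  model <- assemble_model(geom)
  ## hand block: point mass at the wrist-distal point, local in radius frame
  pose <- fk_pose(model, model$reference$q)
  m_hand <- opts$hand_mass_frac * params$mass
  model$hand <- list(
    mass = m_hand,
    inertia_diag = rep(m_hand * 0.04^2, 3L),
    com_local = as.numeric(t(pose$radius$R) %*% (hand_com - pose$radius$o)),
    merged = FALSE)
  anth <- subject_anthropometry("male", params$stature, params$mass,
                                anthro_g$shoulder_width)
  model$r_m_generic <- muscle_percentage(anth)
  model <- apply_bsip(model, scale_bsip(anth), anth)
  model
}

#' Export noisy marker trajectories for a joint trajectory
#'
#' Writes (or returns) per-frame thorax-frame positions of every segment
#' landmark with additive isotropic Gaussian noise, in the wide CSV layout
#' consumed by [fit_landmarks()].
#'
#' @param model an `msm_model`
#' @param traj an `msm_trajectory`
#' @param noise_sd marker noise standard deviation [m]
#' @param seed RNG seed for the noise
#' @param path optional output CSV path
#' @return the marker data.frame (invisibly if `path` is given)
#' @export
export_marker_motion <- function(model, traj, noise_sd = 0, seed = 1L,
                                 path = NULL) {
  set.seed(seed)
  lm_names <- unlist(lapply(model$segments,
                            function(s) names(s$landmarks_local)))
  n <- length(traj$times)
  cols <- c("time", as.vector(t(outer(lm_names, c("_x", "_y", "_z"),
                                      paste0))))
  out <- as.data.frame(matrix(NA_real_, n, length(cols)))
  names(out) <- cols
  out$time <- traj$times
  for (i in seq_len(n)) {
    lms <- fk_landmarks(model, traj$q[i, ])
    for (ln in lm_names) {
      p <- lms[[ln]] + stats::rnorm(3L, 0, noise_sd)
      out[[paste0(ln, "_x")]][i] <- p[1L]
      out[[paste0(ln, "_y")]][i] <- p[2L]
      out[[paste0(ln, "_z")]][i] <- p[3L]
    }
  }
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
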