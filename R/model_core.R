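## Domain types and schema I/O for the generic shoulder--elbow model.
##
## A model (S3 class "msm_model") is a plain list with components:
##   segments      five bone segments (clavicle, scapula, humerus, ulna,
##                 radius): mass [kg], inertia_diag [kg m^2] in the bone-fixed
##                 chain frame, com_local [m], length [m], landmarks_local
##                 (named 3-vectors in the chain frame)
##   hand          point-mass block rigidly tied to the radius
##   chain         joint centers, reference rotations and the fixed alignment
##                 rotations of the 11-coordinate kinematic chain
##   thorax        landmarks fixed in the thorax (inertial) frame
##   ellipsoids    base/TS/AI ribcage ellipsoids and their dilation factors
##   wraps         sphere/cylinder wrapping obstacles
##   muscles       42 muscle groups (origin, insertion, via points, wraps,
##                 number of strings, PCSA [cm^2], spanned coordinates)
##   glenoid       rim points, center, measured inclination/version, cone spec
##   anthropometry_generic  gender/height/mass/shoulder width of the generic
##                 subject the model was built from
##   reference     the reference pose (q = 0) and all landmark positions in it
##   options       gravity, muscle stress sigma, coordinate ranges, etc.
##
## Internal units are SI (m, kg, s, N, rad).  Schema files use cm / deg /
## kg cm^2 / cm^2 and are converted at the boundary.

SEGMENT_NAMES <- c("clavicle", "scapula", "humerus", "ulna", "radius")

#' Names of the 14 elbow-spanning muscle groups
#' @keywords internal
ELBOW_MUSCLES <- c(
  "triceps_long", "triceps_medial", "triceps_lateral",
  "biceps_short", "biceps_long", "brachialis", "brachioradialis",
  "supinator", "pronator_teres",
  "flexor_carpi_radialis", "flexor_carpi_ulnaris",
  "extensor_carpi_radialis_longus", "extensor_carpi_radialis_brevis",
  "extensor_carpi_ulnaris")

#' Default model options
#' @keywords internal
default_options <- function() {
  list(gravity = 9.81,           # [m/s^2], acting along -z of the thorax
       sigma = 25,               # max muscle stress [N/cm^2] (Fick law)
       lambda_ub = 1e7,          # practical +Inf bound for the multipliers [N]
       lambda_p = 1e-9,          # regularization weight of lambda in P
       hand_mass_frac = 0.006,   # hand mass as fraction of body mass
       q10_range = c(0, 150) * pi / 180,
       q11_range = c(-90, 90) * pi / 180,
       cone_facets = 8L,
       euler = list(sc = "zyx", ac = "zyx", gh = "zxy"))
}

new_ellipsoid <- function(center, axes) {
  stopifnot(length(center) == 3L, length(axes) == 3L)
  list(center = as.numeric(center), axes = as.numeric(axes))
}

#' Quadric matrix of an axis-aligned ellipsoid
#' @param e ellipsoid (list with center, axes)
#' @return 3x3 matrix diag(1/a^2, 1/b^2, 1/c^2)
#' @keywords internal
ellipsoid_quadric <- function(e) diag(1 / e$axes^2)

#' Signed ellipsoid residual (x - e0)^T E (x - e0) - 1
#'
#' Zero on the surface, -1 at the center, positive outside.
#' @param p point (3-vector, thorax frame)
#' @param e ellipsoid
#' @keywords internal
ellipsoid_residual <- function(p, e) {
  d <- (p - e$center) / e$axes
  sum(d * d) - 1
}

## ---------------------------------------------------------------------------
## Validation

violation <- function(field, severity, message) {
  data.frame(field = field, severity = severity, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a generic model
#'
#' Checks every structural invariant of the model: the five named segments
#' with positive masses and admissible inertia tensors, orthonormal stored
#' rotations, positive ellipsoid semi-axes, resolvable muscle wrap references,
#' positive PCSAs, the expected muscle inventory (42 groups, 14 of them
#' elbow-spanning), and that the reference pose satisfies both scapulothoracic
#' ellipsoid constraints.
#'
#' Violations are returned as data, not raised as conditions.
#'
#' @param model an `msm_model`
#' @return a data.frame with columns `field`, `severity` ("error"/"warning"),
#'   `message`; zero rows for a fully valid model
#' @export
validate_model <- function(model) {
  v <- list()
  add <- function(...) v[[length(v) + 1L]] <<- violation(...)

  segs <- model$segments
  if (!identical(sort(names(segs)), sort(SEGMENT_NAMES)))
    add("segments", "error",
        paste("expected exactly the 5 segments",
              paste(SEGMENT_NAMES, collapse = ", ")))
  for (nm in intersect(names(segs), SEGMENT_NAMES)) {
    s <- segs[[nm]]
    if (!is.finite(s$mass) || s$mass <= 0)
      add(paste0("segments.", nm, ".mass"), "error", "mass must be > 0")
    I <- s$inertia_diag
    if (length(I) != 3L || any(!is.finite(I)) || any(I < 0)) {
      add(paste0("segments.", nm, ".inertia_diag"), "error",
          "inertia must be 3 finite nonnegative values")
    } else if (I[1L] > I[2L] + I[3L] + 1e-12 ||
               I[2L] > I[1L] + I[3L] + 1e-12 ||
               I[3L] > I[1L] + I[2L] + 1e-12) {
      add(paste0("segments.", nm, ".inertia_diag"), "error",
          "inertia triangle inequality violated")
    }
    for (lm in names(s$landmarks_local))
      if (any(!is.finite(s$landmarks_local[[lm]])))
        add(paste0("segments.", nm, ".landmarks.", lm), "error",
            "non-finite landmark coordinates")
  }

  for (rn in c("clavicle", "scapula", "humerus", "ulna", "radius"))
    if (!is_rotation(model$chain$R_ref[[rn]], tol = 1e-8))
      add(paste0("chain.R_ref.", rn), "error",
          "stored rotation is not orthonormal with det +1")
  for (rn in c("Rf_hu", "Rf_ur"))
    if (!is_rotation(model$chain[[rn]], tol = 1e-8))
      add(paste0("chain.", rn), "error",
          "alignment rotation is not orthonormal with det +1")

  for (en in c("base", "ts", "ai")) {
    e <- model$ellipsoids[[en]]
    if (is.null(e) || any(!is.finite(e$axes)) || any(e$axes <= 0))
      add(paste0("ellipsoids.", en), "error", "semi-axes must be > 0")
  }

  for (wn in names(model$wraps)) {
    w <- model$wraps[[wn]]
    if (!is.finite(w$radius) || w$radius <= 0)
      add(paste0("wraps.", wn, ".radius"), "error", "radius must be > 0")
    if (!w$attached_segment %in% SEGMENT_NAMES)
      add(paste0("wraps.", wn, ".attached_segment"), "error",
          "unknown attached segment")
    if (identical(w$kind, "cylinder") &&
        (length(w$axis) != 3L || abs(norm3(w$axis) - 1) > 1e-8))
      add(paste0("wraps.", wn, ".axis"), "error", "axis must be unit length")
    if (!w$kind %in% c("sphere", "cylinder"))
      add(paste0("wraps.", wn, ".kind"), "error", "kind must be sphere/cylinder")
    if (!w$wrap_side %in% c("left", "right"))
      add(paste0("wraps.", wn, ".wrap_side"), "error",
          "wrap_side must be left/right")
  }

  n_elbow <- 0L
  for (mn in names(model$muscles)) {
    m <- model$muscles[[mn]]
    if (!is.finite(m$pcsa) || m$pcsa <= 0)
      add(paste0("muscles.", mn, ".pcsa"), "error", "pcsa must be > 0")
    if (m$n_strings < 1L || m$n_strings > 20L)
      add(paste0("muscles.", mn, ".n_strings"), "error",
          "n_strings must be in 1..20")
    for (w in m$wraps)
      if (!w$name %in% names(model$wraps))
        add(paste0("muscles.", mn, ".wraps"), "error",
            paste("unresolved wrap reference", w$name))
    for (att in list(m$origin, m$insertion))
      if (!att$segment %in% c("thorax", SEGMENT_NAMES))
        add(paste0("muscles.", mn), "error",
            paste("unknown attachment segment", att$segment))
    if (isTRUE(m$elbow_spanning)) n_elbow <- n_elbow + 1L
  }
  if (length(model$muscles) != 42L)
    add("muscles", "warning",
        sprintf("expected 42 muscle groups, found %d", length(model$muscles)))
  if (n_elbow != 14L)
    add("muscles", "warning",
        sprintf("expected 14 elbow-spanning muscle groups, found %d", n_elbow))

  g <- model$glenoid
  for (pn in c("IG", "SG", "PG", "AG", "GC"))
    if (is.null(g$points_local[[pn]]) || any(!is.finite(g$points_local[[pn]])))
      add(paste0("glenoid.", pn), "error", "missing or non-finite rim point")
  if (!is.null(g$cone_half_angle) &&
      (g$cone_half_angle <= 0 || g$cone_half_angle >= 90))
    add("glenoid.cone_half_angle", "error", "must lie in (0, 90) degrees")

  ## reference pose must sit on both ribcage ellipsoids
  phi <- tryCatch(ribcage_residuals(model, model$reference$q),
                  error = function(e) NULL)
  if (is.null(phi)) {
    add("reference", "error", "reference-pose constraint residuals not computable")
  } else {
    if (abs(phi[["phi_ts"]]) > 1e-8)
      add("reference.phi_ts", "error",
          sprintf("reference pose off the TS ellipsoid (phi = %.3g)",
                  phi[["phi_ts"]]))
    if (abs(phi[["phi_ai"]]) > 1e-8)
      add("reference.phi_ai", "error",
          sprintf("reference pose off the AI ellipsoid (phi = %.3g)",
                  phi[["phi_ai"]]))
  }

  if (length(v) == 0L)
    return(data.frame(field = character(), severity = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

## ---------------------------------------------------------------------------
## Schema serialization (YAML; cm / deg / kg cm^2 / cm^2 in-file)

m2cm <- function(x) x * 100
cm2m <- function(x) x / 100

mat_to_rows <- function(R) lapply(seq_len(nrow(R)), function(i) as.numeric(R[i, ]))
rows_to_mat <- function(rows) do.call(rbind, lapply(rows, as.numeric))

point_list <- function(points, f) lapply(points, function(p) as.numeric(f(p)))

serialize_model <- function(model) {
  segs <- lapply(model$segments, function(s) {
    list(mass = s$mass,
         inertia_diag = as.numeric(s$inertia_diag * 1e4),  # kg m^2 -> kg cm^2
         com_local = m2cm(as.numeric(s$com_local)),
         length = m2cm(s$length),
         landmarks_local = point_list(s$landmarks_local, m2cm))
  })
  muscles <- lapply(model$muscles, function(m) {
    list(origin = list(segment = m$origin$segment,
                       point = m2cm(as.numeric(m$origin$point))),
         insertion = list(segment = m$insertion$segment,
                          point = m2cm(as.numeric(m$insertion$point))),
         via = lapply(m$via, function(vp)
           list(segment = vp$segment, point = m2cm(as.numeric(vp$point)))),
         wraps = lapply(m$wraps, function(w)
           list(name = w$name, gap = as.integer(w$gap),
                side_dir = if (is.null(w$side_dir)) NULL else
                  as.numeric(w$side_dir))),
         n_strings = as.integer(m$n_strings),
         pcsa = m$pcsa,
         spanned = as.integer(m$spanned),
         elbow_spanning = isTRUE(m$elbow_spanning))
  })
  wraps <- lapply(model$wraps, function(w) {
    list(kind = w$kind, center = m2cm(as.numeric(w$center)),
         axis = if (is.null(w$axis)) NULL else as.numeric(w$axis),
         radius = m2cm(w$radius),
         attached_segment = w$attached_segment, wrap_side = w$wrap_side)
  })
  list(
    schema = "shoulderelbow-model",
    units = list(length = "cm", angle = "deg", inertia = "kg.cm^2",
                 pcsa = "cm^2", mass = "kg"),
    anthropometry = list(
      gender = model$anthropometry_generic$gender,
      height = m2cm(model$anthropometry_generic$height),
      mass = model$anthropometry_generic$mass,
      shoulder_width = m2cm(model$anthropometry_generic$shoulder_width)),
    segments = segs,
    hand = list(mass = model$hand$mass,
                inertia_diag = as.numeric(model$hand$inertia_diag * 1e4),
                com_local = m2cm(as.numeric(model$hand$com_local)),
                merged = isTRUE(model$hand$merged)),
    chain = list(
      sc_pos = m2cm(as.numeric(model$chain$sc_pos)),
      ac_local = m2cm(as.numeric(model$chain$ac_local)),
      gh_local = m2cm(as.numeric(model$chain$gh_local)),
      R_ref = lapply(model$chain$R_ref, mat_to_rows),
      Rf_hu = mat_to_rows(model$chain$Rf_hu),
      Rf_ur = mat_to_rows(model$chain$Rf_ur)),
    thorax = list(landmarks = point_list(model$thorax$landmarks, m2cm)),
    ellipsoids = list(
      base = list(center = m2cm(model$ellipsoids$base$center),
                  axes = m2cm(model$ellipsoids$base$axes)),
      ts = list(center = m2cm(model$ellipsoids$ts$center),
                axes = m2cm(model$ellipsoids$ts$axes)),
      ai = list(center = m2cm(model$ellipsoids$ai$center),
                axes = m2cm(model$ellipsoids$ai$axes)),
      delta_ts = m2cm(model$ellipsoids$delta_ts),
      delta_ai = m2cm(model$ellipsoids$delta_ai)),
    wraps = wraps,
    muscles = muscles,
    ligaments = lapply(model$ligaments, function(l)
      list(origin = list(segment = l$origin$segment,
                         point = m2cm(as.numeric(l$origin$point))),
           insertion = list(segment = l$insertion$segment,
                            point = m2cm(as.numeric(l$insertion$point))),
           f_max = l$f_max, spanned = as.integer(l$spanned))),
    glenoid = list(
      points_local = point_list(model$glenoid$points_local, m2cm),
      alpha_gi = model$glenoid$alpha_gi,
      alpha_gv = model$glenoid$alpha_gv,
      cone_half_angle = model$glenoid$cone_half_angle,
      cone_facets = as.integer(model$options$cone_facets)),
    reference = list(q = as.numeric(model$reference$q) * 180 / pi,
                     landmarks = point_list(model$reference$landmarks, m2cm)),
    options = list(gravity = model$options$gravity,
                   sigma = model$options$sigma,
                   lambda_ub = model$options$lambda_ub,
                   lambda_p = model$options$lambda_p,
                   hand_mass_frac = model$options$hand_mass_frac,
                   q10_range = as.numeric(model$options$q10_range) * 180 / pi,
                   q11_range = as.numeric(model$options$q11_range) * 180 / pi,
                   cone_facets = as.integer(model$options$cone_facets),
                   euler = model$options$euler),
    r_m_generic = model$r_m_generic,
    seed = model$seed)
}

deserialize_model <- function(doc) {
  req <- function(field) {
    x <- doc[[field]]
    if (is.null(x)) stop("model schema violation: missing section '", field, "'")
    x
  }
  if (!identical(doc$schema, "shoulderelbow-model"))
    stop("model schema violation: field 'schema' must be 'shoulderelbow-model'")
  segs_in <- req("segments")
  segments <- lapply(segs_in, function(s) {
    list(mass = as.numeric(s$mass),
         inertia_diag = as.numeric(s$inertia_diag) * 1e-4,
         com_local = cm2m(as.numeric(s$com_local)),
         length = cm2m(as.numeric(s$length)),
         landmarks_local = point_list(s$landmarks_local, cm2m))
  })
  muscles_in <- req("muscles")
  muscles <- Map(function(m, nm) {
    if (as.numeric(m$pcsa) <= 0)
      stop("model schema violation: muscle '", nm,
           "' has pcsa <= 0 (field 'pcsa')")
    list(name = nm,
         origin = list(segment = m$origin$segment,
                       point = cm2m(as.numeric(m$origin$point))),
         insertion = list(segment = m$insertion$segment,
                          point = cm2m(as.numeric(m$insertion$point))),
         via = lapply(m$via, function(vp)
           list(segment = vp$segment, point = cm2m(as.numeric(vp$point)))),
         wraps = lapply(m$wraps, function(w)
           list(name = w$name, gap = as.integer(w$gap),
                side_dir = if (is.null(w$side_dir)) NULL else
                  as.numeric(w$side_dir))),
         n_strings = as.integer(m$n_strings),
         pcsa = as.numeric(m$pcsa),
         spanned = as.integer(m$spanned),
         elbow_spanning = isTRUE(m$elbow_spanning))
  }, muscles_in, names(muscles_in))
  wraps <- lapply(req("wraps"), function(w) {
    list(kind = w$kind, center = cm2m(as.numeric(w$center)),
         axis = if (is.null(w$axis)) NULL else as.numeric(w$axis),
         radius = cm2m(as.numeric(w$radius)),
         attached_segment = w$attached_segment, wrap_side = w$wrap_side)
  })
  ch <- req("chain")
  R_ref <- lapply(ch$R_ref, rows_to_mat)
  for (rn in names(R_ref))
    if (!is_rotation(R_ref[[rn]]))
      stop("model schema violation: chain.R_ref.", rn,
           " is not a proper rotation")
  Rf_hu <- rows_to_mat(ch$Rf_hu); Rf_ur <- rows_to_mat(ch$Rf_ur)
  if (!is_rotation(Rf_hu) || !is_rotation(Rf_ur))
    stop("model schema violation: alignment rotation is not a proper rotation")
  el <- req("ellipsoids")
  anth <- req("anthropometry")
  gl <- req("glenoid")
  opt <- req("options")
  options <- list(gravity = as.numeric(opt$gravity),
                  sigma = as.numeric(opt$sigma),
                  lambda_ub = as.numeric(opt$lambda_ub),
                  lambda_p = as.numeric(opt$lambda_p),
                  hand_mass_frac = as.numeric(opt$hand_mass_frac),
                  q10_range = as.numeric(opt$q10_range) * pi / 180,
                  q11_range = as.numeric(opt$q11_range) * pi / 180,
                  cone_facets = as.integer(opt$cone_facets),
                  euler = opt$euler)
  model <- list(
    segments = segments,
    hand = list(mass = as.numeric(doc$hand$mass),
                inertia_diag = as.numeric(doc$hand$inertia_diag) * 1e-4,
                com_local = cm2m(as.numeric(doc$hand$com_local)),
                merged = isTRUE(doc$hand$merged)),
    chain = list(sc_pos = cm2m(as.numeric(ch$sc_pos)),
                 ac_local = cm2m(as.numeric(ch$ac_local)),
                 gh_local = cm2m(as.numeric(ch$gh_local)),
                 R_ref = R_ref, Rf_hu = Rf_hu, Rf_ur = Rf_ur,
                 euler = options$euler),
    thorax = list(landmarks = point_list(doc$thorax$landmarks, cm2m)),
    ellipsoids = list(
      base = new_ellipsoid(cm2m(as.numeric(el$base$center)),
                           cm2m(as.numeric(el$base$axes))),
      ts = new_ellipsoid(cm2m(as.numeric(el$ts$center)),
                         cm2m(as.numeric(el$ts$axes))),
      ai = new_ellipsoid(cm2m(as.numeric(el$ai$center)),
                         cm2m(as.numeric(el$ai$axes))),
      delta_ts = cm2m(as.numeric(el$delta_ts)),
      delta_ai = cm2m(as.numeric(el$delta_ai))),
    wraps = wraps,
    muscles = muscles,
    ligaments = Map(function(l, nm)
      list(name = nm,
           origin = list(segment = l$origin$segment,
                         point = cm2m(as.numeric(l$origin$point))),
           insertion = list(segment = l$insertion$segment,
                            point = cm2m(as.numeric(l$insertion$point))),
           via = list(), wraps = list(), n_strings = 1L,
           f_max = as.numeric(l$f_max), spanned = as.integer(l$spanned)),
      doc$ligaments, names(doc$ligaments)),
    glenoid = list(points_local = point_list(gl$points_local, cm2m),
                   alpha_gi = as.numeric(gl$alpha_gi),
                   alpha_gv = as.numeric(gl$alpha_gv),
                   cone_half_angle =
                     if (is.null(gl$cone_half_angle)) NULL
                     else as.numeric(gl$cone_half_angle)),
    anthropometry_generic = list(gender = anth$gender,
                                 height = cm2m(as.numeric(anth$height)),
                                 mass = as.numeric(anth$mass),
                                 shoulder_width =
                                   cm2m(as.numeric(anth$shoulder_width))),
    reference = list(q = as.numeric(doc$reference$q) * pi / 180,
                     landmarks = point_list(doc$reference$landmarks, cm2m)),
    options = options,
    r_m_generic = as.numeric(doc$r_m_generic),
    seed = doc$seed)
  model$chain <- precompute_chain(model$chain)
  class(model) <- "msm_model"
  model
}

#' Precompute the fixed composed rotations of the chain
#' @keywords internal
precompute_chain <- function(chain) {
  chain$C_cs <- t(chain$R_ref$clavicle) %*% chain$R_ref$scapula
  chain$C_sh <- t(chain$R_ref$scapula) %*% chain$R_ref$humerus
  chain
}

#' Save a generic model to a YAML schema file
#'
#' @param model an `msm_model`
#' @param path output file path
#' @return `path`, invisibly
#' @export
save_model <- function(model, path) {
  doc <- serialize_model(model)
  txt <- yaml::as.yaml(doc, precision = 17L)
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write model file: ", path)
  invisible(path)
}

#' Load a generic model from a YAML schema file
#'
#' Parses the schema, converts in-file units (cm, deg, kg cm^2) to internal SI,
#' and fails with a descriptive message naming the offending field if the
#' document violates the schema or stores a non-orthonormal rotation.
#'
#' @param path path to a model schema file written by [save_model()]
#' @return an `msm_model`
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file does not exist: ", path)
  doc <- yaml::read_yaml(path)
  model <- deserialize_model(doc)
  rep <- validate_model(model)
  errs <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L)
    stop("invalid model (", errs$field[1L], "): ", errs$message[1L])
  model
}

#' @export
print.msm_model <- function(x, ...) {
  cat("Scaled-generic shoulder--elbow model\n")
  cat(sprintf("  generic subject: %s, %.2f m, %.1f kg\n",
              x$anthropometry_generic$gender, x$anthropometry_generic$height,
              x$anthropometry_generic$mass))
  cat(sprintf("  segments: %d; muscles: %d (%d elbow-spanning); wraps: %d\n",
              length(x$segments), length(x$muscles),
              sum(vapply(x$muscles, function(m) isTRUE(m$elbow_spanning),
                         logical(1))), length(x$wraps)))
  cat(sprintf("  glenoid inclination %.2f deg, version %.2f deg\n",
              x$glenoid$alpha_gi, x$glenoid$alpha_gv))
  invisible(x)
}
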