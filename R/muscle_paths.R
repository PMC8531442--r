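## Obstacle-set muscle paths (single sphere/cylinder per polyline gap,
## chained through via points) and moment arms by the geometric
## (virtual-work) and tendon-excursion definitions.

## 2D circle wrap: tangent points and arc for endpoints outside a circle of
## radius r at the origin.  `sense` +1 traverses the arc counterclockwise
## from T1 to T2, -1 clockwise; NA picks the shorter of the two.
circle_wrap_2d <- function(p1, p2, r, sense = NA) {
  d1 <- sqrt(sum(p1^2)); d2 <- sqrt(sum(p2^2))
  if (d1 <= r || d2 <= r)
    stop("wrap endpoint inside the obstacle")
  ## does the segment p1-p2 come within r of the origin?
  dp <- p2 - p1
  if (sum(dp * dp) < 1e-20) return(NULL)  # degenerate projection: no wrap
  tt <- -sum(p1 * dp) / sum(dp * dp)
  tt <- max(0, min(1, tt))
  if (sqrt(sum((p1 + tt * dp)^2)) >= r) return(NULL)  # no wrap engaged
  a1 <- atan2(p1[2L], p1[1L]); a2 <- atan2(p2[2L], p2[1L])
  t1 <- acos(min(1, r / d1)); t2 <- acos(min(1, r / d2))
  cand <- function(s) {
    phi1 <- a1 + s * t1           # tangent point seen from p1, side s
    phi2 <- a2 - s * t2
    dphi <- (s * (phi2 - phi1)) %% (2 * pi)  # arc traversed in direction s
    list(phi1 = phi1, phi2 = phi2, sense = s, arc = dphi,
         len = sqrt(d1^2 - r^2) + sqrt(d2^2 - r^2) + r * dphi)
  }
  cands <- list(cand(1), cand(-1))
  if (is.na(sense)) {
    cands[[which.min(c(cands[[1L]]$len, cands[[2L]]$len))]]
  } else {
    cands[[if (sense > 0) 1L else 2L]]
  }
}

arc_points_2d <- function(sol, r, n = 17L) {
  phis <- sol$phi1 + sol$sense * seq(0, sol$arc, length.out = n)
  cbind(r * cos(phis), r * sin(phis))
}

#' Wrap a path segment over a sphere
#'
#' Single-obstacle solution: if the chord misses the sphere the path is
#' straight; otherwise the geodesic solution in the plane through the two
#' endpoints and the center, with two straight tangent segments and a
#' great-circle arc.  Of the two geodesic candidates the shorter is taken
#' unless `side_dir` (a thorax-frame direction) is given, in which case the
#' arc bulging toward that direction is selected (used to keep e.g. the
#' deltoid on the lateral side of the humeral head at every frame).
#'
#' @param p1,p2 endpoints (3-vectors, thorax frame), outside the sphere
#' @param center sphere center (thorax frame)
#' @param radius sphere radius [m]
#' @param side_dir optional preferred bulge direction (thorax frame)
#' @param n_arc arc discretization for the returned node list
#' @return list `points` (node matrix, rows = points), `length` [m],
#'   `wrapped` (logical)
#' @export
wrap_sphere <- function(p1, p2, center, radius, side_dir = NULL, n_arc = 17L) {
  u <- p1 - center; v <- p2 - center
  e1 <- unit3(u)
  vperp <- v - sum(v * e1) * e1
  if (norm3(vperp) < 1e-12) {
    ## endpoints collinear with center: any plane; pick one orthogonal
    aux <- if (abs(e1[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    vperp <- aux - sum(aux * e1) * e1
  }
  e2 <- unit3(vperp)
  q1 <- c(sum(u * e1), sum(u * e2))
  q2 <- c(sum(v * e1), sum(v * e2))
  pick <- NULL
  if (!is.null(side_dir)) {
    sols <- lapply(c(1, -1), function(s) circle_wrap_2d(q1, q2, radius, s))
    if (!is.null(sols[[1L]])) {
      score <- vapply(sols, function(sol) {
        mid <- sol$phi1 + sol$sense * sol$arc / 2
        dir3 <- cos(mid) * e1 + sin(mid) * e2
        sum(dir3 * side_dir)
      }, numeric(1L))
      pick <- sols[[which.max(score)]]
    }
  } else {
    pick <- circle_wrap_2d(q1, q2, radius, NA)
  }
  if (is.null(pick))
    return(list(points = rbind(p1, p2), length = norm3(p2 - p1),
                wrapped = FALSE))
  arc2 <- arc_points_2d(pick, radius, n_arc)
  arc3 <- t(apply(arc2, 1L, function(a)
    center + a[1L] * e1 + a[2L] * e2))
  pts <- rbind(p1, arc3, p2)
  len <- norm3(arc3[1L, ] - p1) + radius * pick$arc +
    norm3(p2 - arc3[nrow(arc3), ])
  list(points = pts, length = len, wrapped = TRUE)
}

#' Wrap a path segment over a cylinder
#'
#' Standard single-cylinder obstacle-set solution: the transverse projection
#' solves the planar circle problem (traversal sense fixed by `wrap_side`,
#' never inferred per frame), and the axial coordinate is interpolated
#' linearly with developed (unrolled) path length, giving a helical arc and
#' a C1 path.
#'
#' @param p1,p2 endpoints (thorax frame), outside the cylinder surface
#' @param center a point on the cylinder axis
#' @param axis unit axis direction
#' @param radius cylinder radius [m]
#' @param wrap_side "left" (counterclockwise about `axis`) or "right"
#' @param n_arc arc discretization
#' @return list `points`, `length`, `wrapped`
#' @export
wrap_cylinder <- function(p1, p2, center, axis, radius,
                          wrap_side = "left", n_arc = 17L) {
  axis <- unit3(axis)
  aux <- if (abs(axis[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit3(aux - sum(aux * axis) * axis)
  e2 <- cross3(axis, e1)
  tolocal <- function(p) {
    d <- p - center
    c(sum(d * e1), sum(d * e2), sum(d * axis))
  }
  q1 <- tolocal(p1); q2 <- tolocal(p2)
  sense <- if (wrap_side == "left") 1 else -1
  sol <- circle_wrap_2d(q1[1:2], q2[1:2], radius, sense)
  if (is.null(sol))
    return(list(points = rbind(p1, p2), length = norm3(p2 - p1),
                wrapped = FALSE))
  l1 <- sqrt(sum(q1[1:2]^2) - radius^2)
  l2 <- sqrt(sum(q2[1:2]^2) - radius^2)
  arc <- radius * sol$arc
  ltot <- l1 + arc + l2
  z_t1 <- q1[3L] + (q2[3L] - q1[3L]) * l1 / ltot
  z_t2 <- q1[3L] + (q2[3L] - q1[3L]) * (l1 + arc) / ltot
  arc2 <- arc_points_2d(sol, radius, n_arc)
  zs <- seq(z_t1, z_t2, length.out = n_arc)
  arc3 <- t(vapply(seq_len(n_arc), function(i)
    center + arc2[i, 1L] * e1 + arc2[i, 2L] * e2 + zs[i] * axis,
    numeric(3L)))
  pts <- rbind(p1, arc3, p2)
  dz <- q2[3L] - q1[3L]
  len <- sqrt(l1^2 + (dz * l1 / ltot)^2) +
    sqrt(arc^2 + (dz * arc / ltot)^2) +
    sqrt(l2^2 + (dz * l2 / ltot)^2)
  list(points = pts, length = len, wrapped = TRUE)
}

#' Muscle path at a configuration
#'
#' Threads origin -> via points -> insertion, applying at most one wrapping
#' obstacle per polyline gap (the obstacle and its gap are fixed in the
#' model, so engagement is purely geometric and hysteresis-free).
#'
#' @param model an `msm_model`
#' @param q 11-vector
#' @param muscle muscle name or muscle list entry
#' @param pose optional precomputed pose
#' @param detail if TRUE, return the node list with per-node segment
#'   attribution (needed for geometric moment arms and the joint reaction
#'   force); if FALSE only the path length is computed
#' @return list with `length` [m], `wrapped` (named logical per obstacle),
#'   and when `detail` also `points` (node matrix) and `node_segment`
#' @export
muscle_path <- function(model, q, muscle, pose = fk_pose(model, q),
                        detail = FALSE) {
  m <- if (is.character(muscle)) model$muscles[[muscle]] else muscle
  if (is.null(m)) stop("unknown muscle: ", muscle)
  atts <- c(list(m$origin), m$via, list(m$insertion))
  pts <- lapply(atts, function(a) fk_point(pose, a$segment, a$point))
  segs <- vapply(atts, function(a) a$segment, character(1L))
  wrap_by_gap <- list()
  for (w in m$wraps) wrap_by_gap[[as.character(w$gap)]] <- w
  total <- 0
  nodes <- NULL; node_seg <- character(0)
  wrapped <- logical(0)
  n_gap <- length(pts) - 1L
  for (gidx in seq_len(n_gap)) {
    p1 <- pts[[gidx]]; p2 <- pts[[gidx + 1L]]
    wref <- wrap_by_gap[[as.character(gidx)]]
    if (is.null(wref)) {
      total <- total + norm3(p2 - p1)
      if (detail) {
        if (is.null(nodes)) { nodes <- rbind(p1); node_seg <- segs[gidx] }
        nodes <- rbind(nodes, p2); node_seg <- c(node_seg, segs[gidx + 1L])
      }
      next
    }
    obj <- model$wraps[[wref$name]]
    op <- pose[[obj$attached_segment]]
    ctr <- fk_point(pose, obj$attached_segment, obj$center)
    res <- tryCatch({
      if (obj$kind == "sphere") {
        sd <- if (is.null(wref$side_dir)) NULL else
          as.numeric(op$R %*% wref$side_dir)
        wrap_sphere(p1, p2, ctr, obj$radius, side_dir = sd)
      } else {
        ax <- as.numeric(op$R %*% obj$axis)
        wrap_cylinder(p1, p2, ctr, ax, obj$radius, obj$wrap_side)
      }
    }, error = function(e)
      stop("wrap failure for muscle '", m$name, "' on obstacle '",
           wref$name, "': ", conditionMessage(e)))
    total <- total + res$length
    wrapped[wref$name] <- res$wrapped
    if (detail) {
      k <- nrow(res$points)
      if (is.null(nodes)) { nodes <- rbind(p1); node_seg <- segs[gidx] }
      if (k > 2L) {
        nodes <- rbind(nodes, res$points[2:(k - 1L), , drop = FALSE])
        node_seg <- c(node_seg, rep(obj$attached_segment, k - 2L))
      }
      nodes <- rbind(nodes, p2); node_seg <- c(node_seg, segs[gidx + 1L])
    }
  }
  out <- list(length = total, wrapped = wrapped)
  if (detail) {
    rownames(nodes) <- NULL
    out$points <- nodes
    out$node_segment <- node_seg
  }
  out
}

#' Per-node unit-tension forces of a path polyline
#'
#' Interior nodes receive the sum of the unit vectors toward both neighbours
#' (the discretized normal load of arcs and via points); the end nodes the
#' pull toward their single neighbour.
#' @keywords internal
path_node_forces <- function(points) {
  n <- nrow(points)
  F <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    if (i > 1L) {
      d <- points[i - 1L, ] - points[i, ]
      nd <- norm3(d); if (nd > 1e-12) F[i, ] <- F[i, ] + d / nd
    }
    if (i < n) {
      d <- points[i + 1L, ] - points[i, ]
      nd <- norm3(d); if (nd > 1e-12) F[i, ] <- F[i, ] + d / nd
    }
  }
  F
}

#' Moment-arm matrix at a configuration
#'
#' Tendon excursion: `W[k, j] = -dL_j/dq_k` by central differences of the
#' path length.  Geometric: virtual work of the unit-tension node forces
#' through the exact rigid-body point Jacobians `a_k x (p - c_k)`.
#' Coordinates a muscle does not span are exactly zero.
#'
#' @param model an `msm_model`
#' @param q 11-vector
#' @param method "excursion" or "geometric"
#' @param dq finite-difference step [rad] (excursion)
#' @param muscles optional subset of muscle names
#' @return 11 x n matrix [m], columns named by muscle
#' @export
moment_arms <- function(model, q, method = c("excursion", "geometric"),
                        dq = 1e-5, muscles = names(model$muscles)) {
  method <- match.arg(method)
  W <- matrix(0, 11L, length(muscles),
              dimnames = list(NULL, muscles))
  if (method == "excursion") {
    ## group path evaluations by perturbed coordinate
    span <- lapply(muscles, function(mn) model$muscles[[mn]]$spanned)
    all_k <- sort(unique(unlist(span)))
    for (k in all_k) {
      qp <- q; qp[k] <- q[k] + dq
      qm <- q; qm[k] <- q[k] - dq
      posep <- fk_pose(model, qp); posem <- fk_pose(model, qm)
      for (j in seq_along(muscles)) {
        if (!(k %in% span[[j]])) next
        lp <- muscle_path(model, qp, muscles[j], posep)$length
        lm <- muscle_path(model, qm, muscles[j], posem)$length
        W[k, j] <- -(lp - lm) / (2 * dq)
      }
    }
  } else {
    pose <- fk_pose(model, q)
    ja <- joint_axes(model, q, pose)
    for (j in seq_along(muscles)) {
      m <- model$muscles[[muscles[j]]]
      path <- muscle_path(model, q, muscles[j], pose, detail = TRUE)
      F <- path_node_forces(path$points)
      for (k in m$spanned) {
        tau_k <- 0
        for (i in seq_len(nrow(path$points))) {
          sn <- path$node_segment[i]
          if (sn == "thorax" || !(k %in% segment_coords(sn))) next
          Jp <- cross3(ja$axes[, k], path$points[i, ] - ja$centers[, k])
          tau_k <- tau_k + sum(F[i, ] * Jp)
        }
        W[k, j] <- tau_k
      }
    }
  }
  W
}
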