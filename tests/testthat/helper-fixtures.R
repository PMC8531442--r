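## Shared fixtures, memoized so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

generic_model <- function() memo("generic", generate_generic_model())

generic_anthro <- function() {
  m <- generic_model()
  subject_anthropometry("male", 1.86, 85.5,
                        m$anthropometry_generic$shoulder_width)
}

## short feasible abduction trajectory for dynamics/load-sharing tests
short_trajectory <- function() memo("short_traj",
  abduction_trajectory(generic_model(), 20, 150, n_steps = 15,
                       duration = 3.25))

## random physiological configuration drawn from the trajectory manifold
## plus a perturbation of the free coordinates
random_configuration <- function(model, elev_frac = runif(1)) {
  traj <- short_trajectory()
  i <- 1L + floor(elev_frac * (nrow(traj$q) - 1L))
  q <- traj$q[i, ]
  q[7:11] <- q[7:11] + runif(5, -0.1, 0.1)
  q
}

## Full six-scenario abduction battery used by the acceptance tests
## (generic, gender, two weights, two heights); 131 frames each.
abduction_battery <- function() memo("battery", {
  m <- generic_model()
  wg <- m$anthropometry_generic$shoulder_width
  scen <- list(
    generic = subject_anthropometry("male", 1.86, 85.5, wg),
    female = subject_anthropometry("female", 1.86, 85.5, wg),
    w60 = subject_anthropometry("male", 1.86, 60, wg),
    w100 = subject_anthropometry("male", 1.86, 100, wg),
    h160 = subject_anthropometry("male", 1.60, 85.5, wg * 1.60 / 1.86),
    h195 = subject_anthropometry("male", 1.95, 85.5, wg * 1.95 / 1.86))
  t0 <- Sys.time()
  out <- lapply(names(scen), function(nm) {
    sm <- scale_subject(m, scen[[nm]])$model
    traj <- abduction_trajectory(sm, 20, 150, n_steps = 131,
                                 duration = 3.25)
    simulate_abduction(sm, traj)
  })
  names(out) <- names(scen)
  attr(out, "elapsed_s") <- as.numeric(Sys.time() - t0, units = "secs")
  out
})

## Dense brute-force QP reference: enumerate active sets of an inequality/
## bound-constrained strictly convex QP (diagonal P) with equality
## constraints; returns the optimal x.  Only viable for a handful of
## variables -- that is the point: it is independent of the QP solver.
brute_force_qp <- function(P, Aeq, beq, lb, ub, G = NULL, h = NULL) {
  n <- length(P)
  m_ineq <- if (is.null(G)) 0L else nrow(G)
  best <- NULL; best_val <- Inf
  ## active-set candidates: each variable free, at lb, or at ub; each
  ## inequality inactive or active
  var_states <- expand.grid(rep(list(0:2), n))
  ineq_states <- if (m_ineq > 0) expand.grid(rep(list(0:1), m_ineq)) else
    data.frame(x = 0)[, 0, drop = FALSE]
  for (vi in seq_len(nrow(var_states))) {
    vs <- as.integer(var_states[vi, ])
    free <- which(vs == 0L)
    x_fixed <- numeric(n)
    x_fixed[vs == 1L] <- lb[vs == 1L]
    x_fixed[vs == 2L] <- ub[vs == 2L]
    for (ii in seq_len(max(1L, nrow(ineq_states)))) {
      act <- if (m_ineq > 0) which(as.integer(ineq_states[ii, ]) == 1L) else
        integer(0)
      ## KKT system on free variables: minimize sum P x^2 s.t. equalities
      ## and active inequalities as equalities
      A <- Aeq
      b <- beq
      if (length(act) > 0L) { A <- rbind(A, G[act, , drop = FALSE])
                              b <- c(b, h[act]) }
      if (length(free) == 0L) {
        x <- x_fixed
        if (max(abs(A %*% x - b)) > 1e-8) next
      } else {
        Af <- A[, free, drop = FALSE]
        bf <- b - A[, -free, drop = FALSE] %*% x_fixed[-free]
        if (length(free) == n) bf <- b
        ## stationarity: 2 P_f x_f = Af' nu  ->  solve bordered system
        k <- nrow(Af)
        K <- rbind(cbind(diag(2 * P[free], length(free)), t(Af)),
                   cbind(Af, matrix(0, k, k)))
        rhs <- c(numeric(length(free)), bf)
        sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        x <- x_fixed
        x[free] <- sol[seq_along(free)]
      }
      ## primal feasibility
      if (any(x < lb - 1e-9) || any(x > ub + 1e-9)) next
      if (m_ineq > 0 && any(G %*% x > h + 1e-9)) next
      if (max(abs(Aeq %*% x - beq)) > 1e-8) next
      val <- sum(P * x^2)
      if (val < best_val - 1e-12) { best <- x; best_val <- val }
    }
  }
  list(x = best, value = best_val)
}
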