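# Axisymmetric nonlinear membrane solver with volume-controlled loading.
#
# The balloon meridian is discretised into two-node axisymmetric membrane
# elements.  Each element carries a meridional stretch lm = L/L0 and a
# circumferential stretch lt = (r_l + r_r)/(r0_l + r0_r); the membrane is
# fully incompressible (plane stress, l3 = 1/(lm*lt)).  Static equilibrium
# is the stationarity of
#     Pi(x, P) = E_int(x) - P * V(x) + contact terms,
# with the cavity pressure P a Lagrange-multiplier unknown enforcing the
# prescribed cavity volume V(x) = V_target (the incompressible-fluid
# reduction of fluid-cavity loading).  Membranes cannot carry compression:
# elements whose biaxial stress would be compressive use a tension-field
# (wrinkling-relaxed) energy, with a small stabilising fraction of the
# biaxial energy retained so slack regions keep a well-posed tangent.

REGIME_TAUT <- 0L
REGIME_WRINKLE_T <- 1L   # circumferential wrinkling: sigma_theta relaxed to 0
REGIME_WRINKLE_M <- 2L   # meridional wrinkling: sigma_m relaxed to 0
REGIME_SLACK <- 3L

solver_options <- function(options = list()) {
  defaults <- list(dV_max_ml = 0.25, tol = 1e-7, max_iter = 40,
                   max_regime_iter = 40, reg = 1e-3, penalty = NULL,
                   max_penalty_escalations = 4, verbose = FALSE)
  defaults[names(options)] <- options
  defaults
}

# internal assembly: energy, gradient, volume, volume gradient, stretches,
# taut-formula stresses, and contact pressures, for deformed coords (z, r).
# regimes: integer per element.  contact: NULL or list(rp0, cmpl, k) where
# rp0/cmpl are per-node baseline radius (Inf = no wall) and compliance.
assemble_system <- function(z, r, mesh, model, regimes, contact = NULL,
                            reg = 1e-4) {
  nn <- length(z); n <- nn - 1L
  dz <- z[-1] - z[-nn]; dr <- r[-1] - r[-nn]
  L <- sqrt(dz^2 + dr^2)
  lm <- L / mesh$L0
  m0 <- mesh$r0[-nn] + mesh$r0[-1]
  m <- r[-nn] + r[-1]
  lt <- m / m0
  if (any(lm <= 0) || any(lt <= 0)) {
    bad <- which(lm <= 0 | lt <= 0)[1]
    bm_stop(sprintf("non-positive stretch in element %d", bad),
            class = "balloonmech_solver_error")
  }
  w <- pi * m0 * mesh$L0 * mesh$t0   # reference membrane volume per element

  sig <- ogden_membrane_stress(lm, lt, model)
  du_dlm_b <- sig$sigma_m / lm
  du_dlt_b <- sig$sigma_t / lt
  u_b <- ogden_membrane_energy(lm, lt, model)

  u <- u_b; du_dlm <- du_dlm_b; du_dlt <- du_dlt_b
  iw_t <- which(regimes == REGIME_WRINKLE_T)
  iw_m <- which(regimes == REGIME_WRINKLE_M)
  isl <- which(regimes == REGIME_SLACK)
  if (length(iw_t)) {
    u[iw_t] <- ogden_uniaxial_energy(lm[iw_t], model) + reg * u_b[iw_t]
    du_dlm[iw_t] <- ogden_uniaxial_stress(lm[iw_t], model, "nominal") +
      reg * du_dlm_b[iw_t]
    du_dlt[iw_t] <- reg * du_dlt_b[iw_t]
  }
  if (length(iw_m)) {
    u[iw_m] <- ogden_uniaxial_energy(lt[iw_m], model) + reg * u_b[iw_m]
    du_dlt[iw_m] <- ogden_uniaxial_stress(lt[iw_m], model, "nominal") +
      reg * du_dlt_b[iw_m]
    du_dlm[iw_m] <- reg * du_dlm_b[iw_m]
  }
  if (length(isl)) {
    u[isl] <- reg * u_b[isl]
    du_dlm[isl] <- reg * du_dlm_b[isl]
    du_dlt[isl] <- reg * du_dlt_b[isl]
  }

  E <- sum(w * u)
  a_m <- w * du_dlm / (L * mesh$L0)
  g_z <- numeric(nn); g_r <- numeric(nn)
  g_z[1:n] <- g_z[1:n] - a_m * dz
  g_z[2:nn] <- g_z[2:nn] + a_m * dz
  ct <- w * du_dlt / m0
  g_r[1:n] <- g_r[1:n] - a_m * dr + ct
  g_r[2:nn] <- g_r[2:nn] + a_m * dr + ct

  rl <- r[-nn]; rr <- r[-1]
  S <- rl^2 + rl * rr + rr^2
  V <- sum((pi / 3) * S * dz)
  gV_z <- numeric(nn); gV_r <- numeric(nn)
  gV_z[1:n] <- gV_z[1:n] - (pi / 3) * S
  gV_z[2:nn] <- gV_z[2:nn] + (pi / 3) * S
  gV_r[1:n] <- gV_r[1:n] + (pi / 3) * (2 * rl + rr) * dz
  gV_r[2:nn] <- gV_r[2:nn] + (pi / 3) * (rl + 2 * rr) * dz

  q <- numeric(nn)
  if (!is.null(contact)) {
    rp0 <- contact$rp0_fn(z)
    cmpl <- contact$cmpl_fn(z)
    gap <- r - rp0
    act <- is.finite(rp0) & gap > 0
    if (any(act)) {
      q[act] <- contact$k * gap[act] / (1 + contact$k * cmpl[act])
      Ltrib <- numeric(nn)
      Ltrib[1:n] <- Ltrib[1:n] + L / 2
      Ltrib[2:nn] <- Ltrib[2:nn] + L / 2
      g_r <- g_r + q * 2 * pi * r * Ltrib
    }
  }

  list(E = E, g_z = g_z, g_r = g_r, V = V, gV_z = gV_z, gV_r = gV_r,
       lm = lm, lt = lt, sigma_m = sig$sigma_m, sigma_t = sig$sigma_t,
       q = q)
}

# internal: choose the membrane regime of each element from its stretches.
# Stress-based tension-field test: taut if both biaxial stresses tensile;
# otherwise relax the compressive direction if the complementary uniaxial
# state is tensile, else slack.
classify_regimes <- function(lm, lt, model, tolS) {
  sig <- ogden_membrane_stress(lm, lt, model)
  uni_m <- ogden_uniaxial_stress(lm, model)
  uni_t <- ogden_uniaxial_stress(lt, model)
  reg <- rep(REGIME_TAUT, length(lm))
  not_taut <- sig$sigma_m < -tolS | sig$sigma_t < -tolS
  wt <- not_taut & sig$sigma_t <= sig$sigma_m & uni_m > tolS
  wm <- not_taut & sig$sigma_m < sig$sigma_t & uni_t > tolS
  reg[wt] <- REGIME_WRINKLE_T
  reg[wm] <- REGIME_WRINKLE_M
  reg[not_taut & !wt & !wm] <- REGIME_SLACK
  reg
}

# internal Newton solve of {equilibrium = 0, V = V_target} at frozen
# regimes.  u packs free dofs (z of nodes 2..nn, r of nodes 2..nn-1);
# r at both ends and z of node 1 are fixed.
newton_volume_step <- function(u, P, V_target_mm3, mesh, model, regimes,
                               contact, opts) {
  nn <- length(mesh$z0)
  n_zfree <- nn - 1L
  n_rfree <- nn - 2L
  nfree <- n_zfree + n_rfree
  unpack <- function(u) {
    z <- c(mesh$z0[1], u[1:n_zfree])
    r <- c(mesh$r0[1], u[(n_zfree + 1):nfree], mesh$r0[nn])
    list(z = z, r = r)
  }
  free_idx_z <- 2:nn
  free_idx_r <- 2:(nn - 1)
  resid <- function(u, P) {
    x <- unpack(u)
    a <- assemble_system(x$z, x$r, mesh, model, regimes, contact, opts$reg)
    Rz <- a$g_z - P * a$gV_z
    Rr <- a$g_r - P * a$gV_r
    list(R = c(Rz[free_idx_z], Rr[free_idx_r]), a = a)
  }

  # colouring for the banded FD Jacobian: residual rows at node j depend on
  # u-columns of nodes j-1..j+1, so nodes spaced 3 apart are independent
  node_of_u <- c(free_idx_z, free_idx_r)
  dof_of_u <- c(rep(1L, n_zfree), rep(2L, n_rfree))
  color <- (node_of_u %% 3L) * 2L + dof_of_u
  rows_of_node <- vector("list", nn)
  for (i in seq_len(nfree)) {
    j <- node_of_u[i]
    rows_of_node[[j]] <- c(rows_of_node[[j]], i)
  }
  affected_rows <- lapply(seq_len(nfree), function(i) {
    j <- node_of_u[i]
    unlist(rows_of_node[max(1, j - 1):min(nn, j + 1)], use.names = FALSE)
  })

  jacobian <- function(u, P, R0) {
    # central differences: forward-difference truncation error is large
    # relative to the weak radial stiffness near the stress-free state and
    # destroys the Newton rate
    J <- matrix(0, nfree, nfree)
    for (cl in unique(color)) {
      idx <- which(color == cl)
      h <- 1e-6 * (1 + abs(u[idx]))
      up <- u; up[idx] <- up[idx] + h
      um <- u; um[idx] <- um[idx] - h
      Rp <- resid(up, P)$R
      Rm <- resid(um, P)$R
      for (k in seq_along(idx)) {
        i <- idx[k]
        rows <- affected_rows[[i]]
        J[rows, i] <- (Rp[rows] - Rm[rows]) / (2 * h[k])
      }
    }
    J
  }

  Vs <- max(V_target_mm3, 1)
  r0 <- resid(u, P)

  # Newton with affine-invariant (natural monotonicity) damping: a trial
  # point is accepted when the simplified Newton correction computed with
  # the current factorisation shrinks (Deuflhard's test), which is immune
  # to the poor scaling of raw residual norms near the stress-free state.
  for (iter in seq_len(opts$max_iter)) {
    a <- r0$a
    Fs <- max(1e-3, abs(P) * max(abs(c(a$gV_z, a$gV_r))),
              max(abs(c(a$g_z, a$g_r))))
    cV <- a$V - V_target_mm3
    if (max(abs(r0$R)) <= opts$tol * Fs && abs(cV) <= 1e-8 * Vs)
      return(list(u = u, P = P, a = a, converged = TRUE, iters = iter))
    J <- jacobian(u, P, r0$R)
    gVf <- c(a$gV_z[free_idx_z], a$gV_r[free_idx_r])
    A <- rbind(cbind(J, -gVf), c(gVf, 0))
    qrA <- tryCatch(qr(A), error = function(e) NULL)
    if (is.null(qrA))
      return(list(u = u, P = P, a = a, converged = FALSE, iters = iter))
    step <- tryCatch(qr.coef(qrA, -c(r0$R, cV)), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(u = u, P = P, a = a, converged = FALSE, iters = iter))
    nstep <- sqrt(sum(step^2))
    if (nstep <= 1e-9 * (1 + sqrt(sum(u^2)))) {
      # step at roundoff level: converged iff the volume constraint holds
      conv <- abs(cV) <= 1e-8 * Vs
      return(list(u = u, P = P, a = a, converged = conv, iters = iter))
    }
    alpha <- 1
    ok <- FALSE
    for (ls in 1:25) {
      u_try <- u + alpha * step[1:nfree]
      P_try <- P + alpha * step[nfree + 1]
      r_try <- tryCatch(resid(u_try, P_try), error = function(e) NULL)
      if (!is.null(r_try)) {
        simp <- qr.coef(qrA, -c(r_try$R, r_try$a$V - V_target_mm3))
        if (all(is.finite(simp)) &&
            sqrt(sum(simp^2)) <= (1 - alpha / 4) * nstep) {
          u <- u_try; P <- P_try; r0 <- r_try; ok <- TRUE
          break
        }
      }
      alpha <- alpha / 2
    }
    if (!ok)
      return(list(u = u, P = P, a = r0$a, converged = FALSE, iters = iter))
  }
  list(u = u, P = P, a = r0$a, converged = FALSE, iters = opts$max_iter)
}

# internal: solve to one target volume with regime (tension-field) updates
solve_state_at_volume <- function(u, P, regimes, V_target_mm3, mesh, model,
                                  contact, opts, tolS) {
  # elements flip-flopping across the taut/wrinkled boundary at negligible
  # stress are accepted as-is: their force contribution is immaterial and
  # the active set would otherwise chatter indefinitely
  tol_accept <- 1e-6 * 3 * abs(sum(model$mu))
  for (k in seq_len(opts$max_regime_iter)) {
    ns <- newton_volume_step(u, P, V_target_mm3, mesh, model, regimes,
                             contact, opts)
    if (!ns$converged)
      return(c(ns, list(regimes = regimes, regime_converged = FALSE)))
    new_reg <- classify_regimes(ns$a$lm, ns$a$lt, model, tolS)
    u <- ns$u; P <- ns$P
    changed <- which(new_reg != regimes)
    if (!length(changed))
      return(c(ns, list(regimes = regimes, regime_converged = TRUE)))
    near_zero <- pmin(abs(ns$a$sigma_m[changed]), abs(ns$a$sigma_t[changed]))
    if (max(near_zero) < tol_accept)
      return(c(ns, list(regimes = regimes, regime_converged = TRUE)))
    regimes <- new_reg
  }
  c(ns, list(regimes = regimes, regime_converged = FALSE))
}

# internal: package a converged solve into a membrane_state
make_membrane_state <- function(mesh, z, r, P_MPa, a, regimes) {
  structure(list(z = z, r = r,
                 P_mmHg = MPa_to_mmHg(P_MPa),
                 V_ml = mm3_to_ml(a$V),
                 lambda_m = a$lm, lambda_t = a$lt,
                 sigma_m_MPa = a$sigma_m, sigma_t_MPa = a$sigma_t,
                 regime = regimes,
                 slack = any(regimes != REGIME_TAUT),
                 contact_pressure_MPa = a$q,
                 contact_active = a$q > 0),
            class = "membrane_state")
}

#' @export
print.membrane_state <- function(x, ...) {
  cat(sprintf("Membrane state: V = %.3f ml, P = %.1f mmHg, d_mid = %.2f mm%s\n",
              x$V_ml, x$P_mmHg, central_diameter_of_state(x),
              if (x$slack) " [wrinkled/slack elements present]" else ""))
  invisible(x)
}

# internal: diameter at the axial midpoint of the deformed meridian
central_diameter_of_state <- function(state) {
  zmid <- (min(state$z) + max(state$z)) / 2
  2 * stats::approx(state$z, state$r, xout = zmid)$y
}

#' Total stored membrane strain energy of a state
#'
#' Integrates the (regime-aware) strain-energy density over the reference
#' membrane volume.  Along a quasi-static taut inflation path this balances
#' the pressure work `integral P dV`.
#'
#' @param state a `membrane_state` from a solver run.
#' @param mesh the `meridian_mesh` the state was solved on.
#' @param material the [ogden_model()] used.
#' @return energy in mJ (N mm).
#' @export
membrane_strain_energy <- function(state, mesh, material) {
  nn <- length(mesh$z0)
  m0 <- mesh$r0[-nn] + mesh$r0[-1]
  w <- pi * m0 * mesh$L0 * mesh$t0
  u <- ogden_membrane_energy(state$lambda_m, state$lambda_t, material)
  iw_t <- state$regime == REGIME_WRINKLE_T
  iw_m <- state$regime == REGIME_WRINKLE_M
  isl <- state$regime == REGIME_SLACK
  u[iw_t] <- ogden_uniaxial_energy(state$lambda_m[iw_t], material)
  u[iw_m] <- ogden_uniaxial_energy(state$lambda_t[iw_m], material)
  u[isl] <- 0
  sum(w * u)
}

#' Nodal equilibrium residual of a membrane state
#'
#' Virtual-work residual of the internal membrane forces minus the follower
#' pressure load, per node (axial and radial components, N).  Exactly zero
#' at the reference configuration with zero pressure; `max(abs(...))` small
#' at any converged solver state.
#'
#' @param state a `membrane_state` (or list with `z`, `r`).
#' @param mesh the `meridian_mesh`.
#' @param material the [ogden_model()].
#' @param P_mmHg cavity pressure; defaults to the state's own.
#' @return list with numeric vectors `R_z`, `R_r` (constrained dofs zeroed).
#' @examples
#' mesh <- build_profile_mesh(balloon_design(), 60)
#' st <- list(z = mesh$z0, r = mesh$r0)
#' res <- equilibrium_residual(st, mesh, balloon_ogden_coefficients(), P_mmHg = 0)
#' max(abs(c(res$R_z, res$R_r)))   # 0
#' @export
equilibrium_residual <- function(state, mesh, material, P_mmHg = state$P_mmHg) {
  nn <- length(mesh$z0)
  regimes <- state$regime
  if (is.null(regimes)) regimes <- rep(REGIME_TAUT, nn - 1L)
  a <- assemble_system(state$z, state$r, mesh, material, regimes)
  P <- mmHg_to_MPa(P_mmHg)
  Rz <- a$g_z - P * a$gV_z
  Rr <- a$g_r - P * a$gV_r
  Rz[1] <- 0
  Rr[c(1, nn)] <- 0
  list(R_z = Rz, R_r = Rr)
}

#' Closed-form inflation pressure of a cylindrical membrane
#'
#' Analytic Laplace-equilibrium pressure of an infinite incompressible
#' Ogden membrane cylinder at hoop stretch `lambda_t` and axial stretch
#' `lambda_z`:
#' \deqn{P = \sigma_\theta(\lambda_\theta, \lambda_z) \, t_0 /
#'        (r_0 \lambda_\theta^2 \lambda_z)}
#' with \eqn{\sigma_\theta} the incompressible plane-stress Cauchy hoop
#' stress.  Serves as the independent oracle for the membrane FE solver's
#' mid-section response.
#'
#' @param lambda_t hoop stretch(es).
#' @param lambda_z axial stretch(es).
#' @param r0 reference radius (mm).
#' @param t0 reference thickness (mm).
#' @param material an [ogden_model()].
#' @return pressure in mmHg.
#' @examples
#' cylindrical_membrane_pressure(1.1, 1, 11.5, 0.09, balloon_ogden_coefficients())
#' @export
cylindrical_membrane_pressure <- function(lambda_t, lambda_z, r0, t0, material) {
  if (any(lambda_t <= 0) || any(lambda_z <= 0))
    bm_stop("stretches must be positive", class = "balloonmech_invalid_input")
  st <- ogden_membrane_stress(lambda_z, lambda_t, material)$sigma_t
  MPa_to_mmHg(st * t0 / (r0 * lambda_t^2 * lambda_z))
}

# internal continuation driver shared by free and constrained solves
run_inflation <- function(mesh, model, schedule_ml, z_init, r_init, P_init,
                          contact, opts) {
  nn <- length(mesh$z0)
  n_zfree <- nn - 1L
  u <- c(z_init[2:nn], r_init[2:(nn - 1)])
  P <- P_init
  tolS <- 1e-9 * 3 * abs(sum(model$mu))
  x0 <- list(z = z_init, r = r_init)
  a0 <- assemble_system(z_init, r_init, mesh, model,
                        rep(REGIME_TAUT, nn - 1L), contact, opts$reg)
  regimes <- classify_regimes(a0$lm, a0$lt, model, tolS)
  V_cur <- a0$V
  states <- vector("list", length(schedule_ml))
  dV_max <- ml_to_mm3(opts$dV_max_ml)

  for (i in seq_along(schedule_ml)) {
    V_goal <- ml_to_mm3(schedule_ml[i])
    while (TRUE) {
      dV <- V_goal - V_cur
      sub <- if (abs(dV) > dV_max) V_cur + sign(dV) * dV_max else V_goal
      attempt_dV <- sub - V_cur
      repeat {
        sol <- solve_state_at_volume(u, P, regimes, V_cur + attempt_dV,
                                     mesh, model, contact, opts, tolS)
        if (sol$converged && sol$regime_converged) break
        attempt_dV <- attempt_dV / 2
        if (abs(attempt_dV) < ml_to_mm3(1e-4))
          bm_stop(sprintf(
            "Newton continuation failed near V = %.4f ml (last converged %.4f ml)",
            mm3_to_ml(V_cur + attempt_dV * 2), mm3_to_ml(V_cur)),
            class = "balloonmech_solver_error")
      }
      u <- sol$u; P <- sol$P; regimes <- sol$regimes
      V_cur <- sol$a$V
      if (abs(V_cur - V_goal) <= 1e-9 * max(1, V_goal)) break
    }
    z <- c(mesh$z0[1], u[1:n_zfree])
    r <- c(mesh$r0[1], u[(n_zfree + 1):(n_zfree + nn - 2L)], mesh$r0[nn])
    states[[i]] <- make_membrane_state(mesh, z, r, P, sol$a, regimes)
  }
  states
}

# internal: curve data frame from a list of states
states_to_curve <- function(states, times, provenance) {
  inflation_curve(time_s = times,
                  volume_ml = vapply(states, function(s) s$V_ml, 0),
                  pressure_mmHg = vapply(states, function(s) s$P_mmHg, 0),
                  diameter_mm = vapply(states, central_diameter_of_state, 0),
                  provenance = provenance,
                  contact_flag = vapply(states, function(s) any(s$contact_active), NA),
                  slack_flag = vapply(states, function(s) s$slack, NA))
}

#' Free inflation of a balloon under volume control
#'
#' Solves the static axisymmetric membrane equations at each target volume
#' of the protocol schedule, with the cavity pressure as a
#' Lagrange-multiplier unknown enforcing the prescribed volume (Newton with
#' line search, continuation in volume with automatic sub-stepping).  The
#' balloon extremities are constrained radially and free axially.  Elements
#' that would carry compressive stress are wrinkling-relaxed and flagged.
#'
#' @param design a [balloon_design()].
#' @param material an [ogden_model()].
#' @param protocol an [inflation_protocol()]; a `NULL` starting volume means
#'   the mesh's reference (stress-free) volume.
#' @param n_elements meridian elements (default 120).
#' @param options list of solver options: `dV_max_ml` (continuation step
#'   cap, default 0.25 ml), `tol` (Newton residual tolerance, 1e-9
#'   relative), `max_iter`, `reg` (slack-element stabilisation fraction).
#' @return list with `curve` (an [inflation_curve()] of time, volume,
#'   pressure, central diameter), `states` (list of `membrane_state`), and
#'   `mesh`.
#' @examples
#' \donttest{
#' sol <- solve_free_inflation(balloon_design(), balloon_ogden_coefficients(),
#'                             inflation_protocol(injected_ml = 1), n_elements = 60)
#' sol$curve
#' }
#' @export
solve_free_inflation <- function(design, material, protocol,
                                 n_elements = 120, options = list()) {
  opts <- solver_options(options)
  mesh <- build_profile_mesh(design, n_elements)
  V_ref <- mm3_to_ml(revolved_volume_mm3(mesh$z0, mesh$r0))
  V0 <- if (is.null(protocol$V0_ml)) V_ref else protocol$V0_ml
  sched <- volume_schedule(protocol, V0_ml = V0)
  states <- run_inflation(mesh, material, sched$volume_ml,
                          mesh$z0, mesh$r0, 0, NULL, opts)
  list(curve = states_to_curve(states, sched$time_s, "computational"),
       states = states, mesh = mesh, V_ref_ml = V_ref)
}

#' Inflation inside a compliant (or rigid) cylindrical implantation site
#'
#' Same volume-controlled membrane solve as [solve_free_inflation()], plus
#' frictionless penalty contact against a cylindrical phantom: wherever the
#' balloon radius exceeds the phantom's current inner radius, a contact
#' pressure acts on both; the phantom responds as a thin-walled
#' linear-elastic cylinder (radial compliance \eqn{r_{in}^2/(E t)} over its
#' free length, rigid over the constrained end bands).  The penalty
#' stiffness is auto-scaled and escalated until the penetration is below
#' `1e-3` of the phantom radius (and, for compliant phantoms, below 1 % of
#' the indentation so the contact pressure matches the phantom's Laplace
#' pressure at its attained radius).
#'
#' The balloon starts from a radially capped (slack) configuration fitting
#' inside the phantom, standing in for the bench step of deflating the
#' balloon before insertion; the starting volume defaults to that capped
#' configuration's volume.
#'
#' @inheritParams solve_free_inflation
#' @param phantom a [cylinder_phantom()].
#' @param phantom_material a [linear_elastic_model()], or `NULL` for a rigid
#'   phantom.
#' @return as [solve_free_inflation()], plus `contact_report`, a data frame
#'   per output step with `n_active`, `max_contact_pressure_mmHg`,
#'   `max_penetration_mm`.
#' @examples
#' \donttest{
#' sol <- solve_constrained_inflation(
#'   balloon_design(), balloon_ogden_coefficients(),
#'   cylinder_phantom(22, 1.2, 75, end_band = 5),
#'   linear_elastic_model(13.19, poisson = 0.25),
#'   inflation_protocol(injected_ml = 1.5), n_elements = 60)
#' sol$contact_report
#' }
#' @export
solve_constrained_inflation <- function(design, material, phantom,
                                        phantom_material = NULL, protocol,
                                        n_elements = 120, options = list()) {
  opts <- solver_options(options)
  mesh <- build_profile_mesh(design, n_elements)
  nn <- length(mesh$z0)
  r_in <- phantom$diameter / 2
  zc <- (mesh$z0[1] + mesh$z0[nn]) / 2
  z_lo <- zc - phantom$length / 2
  z_hi <- zc + phantom$length / 2
  band <- phantom$end_band
  cmpl_free <- if (is.null(phantom_material)) 0 else
    r_in^2 / (phantom_material$young_modulus * phantom$thickness)
  rp0_fn <- function(z) ifelse(z >= z_lo & z <= z_hi, r_in, Inf)
  cmpl_fn <- function(z) {
    inside_free <- z >= z_lo + band & z <= z_hi - band
    ifelse(inside_free, cmpl_free, 0)
  }
  k0 <- if (!is.null(opts$penalty)) opts$penalty else
    1e3 * 3 * abs(sum(material$mu)) * mesh$t0 / (design$diameter / 2)^2

  # The bench inserts a deflated balloon into the phantom; a slack membrane
  # below its reference volume has a nearly indeterminate shape, so instead
  # of solving that degenerate phase the wall is ramped inward onto the
  # balloon at the (well-posed) reference state, then volume is ramped.
  V_ref <- mm3_to_ml(revolved_volume_mm3(mesh$z0, mesh$r0))
  V0 <- if (is.null(protocol$V0_ml)) V_ref else protocol$V0_ml
  sched <- volume_schedule(protocol, V0_ml = V0)

  k <- k0
  for (esc in seq_len(opts$max_penalty_escalations)) {
    wall_contact <- function(rp) list(
      rp0_fn = function(z) ifelse(z >= z_lo & z <= z_hi, rp, Inf),
      cmpl_fn = cmpl_fn, k = k)
    rp_start <- max(mesh$r0) * 1.02
    ramp <- if (r_in >= rp_start) r_in else
      c(seq(rp_start, r_in, length.out = 9)[-1])
    z_init <- mesh$z0; r_init <- mesh$r0; P_init <- 0
    for (rp in ramp) {
      st <- run_inflation(mesh, material, V_ref, z_init, r_init, P_init,
                          wall_contact(rp), opts)[[1]]
      z_init <- st$z; r_init <- st$r; P_init <- mmHg_to_MPa(st$P_mmHg)
    }
    contact <- wall_contact(r_in)
    states <- run_inflation(mesh, material, sched$volume_ml,
                            z_init, r_init, P_init, contact, opts)
    pen <- vapply(states, function(s) {
      act <- s$contact_active
      if (!any(act)) return(0)
      max(s$contact_pressure_MPa[act] / k)
    }, 0)
    indent <- vapply(states, function(s) {
      act <- s$contact_active
      if (!any(act)) return(Inf)
      max(s$r[act] - r_in)
    }, 0)
    ok <- max(pen) <= 1e-3 * r_in &&
      (cmpl_free == 0 || all(pen <= pmax(0.01 * indent, 1e-12) | pen == 0))
    if (ok) break
    k <- k * 10
  }
  if (!ok)
    bm_stop("contact penalty escalation failed to reach penetration tolerance",
            class = "balloonmech_solver_error")

  report <- data.frame(
    time_s = sched$time_s,
    volume_ml = vapply(states, function(s) s$V_ml, 0),
    n_active = vapply(states, function(s) sum(s$contact_active), 0L),
    max_contact_pressure_mmHg = vapply(states, function(s)
      MPa_to_mmHg(max(s$contact_pressure_MPa)), 0),
    max_penetration_mm = vapply(states, function(s) {
      act <- s$contact_active
      if (!any(act)) 0 else max(s$contact_pressure_MPa[act] / k)
    }, 0))
  list(curve = states_to_curve(states, sched$time_s, "computational"),
       states = states, mesh = mesh, contact_report = report,
       penalty = k, V_start_ml = V0)
}
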