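#' Boundary conditions for the catheter-in-vein flow
#'
#' Encodes the study's boundary conditions: a parabolic venous inflow at the
#' prescribed flow rate, a parabolic saline jet at the catheter inlet, zero
#' gauge pressure at the vein outlet, and no-slip rigid walls. Because the
#' solver works on the 2-D mid-plane, the 3-D volumetric rates must be mapped
#' onto the plane; two equivalences are supported:
#' \describe{
#'   \item{`mean_velocity`}{each inlet reproduces the 3-D mean velocity
#'     `Q/A` of its circular cross-section (default; preserves the jet
#'     velocity scale that drives wall shear),}
#'   \item{`flux_ratio`}{the vein keeps its mean velocity and the catheter
#'     inflow is scaled so the ratio of 2-D fluxes equals the ratio of 3-D
#'     volumetric rates (preserves the mixing balance, so the outlet
#'     flux-weighted blood fraction equals `Q_vein / (Q_vein + Q_cath)`).}
#' }
#' Both the nominal volumetric rates and the imposed 2-D per-depth fluxes are
#' recorded.
#'
#' @param domain A `domain_grid` (supplies vein and catheter dimensions and
#'   the configuration's infusion rate).
#' @param Q_vein_mL_min Venous inflow; defaults to the domain's vein spec.
#' @param Q_cath_mL_min Catheter infusion; defaults to the configuration.
#' @param equivalence 2-D rate equivalence rule, see Details.
#' @param wall_velocity_top Tangential velocity of the near wall in m/s
#'   (non-zero only in Couette-type verification runs).
#' @param vein_inlet_profile Optional `function(y, D, U_mean)` overriding the
#'   parabolic vein inlet profile (verification use).
#' @return An object of class `flow_bc`.
#' @export
boundary_conditions <- function(domain,
                                Q_vein_mL_min = domain$vein$inlet_flow_mL_min,
                                Q_cath_mL_min = domain$config$infusion_rate_mL_min,
                                equivalence = c("mean_velocity", "flux_ratio"),
                                wall_velocity_top = 0,
                                vein_inlet_profile = NULL) {
  equivalence <- match.arg(equivalence)
  stopifnot(Q_vein_mL_min >= 0, Q_cath_mL_min >= 0)
  D <- domain$vein$diameter_mm * 1e-3
  Qv <- .mL_min_to_m3_s(Q_vein_mL_min)
  U_vein <- Qv / (pi * (D / 2)^2)
  U_cath <- 0
  ID <- NA_real_
  if (!is.null(domain$config$catheter) && Q_cath_mL_min > 0) {
    ID <- domain$config$catheter$inner_diameter_mm * 1e-3
    Qc <- .mL_min_to_m3_s(Q_cath_mL_min)
    U_cath <- switch(equivalence,
      mean_velocity = Qc / (pi * (ID / 2)^2),
      flux_ratio = if (Q_vein_mL_min > 0)
        (Q_cath_mL_min / Q_vein_mL_min) * U_vein * D / ID
      else Qc / (pi * (ID / 2)^2))
  }
  structure(list(
    Q_vein_mL_min = Q_vein_mL_min, Q_cath_mL_min = Q_cath_mL_min,
    U_vein = U_vein, U_cath = U_cath,
    q2_vein = U_vein * D, q2_cath = if (is.na(ID)) 0 else U_cath * ID,
    equivalence = equivalence, wall_velocity_top = wall_velocity_top,
    vein_inlet_profile = vein_inlet_profile
  ), class = "flow_bc")
}

# Parabolic profile with mean U on (0, D); integrates exactly to U * D
.parabolic_profile <- function(y, D, U_mean) {
  ifelse(y > 0 & y < D, 1.5 * U_mean * (1 - ((y - D / 2) / (D / 2))^2), 0)
}

# Face geometry/classification shared by the flow and scalar solvers.
# Fixed-value faces carry inlet/aperture/no-slip velocities; ghost-wall faces
# (both adjacent cells solid) are replaced by reflected values in the
# tangential stencils so the wall plane sits exactly on the cell face.
.solver_setup <- function(domain, bc) {
  nx <- domain$nx; ny <- domain$ny; h <- domain$h
  mask <- domain$mask
  infusing <- bc$Q_cath_mL_min > 0
  inflow <- domain$aperture & infusing
  solid <- (mask == MASK_VEIN_WALL | mask == MASK_CATH_WALL) |
    (domain$aperture & !infusing)
  flow <- !solid & !inflow
  D <- domain$vein$diameter_mm * 1e-3

  prof <- bc$vein_inlet_profile
  uin <- if (is.null(prof)) .parabolic_profile(domain$y, D, bc$U_vein)
         else prof(domain$y, D, bc$U_vein)
  uin[solid[1, ]] <- 0

  # catheter jet profile evaluated at an (x, y) point
  jet_vel <- function(px, py) {
    tip <- domain$tip; d <- domain$axis
    ID <- domain$config$catheter$inner_diameter_mm * 1e-3
    xi <- (px - tip[1]) * (-d[2]) + (py - tip[2]) * d[1]
    sp <- pmax(0, 1.5 * bc$U_cath * (1 - (2 * xi / ID)^2))
    list(u = sp * d[1], v = sp * d[2])
  }

  pad_i <- function(m) rbind(m[1, ], m, m[nrow(m), ])

  # --- u faces: (nx+1) x ny, face i between cells (i-1, j) and (i, j)
  Lc <- rbind(solid[1, ], solid); Rc <- rbind(solid, solid[nx, ])
  Li <- rbind(inflow[1, ], inflow); Ri <- rbind(inflow, inflow[nx, ])
  u_fixed <- Lc | Rc | Li | Ri
  u_fixed[1, ] <- TRUE                      # vein inlet
  u_outlet <- rep(FALSE, ny); u_outlet[flow[nx, ]] <- TRUE
  uFix <- matrix(0, nx + 1, ny)
  uFix[1, ] <- uin
  if (any(Li | Ri)) {
    idx <- which((Li | Ri) & !(Lc | Rc))
    fx <- ((idx - 1) %% (nx + 1)) * h       # face i at x = (i-1) h
    fy <- domain$y[(idx - 1) %/% (nx + 1) + 1]
    jv <- jet_vel(fx, fy)
    uFix[idx] <- jv$u
  }
  u_ghost <- Lc & Rc                        # face buried in solid
  u_unknown <- !u_fixed
  u_unknown[nx + 1, ] <- FALSE              # outlet handled separately
  # wall tangential velocity seen through ghost faces (moving near wall)
  u_wall <- matrix(0, nx + 1, ny)
  u_wall[, ny] <- bc$wall_velocity_top

  # --- v faces: nx x (ny+1), face j between cells (i, j-1) and (i, j)
  Bc <- cbind(solid[, 1], solid); Tc <- cbind(solid, solid[, ny])
  Bi <- cbind(inflow[, 1], inflow); Ti <- cbind(inflow, inflow[, ny])
  v_fixed <- Bc | Tc | Bi | Ti
  v_fixed[, 1] <- TRUE; v_fixed[, ny + 1] <- TRUE
  vFix <- matrix(0, nx, ny + 1)
  if (any(Bi | Ti)) {
    idx <- which((Bi | Ti) & !(Bc | Tc))
    fx <- domain$x[(idx - 1) %% nx + 1]
    fy <- (((idx - 1) %/% nx + 1) - 2) * h  # face j at y = (j-2) h
    jv <- jet_vel(fx, fy)
    vFix[idx] <- jv$v
  }
  v_ghost <- Bc & Tc
  v_unknown <- !v_fixed

  # influx through fixed faces bounding the flow region (inlet + aperture)
  flowL <- rbind(FALSE, flow); flowR <- rbind(flow, FALSE)
  u_in_pos <- u_fixed & flowR & !flowL      # flow cell to the right
  u_in_neg <- u_fixed & flowL & !flowR
  flowB <- cbind(FALSE, flow); flowT <- cbind(flow, FALSE)
  v_in_pos <- v_fixed & flowT & !flowB
  v_in_neg <- v_fixed & flowB & !flowT
  influx_of <- function() (sum(uFix[u_in_pos]) - sum(uFix[u_in_neg]) +
                             sum(vFix[v_in_pos]) - sum(vFix[v_in_neg])) * h
  # normalize the discrete face fluxes to the analytic 2-D rates so that
  # mass and species balances close on the imposed fluxes exactly
  vein_disc <- sum(uFix[1, flow[1, ]]) * h
  if (is.null(bc$vein_inlet_profile) && vein_disc > 0 && bc$q2_vein > 0)
    uFix[1, ] <- uFix[1, ] * bc$q2_vein / vein_disc
  if (infusing) {
    ap_u <- (Li | Ri) & !(Lc | Rc)
    ap_v <- (Bi | Ti) & !(Bc | Tc)
    ap_disc <- (sum(uFix[ap_u & u_in_pos]) - sum(uFix[ap_u & u_in_neg]) +
                  sum(vFix[ap_v & v_in_pos]) - sum(vFix[ap_v & v_in_neg])) * h
    if (abs(ap_disc) > 0) {
      uFix[ap_u] <- uFix[ap_u] * bc$q2_cath / ap_disc
      vFix[ap_v] <- vFix[ap_v] * bc$q2_cath / ap_disc
    }
  }
  influx <- influx_of()

  list(nx = nx, ny = ny, h = h, solid = solid, inflow = inflow, flow = flow,
       uFix = uFix, u_fixed = u_fixed, u_unknown = u_unknown,
       u_outlet = u_outlet, u_ghost = u_ghost, u_wall = u_wall,
       vFix = vFix, v_fixed = v_fixed, v_unknown = v_unknown,
       v_ghost = v_ghost, influx = influx, uin = uin, pad_i = pad_i)
}

# Pressure Poisson operator over flow cells: Neumann at fixed-velocity faces,
# Dirichlet p = 0 at the outlet face. Returns the SPD matrix (-laplacian)
# and the flow-cell index map.
.poisson_setup <- function(st) {
  nx <- st$nx; ny <- st$ny
  flow <- st$flow
  kidx <- matrix(0L, nx, ny)
  kidx[flow] <- seq_len(sum(flow))
  n <- sum(flow)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_v <- numeric(n)
  add_nb <- function(di, dj) {
    i <- row(flow); j <- col(flow)
    ok <- flow & i + di >= 1 & i + di <= nx & j + dj >= 1 & j + dj <= ny
    src <- which(ok)
    nb <- src + di + dj * nx
    nb_flow <- flow[nb]
    ii <<- c(ii, kidx[src[nb_flow]]); jj <<- c(jj, kidx[nb[nb_flow]])
    vv <<- c(vv, rep(-1, sum(nb_flow)))
    dv <- numeric(n)
    dv[kidx[src[nb_flow]]] <- 1
    diag_v <<- diag_v + dv
  }
  add_nb(1L, 0L); add_nb(-1L, 0L); add_nb(0L, 1L); add_nb(0L, -1L)
  # outlet Dirichlet: east face of flow cells in the last column
  out_cells <- which(flow & row(flow) == nx)
  diag_v[kidx[out_cells]] <- diag_v[kidx[out_cells]] + 2
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(vv, diag_v), dims = c(n, n)) / st$h^2
  list(A = A, chol = Matrix::Cholesky(Matrix::forceSymmetric(A)),
       kidx = kidx, n = n)
}

#' Solve steady incompressible flow in the catheter-in-vein domain
#'
#' Pseudo-transient projection solver on a staggered (MAC) grid with the
#' catheter rendered as a stair-step mask. First-order upwind convection,
#' second-order diffusion with ghost-cell walls (the no-slip plane sits on
#' the cell face), exact discrete pressure projection with zero gauge
#' pressure at the outlet. The mixture viscosity field may vary with the
#' blood mass fraction.
#'
#' Closures for the high-rate runs: the flow is laminar by construction;
#' `"reynolds_scaled"` reduces both inflows so the catheter Reynolds number
#' does not exceed `re_target`, solves the reduced problem, and rescales the
#' velocity field linearly back to the nominal rates (results are labelled
#' scaled; the extrapolation ignores inertial amplification).
#' `"eddy_viscosity"` instead augments the molecular viscosity with a
#' constant eddy viscosity from a mixing-length estimate in the jet,
#' `nu_t = 0.01 * U_jet * ID`. `"auto"` picks laminar when the catheter
#' Reynolds number is at most 2000 and the Reynolds-scaled mode otherwise.
#'
#' @param domain A `domain_grid`.
#' @param bc A `flow_bc`; defaults to `boundary_conditions(domain)`.
#' @param blood,saline Component `fluid_properties`.
#' @param closure One of `"laminar"`, `"reynolds_scaled"`,
#'   `"eddy_viscosity"`, `"auto"`.
#' @param mass_fraction Optional blood mass-fraction matrix for the mixture
#'   properties (defaults to pure blood).
#' @param tol Convergence tolerance on the normalized velocity residual.
#' @param max_iter Iteration cap.
#' @param re_target Catheter Reynolds number targeted by the scaled mode.
#' @param cfl Time-step safety factor.
#' @param init Optional `flow_field` used as warm start.
#' @param check_every Residual evaluation interval (iterations).
#' @return An object of class `flow_field` with staggered `u`, `v`, cell
#'   pressure `p`, cell-centered velocities `uc`, `vc`, the closure actually
#'   used, the velocity `scale_factor`, convergence history and the relative
#'   mass imbalance.
#' @export
solve_steady_flow <- function(domain, bc = boundary_conditions(domain),
                              blood = blood_properties(),
                              saline = saline_properties(),
                              closure = c("laminar", "reynolds_scaled",
                                          "eddy_viscosity", "auto"),
                              mass_fraction = NULL,
                              tol = 1e-6, max_iter = 50000,
                              re_target = 500, cfl = 0.8,
                              init = NULL, check_every = 25L) {
  closure <- match.arg(closure)
  nx <- domain$nx; ny <- domain$ny; h <- domain$h

  re_cath <- if (!is.null(domain$config$catheter) && bc$Q_cath_mL_min > 0)
    reynolds(saline, bc$Q_cath_mL_min,
             domain$config$catheter$inner_diameter_mm) else 0
  if (closure == "auto")
    closure <- if (re_cath <= 2000) "laminar" else "reynolds_scaled"
  scale_factor <- 1
  bc_run <- bc
  if (closure == "reynolds_scaled" && re_cath > re_target) {
    scale_factor <- re_target / re_cath
    bc_run <- bc
    bc_run$U_vein <- bc$U_vein * scale_factor
    bc_run$U_cath <- bc$U_cath * scale_factor
    bc_run$q2_vein <- bc$q2_vein * scale_factor
    bc_run$q2_cath <- bc$q2_cath * scale_factor
    bc_run$wall_velocity_top <- bc$wall_velocity_top * scale_factor
  }

  st <- .solver_setup(domain, bc_run)
  ps <- .poisson_setup(st)

  # mixture kinematic viscosity per cell
  f <- if (is.null(mass_fraction)) matrix(1, nx, ny) else mass_fraction
  mix <- mixture_properties(f, blood, saline)
  nu <- mix$viscosity / mix$density
  if (closure == "eddy_viscosity" && re_cath > 2000) {
    ID <- domain$config$catheter$inner_diameter_mm * 1e-3
    nu <- nu + 0.01 * bc_run$U_cath * ID
  }
  rho0 <- blood$density
  pad_i <- st$pad_i
  nu_pad <- pad_i(nu)
  nu_u <- 0.5 * (nu_pad[1:(nx + 1), ] + nu_pad[2:(nx + 2), ])
  nu_pad_j <- cbind(nu[, 1], nu, nu[, ny])
  nu_v <- 0.5 * (nu_pad_j[, 1:(ny + 1)] + nu_pad_j[, 2:(ny + 2)])

  u <- st$uFix; v <- st$vFix
  if (!is.null(init) && inherits(init, "flow_field") &&
      all(dim(init$u) == dim(u))) {
    k0 <- if (is.null(init$scale_factor)) 1 else init$scale_factor
    u[st$u_unknown] <- init$u[st$u_unknown] / k0 * scale_factor
    v[st$v_unknown] <- init$v[st$v_unknown] / k0 * scale_factor
    u[nx + 1, st$u_outlet] <- init$u[nx + 1, st$u_outlet] / k0 * scale_factor
  }
  p <- matrix(0, nx, ny)

  Uref <- max(bc_run$U_vein, 1.5 * bc_run$U_cath,
              abs(bc_run$wall_velocity_top), 1e-6)
  nu_max <- max(nu)
  D <- domain$vein$diameter_mm * 1e-3

  res_hist <- numeric(0); it_hist <- integer(0)
  res <- Inf; iter <- 0L
  uo <- st$u_outlet
  gN_u <- cbind(st$u_ghost[, 2:ny], FALSE)       # is face (i, j+1) buried
  gS_u <- cbind(FALSE, st$u_ghost[, 1:(ny - 1)]) # is face (i, j-1) buried
  wN_u <- cbind(st$u_wall[, 2:ny], st$u_wall[, ny])
  wS_u <- cbind(st$u_wall[, 1], st$u_wall[, 1:(ny - 1)])
  gE_v <- rbind(st$v_ghost[2:nx, ], FALSE)
  gW_v <- rbind(FALSE, st$v_ghost[1:(nx - 1), ])

  while (iter < max_iter) {
    iter <- iter + 1L
    umax <- max(abs(u), abs(v), Uref)
    dt <- cfl / (umax / h + 6 * nu_max / h^2)

    ## --- u momentum ---------------------------------------------------
    ## buried tangential neighbors are replaced by a quadratic ghost
    ## (exact for a parabolic profile with the wall on the cell face);
    ## one-cell-wide passages fall back to linear reflection
    uE <- rbind(u[2:(nx + 1), ], u[nx + 1, ])
    uW <- rbind(u[1, ], u[1:nx, ])
    uNr <- cbind(u[, 2:ny], u[, ny])
    uSr <- cbind(u[, 1], u[, 1:(ny - 1)])
    uN <- uNr; uS <- uSr
    uN[gN_u] <- (uSr[gN_u] - 6 * u[gN_u] + 8 * wN_u[gN_u]) / 3
    uS[gS_u] <- (uNr[gS_u] - 6 * u[gS_u] + 8 * wS_u[gS_u]) / 3
    both_u <- gN_u & gS_u
    uN[both_u] <- 2 * wN_u[both_u] - u[both_u]
    uS[both_u] <- 2 * wS_u[both_u] - u[both_u]
    vpad <- pad_i(v)
    vbar <- 0.25 * (vpad[1:(nx + 1), 1:ny] + vpad[1:(nx + 1), 2:(ny + 1)] +
                      vpad[2:(nx + 2), 1:ny] + vpad[2:(nx + 2), 2:(ny + 1)])
    adv_u <- u * ifelse(u > 0, (u - uW), (uE - u)) / h +
      vbar * ifelse(vbar > 0, (u - uS), (uN - u)) / h
    lap_u <- (uE + uW + uN + uS - 4 * u) / h^2
    un <- u
    un[st$u_unknown] <- u[st$u_unknown] +
      dt * (-adv_u[st$u_unknown] + (nu_u * lap_u)[st$u_unknown])

    ## --- v momentum ---------------------------------------------------
    vN <- cbind(v[, 2:(ny + 1)], v[, ny + 1])
    vS <- cbind(v[, 1], v[, 1:ny])
    vEr <- rbind(v[2:nx, ], v[nx, ])
    vWr <- rbind(-v[1, ], v[1:(nx - 1), ])       # inlet plane: v = 0
    vE <- vEr; vW <- vWr
    vE[gE_v] <- (vWr[gE_v] - 6 * v[gE_v]) / 3
    vW[gW_v] <- (vEr[gW_v] - 6 * v[gW_v]) / 3
    both_v <- gE_v & gW_v
    vE[both_v] <- -v[both_v]
    vW[both_v] <- -v[both_v]
    upad <- cbind(u[, 1], u, u[, ny])
    ubar <- 0.25 * (upad[1:nx, 1:(ny + 1)] + upad[1:nx, 2:(ny + 2)] +
                      upad[2:(nx + 1), 1:(ny + 1)] + upad[2:(nx + 1), 2:(ny + 2)])
    adv_v <- ubar * ifelse(ubar > 0, (v - vW), (vE - v)) / h +
      v * ifelse(v > 0, (v - vS), (vN - v)) / h
    lap_v <- (vE + vW + vN + vS - 4 * v) / h^2
    vn <- v
    vn[st$v_unknown] <- v[st$v_unknown] +
      dt * (-adv_v[st$v_unknown] + (nu_v * lap_v)[st$v_unknown])

    ## --- outlet: zero gradient, then global mass rescale ---------------
    vn_out <- un[nx, ]
    out_flux <- sum(vn_out[uo]) * h
    if (abs(st$influx) > 1e-14 && abs(out_flux) > 1e-14) {
      un[nx + 1, uo] <- vn_out[uo] * st$influx / out_flux
    } else {
      un[nx + 1, uo] <- if (abs(st$influx) > 1e-14)
        st$influx / (h * sum(uo)) else 0
    }

    ## --- projection ----------------------------------------------------
    div <- (un[2:(nx + 1), ] - un[1:nx, ] + vn[, 2:(ny + 1)] - vn[, 1:ny]) / h
    rhs <- -(rho0 / dt) * div[st$flow]
    pv <- as.numeric(Matrix::solve(ps$chol, rhs))
    p[] <- 0; p[st$flow] <- pv
    # correct faces between two flow cells, and the outlet faces
    fl <- st$flow
    intu <- rbind(FALSE, fl[1:(nx - 1), ] & fl[2:nx, ], FALSE)
    intu <- intu & st$u_unknown
    gpx <- matrix(0, nx + 1, ny)
    gpx[2:nx, ] <- (p[2:nx, ] - p[1:(nx - 1), ]) / h
    un[intu] <- un[intu] - dt / rho0 * gpx[intu]
    un[nx + 1, uo] <- un[nx + 1, uo] - dt / rho0 * (-2 * p[nx, uo] / h)
    intv <- cbind(FALSE, fl[, 1:(ny - 1)] & fl[, 2:ny], FALSE)
    intv <- intv & st$v_unknown
    gpy <- matrix(0, nx, ny + 1)
    gpy[, 2:ny] <- (p[, 2:ny] - p[, 1:(ny - 1)]) / h
    vn[intv] <- vn[intv] - dt / rho0 * gpy[intv]

    if (iter %% check_every == 0L || iter == 1L) {
      res <- max(max(abs(un - u)), max(abs(vn - v))) / (dt * Uref^2 / D)
      res_hist <- c(res_hist, res); it_hist <- c(it_hist, iter)
      u <- un; v <- vn
      if (res < tol) break
    } else {
      u <- un; v <- vn
    }
  }

  if (res >= tol) {
    cond <- structure(
      class = c("pivcflow_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "flow solver did not converge: residual %.3g after %d iterations",
        res, iter), call = sys.call(-1),
        residual_history = data.frame(iteration = it_hist,
                                      residual = res_hist)))
    stop(cond)
  }

  # final mass imbalance of the projected field (relative to the influx)
  outflux <- sum(u[nx + 1, uo]) * h
  imb <- if (abs(st$influx) > 1e-14)
    abs(st$influx - outflux) / abs(st$influx) else abs(outflux)
  div <- (u[2:(nx + 1), ] - u[1:nx, ] + v[, 2:(ny + 1)] - v[, 1:ny]) / h
  div_norm <- max(abs(div[st$flow])) * h / max(Uref, 1e-12)

  if (scale_factor < 1) {               # linear extrapolation to nominal rates
    u <- u / scale_factor; v <- v / scale_factor; p <- p / scale_factor
  }
  uc <- 0.5 * (u[1:nx, ] + u[2:(nx + 1), ])
  vc <- 0.5 * (v[, 1:ny] + v[, 2:(ny + 1)])
  uc[!st$flow] <- 0; vc[!st$flow] <- 0

  structure(list(
    u = u, v = v, p = p, uc = uc, vc = vc,
    domain = domain, bc = bc, closure = closure,
    scale_factor = scale_factor, scaled = scale_factor < 1,
    mass_fraction = f, iterations = iter, converged = TRUE,
    residuals = data.frame(iteration = it_hist, residual = res_hist),
    mass_imbalance = imb, div_norm = div_norm, dt = NA_real_,
    setup = st
  ), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "Flow field: %d x %d cells, closure %s%s, %d iterations, residual %.2e\n",
    x$domain$nx, x$domain$ny, x$closure,
    if (x$scaled) sprintf(" (Reynolds-scaled, factor %.3g)", x$scale_factor)
    else "", x$iterations, utils::tail(x$residuals$residual, 1)))
  cat(sprintf("  max speed %.3g m/s, mass imbalance %.2e\n",
              max(sqrt(x$uc^2 + x$vc^2)), x$mass_imbalance))
  invisible(x)
}

#' @export
plot.flow_field <- function(x, what = c("speed", "pressure"), ...) {
  what <- match.arg(what)
  z <- if (what == "speed") sqrt(x$uc^2 + x$vc^2) else x$p
  z[!x$setup$flow] <- NA
  graphics::image(x$domain$x * 1e3, x$domain$y * 1e3, z,
                  xlab = "x [mm]", ylab = "y [mm]",
                  main = paste("mid-plane", what), ...)
  invisible(x)
}

#' Axisymmetric fully developed pipe flow (validation mode)
#'
#' Finite-difference solution of fully developed laminar flow in a circular
#' pipe, used to validate the wall-shear machinery against the closed form
#' `tau_w = 4 mu Q / (pi R^3)`. The axial momentum equation
#' `(1/r) d/dr (r mu du/dr) = dp/dx` is discretized on `n` radial cells with
#' a ghost-cell wall; the pressure gradient is scaled so the profile carries
#' exactly the requested flow rate.
#'
#' @param Q_mL_min Volumetric flow rate in mL/min.
#' @param diameter_mm Pipe diameter in mm.
#' @param properties `fluid_properties` of the fluid.
#' @param n Number of radial cells.
#' @return A list with the radial grid `r`, axial velocity `u`, mean
#'   velocity `U_mean`, numerically extracted wall shear `tau_wall`, and the
#'   analytic value `tau_analytic`.
#' @examples
#' pipe_flow_profile(28, 2.4)$tau_wall   # ~0.956 Pa with blood properties
#' @export
pipe_flow_profile <- function(Q_mL_min, diameter_mm,
                              properties = blood_properties(), n = 400) {
  R <- diameter_mm / 2 * 1e-3
  dr <- R / n
  r <- (seq_len(n) - 0.5) * dr
  rf_lo <- (seq_len(n) - 1) * dr
  rf_hi <- seq_len(n) * dr
  # tridiagonal (1/r)[ r_+ (u_{i+1}-u_i) - r_- (u_i - u_{i-1}) ] / dr^2 = G/mu
  lo <- rf_lo / (r * dr^2)
  hi <- rf_hi / (r * dr^2)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, i] <- -(lo[i] + hi[i])
    if (i > 1) A[i, i - 1] <- lo[i]
    if (i < n) A[i, i + 1] <- hi[i]
  }
  A[n, n] <- A[n, n] - hi[n]            # ghost: u(R) = 0 -> u_{n+1} = -u_n
  u1 <- solve(A, rep(1 / properties$viscosity, n))   # response to unit G
  Q1 <- sum(u1 * 2 * pi * r * dr)
  Q <- .mL_min_to_m3_s(Q_mL_min)
  u <- u1 * Q / Q1
  tau_wall <- properties$viscosity * abs(9 * u[n] - u[n - 1]) / (3 * dr)
  list(r = r, u = u, U_mean = Q / (pi * R^2),
       tau_wall = tau_wall,
       tau_analytic = 4 * properties$viscosity * Q / (pi * R^3))
}
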