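# Steady upwind advection-diffusion assembly on the converged face
# velocities. Dirichlet values enter through the inlet and aperture faces
# (half-cell diffusion distance); walls are zero-flux; the outlet is a pure
# advective outflow. Returns the solution matrix (NA outside flow cells).
.solve_scalar <- function(flow, inlet_value, aperture_value, source,
                          schmidt = 1000) {
  domain <- flow$domain
  st <- flow$setup
  nx <- st$nx; ny <- st$ny; h <- st$h
  u <- flow$u; v <- flow$v
  mix <- mixture_properties(flow$mass_fraction)
  gam <- (mix$viscosity / mix$density) / schmidt      # scalar diffusivity
  kidx <- matrix(0L, nx, ny)
  kidx[st$flow] <- seq_len(sum(st$flow))
  n <- sum(st$flow)
  diag_v <- numeric(n)
  rhs <- rep(source * h^2, n)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)

  cells <- which(st$flow)
  ci <- (cells - 1L) %% nx + 1L
  cj <- (cells - 1L) %/% nx + 1L
  k <- kidx[cells]

  face <- function(Fout, nb_i, nb_j, u_face_fixed, boundary_value) {
    inside <- nb_i >= 1 & nb_i <= nx & nb_j >= 1 & nb_j <= ny
    nb_lin <- ifelse(inside, nb_i + (nb_j - 1L) * nx, NA_integer_)
    nb_flow <- inside & st$flow[ifelse(inside, nb_lin, 1L)]
    gam_f <- ifelse(nb_flow,
                    0.5 * (gam[cells] + gam[ifelse(nb_flow, nb_lin, 1L)]),
                    gam[cells])
    # neighbor is a flow cell: upwind advection + diffusion
    sel <- which(nb_flow)
    if (length(sel)) {
      diag_v[k[sel]] <<- diag_v[k[sel]] + pmax(Fout[sel], 0) + gam_f[sel]
      ii <<- c(ii, k[sel]); jj <<- c(jj, kidx[nb_lin[sel]])
      vv <<- c(vv, pmin(Fout[sel], 0) - gam_f[sel])
    }
    # boundary face with a known Dirichlet value (inlet or aperture)
    fixed <- !nb_flow & u_face_fixed
    sel <- which(fixed & !is.na(boundary_value))
    if (length(sel)) {
      diag_v[k[sel]] <<- diag_v[k[sel]] + pmax(Fout[sel], 0) + 2 * gam_f[sel]
      rhs[k[sel]] <<- rhs[k[sel]] +
        (-pmin(Fout[sel], 0) + 2 * gam_f[sel]) * boundary_value[sel]
    }
    # outflow (advective only)
    sel <- which(!nb_flow & !u_face_fixed)
    if (length(sel)) diag_v[k[sel]] <<- diag_v[k[sel]] + pmax(Fout[sel], 0)
  }

  # boundary scalar value by face: inlet_value at the vein inlet,
  # aperture_value at catheter-inlet faces, NA (no-flux) at walls
  bval <- function(is_aperture_nb, is_inlet) {
    out <- rep(NA_real_, length(cells))
    out[is_aperture_nb] <- aperture_value
    out[is_inlet] <- inlet_value
    out
  }
  apert <- st$inflow
  ap_at <- function(nb_i, nb_j) {
    inside <- nb_i >= 1 & nb_i <= nx & nb_j >= 1 & nb_j <= ny
    inside & apert[ifelse(inside, nb_i + (nb_j - 1L) * nx, 1L)]
  }

  # east face: velocity u[i+1, j], outward flux +u*h
  FE <- u[cbind(ci + 1L, cj)] * h
  face(FE, ci + 1L, cj, st$u_fixed[cbind(ci + 1L, cj)],
       bval(ap_at(ci + 1L, cj), rep(FALSE, length(cells))))
  # west face: outward flux -u*h; i = 1 is the vein inlet
  FW <- -u[cbind(ci, cj)] * h
  face(FW, ci - 1L, cj, st$u_fixed[cbind(ci, cj)],
       bval(ap_at(ci - 1L, cj), ci == 1L))
  # north face: v[i, j+1], outward +v*h
  FN <- v[cbind(ci, cj + 1L)] * h
  face(FN, ci, cj + 1L, st$v_fixed[cbind(ci, cj + 1L)],
       bval(ap_at(ci, cj + 1L), rep(FALSE, length(cells))))
  # south face
  FS <- -v[cbind(ci, cj)] * h
  face(FS, ci, cj - 1L, st$v_fixed[cbind(ci, cj)],
       bval(ap_at(ci, cj - 1L), rep(FALSE, length(cells))))

  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(vv, diag_v), dims = c(n, n))
  phi <- as.numeric(Matrix::solve(A, rhs))
  out <- matrix(NA_real_, nx, ny)
  out[st$flow] <- phi
  out
}

#' Transport the blood mass fraction through the flow field
#'
#' Steady advection-diffusion of the blood mass fraction `f`: the vein inlet
#' carries pure blood (`f = 1`), the catheter inlet pure saline (`f = 0`).
#' The upwind discretization obeys the discrete maximum principle, so `f`
#' stays within `[0, 1]` up to roundoff; values are clamped to the unit
#' interval after a tolerance check.
#'
#' @param flow A converged `flow_field`.
#' @param schmidt Schmidt number setting the scalar diffusivity relative to
#'   the local kinematic viscosity (default 1000, liquid-like mass
#'   diffusion).
#' @return An object of class `scalar_field` with `kind = "mass_fraction"`.
#' @export
solve_species <- function(flow, schmidt = 1000) {
  stopifnot(inherits(flow, "flow_field"), isTRUE(flow$converged))
  f <- .solve_scalar(flow, inlet_value = 1, aperture_value = 0,
                     source = 0, schmidt = schmidt)
  eps <- 1e-6
  rng <- range(f, na.rm = TRUE)
  if (rng[1] < -eps || rng[2] > 1 + eps)
    stop(sprintf("mass fraction escaped [0,1]: range [%.3g, %.3g]",
                 rng[1], rng[2]))
  f <- pmin(pmax(f, 0), 1)
  structure(list(kind = "mass_fraction", values = f, schmidt = schmidt,
                 domain = flow$domain, flow = flow),
            class = "scalar_field")
}

#' Transport residence time through the flow field
#'
#' Steady transport of a passive scalar with a unit volumetric source
#' (1 second per second) and zero value on both inlets: the solution is the
#' mean age of fluid at each point, i.e. the residence time. Near-stagnant
#' cells are capped at `cap` seconds to keep the report bounded; the number
#' of capped cells is recorded and a warning is emitted when any cap.
#'
#' @param flow A converged `flow_field`.
#' @param schmidt Schmidt number for the scalar diffusivity.
#' @param cap Residence-time ceiling in seconds.
#' @return An object of class `scalar_field` with `kind = "residence_time"`.
#' @export
solve_residence <- function(flow, schmidt = 1000, cap = 1000) {
  stopifnot(inherits(flow, "flow_field"), isTRUE(flow$converged))
  T_ <- .solve_scalar(flow, inlet_value = 0, aperture_value = 0,
                      source = 1, schmidt = schmidt)
  if (any(T_ < -1e-9, na.rm = TRUE))
    stop("negative residence time in transport solution")
  T_ <- pmax(T_, 0)
  ncap <- sum(T_ > cap, na.rm = TRUE)
  if (ncap > 0) {
    warning(sprintf("%d near-stagnant cells capped at %g s", ncap, cap))
    T_ <- pmin(T_, cap)
  }
  structure(list(kind = "residence_time", values = T_, schmidt = schmidt,
                 cap = cap, n_capped = ncap,
                 domain = flow$domain, flow = flow),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("Scalar field '%s': range [%.4g, %.4g]%s\n", x$kind,
              rng[1], rng[2],
              if (!is.null(x$n_capped) && x$n_capped > 0)
                sprintf(" (%d cells at cap)", x$n_capped) else ""))
  invisible(x)
}

#' Outlet flux-weighted mean of a scalar field
#'
#' The advective average of the scalar over the vein outlet,
#' `sum(u_out * phi) / sum(u_out)`. For the blood mass fraction this equals
#' the inlet blood share of the imposed 2-D fluxes at convergence (species
#' conservation).
#'
#' @param field A `scalar_field`.
#' @return A single number.
#' @export
outlet_mean <- function(field) {
  stopifnot(inherits(field, "scalar_field"))
  flow <- field$flow
  st <- flow$setup
  nx <- st$nx
  uo <- st$u_outlet
  w <- flow$u[nx + 1, uo]
  sum(w * field$values[nx, uo]) / sum(w)
}
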