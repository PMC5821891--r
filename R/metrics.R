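#' Power-law hemolysis constants
#'
#' Constants of the blood-damage (hemolysis) power law
#' `sigma = C^(1/alpha) * (tau * f)^(beta/alpha)`, where `tau` is the shear
#' stress and `f` the local blood mass fraction (the mass-fraction
#' modification discounts shear applied to saline rather than to red cells).
#'
#' @param C,alpha,beta Positive constants; defaults `3.62e-7`, `0.785`,
#'   `2.416`.
#' @return An object of class `hemolysis_params`.
#' @export
hemolysis_params <- function(C = 3.62e-7, alpha = 0.785, beta = 2.416) {
  stopifnot(C > 0, alpha > 0, beta > 0)
  if (beta / alpha <= 1) stop("beta/alpha must exceed 1")
  structure(list(C = C, alpha = alpha, beta = beta),
            class = "hemolysis_params")
}

#' Blood damage rate from shear stress
#'
#' Evaluates the hemolysis power law per cell:
#' `sigma = C^(1/alpha) * (tau * f_blood)^(beta/alpha)`.
#'
#' @param tau Shear stress in Pa (scalar, vector or matrix), non-negative.
#' @param f_blood Blood mass fraction in `[0, 1]`, recycled against `tau`.
#' @param params A `hemolysis_params` object.
#' @return The damage rate, shaped like `tau`.
#' @examples
#' damage_rate(1)           # ~6.2e-9
#' damage_rate(2) / damage_rate(1)  # 2^(2.416/0.785) ~ 8.44
#' @export
damage_rate <- function(tau, f_blood = 1, params = hemolysis_params()) {
  if (any(tau < 0, na.rm = TRUE)) stop("shear stress must be non-negative")
  if (any(f_blood < 0 | f_blood > 1, na.rm = TRUE))
    stop("blood mass fraction must lie in [0, 1]")
  params$C^(1 / params$alpha) * (tau * f_blood)^(params$beta / params$alpha)
}

#' Wall shear stress along the vein wall
#'
#' Extracts `tau = mu |du_t/dn|` on the vein wall (both the near and the far
#' wall) with a second-order one-sided stencil: with the wall plane on the
#' cell face and tangential velocities at the first two cell centers,
#' `du/dn = (9 u1 - u2) / (3 h)` (exact for a parabolic profile). Columns
#' whose first two off-wall cells are not vein-lumen fluid (they belong to
#' the catheter) are excluded. Catheter-wall shear is not part of the
#' endothelial summary and is not reported here.
#'
#' @param flow A converged `flow_field`.
#' @param mass_fraction Optional blood mass-fraction matrix for the mixture
#'   viscosity at the wall (defaults to the fraction the flow was solved
#'   with).
#' @param warn If `TRUE`, warn when wall columns are excluded.
#' @return An object of class `wall_shear_profile`: a data frame with
#'   columns `wall` ("far"/"near"), `x_mm`, `s_mm` (signed distance from the
#'   catheter tip projection) and `tau` (Pa).
#' @export
wall_shear <- function(flow, mass_fraction = NULL, warn = TRUE) {
  stopifnot(inherits(flow, "flow_field"))
  domain <- flow$domain
  nx <- domain$nx; ny <- domain$ny; h <- domain$h
  mask <- domain$mask
  f <- if (is.null(mass_fraction)) flow$mass_fraction else mass_fraction
  mu <- mixture_properties(f)$viscosity
  uc <- flow$uc
  x_tip <- if (is.null(domain$tip)) 0 else domain$tip[1]

  one_side <- function(j_wall, j1, j2, u_wall) {
    ok <- mask[, j_wall] == MASK_VEIN_WALL &
      mask[, j1] == MASK_FLUID & mask[, j2] == MASK_FLUID
    tau <- mu[, j1] * abs(9 * (uc[, j1] - u_wall) - (uc[, j2] - u_wall)) /
      (3 * h)
    list(ok = ok, tau = tau)
  }
  far <- one_side(1L, 2L, 3L, 0)
  near <- one_side(ny, ny - 1L, ny - 2L, flow$bc$wall_velocity_top)
  n_excl <- sum(!far$ok) + sum(!near$ok)
  if (warn && n_excl > 0)
    warning(sprintf("%d wall columns without adjacent vein-lumen fluid excluded",
                    n_excl))
  out <- rbind(
    data.frame(wall = "far", x_mm = domain$x[far$ok] * 1e3,
               tau = far$tau[far$ok]),
    data.frame(wall = "near", x_mm = domain$x[near$ok] * 1e3,
               tau = near$tau[near$ok])
  )
  out$s_mm <- out$x_mm - x_tip * 1e3
  structure(out[, c("wall", "x_mm", "s_mm", "tau")],
            class = c("wall_shear_profile", "data.frame"),
            n_excluded = n_excl)
}

# Cell-centered scalar shear stress magnitude mu * gamma_dot, with ghost
# reflection at walls so the near-wall gradient sees the no-slip plane.
.shear_stress_field <- function(flow, mass_fraction = NULL) {
  domain <- flow$domain
  st <- flow$setup
  nx <- domain$nx; ny <- domain$ny; h <- domain$h
  u <- flow$u; v <- flow$v
  uc <- flow$uc; vc <- flow$vc
  fl <- st$flow
  refl <- function(m, di, dj) {
    # neighbor cell value with reflection into solids (value -> -self)
    i <- pmin(pmax(row(m) + di, 1L), nx)
    j <- pmin(pmax(col(m) + dj, 1L), ny)
    nb <- m[cbind(as.vector(i), as.vector(j))]
    dim(nb) <- dim(m)
    solid_nb <- !fl[cbind(as.vector(i), as.vector(j))]
    dim(solid_nb) <- dim(m)
    nb[solid_nb] <- -m[solid_nb]
    nb
  }
  ux <- (u[2:(nx + 1), ] - u[1:nx, ]) / h
  vy <- (v[, 2:(ny + 1)] - v[, 1:ny]) / h
  uy <- (refl(uc, 0L, 1L) - refl(uc, 0L, -1L)) / (2 * h)
  vx <- (refl(vc, 1L, 0L) - refl(vc, -1L, 0L)) / (2 * h)
  gdot <- sqrt(2 * ux^2 + 2 * vy^2 + (uy + vx)^2)
  f <- if (is.null(mass_fraction)) flow$mass_fraction else mass_fraction
  tau <- mixture_properties(f)$viscosity * gdot
  tau[!fl] <- NA_real_
  tau
}

#' Venous stasis volume percentages
#'
#' Percentage of the venous volume (2-D: area; axisymmetric fixtures: the
#' radially weighted volume) whose residence time exceeds each threshold.
#' The denominator is the vein lumen only; the catheter lumen is excluded.
#'
#' @param field A `scalar_field` of kind `residence_time`, or an
#'   `axisym_field` fixture carrying exact residence times and volume
#'   weights.
#' @param thresholds Residence-time thresholds in seconds (study values 1,
#'   2, 5).
#' @return A named numeric vector of percentages, one per threshold.
#' @export
stasis_volumes <- function(field, thresholds = c(1, 2, 5)) {
  stopifnot(all(thresholds > 0))
  if (inherits(field, "axisym_field")) {
    w <- field$weights
    T_ <- field$residence
  } else if (inherits(field, "scalar_field")) {
    if (field$kind != "residence_time")
      stop("stasis volumes require a residence-time field")
    domain <- field$domain
    sel <- domain$mask == MASK_FLUID &
      col(domain$mask) >= 2 & col(domain$mask) <= domain$ny - 1
    T_ <- field$values[sel]
    w <- rep(1, length(T_))
  } else stop("unsupported field type")
  if (!length(T_)) stop("empty stasis region")
  out <- vapply(thresholds, function(th)
    100 * sum(w[T_ > th]) / sum(w), numeric(1))
  names(out) <- paste0(">", thresholds, "s")
  out
}

#' Summarize hemodynamic metrics and normalize to the patent baseline
#'
#' Collects the study metrics from one run: maximum and mean vein-wall shear
#' stress, volume-integrated and maximum blood damage (the damage rate uses
#' the local scalar shear stress weighted by the blood mass fraction),
#' stasis percentages at the 1/2/5 s thresholds, and the maximum residence
#' time over the vein lumen. When baseline metrics from the patent-vein
#' control (computed with identical grid settings) are supplied, the WSS and
#' damage metrics are also reported as ratios to the baseline; the baseline
#' run itself normalizes to exactly 1.
#'
#' @param flow A converged `flow_field`.
#' @param species `scalar_field` of blood mass fraction (or `NULL` for pure
#'   blood).
#' @param residence `scalar_field` of residence time.
#' @param baseline Optional `hemo_metrics` row of the patent-vein control.
#' @param params `hemolysis_params`.
#' @param thresholds Stasis thresholds in seconds.
#' @return A one-row data frame of class `hemo_metrics`.
#' @export
summarize_and_normalize <- function(flow, species = NULL, residence = NULL,
                                    baseline = NULL,
                                    params = hemolysis_params(),
                                    thresholds = c(1, 2, 5)) {
  stopifnot(inherits(flow, "flow_field"))
  domain <- flow$domain
  f <- if (is.null(species)) flow$mass_fraction else species$values
  fmat <- f; fmat[is.na(fmat)] <- 1
  ws <- wall_shear(flow, mass_fraction = fmat, warn = FALSE)
  tau_cell <- .shear_stress_field(flow, mass_fraction = fmat)
  sel <- .interior_fluid(domain)
  sigma <- damage_rate(ifelse(is.na(tau_cell), 0, tau_cell),
                       pmin(pmax(fmat, 0), 1), params)
  damage_total <- sum(sigma[sel]) * domain$h^2
  damage_max <- max(sigma[sel])

  st_pct <- rep(NA_real_, length(thresholds))
  max_res <- res_p99 <- NA_real_
  if (!is.null(residence)) {
    st_pct <- stasis_volumes(residence, thresholds)
    vein_sel <- domain$mask == MASK_FLUID &
      col(domain$mask) >= 2 & col(domain$mask) <= domain$ny - 1
    tv <- residence$values[vein_sel]
    max_res <- max(tv, na.rm = TRUE)
    # the literal maximum sits in stagnant corners where the steady scalar
    # saturates at the cap; the 99th percentile is the well-posed summary
    res_p99 <- unname(stats::quantile(tv, 0.99, na.rm = TRUE))
  }

  out <- data.frame(
    max_wss = max(ws$tau), mean_wss = mean(ws$tau),
    damage_total = damage_total, damage_max = damage_max,
    max_residence = max_res, residence_p99 = res_p99,
    scaled = isTRUE(flow$scaled), closure = flow$closure,
    stringsAsFactors = FALSE
  )
  for (k in seq_along(thresholds))
    out[[paste0("stasis_pct_", thresholds[k], "s")]] <- unname(st_pct[k])
  if (!is.null(baseline)) {
    if (baseline$max_wss <= 0 || baseline$damage_total <= 0)
      stop("baseline metrics must be strictly positive for normalization")
    out$wss_norm <- out$max_wss / baseline$max_wss
    out$damage_norm <- out$damage_total / baseline$damage_total
  } else {
    out$wss_norm <- NA_real_
    out$damage_norm <- NA_real_
  }
  class(out) <- c("hemo_metrics", "data.frame")
  out
}
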