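#' Analytic flow fixtures
#'
#' Generates closed-form flow fields on the solver's own grid so that every
#' metric kernel can be tested independently of the solver. Supported kinds:
#' \describe{
#'   \item{`plane_poiseuille`}{fully developed channel flow at the vein's
#'     mean velocity; exact parabolic profile, divergence-free, no-slip.}
#'   \item{`couette`}{linear shear driven by the near wall moving at
#'     `U_top`.}
#'   \item{`plug`}{uniform velocity `U` (slip walls by construction; used
#'     for residence-time checks, not for wall shear).}
#'   \item{`stagnant`}{zero velocity everywhere.}
#'   \item{`pipe_poiseuille_axisym`}{axisymmetric pipe flow on an (x, r)
#'     grid with exact advection-only residence times `x/u(r)` and radial
#'     volume weights; the no-diffusion oracle for stasis volumes.}
#' }
#'
#' @param kind Fixture kind, see Details.
#' @param vein A `vein_spec` (planar kinds).
#' @param cell_size_mm Grid cell size for the planar kinds.
#' @param U_top Wall velocity for `couette` (m/s).
#' @param U Plug velocity (m/s).
#' @param n_r,n_x Grid resolution for the axisymmetric kind.
#' @return For planar kinds, a list with `flow` (a `flow_field`) and, where
#'   defined, `residence` (the exact advection-only residence times). For
#'   the axisymmetric kind, an `axisym_field` with `u`, `residence` and
#'   volume `weights`.
#' @export
generate_analytic_field <- function(kind = c("plane_poiseuille", "couette",
                                             "plug", "stagnant",
                                             "pipe_poiseuille_axisym"),
                                    vein = vein_spec(),
                                    cell_size_mm = 0.15,
                                    U_top = 0.1, U = 0.1,
                                    n_r = 200, n_x = 400) {
  kind <- match.arg(kind)
  if (kind == "pipe_poiseuille_axisym") {
    R <- vein$diameter_mm / 2 * 1e-3
    L <- vein$length_mm * 1e-3
    Um <- .mL_min_to_m3_s(vein$inlet_flow_mL_min) / (pi * R^2)
    dr <- R / n_r; dx <- L / n_x
    r <- (seq_len(n_r) - 0.5) * dr
    x <- (seq_len(n_x) - 0.5) * dx
    u <- 2 * Um * (1 - (r / R)^2)
    Tm <- outer(x, u, `/`)                      # residence = x / u(r)
    w <- matrix(rep(2 * pi * r * dr * dx, each = n_x), n_x, n_r)
    return(structure(list(kind = kind, x = x, r = r, u = u,
                          U_mean = Um, L = L, R = R,
                          residence = as.vector(Tm),
                          weights = as.vector(w)),
                     class = "axisym_field"))
  }

  dom <- build_domain(configuration(NULL), vein, cell_size_mm)
  D <- vein$diameter_mm * 1e-3
  Um <- .mL_min_to_m3_s(vein$inlet_flow_mL_min) / (pi * (D / 2)^2)
  bc <- switch(kind,
    plane_poiseuille = boundary_conditions(dom),
    couette = boundary_conditions(dom, Q_vein_mL_min = 0,
      wall_velocity_top = U_top,
      vein_inlet_profile = function(y, D, U_mean)
        ifelse(y > 0 & y < D, U_top * y / D, 0)),
    plug = boundary_conditions(dom,
      vein_inlet_profile = function(y, D, U_mean) rep(U, length(y))),
    stagnant = boundary_conditions(dom, Q_vein_mL_min = 0))
  st <- .solver_setup(dom, bc)
  nx <- dom$nx; ny <- dom$ny; h <- dom$h
  yc <- dom$y
  uprof <- switch(kind,
    plane_poiseuille = .parabolic_profile(yc, D, Um),
    couette = ifelse(yc > 0 & yc < D, U_top * yc / D, 0),
    plug = rep(U, ny),
    stagnant = rep(0, ny))
  u <- matrix(rep(uprof, each = nx + 1), nx + 1, ny)
  if (kind != "plug") {
    wet <- rbind(st$flow[1, ], st$flow) & rbind(st$flow, st$flow[nx, ])
    u[!wet] <- 0
  }
  v <- matrix(0, nx, ny + 1)
  mu <- blood_properties()$viscosity
  p <- switch(kind,
    plane_poiseuille = matrix(rep(12 * mu * Um / D^2 *
                                    (dom$x[nx] - dom$x + h / 2), ny), nx, ny),
    matrix(0, nx, ny))
  uc <- 0.5 * (u[1:nx, ] + u[2:(nx + 1), ])
  vc <- 0.5 * (v[, 1:ny] + v[, 2:(ny + 1)])
  flow <- structure(list(
    u = u, v = v, p = p, uc = uc, vc = vc, domain = dom, bc = bc,
    closure = "analytic", scale_factor = 1, scaled = FALSE,
    mass_fraction = matrix(1, nx, ny), iterations = 0L, converged = TRUE,
    residuals = data.frame(iteration = integer(0), residual = numeric(0)),
    mass_imbalance = 0, div_norm = 0, dt = NA_real_, setup = st
  ), class = "flow_field")
  residence <- NULL
  if (kind %in% c("plane_poiseuille", "couette", "plug")) {
    Tm <- matrix(NA_real_, nx, ny)
    xc <- matrix(dom$x, nx, ny)
    up <- matrix(rep(uprof, each = nx), nx, ny)
    sel <- st$flow & up > 0
    Tm[sel] <- xc[sel] / up[sel]
    residence <- structure(list(kind = "residence_time", values = Tm,
                                schmidt = Inf, cap = Inf, n_capped = 0L,
                                domain = dom, flow = flow),
                           class = "scalar_field")
  }
  list(flow = flow, residence = residence)
}

#' Specification of a synthetic factorial response surface
#'
#' Describes a multiplicative response model over the study design:
#' `response = baseline * prod(factor multipliers) * exp(noise)` with
#' log-normal noise, emulating the order-of-magnitude spans and effect
#' directions of the study's normalized metrics (rate dominates, edge
#' position amplifies, the smaller 20G lumen amplifies, angle is modest).
#'
#' @param baseline Baseline response (patent-vein units of 1).
#' @param rate,gauge,angle,position Named numeric multiplier vectors over
#'   the study levels.
#' @param noise_sd Standard deviation of the log-scale noise (`>= 0`).
#' @param seed Integer seed for the table's private random stream.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(baseline = 1,
                        rate = c("2.1" = 1, "50" = 8, "300" = 60),
                        gauge = c("18G" = 1, "20G" = 2.5),
                        angle = c("5" = 1, "10" = 1, "15" = 1.2, "20" = 1.4),
                        position = c("centre" = 1, "edge" = 4),
                        noise_sd = 0.15, seed = 1L) {
  stopifnot(noise_sd >= 0, baseline > 0)
  structure(list(baseline = baseline,
                 multipliers = list(rate = rate, gauge = gauge,
                                    angle = angle, position = position),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "effect_spec")
}

#' Generate a synthetic factorial response table
#'
#' One row per design cell of the full study (ten geometric configurations
#' crossed with three infusion rates, 30 rows), with the multiplicative
#' response of an [effect_spec()]. Deterministic under the spec's seed; the
#' seed is recorded as an attribute.
#'
#' @param spec An `effect_spec`.
#' @return A data frame with columns `gauge`, `angle`, `position`, `rate`
#'   and `response`, of class `factorial_table`.
#' @export
generate_factorial_table <- function(spec = effect_spec()) {
  stopifnot(inherits(spec, "effect_spec"))
  configs <- enumerate_configurations()
  tab <- configurations_table(configs)
  names(tab) <- c("gauge", "angle", "position", "rate")
  mult <- function(which, level) {
    m <- spec$multipliers[[which]]
    v <- m[as.character(level)]
    if (any(is.na(v))) stop(sprintf("no multiplier for %s level", which))
    unname(v)
  }
  resp <- spec$baseline * mult("rate", tab$rate) * mult("gauge", tab$gauge) *
    mult("angle", tab$angle) * mult("position", tab$position)
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    resp <- resp * exp(stats::rnorm(nrow(tab), 0, spec$noise_sd))
  }
  tab$response <- resp
  attr(tab, "seed") <- spec$seed
  class(tab) <- c("factorial_table", "data.frame")
  tab
}
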