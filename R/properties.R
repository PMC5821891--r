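#' Fluid properties for the blood/saline system
#'
#' Constructs a `fluid_properties` record in SI units. Viscosity may be given
#' in Pa.s or mPa.s; values are normalized to Pa.s and the unit conversion is
#' recorded on the object, so the physiological magnitudes used internally are
#' always explicit.
#'
#' @param density Mass density in kg/m^3.
#' @param viscosity Dynamic viscosity, in the unit given by `viscosity_unit`.
#' @param viscosity_unit Either `"Pa.s"` or `"mPa.s"`.
#' @param label Optional label (e.g. `"blood"`).
#' @return An object of class `fluid_properties` with fields `density`
#'   (kg/m^3) and `viscosity` (Pa.s).
#' @examples
#' blood_properties()
#' fluid_properties(1005, 1.02, "mPa.s", "saline")
#' @export
fluid_properties <- function(density, viscosity,
                             viscosity_unit = c("mPa.s", "Pa.s"),
                             label = NULL) {
  viscosity_unit <- match.arg(viscosity_unit)
  stopifnot(is.numeric(density), length(density) == 1L,
            is.numeric(viscosity), length(viscosity) == 1L)
  if (density <= 0) stop("density must be strictly positive")
  if (viscosity <= 0) stop("viscosity must be strictly positive")
  mu <- if (viscosity_unit == "mPa.s") viscosity * 1e-3 else viscosity
  structure(
    list(density = density, viscosity = mu,
         viscosity_input = viscosity, viscosity_unit = viscosity_unit,
         label = label),
    class = "fluid_properties"
  )
}

#' @rdname fluid_properties
#' @details `blood_properties()` and `saline_properties()` return the study
#'   values: blood 1050 kg/m^3 and 2.78 mPa.s, saline 1005 kg/m^3 and
#'   1.02 mPa.s. The millipascal-second interpretation of the viscosities is
#'   the physiological one and is applied explicitly.
#' @export
blood_properties <- function() {
  fluid_properties(1050, 2.78, "mPa.s", "blood")
}

#' @rdname fluid_properties
#' @export
saline_properties <- function() {
  fluid_properties(1005, 1.02, "mPa.s", "saline")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid%s: density %.1f kg/m^3, viscosity %.4g Pa.s (input %g %s)\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$density, x$viscosity, x$viscosity_input, x$viscosity_unit))
  invisible(x)
}

#' Mixture properties from the blood mass fraction
#'
#' Density and dynamic viscosity of the blood/saline mixture, linear in the
#' blood mass fraction `f` (the declared mixing rule of the two-component
#' model).
#'
#' @param f_blood Blood mass fraction, in `[0, 1]` (vector or matrix).
#' @param blood,saline `fluid_properties` for the two components.
#' @param tol Tolerance for out-of-range `f` before erroring; values within
#'   `tol` of the interval are clamped.
#' @return A list with `density` and `viscosity` arrays shaped like `f_blood`.
#' @examples
#' mixture_properties(0.5)$viscosity  # 1.90e-3 Pa.s
#' @export
mixture_properties <- function(f_blood, blood = blood_properties(),
                               saline = saline_properties(), tol = 1e-6) {
  if (any(f_blood < -tol | f_blood > 1 + tol, na.rm = TRUE))
    stop("blood mass fraction outside [0, 1] beyond tolerance")
  f <- pmin(pmax(f_blood, 0), 1)
  list(density = f * blood$density + (1 - f) * saline$density,
       viscosity = f * blood$viscosity + (1 - f) * saline$viscosity)
}

#' Reynolds number of pipe flow
#'
#' `Re = 4 rho Q / (pi d mu)` for volumetric rate `Q` through a circular
#' lumen of diameter `d`. Used to classify the flow regime in the catheter
#' and the vein.
#'
#' @param properties A `fluid_properties` object.
#' @param flow_rate_mL_min Volumetric flow rate in mL/min.
#' @param diameter_mm Lumen diameter in mm.
#' @return The dimensionless Reynolds number.
#' @examples
#' reynolds(saline_properties(), 300, 0.61)  # > 10,000 in the 20G catheter
#' @export
reynolds <- function(properties, flow_rate_mL_min, diameter_mm) {
  stopifnot(inherits(properties, "fluid_properties"))
  if (diameter_mm <= 0) stop("diameter must be strictly positive")
  if (flow_rate_mL_min < 0) stop("flow rate must be non-negative")
  Q <- flow_rate_mL_min * 1e-6 / 60    # m^3/s
  d <- diameter_mm * 1e-3
  4 * properties$density * Q / (pi * d * properties$viscosity)
}

# mL/min -> m^3/s
.mL_min_to_m3_s <- function(q) q * 1e-6 / 60
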