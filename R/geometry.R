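# Mask codes for the rasterized domain
MASK_FLUID <- 0L
MASK_VEIN_WALL <- 1L
MASK_CATH_WALL <- 2L
MASK_CATH_LUMEN <- 3L

#' Idealized vein specification
#'
#' Straight cephalic-vein segment used as the computational vessel: a rigid
#' tube of constant diameter carrying a fixed venous inflow.
#'
#' @param diameter_mm Vein diameter in mm (study value 2.4).
#' @param length_mm Vein length in mm (study value 100); must exceed ten
#'   diameters so the outlet is far from the catheter region.
#' @param inlet_flow_mL_min Venous inflow in mL/min (study value 28, from
#'   Doppler measurement of the cephalic vein).
#' @return An object of class `vein_spec`.
#' @export
vein_spec <- function(diameter_mm = 2.4, length_mm = 100,
                      inlet_flow_mL_min = 28) {
  if (diameter_mm <= 0) stop("vein diameter must be positive")
  if (length_mm <= 10 * diameter_mm)
    stop("vein length must exceed 10 diameters")
  if (inlet_flow_mL_min < 0) stop("vein inlet flow must be non-negative")
  structure(list(diameter_mm = diameter_mm, length_mm = length_mm,
                 inlet_flow_mL_min = inlet_flow_mL_min),
            class = "vein_spec")
}

# Catalogue of supported catheter gauges (dimensions in mm)
.gauge_catalogue <- list(
  "18G" = list(inner_diameter_mm = 0.84, outer_diameter_mm = 1.27),
  "20G" = list(inner_diameter_mm = 0.61, outer_diameter_mm = 0.91)
)

#' Catheter specification by gauge
#'
#' Returns the lumen and outer diameters of a supported peripheral
#' intravenous catheter gauge. 18G: ID 0.84 mm, OD 1.27 mm. 20G: ID 0.61 mm,
#' OD 0.91 mm. Catheter length defaults to the standard 35 mm.
#'
#' @param gauge_label `"18G"` or `"20G"`.
#' @param length_mm Catheter length in mm.
#' @return An object of class `catheter_spec`.
#' @examples
#' gauge_spec("20G")
#' @export
gauge_spec <- function(gauge_label, length_mm = 35) {
  if (!is.character(gauge_label) || length(gauge_label) != 1L ||
      !gauge_label %in% names(.gauge_catalogue))
    stop(sprintf("unsupported gauge '%s'; supported: %s",
                 as.character(gauge_label)[1],
                 paste(names(.gauge_catalogue), collapse = ", ")))
  g <- .gauge_catalogue[[gauge_label]]
  if (length_mm <= 0) stop("catheter length must be positive")
  structure(list(gauge_label = gauge_label,
                 inner_diameter_mm = g$inner_diameter_mm,
                 outer_diameter_mm = g$outer_diameter_mm,
                 length_mm = length_mm),
            class = "catheter_spec")
}

#' @export
print.catheter_spec <- function(x, ...) {
  cat(sprintf("Catheter %s: ID %.2f mm, OD %.2f mm, length %g mm\n",
              x$gauge_label, x$inner_diameter_mm, x$outer_diameter_mm,
              x$length_mm))
  invisible(x)
}

# The five clinically relevant (position, angle) pairs per gauge. Edge tips
# are excluded at 5 deg (nearly the whole catheter would lie intravascular);
# centre tips are excluded at 15 and 20 deg (almost none of it would).
.allowed_pairs <- data.frame(
  tip_position = c("centre", "centre", "edge", "edge", "edge"),
  angle_deg = c(5, 10, 10, 15, 20),
  stringsAsFactors = FALSE
)

#' One study arm: catheter configuration in the vein
#'
#' @param gauge `"18G"`, `"20G"`, or `NULL` for the patent-vein control.
#' @param angle_deg Insertion angle in degrees, one of 5, 10, 15, 20.
#' @param tip_position `"centre"` or `"edge"`.
#' @param infusion_rate_mL_min Saline infusion rate through the catheter in
#'   mL/min (study levels 0, 2.1, 50, 300).
#' @return An object of class `pivc_config`.
#' @export
configuration <- function(gauge = NULL, angle_deg = NA, tip_position = NA,
                          infusion_rate_mL_min = 0) {
  if (is.null(gauge)) {
    if (infusion_rate_mL_min != 0)
      stop("the patent-vein control has no catheter and no infusion")
    return(structure(list(catheter = NULL, angle_deg = NA_real_,
                          tip_position = NA_character_,
                          infusion_rate_mL_min = 0),
                     class = "pivc_config"))
  }
  cath <- if (inherits(gauge, "catheter_spec")) gauge else gauge_spec(gauge)
  if (!angle_deg %in% c(5, 10, 15, 20))
    stop("insertion angle must be one of 5, 10, 15, 20 degrees")
  tip_position <- match.arg(tip_position, c("centre", "edge"))
  ok <- any(.allowed_pairs$tip_position == tip_position &
              .allowed_pairs$angle_deg == angle_deg)
  if (!ok)
    stop(sprintf("(%s, %g deg) is not a clinically relevant pair",
                 tip_position, angle_deg))
  if (infusion_rate_mL_min < 0) stop("infusion rate must be non-negative")
  structure(list(catheter = cath, angle_deg = angle_deg,
                 tip_position = tip_position,
                 infusion_rate_mL_min = infusion_rate_mL_min),
            class = "pivc_config")
}

#' @export
print.pivc_config <- function(x, ...) {
  if (is.null(x$catheter)) {
    cat("PIVC configuration: patent vein (control, no catheter)\n")
  } else {
    cat(sprintf("PIVC configuration: %s, %g deg, %s tip, %g mL/min infusion\n",
                x$catheter$gauge_label, x$angle_deg, x$tip_position,
                x$infusion_rate_mL_min))
  }
  invisible(x)
}

#' Enumerate the study's catheter-in-vein configurations
#'
#' Crosses gauges, insertion angles and tip positions, removes the
#' combinations that are not clinically relevant (edge position at 5 deg;
#' centre position at 15 and 20 deg), then crosses the survivors with the
#' infusion rates. The full study request yields five geometric combinations
#' per gauge. Optionally appends the patent-vein control and the qualitative
#' 20G / 20 deg / edge run without infusion.
#'
#' @param gauges Character vector of gauge labels.
#' @param angles Numeric vector of insertion angles (degrees).
#' @param positions Character vector of tip positions.
#' @param rates Numeric vector of infusion rates (mL/min).
#' @param include_controls If `TRUE`, append the control runs.
#' @return A list of `pivc_config` objects (empty request gives an empty
#'   list).
#' @examples
#' length(enumerate_configurations(rates = 2.1))           # 10
#' length(enumerate_configurations(include_controls = TRUE))  # 32
#' @export
enumerate_configurations <- function(gauges = c("18G", "20G"),
                                     angles = c(5, 10, 15, 20),
                                     positions = c("centre", "edge"),
                                     rates = c(2.1, 50, 300),
                                     include_controls = FALSE) {
  stopifnot(all(gauges %in% names(.gauge_catalogue)),
            all(angles %in% c(5, 10, 15, 20)),
            all(positions %in% c("centre", "edge")),
            all(rates >= 0))
  out <- list()
  for (g in gauges) {
    keep <- .allowed_pairs[.allowed_pairs$angle_deg %in% angles &
                             .allowed_pairs$tip_position %in% positions, ,
                           drop = FALSE]
    for (k in seq_len(nrow(keep))) {
      for (r in rates) {
        out[[length(out) + 1L]] <-
          configuration(g, keep$angle_deg[k], keep$tip_position[k], r)
      }
    }
  }
  if (include_controls) {
    out[[length(out) + 1L]] <- configuration(NULL)
    out[[length(out) + 1L]] <- configuration("20G", 20, "edge", 0)
  }
  out
}

#' Tabulate configurations
#'
#' @param configs A list of `pivc_config` objects.
#' @return A data frame with columns gauge, angle_deg, tip_position,
#'   infusion_rate_mL_min.
#' @export
configurations_table <- function(configs) {
  do.call(rbind, lapply(configs, function(cf) {
    data.frame(
      gauge = if (is.null(cf$catheter)) "none" else cf$catheter$gauge_label,
      angle_deg = cf$angle_deg,
      tip_position = cf$tip_position,
      infusion_rate_mL_min = cf$infusion_rate_mL_min,
      stringsAsFactors = FALSE
    )
  }))
}

#' Rasterize a configuration onto a 2-D computational domain
#'
#' Builds the mid-plane stair-step grid: the vein is a rectangle of length L
#' and height D bounded by one-cell wall layers; the catheter, when present,
#' is an angled channel of finite wall thickness `(OD - ID)/2` entering
#' through the near wall and terminating in a blunt tip face perpendicular to
#' the catheter axis. Edge-position tips stand off 0.10 mm from the far wall.
#' Lumen cells in the wall layer form the catheter inlet aperture.
#'
#' @param config A `pivc_config`.
#' @param vein A `vein_spec`.
#' @param cell_size_mm Uniform cell size in mm; must not exceed a quarter of
#'   the catheter inner diameter.
#' @param tip_axial_mm Axial station of the tip face, in mm from the vein
#'   inlet; defaults to 40 percent of the vein length.
#' @param standoff_mm Edge-position gap between the catheter outer surface
#'   and the far wall (default 0.10 mm).
#' @return An object of class `domain_grid`.
#' @export
build_domain <- function(config, vein = vein_spec(), cell_size_mm = 0.1,
                         tip_axial_mm = 0.4 * vein$length_mm,
                         standoff_mm = 0.10) {
  stopifnot(inherits(config, "pivc_config"), inherits(vein, "vein_spec"))
  D <- vein$diameter_mm * 1e-3
  L <- vein$length_mm * 1e-3
  has_cath <- !is.null(config$catheter)
  if (has_cath && cell_size_mm > config$catheter$inner_diameter_mm / 4 + 1e-12)
    stop("cell size must be at most a quarter of the catheter inner diameter")
  ny_f <- max(4L, round(vein$diameter_mm / cell_size_mm))
  h <- D / ny_f                       # adjust so D is an exact multiple
  nx <- max(8L, round(L / h))
  ny <- ny_f + 2L                     # one wall layer top and bottom
  x <- (seq_len(nx) - 0.5) * h
  y <- (seq_len(ny) - 1.5) * h        # y=0 at far wall face, y=D at near wall
  mask <- matrix(MASK_FLUID, nx, ny)
  mask[, 1] <- MASK_VEIN_WALL
  mask[, ny] <- MASK_VEIN_WALL
  aperture <- matrix(FALSE, nx, ny)

  tip <- axis_dir <- entry_x <- NULL
  insertion_len_mm <- embedded_len_mm <- NA_real_
  if (has_cath) {
    cath <- config$catheter
    ID <- cath$inner_diameter_mm * 1e-3
    OD <- cath$outer_diameter_mm * 1e-3
    th <- config$angle_deg * pi / 180
    y_tip <- if (config$tip_position == "centre") D / 2 else
      standoff_mm * 1e-3 + OD / 2
    x_tip <- tip_axial_mm * 1e-3
    # axis direction from wall entry towards the tip
    d_hat <- c(cos(th), -sin(th))
    n_hat <- c(sin(th), cos(th))
    insertion_len <- (D - y_tip) / sin(th)
    insertion_len_mm <- insertion_len * 1e3
    # embedded length: from where the trailing (upper) surface clears the
    # near wall to the tip face, by the plane trigonometric estimate
    embedded_len_mm <- (D - OD / 2 - y_tip) / sin(th) * 1e3
    entry_x <- x_tip - (D - y_tip) / tan(th)
    if (insertion_len > cath$length_mm * 1e-3)
      stop("configuration error: intravascular path exceeds catheter length")
    if (entry_x < 4 * h || x_tip > L - 10 * h)
      stop("configuration error: catheter does not fit the vein domain")
    if (y_tip - OD / 2 < -1e-12 || y_tip + OD / 2 > D)
      stop("configuration error: catheter tip outside the vein")
    xc <- matrix(x, nx, ny)
    yc <- matrix(y, nx, ny, byrow = TRUE)
    s <- (xc - x_tip) * d_hat[1] + (yc - y_tip) * d_hat[2]
    xi <- (xc - x_tip) * n_hat[1] + (yc - y_tip) * n_hat[2]
    in_lumen <- s <= 0 & abs(xi) <= ID / 2
    in_wall <- s <= 0 & abs(xi) <= OD / 2 & !in_lumen
    # carve into the vein interior and the near wall layer
    body <- mask != MASK_VEIN_WALL | col(mask) == ny
    mask[in_wall & body] <- MASK_CATH_WALL
    mask[in_lumen & body] <- MASK_CATH_LUMEN
    aperture <- mask == MASK_CATH_LUMEN & col(mask) == ny
    if (!any(aperture))
      stop("configuration error: catheter inlet aperture is empty")
    tip <- c(x_tip, y_tip)
    axis_dir <- d_hat
  }

  structure(list(
    h = h, nx = nx, ny = ny, x = x, y = y,
    cell_size_mm = h * 1e3, mask = mask, aperture = aperture,
    config = config, vein = vein, tip = tip, axis = axis_dir,
    entry_x = entry_x, standoff_mm = standoff_mm,
    insertion_len_mm = insertion_len_mm,
    embedded_len_mm = embedded_len_mm
  ), class = "domain_grid")
}

#' @export
print.domain_grid <- function(x, ...) {
  cat(sprintf("Domain grid: %d x %d cells, h = %.3g mm\n",
              x$nx, x$ny, x$cell_size_mm))
  print(x$config)
  tab <- table(factor(x$mask, levels = 0:3,
                      labels = c("fluid", "vein_wall", "catheter_wall",
                                 "catheter_lumen")))
  print(tab)
  invisible(x)
}

# Fluid cells (vein lumen + catheter lumen) inside the vessel interior
.interior_fluid <- function(domain) {
  j <- col(domain$mask)
  (domain$mask == MASK_FLUID | domain$mask == MASK_CATH_LUMEN) &
    j >= 2 & j <= domain$ny - 1
}

#' Rasterized and analytic fluid area of a domain
#'
#' The rasterized area counts interior fluid cells (vein plus catheter lumen)
#' times the cell area; the analytic area subtracts the exact clipped
#' catheter-wall polygon area from the vein rectangle. Their difference
#' shrinks at first order in the cell size.
#'
#' @param domain A `domain_grid`.
#' @return A list with `raster_m2` and `analytic_m2`.
#' @export
fluid_area <- function(domain) {
  raster <- sum(.interior_fluid(domain)) * domain$h^2
  vein <- domain$vein
  D <- vein$diameter_mm * 1e-3
  L <- vein$length_mm * 1e-3
  analytic <- L * D
  cf <- domain$config
  if (!is.null(cf$catheter)) {
    ID <- cf$catheter$inner_diameter_mm * 1e-3
    OD <- cf$catheter$outer_diameter_mm * 1e-3
    tip <- domain$tip; d <- domain$axis
    n <- c(-d[2], d[1])
    ext <- (D / abs(d[2])) + 2 * OD   # reach well beyond the near wall
    band <- function(lo, hi) {
      p1 <- tip + lo * n; p2 <- tip + hi * n
      rbind(p1, p2, p2 - ext * d, p1 - ext * d)
    }
    a1 <- .poly_area(.clip_rect(band(ID / 2, OD / 2), 0, L, 0, D))
    a2 <- .poly_area(.clip_rect(band(-OD / 2, -ID / 2), 0, L, 0, D))
    analytic <- analytic - a1 - a2
  }
  list(raster_m2 = raster, analytic_m2 = analytic)
}

# Sutherland-Hodgman clip of polygon (matrix of xy rows) to an axis-aligned
# rectangle; returns the clipped polygon (possibly with 0 rows)
.clip_rect <- function(poly, xmin, xmax, ymin, ymax) {
  clip1 <- function(p, inside, intersect) {
    n <- nrow(p)
    if (n == 0L) return(p)
    out <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n)) {
      a <- p[i, ]; b <- p[if (i == n) 1L else i + 1L, ]
      ia <- inside(a); ib <- inside(b)
      if (ia && ib) out <- rbind(out, b)
      else if (ia && !ib) out <- rbind(out, intersect(a, b))
      else if (!ia && ib) out <- rbind(out, intersect(a, b), b)
    }
    out
  }
  ix <- function(a, b, val, k) {      # intersection with coordinate plane k = val
    t <- (val - a[k]) / (b[k] - a[k])
    a + t * (b - a)
  }
  p <- poly
  p <- clip1(p, function(q) q[1] >= xmin, function(a, b) ix(a, b, xmin, 1))
  p <- clip1(p, function(q) q[1] <= xmax, function(a, b) ix(a, b, xmax, 1))
  p <- clip1(p, function(q) q[2] >= ymin, function(a, b) ix(a, b, ymin, 2))
  p <- clip1(p, function(q) q[2] <= ymax, function(a, b) ix(a, b, ymax, 2))
  p
}

.poly_area <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3L) return(0)
  i2 <- c(2:n, 1L)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}
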