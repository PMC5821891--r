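#' Write a domain or flow solution as a legacy VTK file
#'
#' Exports the rasterized domain and any cell fields as an ASCII legacy VTK
#' `STRUCTURED_POINTS` dataset (cell data), readable by ParaView and
#' similar tools. The mask is always written; a `flow_field` adds velocity
#' and pressure, and extra named matrices can be appended.
#'
#' @param x A `domain_grid` or `flow_field`.
#' @param path Output file path (`.vtk`).
#' @param fields Optional named list of additional `nx x ny` matrices to
#'   write as scalar cell fields.
#' @return The path, invisibly.
#' @export
write_vtk <- function(x, path, fields = list()) {
  if (inherits(x, "flow_field")) {
    flow <- x
    domain <- x$domain
    fields <- c(list(velocity_u = flow$uc, velocity_v = flow$vc,
                     pressure = flow$p), fields)
  } else if (inherits(x, "domain_grid")) {
    domain <- x
  } else stop("x must be a domain_grid or flow_field")
  nx <- domain$nx; ny <- domain$ny; h <- domain$h
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("pivcflow mid-plane field")
  wl("ASCII")
  wl("DATASET STRUCTURED_POINTS")
  wl("DIMENSIONS %d %d 1", nx + 1L, ny + 1L)
  wl("ORIGIN 0 %g 0", -h)
  wl("SPACING %g %g 1", h, h)
  wl("CELL_DATA %d", nx * ny)
  put <- function(name, m, type = "float") {
    wl("SCALARS %s %s 1", name, type)
    wl("LOOKUP_TABLE default")
    vals <- as.vector(m)          # column-major = x fastest, VTK order
    vals[is.na(vals)] <- 0
    writeLines(paste(formatC(vals, format = "g", digits = 7)), con)
  }
  put("mask", domain$mask, "int")
  for (nm in names(fields)) put(nm, fields[[nm]])
  invisible(path)
}
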