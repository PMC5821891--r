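#' Study configuration
#'
#' Collects every knob of a parameter sweep in one object. The `"ci"` sweep
#' is the package's desk-scale default: a 48 mm vein at 0.15 mm cells, the
#' full rate ladder {2.1, 50, 300} mL/min on the 20G centre 10-degree
#' geometry (300 mL/min in the Reynolds-scaled closure), the edge angle
#' ladder {10, 15, 20} degrees at 2.1 mL/min, plus the patent-vein control
#' — enough to exercise every metric and the direction-of-effect
#' properties in minutes. The `"full"` sweep enumerates all study arms on
#' the 100 mm vein (hours of compute).
#'
#' @param sweep `"ci"`, `"full"`, or `"custom"` (then `configs` is used).
#' @param vein A `vein_spec`; default depends on the sweep.
#' @param cell_size_mm Grid cell size.
#' @param tip_axial_mm Axial station of the catheter tip.
#' @param configs List of `pivc_config` for `sweep = "custom"`.
#' @param closure_high_rate Closure for runs whose catheter Reynolds number
#'   exceeds 2000 (`"reynolds_scaled"` or `"eddy_viscosity"`).
#' @param equivalence 2-D rate equivalence (see [boundary_conditions()]).
#' @param tol,max_iter Solver convergence settings.
#' @param n_outer Flow/species coupling iterations.
#' @param schmidt Scalar Schmidt number.
#' @param keep_fields Keep the solved fields on the result (needed for VTK
#'   export).
#' @return An object of class `study_config`.
#' @export
study_config <- function(sweep = c("ci", "full", "custom"),
                         vein = NULL, cell_size_mm = 0.15,
                         tip_axial_mm = 14,
                         configs = NULL,
                         closure_high_rate = c("reynolds_scaled",
                                               "eddy_viscosity"),
                         equivalence = c("mean_velocity", "flux_ratio"),
                         tol = 1e-5, max_iter = 80000, n_outer = 2,
                         schmidt = 1000, keep_fields = FALSE) {
  sweep <- match.arg(sweep)
  closure_high_rate <- match.arg(closure_high_rate)
  equivalence <- match.arg(equivalence)
  if (is.null(vein))
    vein <- if (sweep == "full") vein_spec(2.4, 100, 28)
            else vein_spec(2.4, 48, 28)
  if (sweep == "full" && missing(tip_axial_mm))
    tip_axial_mm <- 0.4 * vein$length_mm
  cfgs <- switch(sweep,
    full = enumerate_configurations(include_controls = TRUE),
    ci = c(lapply(c(2.1, 50, 300), function(r)
             configuration("20G", 10, "centre", r)),
           lapply(c(10, 15, 20), function(a)
             configuration("20G", a, "edge", 2.1)),
           list(configuration(NULL))),
    custom = {
      if (is.null(configs)) stop("custom sweep requires configs")
      configs
    })
  structure(list(sweep = sweep, vein = vein, cell_size_mm = cell_size_mm,
                 tip_axial_mm = tip_axial_mm, configs = cfgs,
                 closure_high_rate = closure_high_rate,
                 equivalence = equivalence, tol = tol, max_iter = max_iter,
                 n_outer = n_outer, schmidt = schmidt,
                 keep_fields = keep_fields),
            class = "study_config")
}

#' Read a study configuration from YAML or JSON
#'
#' Recognized keys mirror the arguments of [study_config()]; vein
#' dimensions come as `vein: {diameter_mm, length_mm, inlet_flow_mL_min}`
#' and custom run lists as `configs: [{gauge, angle_deg, tip_position,
#' infusion_rate_mL_min}, ...]`.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  args <- raw
  if (!is.null(raw$vein)) args$vein <- do.call(vein_spec, raw$vein)
  if (!is.null(raw$configs)) {
    args$configs <- lapply(raw$configs, function(cf) {
      if (is.null(cf$gauge) || identical(cf$gauge, "none"))
        configuration(NULL)
      else configuration(cf$gauge, cf$angle_deg, cf$tip_position,
                         cf$infusion_rate_mL_min)
    })
    args$sweep <- "custom"
  }
  do.call(study_config, args)
}

# Solve one configuration: flow with species coupling, then residence.
.run_one <- function(cf, sc, init = NULL) {
  dom <- build_domain(cf, sc$vein, sc$cell_size_mm,
                      tip_axial_mm = sc$tip_axial_mm)
  bc <- boundary_conditions(dom, equivalence = sc$equivalence)
  re_c <- if (!is.null(cf$catheter) && cf$infusion_rate_mL_min > 0)
    reynolds(saline_properties(), cf$infusion_rate_mL_min,
             cf$catheter$inner_diameter_mm) else 0
  closure <- if (re_c > 2000) sc$closure_high_rate else "laminar"
  fl <- solve_steady_flow(dom, bc, closure = closure, tol = sc$tol,
                          max_iter = sc$max_iter, init = init)
  sp <- NULL
  if (!is.null(cf$catheter) && cf$infusion_rate_mL_min > 0) {
    sp <- solve_species(fl, schmidt = sc$schmidt)
    for (k in seq_len(sc$n_outer - 1L)) {
      fmat <- sp$values; fmat[is.na(fmat)] <- 1
      fl <- solve_steady_flow(dom, bc, closure = closure, tol = sc$tol,
                              max_iter = sc$max_iter,
                              mass_fraction = fmat, init = fl)
      sp <- solve_species(fl, schmidt = sc$schmidt)
    }
  }
  res <- suppressWarnings(solve_residence(fl, schmidt = sc$schmidt))
  list(config = cf, domain = dom, flow = fl, species = sp, residence = res)
}

#' Run the parametric study
#'
#' Executes the sweep of a [study_config()]: the patent-vein control first
#' (it provides the normalization baseline), then every configured run with
#' flow/species coupling; collects the tidy metrics table, the stasis-by-
#' rate table (configurations averaged within each rate, as the absence of
#' rate interactions permits), subset ANOVA effects per metric when the
#' sweep covers the full design, and quadratic surrogate fits of normalized
#' WSS against infusion rate per gauge/position group together with their
#' 38 Pa critical rates.
#'
#' If a run fails, the error condition carries the rows completed so far
#' (`$completed_rows`); passing that condition (or the rows) as `resume`
#' re-runs only the missing configurations.
#'
#' @param sc A `study_config` (or a path accepted by
#'   [read_study_config()]).
#' @param progress Print one line per completed run.
#' @param resume A `pivcflow_run_error` condition (or its `completed_rows`
#'   data frame) from a previous partial run.
#' @return An object of class `study_results` with elements `metrics`
#'   (tidy data frame), `baseline`, `stasis_table`, `effects`,
#'   `surrogates`, `critical_rates`, `manifest` and (optionally) `runs`.
#' @export
run_study <- function(sc = study_config(), progress = interactive(),
                      resume = NULL) {
  if (is.character(sc)) sc <- read_study_config(sc)
  stopifnot(inherits(sc, "study_config"))
  configs <- sc$configs
  is_ctrl <- vapply(configs, function(cf) is.null(cf$catheter), logical(1))
  ord <- order(!is_ctrl)                # control(s) first
  configs <- configs[ord]
  if (!any(is_ctrl))
    configs <- c(list(configuration(NULL)), configs)

  done <- NULL
  if (!is.null(resume)) {
    done <- if (inherits(resume, "condition")) resume$completed_rows
            else resume
  }
  run_key <- function(info) paste(info$gauge, info$angle, info$position,
                                  info$rate)
  completed <- list()
  baseline <- NULL
  rows <- list()
  for (idx in seq_along(configs)) {
    cf <- configs[[idx]]
    info <- configurations_table(list(cf))
    names(info) <- c("gauge", "angle", "position", "rate")
    if (!is.null(done) && run_key(info) %in% run_key(done) &&
        !(is.null(baseline) && info$gauge == "none")) {
      rows[[idx]] <- done[run_key(done) == run_key(info), , drop = FALSE][1, ]
      next
    }
    run <- tryCatch(.run_one(cf, sc), error = function(e) {
      stop(structure(class = c("pivcflow_run_error", "error", "condition"),
        list(message = sprintf("run %d (%s) failed: %s", idx,
                               paste(configurations_table(list(cf))[1, ],
                                     collapse = "/"),
                               conditionMessage(e)),
             call = sys.call(-1),
             completed_rows = if (length(rows))
               do.call(rbind, Filter(Negate(is.null), rows)) else NULL)))
    })
    m <- summarize_and_normalize(run$flow, run$species, run$residence,
                                 baseline = baseline)
    if (is.null(run$config$catheter) && is.null(baseline)) {
      baseline <- m
      m$wss_norm <- 1; m$damage_norm <- 1
    }
    m$iterations <- run$flow$iterations
    m$residual <- utils::tail(run$flow$residuals$residual, 1)
    rows[[idx]] <- cbind(info, m)
    completed[[idx]] <- if (sc$keep_fields) run else run["config"]
    if (progress)
      cat(sprintf("[%d/%d] %s %s %s %g mL/min: max WSS %.3g Pa\n",
                  idx, length(configs), info$gauge,
                  ifelse(is.na(info$angle), "-", info$angle),
                  ifelse(is.na(info$position), "-", info$position),
                  info$rate, m$max_wss))
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL

  # stasis-by-rate table: patent vein row, then configuration means per rate
  cath <- metrics[metrics$gauge != "none", , drop = FALSE]
  ctrl <- metrics[metrics$gauge == "none", , drop = FALSE][1, ]
  scols <- grep("^stasis_pct_", names(metrics), value = TRUE)
  stasis_table <- rbind(
    data.frame(infusion_rate_mL_min = "patent vein",
               as.list(ctrl[scols]), check.names = FALSE),
    do.call(rbind, lapply(sort(unique(cath$rate)), function(r) {
      sub <- cath[cath$rate == r, scols, drop = FALSE]
      data.frame(infusion_rate_mL_min = as.character(r),
                 as.list(colMeans(sub)), check.names = FALSE)
    }))
  )
  names(stasis_table) <- c("infusion_rate_mL_min",
                           sub("stasis_pct_", ">", scols))

  # subset ANOVAs per metric, when the sweep covers the full design
  effects <- NULL
  eff_try <- lapply(c("wss_norm", "damage_norm", "stasis_pct_1s"),
    function(resp) {
      tryCatch(cbind(response = resp,
                     effects_table(study_subsets(cath, resp))),
               error = function(e) NULL)
    })
  eff_try <- Filter(Negate(is.null), eff_try)
  if (length(eff_try)) effects <- do.call(rbind, eff_try)

  # quadratic surrogates of normalized WSS vs rate (mL/s) per gauge/position
  surrogates <- list(); crit <- NULL
  for (g in unique(cath$gauge)) for (p in unique(cath$position)) {
    sub <- cath[cath$gauge == g & cath$position == p, , drop = FALSE]
    if (length(unique(sub$rate)) >= 3) {
      lbl <- paste0(g, "-", p)
      mdl <- fit_wss_model(sub$rate / 60, sub$wss_norm, label = lbl)
      surrogates[[lbl]] <- mdl
    }
  }
  if (length(surrogates))
    crit <- critical_rate_table(surrogates, threshold = 38)

  manifest <- list(
    package_version = as.character(utils::packageVersion("pivcflow")),
    sweep = sc$sweep,
    vein = unclass(sc$vein),
    cell_size_mm = sc$cell_size_mm, tip_axial_mm = sc$tip_axial_mm,
    closure_high_rate = sc$closure_high_rate,
    equivalence = sc$equivalence, tol = sc$tol, n_outer = sc$n_outer,
    schmidt = sc$schmidt,
    configs = configurations_table(configs)
  )
  structure(list(metrics = metrics, baseline = baseline,
                 stasis_table = stasis_table, effects = effects,
                 surrogates = surrogates, critical_rates = crit,
                 manifest = manifest,
                 runs = if (sc$keep_fields) completed else NULL),
            class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("Study results: %d runs (%s sweep)\n", nrow(x$metrics),
              x$manifest$sweep))
  cat("\nStasis volumes [% of vein] by infusion rate:\n")
  print.data.frame(x$stasis_table, digits = 3, row.names = FALSE)
  cat("\nNormalized max WSS by run:\n")
  print.data.frame(x$metrics[, c("gauge", "angle", "position", "rate",
                                 "max_wss", "wss_norm")],
                   digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write study outputs to a directory
#'
#' Emits the tidy metrics CSV, the stasis-by-rate table, the ANOVA effects
#' table, surrogate coefficients with critical rates, a JSON manifest, log-
#' scale summary figures (PDF), and — when the results carry fields — one
#' VTK file per run.
#'
#' @param results A `study_results`.
#' @param out_dir Output directory (created if absent).
#' @param plots Write summary figures.
#' @return Invisibly, the vector of files written.
#' @export
report <- function(results, out_dir, plots = TRUE) {
  stopifnot(inherits(results, "study_results"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  files <- character(0)
  wcsv <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  wcsv(results$metrics, "metrics.csv")
  wcsv(results$stasis_table, "stasis_table.csv")
  if (!is.null(results$effects)) wcsv(results$effects, "effects.csv")
  if (!is.null(results$critical_rates)) {
    wcsv(results$critical_rates, "critical_rates.csv")
    coefs <- do.call(rbind, lapply(results$surrogates, function(m)
      data.frame(label = m$label, a = m$coefficients["a"],
                 b = m$coefficients["b"], c = m$coefficients["c"],
                 row.names = NULL)))
    wcsv(coefs, "surrogate_coefficients.csv")
  }
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(results$manifest, mf, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, mf)
  if (!is.null(results$runs)) {
    for (i in seq_along(results$runs)) {
      run <- results$runs[[i]]
      if (is.null(run$flow)) next
      extra <- list()
      if (!is.null(run$species)) extra$mass_fraction <- run$species$values
      if (!is.null(run$residence)) extra$residence <- run$residence$values
      f <- file.path(out_dir, sprintf("run_%02d.vtk", i))
      write_vtk(run$flow, f, fields = extra)
      files <- c(files, f)
    }
  }
  if (plots) {
    f <- file.path(out_dir, "summary_figures.pdf")
    grDevices::pdf(f, width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    m <- results$metrics[results$metrics$gauge != "none", ]
    if (nrow(m)) {
      graphics::plot(m$rate, m$wss_norm, log = "xy",
                     xlab = "infusion rate [mL/min]",
                     ylab = "normalized max WSS",
                     main = "Wall shear vs infusion rate",
                     pch = ifelse(m$position == "edge", 17, 19))
      graphics::legend("topleft", pch = c(19, 17),
                       legend = c("centre", "edge"))
      graphics::plot(m$rate, m$stasis_pct_1s, log = "x",
                     xlab = "infusion rate [mL/min]",
                     ylab = "stasis volume > 1 s [%]",
                     main = "Venous stasis vs infusion rate", pch = 19)
      e <- m[m$position == "edge" & !is.na(m$residence_p99), ]
      if (nrow(e) > 1)
        graphics::plot(e$angle, e$residence_p99, log = "y",
                       xlab = "insertion angle [deg]",
                       ylab = "residence time, 99th pct [s]",
                       main = "Residence time vs insertion angle", pch = 19)
    }
    files <- c(files, f)
  }
  invisible(files)
}
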