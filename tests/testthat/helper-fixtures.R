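# Shared fixtures, memoized so expensive solver runs happen once per session.
.fix <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fix)) assign(name, force(expr), .fix)
  get(name, .fix)
}

test_vein <- function(length_mm = 48) vein_spec(2.4, length_mm, 28)

# patent-vein control solve on the desk-scale grid
patent_flow <- function() memo("patent_flow", {
  dom <- build_domain(configuration(NULL), test_vein(), 0.15)
  solve_steady_flow(dom, tol = 1e-6, max_iter = 30000)
})

# one infusing catheter run (20G, 10 deg, edge, 50 mL/min)
cath_flow <- function() memo("cath_flow", {
  dom <- build_domain(configuration("20G", 10, "edge", 50), test_vein(),
                      0.15, tip_axial_mm = 14)
  solve_steady_flow(dom, tol = 1e-5, max_iter = 80000)
})

# the study's desk-scale sweep (control + rate ladder + angle ladder)
ci_results <- function() memo("ci_results", {
  run_study(study_config("ci"), progress = FALSE)
})

# no-infusion catheter (dead-end lumen) run
noinf_flow <- function() memo("noinf_flow", {
  dom <- build_domain(configuration("20G", 20, "edge", 0), test_vein(),
                      0.15, tip_axial_mm = 14)
  solve_steady_flow(dom, tol = 1e-5, max_iter = 60000)
})

# catheter run under the flux-ratio 2-D equivalence (species balance check)
flux_ratio_run <- function() memo("flux_ratio_run", {
  dom <- build_domain(configuration("18G", 10, "centre", 50), test_vein(),
                      0.15, tip_axial_mm = 14)
  bc <- boundary_conditions(dom, equivalence = "flux_ratio")
  fl <- solve_steady_flow(dom, bc, tol = 1e-5, max_iter = 80000)
  list(flow = fl, species = solve_species(fl))
})

# Independent brute-force sums of squares for a balanced factorial table:
# inclusion-exclusion over marginal means, no model fitting involved.
brute_force_ss <- function(table, response, factors) {
  y <- table[[response]]
  grand <- mean(y)
  subsets <- unlist(lapply(seq_along(factors), function(k)
    utils::combn(factors, k, simplify = FALSE)), recursive = FALSE)
  marg <- function(fs) {
    if (!length(fs)) return(rep(grand, nrow(table)))
    means <- tapply(y, table[fs], mean)
    idx <- do.call(cbind, lapply(fs, function(f)
      match(as.character(table[[f]]), dimnames(means)[[which(fs == f)]])))
    means[idx]
  }
  ss <- sapply(subsets, function(S) {
    eff <- rep(0, nrow(table))
    subs_of_S <- unlist(lapply(0:length(S), function(k)
      utils::combn(S, k, simplify = FALSE)), recursive = FALSE)
    for (Tset in subs_of_S) {
      sign <- (-1)^(length(S) - length(Tset))
      eff <- eff + sign * marg(Tset)
    }
    sum(eff^2)
  })
  names(ss) <- sapply(subsets, paste, collapse = ":")
  cell_means <- marg(factors)
  c(ss, Residuals = sum((y - cell_means)^2),
    Total = sum((y - grand)^2))
}
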