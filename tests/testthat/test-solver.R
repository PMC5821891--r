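test_that("fluid properties normalize units and mix linearly", {
  b <- blood_properties()
  s <- saline_properties()
  expect_equal(b$viscosity, 2.78e-3)
  expect_equal(s$viscosity, 1.02e-3)
  expect_equal(b$density, 1050)
  expect_equal(s$density, 1005)
  expect_equal(mixture_properties(1)$viscosity, b$viscosity)
  expect_equal(mixture_properties(0)$density, s$density)
  expect_equal(mixture_properties(0.5)$viscosity, 1.90e-3)
  expect_error(mixture_properties(1.5), "outside")
  expect_error(fluid_properties(-1, 1), "positive")
})

test_that("Reynolds numbers match the study regimes", {
  expect_gt(reynolds(saline_properties(), 300, 0.61), 1e4)
  expect_equal(reynolds(saline_properties(), 300, 0.61), 1.03e4,
               tolerance = 0.005)
  expect_equal(reynolds(blood_properties(), 28, 2.4), 94, tolerance = 0.01)
  expect_equal(reynolds(blood_properties(), 0, 2.4), 0)
  expect_error(reynolds(blood_properties(), 28, 0), "diameter")
})

test_that("inlet profile integrates exactly to its flow rate", {
  dom <- build_domain(configuration(NULL), test_vein(), 0.15)
  bc <- boundary_conditions(dom)
  D <- 2.4e-3
  got <- stats::integrate(function(y)
    pivcflow:::.parabolic_profile(y, D, bc$U_vein), 0, D,
    rel.tol = 1e-12)$value
  expect_equal(got, bc$q2_vein, tolerance = 1e-10)
})

test_that("patent vein recovers plane Poiseuille", {
  fl <- patent_flow()
  dom <- fl$domain
  D <- 2.4e-3
  U <- fl$bc$U_vein
  exact <- pivcflow:::.parabolic_profile(dom$y, D, U)
  mid <- round(dom$nx / 2)
  sel <- dom$mask[mid, ] == 0L
  expect_lt(max(abs(fl$uc[mid, sel] - exact[sel]) / max(exact)), 0.01)
  # centerline to mean velocity ratio of the planar channel
  expect_equal(max(fl$uc[mid, ]) / U, 1.5, tolerance = 0.01)
  # wall shear against the plane-channel formula tau = 6 mu Q' / D^2
  tau_exact <- 6 * blood_properties()$viscosity * fl$bc$q2_vein / D^2
  ws <- wall_shear(fl)
  expect_equal(max(ws$tau), tau_exact, tolerance = 0.01)
  expect_lt(fl$mass_imbalance, 1e-8)
  expect_lt(fl$div_norm, 1e-10)
})

test_that("halving the cell size changes patent wall shear by < 2%", {
  fl <- patent_flow()
  dom2 <- build_domain(configuration(NULL), test_vein(), 0.075)
  fl2 <- solve_steady_flow(dom2, tol = 1e-6, max_iter = 60000)
  t1 <- max(wall_shear(fl)$tau)
  t2 <- max(wall_shear(fl2)$tau)
  expect_lt(abs(t2 - t1) / t1, 0.02)
})

test_that("Couette flow recovers the linear profile and tau = mu gamma", {
  U_top <- 0.05
  vein <- vein_spec(2.4, 30, 28)
  dom <- build_domain(configuration(NULL), vein, 0.15)
  bc <- boundary_conditions(dom, Q_vein_mL_min = 0,
    wall_velocity_top = U_top,
    vein_inlet_profile = function(y, D, U) ifelse(y > 0 & y < D,
                                                  U_top * y / D, 0))
  fl <- solve_steady_flow(dom, bc, tol = 1e-6, max_iter = 40000)
  D <- 2.4e-3
  mid <- round(dom$nx / 2)
  sel <- dom$mask[mid, ] == 0L
  exact <- U_top * dom$y[sel] / D
  expect_lt(max(abs(fl$uc[mid, sel] - exact)) / U_top, 0.01)
  gamma <- U_top / D
  tau_exact <- blood_properties()$viscosity * gamma
  ws <- wall_shear(fl)
  expect_equal(mean(ws$tau[ws$x_mm > 5 & ws$x_mm < 25]), tau_exact,
               tolerance = 0.01)
})

test_that("axisymmetric validation mode reproduces pipe Poiseuille shear", {
  pf <- pipe_flow_profile(28, 2.4, blood_properties())
  expect_equal(pf$tau_analytic, 0.956, tolerance = 0.001)
  expect_equal(pf$tau_wall, pf$tau_analytic, tolerance = 0.005)
})

test_that("symmetric control solution is mirror invariant", {
  fl <- patent_flow()
  ny <- fl$domain$ny
  expect_lt(max(abs(fl$uc - fl$uc[, ny:1])), 1e-10 * max(fl$uc))
  expect_lt(max(abs(fl$vc + fl$vc[, ny:1])), 1e-10 * max(fl$uc))
})

test_that("capped catheter lumen carries no net flow", {
  fl <- noinf_flow()
  dom <- fl$domain
  # the capped lumen is a dead-end cavity: the tip-mouth recirculation
  # decays with depth, leaving the lumen interior effectively stagnant
  idx <- which(dom$mask == 3L, arr.ind = TRUE)
  s <- (dom$x[idx[, 1]] - dom$tip[1]) * dom$axis[1] +
    (dom$y[idx[, 2]] - dom$tip[2]) * dom$axis[2]
  speed <- sqrt(fl$uc[idx]^2 + fl$vc[idx]^2)
  deep <- s < -2.5e-3
  expect_gt(sum(deep), 0)
  expect_lt(max(speed[deep]) / fl$bc$U_vein, 1e-6)
})

test_that("non-convergence raises a diagnostic error with history", {
  dom <- build_domain(configuration(NULL), test_vein(), 0.15)
  err <- tryCatch(solve_steady_flow(dom, max_iter = 10),
                  pivcflow_nonconvergence = function(e) e)
  expect_s3_class(err, "pivcflow_nonconvergence")
  expect_true(is.data.frame(err$residual_history))
  expect_gt(nrow(err$residual_history), 0)
})

test_that("Reynolds-scaled closure reports its scale factor", {
  res <- ci_results()
  m <- res$metrics
  hi <- m[m$rate == 300 & m$gauge != "none", ]
  expect_true(all(hi$closure == "reynolds_scaled"))
  expect_true(all(hi$scaled))
  lo <- m[m$rate %in% c(0, 2.1, 50), ]
  expect_true(all(lo$closure == "laminar"))
})
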