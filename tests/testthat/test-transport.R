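test_that("species transport reduces to pure blood without infusion", {
  fl <- patent_flow()
  sp <- solve_species(fl)
  expect_true(all(abs(sp$values - 1) < 1e-9, na.rm = TRUE))
})

test_that("species stays in [0, 1] and conserves the imposed fluxes", {
  fl <- cath_flow()
  sp <- solve_species(fl)
  expect_gte(min(sp$values, na.rm = TRUE), 0)
  expect_lte(max(sp$values, na.rm = TRUE), 1)
  expected <- fl$bc$q2_vein / (fl$bc$q2_vein + fl$bc$q2_cath)
  expect_equal(outlet_mean(sp), expected, tolerance = 1e-3)
})

test_that("flux-ratio equivalence reproduces the volumetric blood share", {
  run <- flux_ratio_run()
  # 28 mL/min of blood against 50 mL/min of saline: f_out = 28/78
  expect_equal(outlet_mean(run$species), 28 / 78, tolerance = 1e-3)
})

test_that("plug-flow residence equals L/U at the outlet", {
  U <- 0.1
  fx <- generate_analytic_field("plug", vein_spec(2.4, 30, 28),
                                cell_size_mm = 0.15, U = U)
  res <- solve_residence(fx$flow)
  dom <- fx$flow$domain
  L <- dom$vein$length_mm * 1e-3
  out_T <- mean(res$values[dom$nx, dom$mask[dom$nx, ] == 0L])
  expect_equal(out_T, L / U, tolerance = 2 * dom$h / L)
  # inlet cells sit within half a cell of the zero-age inlet
  in_T <- res$values[1, dom$mask[1, ] == 0L]
  expect_true(all(in_T < 2 * dom$h / U))
})

test_that("Poiseuille residence follows the characteristics x/u(y)", {
  fx <- generate_analytic_field("plane_poiseuille", vein_spec(2.4, 30, 28),
                                cell_size_mm = 0.15)
  res <- solve_residence(fx$flow)
  dom <- fx$flow$domain
  D <- 2.4e-3
  jmid <- which.min(abs(dom$y - D / 4))       # mid-radius row
  u_mid <- pivcflow:::.parabolic_profile(dom$y[jmid], D, fx$flow$bc$U_vein)
  sel <- dom$x > 0.3 * max(dom$x)
  expect_lt(max(abs(res$values[sel, jmid] - dom$x[sel] / u_mid) /
                  (dom$x[sel] / u_mid)), 0.05)
})

test_that("stagnant domains hit the residence cap with a warning", {
  fx <- generate_analytic_field("stagnant", vein_spec(2.4, 30, 28),
                                cell_size_mm = 0.15)
  expect_warning(res <- solve_residence(fx$flow), "capped")
  expect_equal(max(res$values, na.rm = TRUE), res$cap)
})

test_that("damage law matches independent evaluation and homogeneity", {
  # independent high-precision route through log space
  p <- hemolysis_params()
  log_sigma <- log(p$C) / p$alpha + (p$beta / p$alpha) * log(1)
  expect_equal(damage_rate(1), exp(log_sigma), tolerance = 1e-12)
  expect_equal(damage_rate(1), 6.2e-9, tolerance = 0.01)
  expect_equal(damage_rate(2) / damage_rate(1), 2^(2.416 / 0.785),
               tolerance = 1e-12)
  expect_equal(damage_rate(0), 0)
  expect_equal(damage_rate(5, 0), 0)
  expect_error(damage_rate(-1), "non-negative")
  expect_error(damage_rate(1, 2), "mass fraction")
  expect_error(hemolysis_params(alpha = 3, beta = 2), "exceed")
  # strictly increasing in tau and f
  taus <- seq(0.5, 10, length.out = 20)
  expect_true(all(diff(damage_rate(taus)) > 0))
  fs <- seq(0.1, 1, length.out = 10)
  expect_true(all(diff(damage_rate(2, fs)) > 0))
})

test_that("stasis volumes follow thresholds and the analytic pipe oracle", {
  dom <- build_domain(configuration(NULL), test_vein(), 0.15)
  uni <- structure(list(kind = "residence_time",
                        values = matrix(3, dom$nx, dom$ny),
                        domain = dom), class = "scalar_field")
  expect_equal(unname(stasis_volumes(uni, c(1, 2, 5))), c(100, 100, 0))
  # no-diffusion axisymmetric pipe oracle: fraction = L / (4 U T)
  ax <- generate_analytic_field("pipe_poiseuille_axisym",
                                vein_spec(2.4, 100, 28),
                                n_r = 400, n_x = 800)
  sv <- stasis_volumes(ax, c(1, 2, 5))
  closed <- 100 * ax$L / (4 * ax$U_mean * c(1, 2, 5))
  expect_equal(unname(sv), closed, tolerance = 0.005)
  expect_equal(unname(sv[1]), 24.2, tolerance = 0.005)
  expect_true(all(diff(sv) < 0))
  expect_error(stasis_volumes(uni, c(-1, 2)), "thresholds > 0")
})

test_that("summary metrics normalize and scale as the power law demands", {
  fx <- generate_analytic_field("plane_poiseuille", vein_spec(2.4, 30, 28),
                                cell_size_mm = 0.15)
  res <- solve_residence(fx$flow)
  base <- summarize_and_normalize(fx$flow, NULL, res)
  m1 <- summarize_and_normalize(fx$flow, NULL, res, baseline = base)
  expect_equal(m1$wss_norm, 1)
  expect_equal(m1$damage_norm, 1)
  expect_gte(m1$max_wss, m1$mean_wss)
  # doubling every velocity doubles WSS and scales damage by 2^(beta/alpha)
  fl2 <- fx$flow
  fl2$u <- 2 * fl2$u; fl2$v <- 2 * fl2$v
  fl2$uc <- 2 * fl2$uc; fl2$vc <- 2 * fl2$vc
  m2 <- summarize_and_normalize(fl2, NULL, res, baseline = base)
  expect_equal(m2$max_wss / m1$max_wss, 2, tolerance = 1e-10)
  expect_equal(m2$damage_total / m1$damage_total, 2^(2.416 / 0.785),
               tolerance = 1e-10)
  expect_error(summarize_and_normalize(fx$flow, NULL, res,
    baseline = within(base, max_wss <- 0)), "baseline")
})

test_that("residence summaries react to the sweep monotonically", {
  res <- ci_results()
  m <- res$metrics
  edge <- m[m$position == "edge" & m$rate == 2.1, ]
  edge <- edge[order(edge$angle), ]
  expect_equal(nrow(edge), 3)
  expect_true(all(diff(edge$residence_p99) < 0))
  # stasis thresholds are monotone within every run
  for (k in seq_len(nrow(m))) {
    v <- unlist(m[k, c("stasis_pct_1s", "stasis_pct_2s", "stasis_pct_5s")])
    expect_true(all(diff(v) <= 1e-12))
  }
})
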