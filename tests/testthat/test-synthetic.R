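test_that("analytic fixtures satisfy the solver's own invariants", {
  for (kind in c("plane_poiseuille", "couette", "stagnant")) {
    fx <- generate_analytic_field(kind, vein_spec(2.4, 30, 28), 0.15)
    fl <- fx$flow
    dom <- fl$domain
    nx <- dom$nx; ny <- dom$ny
    div <- (fl$u[2:(nx + 1), ] - fl$u[1:nx, ] +
              fl$v[, 2:(ny + 1)] - fl$v[, 1:ny]) / dom$h
    expect_lt(max(abs(div[fl$setup$flow])), 1e-14)
    # no-slip: every face touching a solid cell carries zero velocity
    solid <- matrix(dom$mask %in% c(1L, 2L), nx, ny)
    u_wallface <- rbind(solid[1, ], solid) | rbind(solid, solid[nx, ])
    expect_true(all(fl$u[u_wallface] == 0))
  }
})

test_that("plane Poiseuille fixture carries its exact residence field", {
  fx <- generate_analytic_field("plane_poiseuille", vein_spec(2.4, 30, 28),
                                0.15)
  dom <- fx$flow$domain
  sel <- !is.na(fx$residence$values)
  expect_true(all(fx$residence$values[sel] >= 0))
  j <- 8; i <- 100
  u <- pivcflow:::.parabolic_profile(dom$y[j], 2.4e-3, fx$flow$bc$U_vein)
  expect_equal(fx$residence$values[i, j], dom$x[i] / u)
})

test_that("factorial tables are deterministic and design-complete", {
  t1 <- generate_factorial_table(effect_spec(seed = 11))
  t2 <- generate_factorial_table(effect_spec(seed = 11))
  expect_identical(t1, t2)
  t3 <- generate_factorial_table(effect_spec(seed = 12))
  expect_false(identical(t1$response, t3$response))
  expect_equal(nrow(t1), 30)
  expect_equal(attr(t1, "seed"), 11L)
  key <- paste(t1$gauge, t1$angle, t1$position, t1$rate)
  expect_equal(anyDuplicated(key), 0)
})

test_that("unit multipliers put exactly zero SS on the factors", {
  spec <- effect_spec(rate = c("2.1" = 1, "50" = 1, "300" = 1),
                      gauge = c("18G" = 1, "20G" = 1),
                      angle = c("5" = 1, "10" = 1, "15" = 1, "20" = 1),
                      position = c("centre" = 1, "edge" = 1),
                      noise_sd = 0)
  tab <- generate_factorial_table(spec)
  ss <- brute_force_ss(tab[tab$position == "edge", ], "response",
                       c("gauge", "angle", "rate"))
  expect_equal(unname(ss["Total"]), 0)
})
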