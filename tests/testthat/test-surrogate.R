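test_that("printed model catalogue is bit-faithful", {
  cat <- printed_models()
  expect_length(cat, 4)
  expect_equal(unname(coef(cat[["20G-edge"]])), c(71.599, 117.92, -1.1518))
  expect_equal(unname(coef(cat[["18G-central"]])), c(4.0746, 6.0725, 3.1187))
  expect_equal(unname(coef(cat[["18G-edge"]])), c(31.182, 20.322, 4.196))
  expect_equal(unname(coef(cat[["20G-central"]])),
               c(6.4093, 20.513, 1.4294))
})

test_that("model evaluation follows the quadratic with guard rails", {
  m1 <- printed_models()[["18G-central"]]
  expect_equal(unname(predict(m1, 0)), 3.1187)
  expect_equal(unname(predict(m1, 1)), 13.2658)
  m4 <- printed_models()[["20G-edge"]]
  expect_warning(v0 <- predict(m4, 0), "negative")
  expect_equal(unname(v0), -1.1518)
  expect_warning(predict(m1, 12), "validity")
  expect_error(predict(m1, -1), "non-negative")
})

test_that("least-squares fit recovers the printed models from samples", {
  xs <- c(0.5, 2, 4, 7, 9)
  for (m in printed_models()) {
    ys <- suppressWarnings(predict(m, xs))
    fit <- fit_wss_model(xs, ys, label = m$label)
    expect_lt(max(abs(coef(fit) - coef(m))), 1e-9)
  }
  # three points interpolate exactly
  m4 <- printed_models()[["20G-edge"]]
  x3 <- c(1, 4, 8)
  fit3 <- fit_wss_model(x3, predict(m4, x3))
  expect_lt(max(abs(coef(fit3) - coef(m4))), 1e-9)
  # a pure line comes back with a ~ 0
  fl <- fit_wss_model(c(1, 2, 5, 8), 2 + 3 * c(1, 2, 5, 8))
  expect_lt(abs(coef(fl)["a"]), 1e-9)
  expect_error(fit_wss_model(c(1, 1, 1), c(1, 2, 3)), "distinct")
})

test_that("critical-rate inversion matches the reported flushing rate", {
  m4 <- printed_models()[["20G-edge"]]
  cr <- critical_rate(m4, 38)
  expect_equal(cr$rate, 0.283, tolerance = 0.002)
  expect_equal(cr$presented, 0.3)
  # round trip before presentation rounding
  expect_equal(unname(suppressWarnings(predict(m4, cr$rate))), 38,
               tolerance = 1e-9)
  # threshold beyond the validity ceiling yields none
  m1 <- printed_models()[["18G-central"]]
  expect_true(is.na(critical_rate(m1, 1000)$rate))
  # strictly increasing in threshold for an increasing model
  ths <- c(10, 20, 38, 80, 150)
  roots <- sapply(ths, function(t) critical_rate(m4, t)$rate)
  expect_true(all(diff(roots) > 0))
  expect_error(critical_rate(wss_quadratic(0, 0, 5), 38), "degenerate")
})
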