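test_that("sums of squares match the brute-force decomposition", {
  set.seed(42)
  # replicated 2x3 and single-replicate 2x3x2 designs
  d1 <- expand.grid(A = c("a", "b"), B = c("x", "y", "z"), rep = 1:3)
  d1$y <- rnorm(nrow(d1), mean = as.integer(d1$A) + 2 * as.integer(d1$B))
  res <- anova_effects(d1, "y", c("A", "B"))
  ora <- brute_force_ss(d1, "y", c("A", "B"))
  for (k in seq_len(nrow(res)))
    expect_equal(res$ss[k], unname(ora[res$effect[k]]), tolerance = 1e-10)
  expect_equal(attr(res, "error_ss"), unname(ora["Residuals"]),
               tolerance = 1e-10)
  # decomposition is exhaustive
  expect_equal(sum(res$ss) + attr(res, "error_ss"), unname(ora["Total"]),
               tolerance = 1e-9)

  d2 <- expand.grid(A = c("a", "b"), B = c("x", "y", "z"), C = c("u", "v"))
  d2$y <- rnorm(nrow(d2))
  res2 <- anova_effects(d2, "y", c("A", "B", "C"))   # pools A:B:C
  ora2 <- brute_force_ss(d2, "y", c("A", "B", "C"))
  for (k in seq_len(nrow(res2)))
    expect_equal(res2$ss[k], unname(ora2[res2$effect[k]]), tolerance = 1e-10)
  expect_equal(attr(res2, "error_ss"), unname(ora2["A:B:C"]),
               tolerance = 1e-10)
  expect_true(attr(res2, "pooled"))
})

test_that("generalized eta-squared behaves as an effect size", {
  # zero noise, non-zero effect: eta2 = 1
  d <- expand.grid(A = c("a", "b"), rep = 1:4)
  d$y <- ifelse(d$A == "a", 1, 3)
  expect_equal(anova_effects(d, "y", "A")$eta2_G, 1)
  # invariance under affine rescaling of the response
  set.seed(7)
  d2 <- expand.grid(A = c("a", "b"), B = c("x", "y", "z"), rep = 1:2)
  d2$y <- rnorm(nrow(d2), as.integer(d2$A))
  e1 <- anova_effects(d2, "y", c("A", "B"))$eta2_G
  d2$y <- 5 * d2$y - 11
  e2 <- anova_effects(d2, "y", c("A", "B"))$eta2_G
  expect_equal(e1, e2, tolerance = 1e-12)
  expect_true(all(e1 >= 0 & e1 <= 1))
})

test_that("degenerate designs are rejected with guidance", {
  d <- expand.grid(A = "a", B = c("x", "y"), rep = 1:2)
  d$y <- rnorm(nrow(d))
  expect_error(anova_effects(d, "y", c("A", "B")), "fewer than 2 levels")
  d2 <- expand.grid(A = c("a", "b"), B = c("x", "y"))
  d2$y <- rnorm(4)
  expect_error(anova_effects(d2, "y", c("A", "B"),
                             error_strategy = "residual"), "pool")
  d3 <- rbind(d2, d2[1, ])
  expect_error(anova_effects(d3, "y", c("A", "B")), "balanced")
})

test_that("study subsets carry the design's row counts and factors", {
  tab <- generate_factorial_table(effect_spec(seed = 3))
  expect_equal(nrow(tab), 30)
  ss <- study_subsets(tab, "response")
  expect_equal(sum(tab$position == "centre"), 12)
  expect_equal(sum(tab$position == "edge"), 18)
  expect_equal(sum(tab$angle == 10), 12)
  expect_setequal(ss$centre$effect[ss$centre$df1 > 0][1:3],
                  c("gauge", "angle", "rate"))
  expect_setequal(ss$position_at_10$effect[1:3],
                  c("position", "gauge", "rate"))
  # missing design cells are reported
  expect_error(study_subsets(tab[-1, ], "response"), "missing design cells")
})

test_that("dominant factors are recovered from synthetic tables", {
  # rate dominates by construction; with growing effect size it must win
  for (seed in 1:3) {
    tab <- generate_factorial_table(effect_spec(
      rate = c("2.1" = 1, "50" = 20, "300" = 400),
      noise_sd = 0.2, seed = seed))
    ss <- study_subsets(tab, "response", log_transform = TRUE)
    for (sub in list(ss$centre, ss$edge)) {
      main <- sub[sub$effect %in% c("gauge", "angle", "rate"), ]
      expect_equal(main$effect[which.max(main$eta2_G)], "rate")
    }
  }
})
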