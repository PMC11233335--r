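# Default-prior Bayes factors against independent oracles.

test_that("JZS paired BF matches the non-central-t oracle", {
  set.seed(501)
  x <- rnorm(30, 0.8, 1)              # d ~ 0.8
  res <- jzs_paired_bf(x)
  expect_equal(res$bf10, jzs_oracle(x), tolerance = 1e-6)
  expect_equal(res$bf01, 1 / res$bf10)
  # other effect sizes and scales
  for (m in c(0, 0.3)) {
    y <- rnorm(24, m, 1)
    for (r in c(0.5, 1)) {
      expect_equal(jzs_paired_bf(y, r = r)$bf10, jzs_oracle(y, r),
                   tolerance = 1e-6)
    }
  }
})

test_that("JZS BF favours the null at t = 0 and is scale invariant", {
  x <- c(-2, -1, 1, 2, -0.5, 0.5)     # mean 0 => t = 0
  expect_lt(jzs_paired_bf(x)$bf10, 1)
  set.seed(502)
  y <- rnorm(20, 0.4, 1)
  expect_equal(jzs_paired_bf(y)$bf10, jzs_paired_bf(10 * y)$bf10,
               tolerance = 1e-8)
  expect_error(jzs_paired_bf(rep(1, 10)), "variance")
  expect_error(jzs_paired_bf(1), "at least 2")
})

test_that("JZS BF grows with n at a fixed true effect", {
  set.seed(503)
  meds <- vapply(c(10, 30, 100), function(n) {
    median(vapply(1:40, function(i)
      jzs_paired_bf(rnorm(n, 0.5, 1))$bf10, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("BANOVA main-effect BFs match the dense-matrix grid oracle", {
  set.seed(504)
  cells <- design_cells()$cell
  # no-effect table: all three BFs below 1, and oracle agreement
  tab0 <- matrix(rnorm(6 * 4, 2, 0.5), 6, 4,
                 dimnames = list(NULL, cells))
  res0 <- rm_banova_bf(tab0, nsim = 2e5)
  expect_lt(res0$bf_pleasantness$bf10, 1)
  expect_lt(res0$bf_difficulty$bf10, 1)
  expect_lt(res0$bf_interaction$bf10, 1)
  expect_equal(res0$bf_pleasantness$bf10, banova_oracle_bf(tab0, "P"),
               tolerance = 0.15)
  expect_equal(res0$bf_difficulty$bf10, banova_oracle_bf(tab0, "D"),
               tolerance = 0.15)
  # table with a large pleasantness effect (d ~ 1.5)
  tab1 <- tab0
  tab1[, c("unpleasant.easy", "unpleasant.difficult")] <-
    tab1[, c("unpleasant.easy", "unpleasant.difficult")] + 1.2
  res1 <- rm_banova_bf(tab1, nsim = 2e5)
  expect_gt(res1$bf_pleasantness$bf10, 100)
  o1 <- banova_oracle_bf(tab1, "P")
  expect_equal(res1$bf_pleasantness$bf10, o1, tolerance = 0.2)
})

test_that("swapping the factor roles swaps the main-effect BFs", {
  set.seed(505)
  cells <- design_cells()
  tab <- matrix(rnorm(8 * 4, 2, 0.4), 8, 4,
                dimnames = list(NULL, cells$cell))
  tab[, cells$cell[cells$difficulty == "difficult"]] <-
    tab[, cells$cell[cells$difficulty == "difficult"]] + 0.5
  swapped <- tab[, c("unpleasant.easy", "pleasant.easy",
                     "unpleasant.difficult", "pleasant.difficult")]
  colnames(swapped) <- cells$cell  # relabel: difficulty <-> pleasantness
  # the swap is exact for the underlying Bayes factors; the Monte Carlo
  # estimates use per-factor g-draw streams, so they agree to MC error
  set.seed(99); res <- rm_banova_bf(tab, nsim = 2e5)
  set.seed(99); res_sw <- rm_banova_bf(swapped, nsim = 2e5)
  expect_equal(res$bf_difficulty$bf10, res_sw$bf_pleasantness$bf10,
               tolerance = 0.05)
  expect_equal(res$bf_pleasantness$bf10, res_sw$bf_difficulty$bf10,
               tolerance = 0.05)
})

test_that("stepwise BANOVA evidences multiply up to the full model", {
  set.seed(506)
  tab <- matrix(rnorm(10 * 4, 2, 0.5), 10, 4,
                dimnames = list(NULL, design_cells()$cell))
  res <- rm_banova_bf(tab, nsim = 2e5)
  ev <- res$evidence
  full <- ev$bf_vs_subject[ev$model == "full"]
  pd <- ev$bf_vs_subject[ev$model == "PD"]
  expect_equal(res$bf_interaction$bf10, full / pd, tolerance = 1e-10)
  # shared g draws make the stepwise product exact by construction;
  # check it against an independently seeded rerun within MC error
  set.seed(507)
  res2 <- rm_banova_bf(tab, nsim = 2e5)
  expect_equal(res$bf_interaction$bf10, res2$bf_interaction$bf10,
               tolerance = 0.1)
})

test_that("percent change reproduces the worked examples", {
  expect_identical(percent_change(3.172, 2.942), 7.82)
  expect_identical(percent_change(2, 2), 0)
  expect_identical(percent_change(2.051, 2.276), -9.89)
  expect_error(percent_change(1, 0), "positive")
})
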