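# Closed-form LBA distributions against independent oracles.

test_that("finishing-time CDF matches a Monte-Carlo oracle", {
  set.seed(101)
  n <- 1e6
  # A=1, B=1 (b=2), v=2, sv=1 at t=1 under the defective convention
  start <- runif(n, 0, 1)
  v <- rnorm(n, 2, 1)
  ft <- ifelse(v > 0, (2 - start) / v, Inf)
  mc <- mean(ft <= 1)
  se <- sqrt(mc * (1 - mc) / n)
  acc <- accumulator_params(A = 1, B = 1, t0 = 0, mean_v = 2)
  expect_lt(abs(lba_cdf(1, acc, convention = "defective") - mc), 3 * se)
})

test_that("CDF limits and degenerate start point behave analytically", {
  acc <- accumulator_params(A = 1, B = 1, t0 = 0, mean_v = 1)
  expect_identical(lba_cdf(0, acc), 0)
  expect_identical(lba_pdf(0, acc), 0)
  # A -> 0: fixed start point, P(finish <= t) = Phi((t v - b)/(t sv))
  dg <- accumulator_params(A = 1e-12, B = 1, t0 = 0, mean_v = 1)
  expect_equal(lba_cdf(1, dg, convention = "defective"), 0.5,
               tolerance = 1e-6)
  expect_equal(lba_cdf(2, dg, convention = "defective"),
               pnorm((2 * 1 - 1) / 2), tolerance = 1e-6)
  # truncated convention: total mass 1; defective: mass P(v > 0). The
  # limit is approached like O(1/t) (near-zero drifts finish late), so
  # evaluate far out.
  a2 <- accumulator_params(A = 1, B = 1, t0 = 0, mean_v = 2)
  expect_equal(lba_cdf(1e6, a2, convention = "truncated"), 1,
               tolerance = 1e-5)
  expect_equal(lba_cdf(1e6, a2, convention = "defective"), pnorm(2),
               tolerance = 1e-5)
})

test_that("CDF is non-decreasing and bounded on a parameter grid", {
  set.seed(102)
  ts <- seq(0, 6, by = 0.05)
  for (i in 1:20) {
    acc <- accumulator_params(A = runif(1, 0.1, 3), B = runif(1, 0.5, 3),
                              t0 = 0, mean_v = runif(1, -0.5, 4),
                              sv = runif(1, 0.5, 2))
    for (conv in c("truncated", "defective")) {
      F <- lba_cdf(ts, acc, convention = conv)
      expect_true(all(F >= 0 & F <= 1))
      expect_true(all(diff(F) >= -1e-12))
    }
  }
})

test_that("pdf agrees with central finite differences of the CDF", {
  acc <- accumulator_params(A = 1, B = 1.5, t0 = 0, mean_v = 2, sv = 1)
  h <- 1e-5
  for (t in c(0.2, 0.5, 1, 2)) {
    for (conv in c("truncated", "defective")) {
      fd <- (lba_cdf(t + h, acc, convention = conv) -
               lba_cdf(t - h, acc, convention = conv)) / (2 * h)
      expect_equal(lba_pdf(t, acc, convention = conv), fd,
                   tolerance = 1e-5)
    }
  }
})

test_that("pdf integrates to the CDF limit", {
  acc <- accumulator_params(A = 2, B = 2, t0 = 0, mean_v = 1.5)
  q <- integrate(function(t) lba_pdf(t, acc, convention = "defective"),
                 0, Inf, rel.tol = 1e-9)
  expect_equal(q$value, pnorm(1.5), tolerance = 1e-6)
  q2 <- integrate(function(t) lba_pdf(t, acc), 0, Inf, rel.tol = 1e-9)
  expect_equal(q2$value, 1, tolerance = 1e-6)
})

test_that("invalid accumulator parameters are rejected", {
  expect_error(accumulator_params(A = -0.1, B = 1, t0 = 0), "A")
  expect_error(accumulator_params(A = 1, B = 0, t0 = 0), "B")
  expect_error(accumulator_params(A = 1, B = 1, t0 = -1), "t0")
  expect_error(accumulator_params(A = 1, B = 1, t0 = 0, sv = 0), "sv")
})

test_that("defective density vanishes at and below non-decision time", {
  cl <- a_cell()
  expect_identical(defective_density(0.29, "normative", cl), 0)
  expect_identical(defective_density(0.3, "aberrant", cl), 0)
  expect_gt(defective_density(0.6, "normative", cl), 0)
})

test_that("identical accumulators give equal choice probabilities", {
  cl <- a_cell(vn = 1.5, va = 1.5)
  for (conv in c("truncated", "defective")) {
    pn <- integrate(function(t) defective_density(t, "normative", cl,
                                                  convention = conv),
                    0.3, Inf, rel.tol = 1e-8)$value
    pa <- integrate(function(t) defective_density(t, "aberrant", cl,
                                                  convention = conv),
                    0.3, Inf, rel.tol = 1e-8)$value
    expect_equal(pn, pa, tolerance = 1e-6)
  }
})

test_that("choices + non-termination mass normalise to 1 on a grid", {
  set.seed(103)
  for (i in 1:20) {
    cl <- a_cell(vn = runif(1, 0.5, 4), va = runif(1, -1, 2),
                 A = runif(1, 0.5, 3), B = runif(1, 0.5, 3),
                 t0 = runif(1, 0.1, 0.5), sv = runif(1, 0.6, 1.5))
    for (conv in c("truncated", "defective")) {
      pn <- integrate(function(t) defective_density(t, "normative", cl,
                                                    convention = conv),
                      0, Inf, rel.tol = 1e-9)$value
      pa <- integrate(function(t) defective_density(t, "aberrant", cl,
                                                    convention = conv),
                      0, Inf, rel.tol = 1e-9)$value
      non_term <- if (conv == "defective") {
        prod(pnorm(c(cl$normative$mean_v / cl$normative$sv,
                     cl$aberrant$mean_v / cl$aberrant$sv),
                   lower.tail = FALSE))
      } else 0
      expect_equal(pn + pa + non_term, 1, tolerance = 1e-4)
    }
  }
})

test_that("normative probability is monotone in normative drift", {
  p_norm <- vapply(seq(0.5, 4, by = 0.5), function(v) {
    cl <- a_cell(vn = v, va = 0.8)
    integrate(function(t) defective_density(t, "normative", cl),
              0.3, Inf, rel.tol = 1e-8)$value
  }, numeric(1))
  expect_true(all(diff(p_norm) > 0))
})

test_that("simulator agrees with the closed form (KS and moments)", {
  set.seed(104)
  cl <- a_cell(vn = 3, va = 0.5, A = 2, B = 2, t0 = 0.3)
  n <- 1e5
  sim <- simulate_trials(cl, n, window = Inf)
  expect_true(all(sim$rt_s > 0.3))
  p_norm <- integrate(function(t) defective_density(t, "normative", cl),
                      0.3, Inf, rel.tol = 1e-9)$value
  expect_lt(abs(mean(sim$choice == "normative") - p_norm),
            3 * sqrt(p_norm * (1 - p_norm) / n))
  # KS distance between simulated normative RTs and the conditional CDF
  rt <- sort(sim$rt_s[sim$choice == "normative"])
  grid_cdf <- function(q) {
    vapply(q, function(u)
      integrate(function(t) defective_density(t, "normative", cl),
                0.3, u, rel.tol = 1e-8)$value / p_norm, numeric(1))
  }
  qs <- rt[seq(1, length(rt), length.out = 200)]
  theo <- grid_cdf(qs)
  emp <- ecdf(rt)(qs)
  expect_lt(max(abs(theo - emp)), 0.01)
  # mean RT against quadrature
  m_quad <- (integrate(function(t) t * defective_density(t, "normative", cl),
                       0.3, Inf, rel.tol = 1e-9)$value +
             integrate(function(t) t * defective_density(t, "aberrant", cl),
                       0.3, Inf, rel.tol = 1e-9)$value)
  expect_lt(abs(mean(sim$rt_s) - m_quad) / m_quad, 0.01)
})

test_that("symmetric race picks each accumulator half the time", {
  set.seed(105)
  cl <- a_cell(vn = 2, va = 2)
  n <- 1e5
  sim <- simulate_trials(cl, n)
  p <- mean(sim$choice == "normative")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / n))
})

test_that("simulation is deterministic under a fixed seed and censors", {
  cl <- a_cell(vn = 0.4, va = 0.1, B = 6)
  set.seed(42); s1 <- simulate_trials(cl, 500)
  set.seed(42); s2 <- simulate_trials(cl, 500)
  expect_identical(s1, s2)
  expect_true(any(s1$censored))          # slow race: some censoring at 8 s
  expect_true(all(s1$rt_s <= 8))
})

test_that("dataset log-likelihood is additive and maximal near truth", {
  cl <- a_cell()
  params <- list(unpleasant.easy = cl)
  expect_identical(dataset_loglik(data.frame(), params), 0)
  tr <- data.frame(rt_s = 1.2, choice = "normative",
                   cell = "unpleasant.easy")
  expect_equal(dataset_loglik(tr, params),
               log(defective_density(1.2, "normative", cl)))
  expect_error(dataset_loglik(transform(tr, cell = "nope"), params),
               "cell")
  # generating parameters beat a drift-shifted alternative almost always
  set.seed(106)
  wins <- 0L
  for (r in 1:100) {
    sim <- simulate_trials(cl, 100)
    sim$cell <- "unpleasant.easy"
    shifted <- list(unpleasant.easy = a_cell(vn = 4))
    if (dataset_loglik(sim, params) > dataset_loglik(sim, shifted))
      wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})
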