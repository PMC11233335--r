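# Hierarchical estimation machinery (cheap checks; the full recovery run
# lives in test-acceptance.R).

test_that("log-posterior matches a brute-force recomputation", {
  set.seed(601)
  spec <- model_spec("null")
  priors <- default_priors(spec)
  cl <- a_cell(vn = 2.5, va = 0.5)
  d <- do.call(rbind, lapply(c("a1", "a2"), function(id) {
    sim <- simulate_trials(cl, 10)
    sim$participant_id <- id
    sim$cell <- sample(design_cells()$cell, 10, replace = TRUE)
    sim
  }))
  d$choice <- d$choice
  theta <- rbind(a1 = c(2, 2, 0.3, 2.5, 0.5),
                 a2 = c(1.8, 2.2, 0.28, 2.7, 0.4))
  mu <- c(2, 2, 0.3, 2.5, 0.5)
  sg <- c(0.2, 0.2, 0.05, 0.3, 0.3)
  got <- log_posterior(theta, mu, sg, d, spec, priors)

  # independent recomputation: per-trial densities, truncated-normal
  # subject terms, truncated-normal location priors, half-normal scales
  ll <- 0
  for (i in 1:2) {
    di <- d[d$participant_id == rownames(theta)[i], ]
    cells <- expand_subject_params(spec, theta[i, ])
    ll <- ll + sum(log(mapply(function(rt, ch, cl2)
      defective_density(rt, ch, cells[[cl2]]), di$rt_s, di$choice,
      di$cell)))
    for (j in 1:5) {
      ll <- ll + dnorm(theta[i, j], mu[j], sg[j], log = TRUE) -
        pnorm(priors$lower[j], mu[j], sg[j], lower.tail = FALSE,
              log.p = TRUE)
    }
  }
  for (j in 1:5) {
    ll <- ll + dnorm(mu[j], priors$mean[j], priors$sd[j], log = TRUE) -
      pnorm(priors$lower[j], priors$mean[j], priors$sd[j],
            lower.tail = FALSE, log.p = TRUE) +
      dnorm(sg[j], 0, 1, log = TRUE) + log(2)
  }
  expect_equal(unname(got), unname(ll), tolerance = 1e-10)
  # outside the support
  expect_identical(log_posterior(theta, mu, c(-1, sg[-1]), d, spec,
                                 priors), -Inf)
  bad <- theta; bad[1, 2] <- -0.5
  expect_identical(log_posterior(bad, mu, sg, d, spec, priors), -Inf)
})

test_that("fits are reproducible under a fixed seed", {
  set.seed(602)
  cohort <- gen_dataset(generator_config(n_participants = 3), seed = 5)
  ctrl <- sampler_control(n_chains = 8, n_burn = 30, n_sample = 60,
                          thin = 3, n_inner = 1, seed = 9)
  f1 <- fit_lba(cohort$trials, model = "null", control = ctrl)
  f2 <- fit_lba(cohort$trials, model = "null", control = ctrl)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$sigma, f2$sigma)
})

test_that("posterior summaries pool chains correctly", {
  set.seed(603)
  cohort <- gen_dataset(generator_config(n_participants = 3), seed = 6)
  fit <- fit_lba(cohort$trials, model = "null",
                 control = sampler_control(n_chains = 8, n_burn = 50,
                                           n_sample = 100, thin = 2,
                                           n_inner = 1, seed = 10))
  ps <- posterior_summary(fit)
  expect_identical(nrow(ps$subjects), 3L)
  loc <- ps$population[ps$population$level == "location", ]
  # pooled mean equals the mean of per-chain means
  for (p in fit$spec$par_names) {
    expect_equal(loc$mean[loc$parameter == p],
                 mean(rowMeans(fit$mu[, , p])), tolerance = 1e-12)
  }
  # summaries are invariant to chain ordering
  perm <- sample(dim(fit$mu)[1])
  fit2 <- fit
  fit2$mu <- fit$mu[perm, , , drop = FALSE]
  fit2$sigma <- fit$sigma[perm, , , drop = FALSE]
  fit2$theta <- fit$theta[perm, , , , drop = FALSE]
  ps2 <- posterior_summary(fit2)
  expect_equal(ps$population$mean, ps2$population$mean)
  # coef and the cell table agree with the summaries
  expect_equal(unname(coef(fit)),
               loc$mean[match(fit$spec$par_names, loc$parameter)])
  tabn <- subject_cell_table(fit, "v_norm")
  expect_identical(dim(tabn), c(3L, 4L))
  expect_equal(unname(tabn[, 1]), unname(tabn[, 2]))  # null: shared drift
})

test_that("prior-only sampling reproduces the hyperprior", {
  # with no data the marginal posterior of each population location is its
  # truncated-normal prior, and of each scale its half-normal prior — a
  # standard sampler-correctness check
  set.seed(604)
  spec <- model_spec("null")
  priors <- default_priors(spec)
  empty <- list(rt = numeric(0), winner = integer(0), cell = integer(0))
  sdat <- list(s1 = empty, s2 = empty, s3 = empty)
  ctrl <- sampler_control(n_chains = 16, n_burn = 300, n_sample = 1500,
                          thin = 3, n_inner = 1)
  fit <- affectlba:::run_demcmc(sdat, spec, priors, ctrl, "truncated", 1)
  for (j in seq_len(spec$n_free)) {
    x <- as.vector(fit$mu[, , j])
    if (is.finite(priors$lower[j])) {
      a <- (priors$lower[j] - priors$mean[j]) / priors$sd[j]
      lam <- dnorm(a) / pnorm(a, lower.tail = FALSE)
      m_th <- priors$mean[j] + priors$sd[j] * lam
      v_th <- priors$sd[j]^2 * (1 + a * lam - lam^2)
    } else {
      m_th <- priors$mean[j]
      v_th <- priors$sd[j]^2
    }
    expect_lt(abs(mean(x) - m_th), 0.25 * sqrt(v_th))
    expect_lt(abs(sd(x) - sqrt(v_th)), 0.25 * sqrt(v_th))
    s <- as.vector(fit$sigma[, , j])
    expect_lt(abs(mean(s) - sqrt(2 / pi)), 0.2)
  }
})

test_that("posterior contraction: more trials shrink population SDs", {
  set.seed(605)
  ctrl <- sampler_control(n_chains = 12, n_burn = 150, n_sample = 300,
                          thin = 3, n_inner = 1, seed = 20)
  small <- gen_dataset(generator_config(n_participants = 4, blocks = 1,
                                        trials_per_block = 30), seed = 21)
  large <- gen_dataset(generator_config(n_participants = 4, blocks = 4,
                                        trials_per_block = 60), seed = 21)
  f_small <- fit_lba(small$trials, model = "null", control = ctrl)
  f_large <- fit_lba(large$trials, model = "null", control = ctrl)
  sd_of <- function(f) mean(apply(f$mu, 3, sd))
  expect_lt(sd_of(f_large), sd_of(f_small))
})
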