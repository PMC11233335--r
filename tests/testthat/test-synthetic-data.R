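# The synthetic-experiment generator.

test_that("the default configuration encodes the study design", {
  cfg <- generator_config()
  expect_equal(cfg$n_participants, 64)
  expect_equal(cfg$blocks, 4)
  expect_equal(cfg$trials_per_block, 60)
  expect_equal(unname(cfg$v_norm["unpleasant.difficult"]), 3.172)
  expect_equal(unname(cfg$v_norm["unpleasant.easy"]), 2.942)
  expect_equal(unname(cfg$v_ab["pleasant.easy"]), 0.742)
  expect_equal(unname(cfg$v_ab["unpleasant.easy"]), 0.017)
  expect_equal(unname(cfg$A), 2)
  expect_equal(cfg$t0, 0.3)
  expect_equal(cfg$pop_scale, 0.2)
})

test_that("per-block counterbalancing holds exactly", {
  cohort <- gen_dataset(generator_config(n_participants = 2), seed = 801)
  d <- cohort$trials
  for (id in unique(d$participant_id)) {
    for (b in 1:4) {
      blk <- d[d$participant_id == id & d$block == b, ]
      expect_identical(nrow(blk), 60L)
      expect_identical(as.integer(table(blk$pleasantness)[c("pleasant",
                                                            "unpleasant")]),
                       c(30L, 30L))
      expect_identical(as.integer(table(blk$cue)[c("color", "conjunction",
                                                   "shape")]),
                       c(20L, 20L, 20L))
      # each cue preceded equally often by each valence
      expect_true(all(table(blk$cue, blk$pleasantness) == 10L))
    }
  }
  # norms respect the stimulus ranges and never hit the neutral point
  neg <- d$picture_norm[d$pleasantness == "unpleasant"]
  pos <- d$picture_norm[d$pleasantness == "pleasant"]
  expect_true(all(neg >= 2 & neg <= 4))
  expect_true(all(pos >= 5.5 & pos <= 6.5))
})

test_that("zero population scale collapses all subjects onto the truth", {
  cohort <- gen_dataset(generator_config(n_participants = 3,
                                         pop_scale = 0), seed = 802)
  subj <- cohort$truth$subjects
  expect_true(all(apply(subj, 2, function(x) diff(range(x)) == 0)))
  expect_equal(unname(subj[1, "v_norm.unpleasant.difficult"]), 3.172)
})

test_that("paper-direction contrasts hold in generated data", {
  cohort <- gen_dataset(generator_config(n_participants = 12), seed = 803)
  d <- cohort$trials
  d$choice2 <- code_response(d$picture_norm, d$report)
  expect_identical(d$choice2, d$choice)   # report encoding is consistent
  ab <- tapply(d$choice == "aberrant", d$pleasantness, mean)
  expect_lt(ab[["unpleasant"]], ab[["pleasant"]])
  rt <- tapply(d$rt_s, d$pleasantness, mean)
  expect_lt(rt[["unpleasant"]], rt[["pleasant"]])
})

test_that("generated truth is sufficient to score recovery claims", {
  cfg <- generator_config(n_participants = 4)
  cohort <- gen_dataset(cfg, seed = 804)
  tr <- cohort$truth
  expect_identical(rownames(tr$subjects),
                   sort(unique(cohort$trials$participant_id)))
  expect_identical(colnames(tr$subjects), model_spec("core")$par_names)
  expect_equal(unname(tr$population["v_norm.pleasant.easy"]), 2.239)
  # determinism
  again <- gen_dataset(cfg, seed = 804)
  expect_identical(cohort$trials, again$trials)
  expect_identical(cohort$truth$subjects, again$truth$subjects)
})

test_that("contaminant injection is exact, seeded, and invertible bookkeeping", {
  res <- contaminated_cohort()
  inj <- res$injected
  pp <- preprocess(res$trials)
  st <- pp$report$steps
  expect_identical(sort(st[[1]]$detail), sort(inj$bad_participants))
  expect_identical(sort(st[[2]]$detail), sort(inj$bad_pictures))
  expect_identical(as.integer(st[[3]]$n_removed),
                   as.integer(inj$n_fast + inj$n_slow))
  expect_identical(as.integer(st[[4]]$n_removed),
                   as.integer(inj$n_extreme))
  # zero rates are the identity
  clean <- gen_dataset(generator_config(n_participants = 2), seed = 805)
  d <- clean$trials
  d$choice <- code_response(d$picture_norm, d$report)
  same <- inject_contaminants(d, seed = 1)
  expect_identical(same$trials, d)
  # seeded determinism
  r1 <- inject_contaminants(d, n_fast = 3, seed = 7)
  r2 <- inject_contaminants(d, n_fast = 3, seed = 7)
  expect_identical(r1$trials, r2$trials)
})

test_that("search-task emulation orders conditions and equates errors", {
  cohort <- gen_dataset(generator_config(n_participants = 10), seed = 806)
  d <- gen_search_data(cohort$trials, seed = 807)
  m <- tapply(d$search_rt_s, d$cue, mean)
  expect_gt(m[["conjunction"]], m[["shape"]])
  expect_gt(m[["shape"]], m[["color"]])
  expect_equal(as.numeric(m[c("color", "shape", "conjunction")]),
               c(1.131, 1.449, 1.832), tolerance = 0.05)
  pe <- tapply(!d$search_correct, d$cue, mean)
  expect_lt(max(abs(as.numeric(pe) - 0.137)), 0.04)
  # error rates statistically indistinguishable at generator defaults:
  # BANOVA-style check via a paired JZS test on per-participant errors
  agg <- aggregate(list(err = !d$search_correct),
                   by = list(id = d$participant_id, cue = d$cue), mean)
  wide <- reshape(agg, idvar = "id", timevar = "cue", direction = "wide")
  bf <- jzs_paired_bf(wide$err.conjunction - wide$err.color)
  expect_lt(bf$bf10, 1)
  # seeded determinism
  d2 <- gen_search_data(cohort$trials, seed = 807)
  expect_identical(d, d2)
})
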