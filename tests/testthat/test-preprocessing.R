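# The four-step exclusion pipeline.

test_that("participant filter removes strict majorities of aberrant responses", {
  d <- tiny_trials()
  out <- filter_participants(d)
  expect_identical(out$excluded, "p1")         # 6/10 aberrant
  expect_identical(unique(out$trials$participant_id), "p2")
  # exactly 50% is retained
  d2 <- d[d$participant_id == "p2", ]
  d2$choice <- rep(c("aberrant", "normative"), 5)
  expect_identical(filter_participants(d2)$excluded, character(0))
  # all-normative cohort: nothing happens
  d3 <- transform(d, choice = "normative")
  expect_identical(filter_participants(d3)$excluded, character(0))
})

test_that("picture filter removes normative rates strictly below half", {
  d <- data.frame(
    participant_id = rep(sprintf("s%d", 1:10), times = 2),
    picture_id = rep(c("bad", "fine"), each = 10),
    pleasantness = "pleasant", difficulty = "easy",
    choice = c(rep("normative", 4), rep("aberrant", 6),   # bad: 40%
               rep("normative", 5), rep("aberrant", 5)),  # fine: 50%
    rt_s = 1, stringsAsFactors = FALSE)
  out <- filter_pictures(d)
  expect_identical(out$excluded, "bad")
  expect_true(all(out$trials$picture_id == "fine"))
})

test_that("RT window bounds are inclusive as documented", {
  d <- data.frame(participant_id = "p", picture_id = sprintf("x%d", 1:5),
                  pleasantness = "pleasant", difficulty = "easy",
                  choice = "normative",
                  rt_s = c(6.1, 6.09, 0.2, 0.201, 1.5),
                  stringsAsFactors = FALSE)
  out <- filter_rt_window(d)
  expect_identical(out$excluded, 2L)
  expect_setequal(out$trials$rt_s, c(6.09, 0.201, 1.5))
})

test_that("z-score filter flags the planted outlier and only it", {
  set.seed(301)
  rt <- c(rnorm(100, 1.8, 0.3), 12)
  d <- data.frame(participant_id = "p", picture_id = sprintf("x%d", 1:101),
                  pleasantness = "unpleasant", difficulty = "difficult",
                  choice = "normative", rt_s = rt, stringsAsFactors = FALSE)
  out <- filter_zscore(d)
  expect_identical(out$excluded, 1L)
  expect_false(12 %in% out$trials$rt_s)
  # constant cell: SD 0 is a no-op; |z| exactly at the bound is retained
  dc <- transform(d, rt_s = 2)
  expect_identical(filter_zscore(dc)$excluded, 0L)
  # a cell with a single trial is skipped and logged
  d1 <- d[1, ]
  out1 <- filter_zscore(d1)
  expect_identical(out1$excluded, 0L)
  expect_length(out1$skipped_cells, 1L)
})

test_that("pipeline order is fixed and the report is arithmetically consistent", {
  res <- contaminated_cohort()
  pp <- preprocess(res$trials)
  rep <- pp$report
  # report percentages recompute exactly from counts
  for (s in rep$steps)
    expect_equal(s$pct_of_remaining,
                 if (s$n_before > 0) 100 * s$n_removed / s$n_before else 0)
  expect_equal(rep$n_in - sum(vapply(rep$steps, `[[`, numeric(1),
                                     "n_removed")), rep$n_out)
  # clean data pass untouched
  clean <- gen_dataset(generator_config(
    n_participants = 4,
    v_norm = c(unpleasant.easy = 4.5, unpleasant.difficult = 4.5,
               pleasant.easy = 4.5, pleasant.difficult = 4.5),
    v_ab = c(unpleasant.easy = -2, unpleasant.difficult = -2,
             pleasant.easy = -2, pleasant.difficult = -2),
    sv = 0.15, pop_scale = 0.1), seed = 77)$trials
  clean$choice <- code_response(clean$picture_norm, clean$report)
  pp2 <- preprocess(clean)
  expect_identical(pp2$report$n_in, pp2$report$n_out)
  # removing everything is a hard error
  allbad <- transform(clean, rt_s = 0.1)
  expect_error(suppressMessages(preprocess(allbad)), "every trial")
})

test_that("steps 1-3 are idempotent on their own output", {
  res <- contaminated_cohort()
  pp <- preprocess(res$trials)
  again <- preprocess(pp$trials)
  for (i in 1:3)
    expect_identical(as.integer(again$report$steps[[i]]$n_removed), 0L)
  # step 4 may cascade, but reaches a fixpoint in at most one extra pass
  third <- preprocess(again$trials)
  expect_identical(third$report$n_in, third$report$n_out)
})

test_that("filter order matters: participants are removed before pictures", {
  # picture pic1 falls below 50% normative only while the to-be-excluded
  # participant is still counted
  d <- data.frame(
    participant_id = rep(c("X", "Y", "Z"), each = 4),
    picture_id = rep(c("pic1", "pic2", "pic3", "pic4"), 3),
    pleasantness = "pleasant", difficulty = "easy",
    choice = c("aberrant", "aberrant", "aberrant", "normative",  # X: 75%
               "aberrant", "normative", "normative", "normative",
               "normative", "normative", "normative", "normative"),
    rt_s = 1, stringsAsFactors = FALSE)
  unordered <- filter_pictures(d)
  expect_identical(unordered$excluded, "pic1")
  ordered <- filter_pictures(filter_participants(d)$trials)
  expect_identical(ordered$excluded, character(0))
  pp <- preprocess(d)
  expect_identical(as.integer(pp$report$steps[[2]]$n_removed), 0L)
})
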