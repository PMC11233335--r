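trial_schema <- function() {
  list(required = c("participant_id", "block", "trial_index", "cue",
                    "picture_id", "picture_norm", "report", "rt_s"),
       cue = c("color", "shape", "conjunction"),
       report = c("pleasant", "unpleasant"),
       search_target = c("present", "absent"))
}

#' Read and validate a trial table
#'
#' Reads a long-format CSV with one row per emotion-report trial and
#' validates it against the package's schema: required columns
#' `participant_id`, `block`, `trial_index`, `cue`, `picture_id`,
#' `picture_norm`, `report`, `rt_s`; closed vocabularies for `cue` and
#' `report`; norms in `[1, 9]`; positive RTs. Extra columns (e.g., the
#' visual-search fields) are preserved. Row-level problems are collected
#' and reported together, with row numbers.
#'
#' @param path CSV file path.
#' @return The validated data frame, with derived columns `difficulty`,
#'   `pleasantness`, and `cell` attached.
#' @export
read_trials <- function(path) {
  sch <- trial_schema()
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(sch$required, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  probs <- character(0)
  bad_row <- function(rows, what) {
    if (length(rows))
      probs <<- c(probs, sprintf("rows %s: %s",
                                 paste(utils::head(rows, 5), collapse = ","),
                                 what))
  }
  bad_row(which(!d$cue %in% sch$cue), "cue not in color/shape/conjunction")
  bad_row(which(!d$report %in% sch$report),
          "report not in pleasant/unpleasant")
  bad_row(which(!is.finite(d$rt_s) | d$rt_s <= 0), "non-positive rt_s")
  bad_row(which(!is.finite(d$picture_norm) | d$picture_norm < 1 |
                  d$picture_norm > 9), "picture_norm outside [1, 9]")
  bad_row(which(d$picture_norm == 5), "picture_norm exactly 5")
  if (length(probs))
    stop("trial table validation failed:\n  ",
         paste(probs, collapse = "\n  "))
  d$difficulty <- cue_to_difficulty(d$cue)
  d$pleasantness <- ifelse(d$picture_norm < 5, "unpleasant", "pleasant")
  d$cell <- cell_label(d$pleasantness, d$difficulty)
  d
}

#' @rdname read_trials
#' @param trials a trial table.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

default_config <- function() {
  list(
    model = "core",
    convention = "truncated",
    profile = "desk",
    generator = list(n_participants = 12, blocks = 4,
                     trials_per_block = 60,
                     contaminants = list(n_bad_participants = 0,
                                         n_bad_pictures = 0, n_fast = 0,
                                         n_slow = 0, n_extreme = 0)),
    preprocess = list(rt_max = 6.1, rt_min = 0.2, z_max = 3.5),
    banova = list(rscale_fixed = 0.5, rscale_random = 1, nsim = 1e5,
                  t_test_r = sqrt(2) / 2),
    sampler = list())
}

#' Read a pipeline configuration from YAML
#'
#' Merges a YAML file over the package defaults (model, drift convention,
#' sampler profile, generator settings, preprocessing thresholds, BANOVA
#' prior scales).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}

#' Run one stage of the analysis pipeline
#'
#' Orchestrates the end-to-end analysis as six stages writing artifacts
#' into a shared directory, each with a JSON manifest recording the
#' configuration, seed and stage inputs so any result reproduces from its
#' manifest alone:
#'
#' * `simulate` — generate a synthetic experiment (`trials.csv`,
#'   `truth.json`);
#' * `preprocess` — code responses and run the four-step exclusion pipeline
#'   (`preprocessed.csv`, `preprocess_report.json`);
#' * `fit` — fit the null or core hierarchical LBA model
#'   (`fit_<model>.rds`, posterior summary CSV);
#' * `compare` — Gelman-Rubin gate and participant-summed DIC comparison of
#'   both fitted models (`comparison.json`/`.csv`);
#' * `banova` — BANOVAs on the normative and aberrant drift tables with
#'   follow-up paired t-tests per difficulty level and the percent-change
#'   summary (`banova.json`);
#' * `report` — assemble the summary of all upstream artifacts
#'   (`report.json`).
#'
#' @param command one of the stage names above.
#' @param config a configuration list from [read_config()] (or a YAML
#'   path).
#' @param out artifact directory shared by all stages.
#' @param seed integer seed recorded in every manifest; stage-specific
#'   streams are derived from it.
#' @return The stage's main artifact, invisibly (also written to disk).
#' @export
run_pipeline <- function(command = c("simulate", "preprocess", "fit",
                                     "compare", "banova", "report"),
                         config = NULL, out = "artifacts", seed = 1) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_config(config)
  if (is.null(config)) config <- default_config()
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  need <- function(f, stage) {
    p <- file.path(out, f)
    if (!file.exists(p))
      stop("missing upstream artifact '", f, "': run the '", stage,
           "' stage first")
    p
  }
  manifest <- function(stage, extra = list()) {
    jsonlite::write_json(
      c(list(stage = stage, seed = seed, config = config,
             timestamp = as.character(Sys.time())), extra),
      file.path(out, paste0("manifest_", stage, ".json")),
      auto_unbox = TRUE, pretty = TRUE, force = TRUE, digits = NA)
  }

  if (command == "simulate") {
    g <- config$generator
    gc <- generator_config(n_participants = g$n_participants,
                           blocks = g$blocks,
                           trials_per_block = g$trials_per_block,
                           convention = config$convention)
    cohort <- gen_dataset(gc, seed = seed)
    trials <- gen_search_data(cohort$trials)
    cm <- g$contaminants
    inj <- list()
    if (any(unlist(cm) > 0)) {
      res <- do.call(inject_contaminants, c(list(trials = trials), cm))
      trials <- res$trials
      inj <- res$injected
    }
    keep <- intersect(c(trial_schema()$required, "search_target",
                        "search_response", "search_correct",
                        "search_rt_s"), names(trials))
    write_trials(trials[, keep], file.path(out, "trials.csv"))
    tr <- cohort$truth
    jsonlite::write_json(
      list(population = as.list(tr$population), pop_scale = tr$pop_scale,
           sv = tr$sv, seed = seed,
           subjects = as.data.frame(cbind(
             participant_id = rownames(tr$subjects),
             as.data.frame(tr$subjects)))),
      file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
    manifest("simulate", list(injected = inj))
    return(invisible(trials))
  }

  if (command == "preprocess") {
    d <- read_trials(need("trials.csv", "simulate"))
    d$choice <- code_response(d$picture_norm, d$report)
    pp <- preprocess(d, rt_max = config$preprocess$rt_max,
                     rt_min = config$preprocess$rt_min,
                     z_max = config$preprocess$z_max)
    write_trials(pp$trials, file.path(out, "preprocessed.csv"))
    jsonlite::write_json(report_as_list(pp$report),
                         file.path(out, "preprocess_report.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest("preprocess")
    return(invisible(pp))
  }

  if (command == "fit") {
    d <- read_trials(need("preprocessed.csv", "preprocess"))
    d$choice <- code_response(d$picture_norm, d$report)
    sc <- config$sampler %||% list()
    ctrl <- do.call(sampler_control,
                    c(list(profile = config$profile, seed = seed), sc))
    fit <- fit_lba(d, model = config$model, control = ctrl,
                   convention = config$convention)
    saveRDS(fit, file.path(out, paste0("fit_", config$model, ".rds")))
    ps <- posterior_summary(fit)
    utils::write.csv(ps$population,
                     file.path(out, paste0("posterior_", config$model,
                                           ".csv")),
                     row.names = FALSE)
    manifest(paste0("fit_", config$model),
             list(model = config$model, sampler = unclass(ctrl)))
    return(invisible(fit))
  }

  if (command == "compare") {
    fn <- readRDS(need("fit_null.rds", "fit (model: null)"))
    fc <- readRDS(need("fit_core.rds", "fit (model: core)"))
    gr_n <- gelman_diag(fn)
    gr_c <- gelman_diag(fc)
    cmp <- compare_models(fn, fc)
    res <- list(max_rhat_null = gr_n$max_rhat,
                max_rhat_core = gr_c$max_rhat,
                rhat_acceptable = max(gr_n$max_rhat,
                                      gr_c$max_rhat) < 1.10,
                total_dic_null = cmp$total_null,
                total_dic_core = cmp$total_core,
                difference = cmp$difference,
                preferred = cmp$preferred, decisive = cmp$decisive)
    jsonlite::write_json(res, file.path(out, "comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(cmp$table, file.path(out, "comparison.csv"),
                     row.names = FALSE)
    manifest("compare")
    return(invisible(cmp))
  }

  if (command == "banova") {
    fc <- readRDS(need("fit_core.rds", "fit (model: core)"))
    bcfg <- config$banova
    res <- drift_banova(fc, rscale_fixed = bcfg$rscale_fixed,
                        rscale_random = bcfg$rscale_random,
                        nsim = bcfg$nsim, t_test_r = bcfg$t_test_r)
    jsonlite::write_json(banova_as_list(res),
                         file.path(out, "banova.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest("banova")
    return(invisible(res))
  }

  # report
  rd <- function(f) jsonlite::read_json(need(f, "upstream"),
                                        simplifyVector = TRUE)
  trials <- read_trials(need("trials.csv", "simulate"))
  rep_list <- list(
    manipulation_check = manipulation_check(trials),
    preprocessing = rd("preprocess_report.json"),
    model_comparison = rd("comparison.json"),
    banova = rd("banova.json"),
    seed = seed)
  jsonlite::write_json(rep_list, file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest("report")
  invisible(rep_list)
}

#' BANOVAs and follow-up tests on the fitted drift rates
#'
#' The inferential battery applied to a fitted core model: a 2x2
#' repeated-measures BANOVA on the per-subject posterior means of the
#' normative drift and of the aberrant drift, two-sided JZS paired t-tests
#' comparing difficult against easy within each pleasantness level for the
#' normative drift, and the percent change in the unpleasant normative
#' drift from easy to difficult anticipation.
#'
#' @param fit a core-model `lba_fit`.
#' @param rscale_fixed,rscale_random,nsim see [rm_banova_bf()].
#' @param t_test_r see [jzs_paired_bf()].
#' @return A list of class `drift_banova` with components `normative`,
#'   `aberrant` (each a `banova_result`), `t_tests`, `cell_means`, and
#'   `percent_change_unpleasant`.
#' @export
drift_banova <- function(fit, rscale_fixed = 0.5, rscale_random = 1,
                         nsim = 1e5, t_test_r = sqrt(2) / 2) {
  stopifnot(inherits(fit, "lba_fit"))
  if (fit$spec$name != "core")
    stop("drift BANOVAs require a core-model fit")
  tab_n <- subject_cell_table(fit, "v_norm")
  tab_a <- subject_cell_table(fit, "v_ab")
  cm <- colMeans(tab_n)
  tt <- list(
    unpleasant = jzs_paired_bf(tab_n[, "unpleasant.difficult"] -
                                 tab_n[, "unpleasant.easy"], r = t_test_r),
    pleasant = jzs_paired_bf(tab_n[, "pleasant.difficult"] -
                               tab_n[, "pleasant.easy"], r = t_test_r))
  structure(list(
    normative = rm_banova_bf(tab_n, rscale_fixed, rscale_random, nsim),
    aberrant = rm_banova_bf(tab_a, rscale_fixed, rscale_random, nsim),
    t_tests = tt,
    cell_means = list(normative = cm, aberrant = colMeans(tab_a)),
    percent_change_unpleasant = percent_change(
      cm[["unpleasant.difficult"]], cm[["unpleasant.easy"]])),
    class = "drift_banova")
}

banova_as_list <- function(x) {
  bfl <- function(b) list(bf10 = b$bf10, bf01 = b$bf01, error = b$error)
  list(
    normative = list(
      pleasantness = bfl(x$normative$bf_pleasantness),
      difficulty = bfl(x$normative$bf_difficulty),
      interaction = bfl(x$normative$bf_interaction)),
    aberrant = list(
      pleasantness = bfl(x$aberrant$bf_pleasantness),
      difficulty = bfl(x$aberrant$bf_difficulty),
      interaction = bfl(x$aberrant$bf_interaction)),
    t_tests = lapply(x$t_tests, bfl),
    cell_means = lapply(x$cell_means, as.list),
    percent_change_unpleasant = x$percent_change_unpleasant)
}

#' Manipulation-check summary of the visual-search data
#'
#' Mean search RT and error proportion per cue condition, with JZS paired
#' t-tests on the participant-level mean RTs for each pair of conditions.
#'
#' @param trials a trial table with search columns (see
#'   [gen_search_data()]).
#' @return A list with `means` (per-cue mean RT and error rate) and
#'   `rt_pairwise_bf10`.
#' @export
manipulation_check <- function(trials) {
  if (!"search_rt_s" %in% names(trials))
    return(list(note = "no search-task columns present"))
  agg <- stats::aggregate(
    cbind(rt = trials$search_rt_s, err = !trials$search_correct),
    by = list(participant_id = trials$participant_id, cue = trials$cue),
    FUN = mean)
  means <- stats::aggregate(cbind(rt = agg$rt, err = agg$err),
                            by = list(cue = agg$cue), FUN = mean)
  wide <- stats::reshape(agg[, c("participant_id", "cue", "rt")],
                         idvar = "participant_id", timevar = "cue",
                         direction = "wide")
  pair_bf <- function(a, b) {
    jzs_paired_bf(wide[[paste0("rt.", a)]] - wide[[paste0("rt.", b)]])$bf10
  }
  list(means = means,
       rt_pairwise_bf10 = c(
         conjunction_vs_color = pair_bf("conjunction", "color"),
         conjunction_vs_shape = pair_bf("conjunction", "shape"),
         shape_vs_color = pair_bf("shape", "color")))
}
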