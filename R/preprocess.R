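#' Four-step exclusion pipeline for emotion-report trials
#'
#' Applies, in fixed order, the four preregistered-style filters to a coded
#' trial table and returns the retained trials together with an audit
#' report:
#'
#' 1. drop participants whose aberrant-response proportion is strictly
#'    above 50%;
#' 2. drop pictures whose across-participant normative-response rate falls
#'    strictly below 50%;
#' 3. drop trials with reaction times at or above 6.1 s or at or below
#'    200 ms;
#' 4. within each participant x pleasantness x difficulty cell, drop trials
#'    whose RT z-score exceeds 3.5 in absolute value (strict).
#'
#' Step 4's grouping is by picture *valence* rather than individual picture:
#' each picture occurs once per participant, so a literal per-picture cell
#' would hold a single trial and the z-score would be undefined.
#' Percentages in the report are relative to the trial count remaining
#' before each step.
#'
#' @param trials a coded trial table: columns `participant_id`,
#'   `picture_id`, `pleasantness`, `difficulty`, `choice`
#'   (`"normative"`/`"aberrant"`), `rt_s`.
#' @param rt_max,rt_min RT window bounds in seconds (trials with
#'   `rt >= rt_max` or `rt <= rt_min` are excluded).
#' @param z_max absolute z-score bound for step 4.
#' @return A list with `trials` (the retained rows) and `report`, a
#'   `preprocess_report` object logging per-step exclusions.
#' @examples
#' d <- data.frame(participant_id = "s1", picture_id = paste0("p", 1:4),
#'                 pleasantness = "unpleasant", difficulty = "easy",
#'                 choice = "normative", rt_s = c(1, 1.2, 0.1, 7))
#' preprocess(d)$report
#' @export
preprocess <- function(trials, rt_max = 6.1, rt_min = 0.2, z_max = 3.5) {
  need <- c("participant_id", "picture_id", "pleasantness", "difficulty",
            "choice", "rt_s")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "))

  steps <- list()
  log_step <- function(label, n_before, n_removed, detail = NULL) {
    steps[[length(steps) + 1L]] <<- list(
      step = label, n_before = n_before, n_removed = n_removed,
      pct_of_remaining = if (n_before > 0) 100 * n_removed / n_before else 0,
      detail = detail)
  }

  s1 <- filter_participants(trials)
  log_step("participants_aberrant_gt_50pct", nrow(trials),
           nrow(trials) - nrow(s1$trials), s1$excluded)
  s2 <- filter_pictures(s1$trials)
  log_step("pictures_normative_lt_50pct", nrow(s1$trials),
           nrow(s1$trials) - nrow(s2$trials), s2$excluded)
  s3 <- filter_rt_window(s2$trials, rt_max = rt_max, rt_min = rt_min)
  log_step("rt_window", nrow(s2$trials), s3$excluded)
  s4 <- filter_zscore(s3$trials, z_max = z_max)
  log_step("rt_zscore", nrow(s3$trials), s4$excluded,
           detail = s4$skipped_cells)

  report <- structure(list(steps = steps, n_in = nrow(trials),
                           n_out = nrow(s4$trials)),
                      class = "preprocess_report")
  if (nrow(s4$trials) == 0L) {
    print(report)
    stop("preprocessing removed every trial")
  }
  list(trials = s4$trials, report = report)
}

#' @rdname preprocess
#' @export
filter_participants <- function(trials) {
  ab <- tapply(trials$choice == "aberrant", trials$participant_id, mean)
  out <- names(ab)[ab > 0.5]
  list(trials = trials[!(trials$participant_id %in% out), , drop = FALSE],
       excluded = out)
}

#' @rdname preprocess
#' @export
filter_pictures <- function(trials) {
  nr <- tapply(trials$choice == "normative", trials$picture_id, mean)
  out <- names(nr)[nr < 0.5]
  list(trials = trials[!(trials$picture_id %in% out), , drop = FALSE],
       excluded = out)
}

#' @rdname preprocess
#' @export
filter_rt_window <- function(trials, rt_max = 6.1, rt_min = 0.2) {
  drop <- trials$rt_s >= rt_max | trials$rt_s <= rt_min
  list(trials = trials[!drop, , drop = FALSE], excluded = sum(drop))
}

#' @rdname preprocess
#' @export
filter_zscore <- function(trials, z_max = 3.5) {
  key <- interaction(trials$participant_id, trials$pleasantness,
                     trials$difficulty, drop = TRUE)
  drop <- logical(nrow(trials))
  skipped <- character(0)
  for (k in levels(key)) {
    i <- which(key == k)
    if (length(i) < 2L) {
      skipped <- c(skipped, k)
      next
    }
    s <- stats::sd(trials$rt_s[i])
    if (!is.finite(s) || s == 0) next  # constant RTs: nothing is extreme
    z <- (trials$rt_s[i] - mean(trials$rt_s[i])) / s
    drop[i] <- abs(z) > z_max
  }
  list(trials = trials[!drop, , drop = FALSE], excluded = sum(drop),
       skipped_cells = skipped)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("Preprocessing: %d trials in, %d out\n", x$n_in, x$n_out))
  for (s in x$steps) {
    n_rm <- s$n_removed
    cat(sprintf("  %-32s removed %5d of %6d (%.2f%%)\n",
                s$step, n_rm, s$n_before, s$pct_of_remaining))
    if (s$step == "participants_aberrant_gt_50pct" && length(s$detail))
      cat("    participants: ", paste(s$detail, collapse = ", "), "\n")
    if (s$step == "pictures_normative_lt_50pct" && length(s$detail))
      cat("    pictures: ", paste(s$detail, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname preprocess
#' @param report a `preprocess_report`.
#' @export
report_as_list <- function(report) {
  list(n_in = report$n_in, n_out = report$n_out,
       steps = lapply(report$steps, function(s)
         list(step = s$step, n_before = s$n_before,
              n_removed = s$n_removed,
              pct_of_remaining = s$pct_of_remaining,
              detail = as.character(s$detail %||% character(0)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
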