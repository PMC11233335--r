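#' Configuration for the synthetic 2x2 experiment generator
#'
#' Defaults emulate the study design the analysis assumes: 64 analyzable
#' participants, 4 blocks of 60 trials, 240 normed pictures (half with
#' valence norms uniform in \[2, 4\], half in \[5.5, 6.5\]), search cues
#' balanced over colour/shape/conjunction, and per-block counterbalancing
#' (30 pleasant and 30 unpleasant pictures per block, 20 trials per cue,
#' each cue preceded equally often by each valence). Generating population
#' drift locations default to reported cell means of the reference
#' analysis: normative drifts 2.942 (unpleasant-easy), 3.172
#' (unpleasant-difficult), 2.239 (pleasant-easy), 2.148
#' (pleasant-difficult); aberrant drifts 0.017 for unpleasant and 0.742
#' for pleasant cells. `A = 2`, `B = 2`, `t0 = 0.3` (prior central values),
#' `sv = 1`, and a common between-subject scale of 0.2 complete the truth.
#'
#' @param n_participants number of participants to generate.
#' @param blocks,trials_per_block design size (trials_per_block must be
#'   divisible by 6: 2 valences x 3 cues).
#' @param v_norm,v_ab named numeric vectors of population mean drifts per
#'   design cell (names as in [design_cells()]).
#' @param A,B,t0,sv remaining population-location parameters (`B` may be a
#'   per-cell named vector).
#' @param pop_scale common between-subject SD of all parameters (truncated
#'   below at each parameter's support bound).
#' @param norm_range_neg,norm_range_pos valence-norm ranges of the
#'   unpleasant and pleasant picture pools.
#' @param window response window in seconds (censoring bound).
#' @param convention drift convention used for simulation.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_participants = 64,
    blocks = 4, trials_per_block = 60,
    v_norm = c(unpleasant.easy = 2.942, unpleasant.difficult = 3.172,
               pleasant.easy = 2.239, pleasant.difficult = 2.148),
    v_ab = c(unpleasant.easy = 0.017, unpleasant.difficult = 0.017,
             pleasant.easy = 0.742, pleasant.difficult = 0.742),
    A = 2, B = 2, t0 = 0.3, sv = 1, pop_scale = 0.2,
    norm_range_neg = c(2, 4), norm_range_pos = c(5.5, 6.5),
    window = 8, convention = "truncated") {
  cells <- design_cells()$cell
  stopifnot(trials_per_block %% 6 == 0, blocks >= 1, n_participants >= 1,
            setequal(names(v_norm), cells), setequal(names(v_ab), cells))
  B <- if (length(B) == 1L) stats::setNames(rep(B, 4), cells)
       else B[cells]
  structure(list(n_participants = n_participants, blocks = blocks,
                 trials_per_block = trials_per_block,
                 v_norm = v_norm[cells], v_ab = v_ab[cells],
                 A = A, B = B, t0 = t0, sv = sv, pop_scale = pop_scale,
                 norm_range_neg = norm_range_neg,
                 norm_range_pos = norm_range_pos,
                 window = window, convention = conv_arg(convention)),
            class = "generator_config")
}

#' Generate a full synthetic experiment
#'
#' Draws per-subject LBA parameters from truncated-Normal population
#' distributions around the configured generating locations, builds a
#' counterbalanced trial structure (every block: equal valence split, equal
#' cue split, cues crossed evenly with valence), and simulates every
#' emotion report through the two-accumulator race. The generating truth
#' (population and per-subject parameters) is returned alongside the data
#' so any recovery claim can be scored without re-simulation.
#'
#' @param config a [generator_config()].
#' @param seed integer seed (all randomness is drawn under it).
#' @return A list with `trials` (the trial table: `participant_id`,
#'   `block`, `trial_index`, `cue`, `picture_id`, `picture_norm`, `report`,
#'   `rt_s`, plus design/bookkeeping columns) and `truth` (a
#'   `generating_truth` list: population locations, scale, per-subject
#'   parameter matrix, config echo, seed).
#' @examples
#' cohort <- gen_dataset(generator_config(n_participants = 2), seed = 1)
#' head(cohort$trials)
#' @export
gen_dataset <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  cells <- design_cells()
  spec <- model_spec("core")

  # picture pool: one picture per trial slot, fixed across participants
  n_pic <- config$blocks * config$trials_per_block
  half <- n_pic / 2
  pictures <- data.frame(
    picture_id = sprintf("pic%03d", seq_len(n_pic)),
    valence = rep(c("unpleasant", "pleasant"), each = half),
    stringsAsFactors = FALSE)
  pictures$norm <- ifelse(
    pictures$valence == "unpleasant",
    stats::runif(n_pic, config$norm_range_neg[1], config$norm_range_neg[2]),
    stats::runif(n_pic, config$norm_range_pos[1], config$norm_range_pos[2]))
  # assign pictures to blocks, half of each valence per block
  per_block <- config$trials_per_block / 2
  pictures$block <- NA_integer_
  for (v in c("unpleasant", "pleasant")) {
    i <- sample(which(pictures$valence == v))
    pictures$block[i] <- rep(seq_len(config$blocks), each = per_block)
  }

  # per-subject parameters from the truncated-Normal population
  par_names <- spec$par_names
  mu <- c(A = unname(config$A), t0 = unname(config$t0),
          stats::setNames(config$B, paste0("B.", cells$cell)),
          stats::setNames(config$v_norm, paste0("v_norm.", cells$cell)),
          stats::setNames(config$v_ab, paste0("v_ab.", cells$cell)))[par_names]
  S <- config$n_participants
  subj_par <- matrix(NA_real_, S, spec$n_free,
                     dimnames = list(sprintf("s%02d", seq_len(S)),
                                     par_names))
  for (j in seq_len(spec$n_free)) {
    subj_par[, j] <- if (config$pop_scale == 0) rep(mu[j], S)
      else rtnorm_lower(S, mu[j], config$pop_scale, spec$lower[j])
  }

  rows <- vector("list", S)
  for (s in seq_len(S)) {
    id <- rownames(subj_par)[s]
    cellp <- expand_subject_params(spec, subj_par[s, ], sv = config$sv)
    btabs <- vector("list", config$blocks)
    for (b in seq_len(config$blocks)) {
      pb <- pictures[pictures$block == b, ]
      # within each valence, cues split evenly: crossing is balanced
      cue <- unlist(lapply(c("unpleasant", "pleasant"), function(v) {
        sample(rep(c("color", "shape", "conjunction"), length.out = per_block))
      }))
      pb <- pb[order(pb$valence == "pleasant"), ]
      pb$cue <- cue
      pb <- pb[sample(nrow(pb)), ]  # presentation order
      pb$trial_index <- seq_len(nrow(pb)) - 1L
      btabs[[b]] <- pb
    }
    tab <- do.call(rbind, Map(function(x, b) {x$block <- b; x},
                              btabs, seq_len(config$blocks)))
    tab$difficulty <- cue_to_difficulty(tab$cue)
    tab$cell <- cell_label(tab$valence, tab$difficulty)
    # simulate each cell's trials in one race call
    tab$choice <- NA_character_
    tab$rt_s <- NA_real_
    tab$censored <- NA
    for (cl in cells$cell) {
      i <- which(tab$cell == cl)
      if (!length(i)) next
      tr <- simulate_trials(cellp[[cl]], length(i),
                            convention = config$convention,
                            window = config$window)
      tab$choice[i] <- tr$choice
      tab$rt_s[i] <- tr$rt_s
      tab$censored[i] <- tr$censored
    }
    tab$report <- decode_response(tab$norm, tab$choice)
    tab$participant_id <- id
    rows[[s]] <- tab
  }
  trials <- do.call(rbind, rows)
  trials <- trials[, c("participant_id", "block", "trial_index", "cue",
                       "picture_id", "picture_norm" = "norm", "report",
                       "rt_s", "valence", "difficulty", "cell", "choice",
                       "censored")]
  names(trials)[names(trials) == "norm"] <- "picture_norm"
  names(trials)[names(trials) == "valence"] <- "pleasantness"
  rownames(trials) <- NULL

  truth <- structure(list(population = mu, pop_scale = config$pop_scale,
                          subjects = subj_par, sv = config$sv,
                          config = config, seed = seed),
                     class = "generating_truth")
  list(trials = trials, truth = truth)
}

#' Inject preprocessing contaminants into a clean trial table
#'
#' Adds, with exact bookkeeping, the four artefact types the exclusion
#' pipeline targets: whole participants responding aberrantly on more than
#' half their trials, pictures answered counter-normatively by most
#' participants, fast guesses (RT below 200 ms), slow outliers (RT at or
#' above 6.1 s), and within-cell extreme RTs (z beyond 3.5). Contaminated
#' trials are chosen so the categories do not overlap; the returned
#' bookkeeping matches the exclusion counts [preprocess()] reports on the
#' contaminated table, provided the clean table itself triggers no filter.
#'
#' @param trials a clean coded trial table (needs `choice`; see
#'   [preprocess()] for required columns).
#' @param n_bad_participants extra aberrant-majority participants to
#'   append (cloned from existing participants, responses flipped).
#' @param n_bad_pictures pictures whose responses are flipped to
#'   majority-aberrant across retained participants.
#' @param n_fast,n_slow,n_extreme trial counts per RT artefact type.
#' @param seed integer seed.
#' @return A list with `trials` (contaminated table) and `injected`
#'   (bookkeeping: IDs and counts per category).
#' @export
inject_contaminants <- function(trials, n_bad_participants = 0,
                                n_bad_pictures = 0, n_fast = 0,
                                n_slow = 0, n_extreme = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- trials
  injected <- list()

  if (n_bad_participants > 0) {
    src <- sample(unique(trials$participant_id), n_bad_participants,
                  replace = n_bad_participants >
                    length(unique(trials$participant_id)))
    bad <- lapply(seq_along(src), function(k) {
      b <- trials[trials$participant_id == src[k], ]
      b$participant_id <- sprintf("bad%02d", k)
      # flip 80% of responses to aberrant: safely above the 50% bound
      i <- sample(nrow(b), ceiling(0.8 * nrow(b)))
      b$choice[i] <- "aberrant"
      b$report[i] <- decode_response(b$picture_norm[i], "aberrant")
      b
    })
    out <- rbind(out, do.call(rbind, bad))
    injected$bad_participants <- sprintf("bad%02d",
                                         seq_len(n_bad_participants))
  }

  good <- !(out$participant_id %in% (injected$bad_participants %||%
                                       character(0)))
  if (n_bad_pictures > 0) {
    pics <- sample(unique(out$picture_id), n_bad_pictures)
    # flip 75% of the retained participants' responses on these pictures
    for (p in pics) {
      i <- which(out$picture_id == p & good)
      flip <- sample(i, ceiling(0.75 * length(i)))
      out$choice[flip] <- "aberrant"
      out$report[flip] <- decode_response(out$picture_norm[flip],
                                          "aberrant")
    }
    injected$bad_pictures <- pics
  }

  # RT artefacts only on rows surviving steps 1-2
  avail <- which(good &
                   !(out$picture_id %in% (injected$bad_pictures %||%
                                            character(0))))
  n_rt <- n_fast + n_slow + n_extreme
  if (n_rt > 0) {
    pick <- sample(avail, n_rt)
    fast <- pick[seq_len(n_fast)]
    slow <- pick[n_fast + seq_len(n_slow)]
    extr <- pick[n_fast + n_slow + seq_len(n_extreme)]
    out$rt_s[fast] <- stats::runif(n_fast, 0.05, 0.2)
    out$rt_s[slow] <- stats::runif(n_slow, 6.1, 7.9)
    if (n_extreme > 0) {
      # large within-cell z but inside the RT window
      key <- interaction(out$participant_id, out$pleasantness,
                         out$difficulty, drop = TRUE)
      for (i in extr) {
        j <- setdiff(which(key == key[i]), c(fast, slow, extr))
        out$rt_s[i] <- min(6.05, mean(out$rt_s[j]) +
                             25 * max(stats::sd(out$rt_s[j]), 0.05))
      }
    }
    injected$n_fast <- n_fast
    injected$n_slow <- n_slow
    injected$n_extreme <- n_extreme
  }
  list(trials = out, injected = injected)
}

#' Simulate the visual-search manipulation-check data
#'
#' Adds search-task columns to a trial table: lognormal reaction times with
#' condition means of 1131 ms (colour), 1449 ms (shape) and 1832 ms
#' (conjunction) and SD of 0.35 times the mean, and error indicators with
#' rates 0.137, 0.135 and 0.139. Only the condition means and error rates
#' are emulated; the distributional shape is a modelling convention.
#'
#' @param trials a trial table with a `cue` column.
#' @param mean_rt_s named mean search RTs in seconds per cue.
#' @param error_rate named error rates per cue.
#' @param cv lognormal coefficient of variation (SD / mean).
#' @param seed integer seed.
#' @return The table with `search_target`, `search_response`,
#'   `search_correct`, `search_rt_s` columns appended.
#' @export
gen_search_data <- function(trials,
                            mean_rt_s = c(color = 1.131, shape = 1.449,
                                          conjunction = 1.832),
                            error_rate = c(color = 0.137, shape = 0.135,
                                           conjunction = 0.139),
                            cv = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot("cue" %in% names(trials))
  n <- nrow(trials)
  m <- mean_rt_s[trials$cue]
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(m) - sdlog^2 / 2
  trials$search_target <- sample(c("present", "absent"), n, replace = TRUE)
  err <- stats::runif(n) < error_rate[trials$cue]
  trials$search_correct <- !err
  trials$search_response <- ifelse(xor(trials$search_target == "present",
                                       err), "present", "absent")
  trials$search_rt_s <- stats::rlnorm(n, meanlog, sdlog)
  trials
}
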