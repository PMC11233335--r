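#' Linear ballistic accumulator parameters
#'
#' Bundle the parameters of a single LBA accumulator. Evidence starts at a
#' point drawn uniformly from `[0, A]`, grows linearly at a drift rate drawn
#' once per trial from `N(mean_v, sv)`, and triggers a response on reaching
#' the boundary `b = A + B`. `B` is the boundary's gap above the top of the
#' start-point range, so `b > A` holds structurally.
#'
#' @param A start-point range upper bound (evidence units, `>= 0`).
#' @param B boundary offset above `A` (evidence units, `> 0`).
#' @param t0 non-decision time in seconds (`>= 0`).
#' @param mean_v mean drift rate (evidence units per second).
#' @param sv across-trial drift standard deviation (`> 0`). Fixed at 1 by
#'   default: it is the scaling parameter of the model and is not estimated.
#' @return An object of class `accumulator_params` with the derived
#'   boundary `b = A + B`.
#' @examples
#' accumulator_params(A = 2, B = 2, t0 = 0.3, mean_v = 2.9)
#' @export
accumulator_params <- function(A, B, t0 = 0, mean_v = 1, sv = 1) {
  check_acc(A, B, t0, sv)
  structure(list(A = A, B = B, b = A + B, t0 = t0, mean_v = mean_v,
                 sv = sv),
            class = "accumulator_params")
}

check_acc <- function(A, B, t0, sv) {
  if (!is.finite(A) || A < 0) stop("'A' must be finite and >= 0")
  if (!is.finite(B) || B <= 0) stop("'B' must be finite and > 0")
  if (!is.finite(t0) || t0 < 0) stop("'t0' must be finite and >= 0")
  if (!is.finite(sv) || sv <= 0) stop("'sv' must be finite and > 0")
  invisible(TRUE)
}

#' Paired accumulators for one design cell
#'
#' The two-choice race has a *normative* accumulator (the response agreeing
#' with the picture's valence norm) and an *aberrant* accumulator (the
#' counter-normative response). Start-point range `A`, non-decision time
#' `t0` and drift dispersion `sv` are shared between the two; boundary and
#' mean drift may differ.
#'
#' @param mean_v_normative,mean_v_aberrant mean drift rates of the two
#'   accumulators.
#' @param A,B,t0,sv shared LBA parameters (see [accumulator_params()]);
#'   `B` may be a length-2 vector `c(normative, aberrant)`.
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(A, B, t0, mean_v_normative, mean_v_aberrant,
                        sv = 1) {
  B <- rep_len(B, 2L)
  norm <- accumulator_params(A, B[1], t0, mean_v_normative, sv)
  aber <- accumulator_params(A, B[2], t0, mean_v_aberrant, sv)
  structure(list(normative = norm, aberrant = aber),
            class = "cell_params")
}

conv_arg <- function(convention) {
  match.arg(convention, c("truncated", "defective"))
}

#' Finishing-time distribution of one accumulator
#'
#' Closed-form CDF and density of the decision time (time from accumulation
#' onset to boundary crossing, excluding `t0`) of a single LBA accumulator.
#'
#' Under the `defective` convention negative sampled drifts never finish, so
#' `lba_cdf` tends to `P(drift > 0)` as `t` grows. Under the `truncated`
#' convention (the default) each accumulator's drift is conditioned on being
#' positive — densities are renormalised by `pnorm(mean_v / sv)` — so every
#' trial terminates, matching a task in which a response always occurred
#' within the response window.
#'
#' @param t decision time(s) in seconds, `>= 0`.
#' @param acc an [accumulator_params()] object.
#' @param convention `"truncated"` or `"defective"` drift-sign handling.
#' @return `lba_cdf`: probabilities in `[0, 1]`; `lba_pdf`: densities.
#' @examples
#' acc <- accumulator_params(A = 1, B = 1, t0 = 0.3, mean_v = 2)
#' lba_cdf(c(0.5, 1, 2), acc)
#' @export
lba_cdf <- function(t, acc, convention = "truncated") {
  stopifnot(inherits(acc, "accumulator_params"), all(t >= 0))
  .lba_cdf_cpp(as.numeric(t), acc$A, acc$b, acc$mean_v, acc$sv,
               conv_arg(convention) == "truncated")
}

#' @rdname lba_cdf
#' @export
lba_pdf <- function(t, acc, convention = "truncated") {
  stopifnot(inherits(acc, "accumulator_params"), all(t >= 0))
  .lba_pdf_cpp(as.numeric(t), acc$A, acc$b, acc$mean_v, acc$sv,
               conv_arg(convention) == "truncated")
}

#' Defective density of (choice, RT) for the two-accumulator race
#'
#' Joint density of observing the given response at the given reaction time:
#' the winning accumulator's finishing density at `rt - t0` times the
#' probability that the rival has not yet finished. Integrated over time it
#' yields the choice probability, not 1 — hence "defective". Returns 0 for
#' `rt <= t0`.
#'
#' @param rt reaction time(s) in seconds (including non-decision time).
#' @param choice `"normative"` or `"aberrant"` (vectorised with `rt`).
#' @param cell a [cell_params()] object.
#' @inheritParams lba_cdf
#' @return Densities, one per trial.
#' @export
defective_density <- function(rt, choice, cell, convention = "truncated") {
  stopifnot(inherits(cell, "cell_params"))
  choice <- match.arg(as.character(choice), c("normative", "aberrant"),
                      several.ok = TRUE)
  choice <- rep_len(choice, length(rt))
  par <- cell_par_matrix(list(cell))
  .race_density_cpp(as.numeric(rt),
                    as.integer(choice == "aberrant"),
                    integer(length(rt)), par,
                    conv_arg(convention) == "truncated")
}

# 4 x 6 parameter matrix (A, B, t0, sv, v_norm, v_ab per row) from a list
# of cell_params, one row per design cell.
cell_par_matrix <- function(cells) {
  m <- t(vapply(cells, function(cl) {
    c(cl$normative$A, cl$normative$B, cl$normative$t0, cl$normative$sv,
      cl$normative$mean_v, cl$aberrant$mean_v)
  }, numeric(6)))
  if (!all(vapply(cells, function(cl)
    isTRUE(all.equal(cl$normative$B, cl$aberrant$B)), logical(1))))
    stop("per-accumulator boundaries are not supported by the matrix form")
  m
}

#' Log-likelihood of a coded trial table
#'
#' Sums the log defective densities of all trials under per-cell LBA
#' parameters. Trials whose density underflows contribute a floor of
#' `-700` per trial rather than `-Inf`, so the sampler can still compare
#' states.
#'
#' @param trials a data frame with columns `rt_s` (seconds), `choice`
#'   (`"normative"`/`"aberrant"`), and `cell` (a label present in
#'   `names(params)`).
#' @param params a named list of [cell_params()], one per design cell.
#' @inheritParams lba_cdf
#' @return The log-likelihood (scalar; 0 for an empty table).
#' @export
dataset_loglik <- function(trials, params, convention = "truncated") {
  if (nrow(trials) == 0L) return(0)
  idx <- match(as.character(trials$cell), names(params))
  if (anyNA(idx))
    stop("trial cell label(s) not present in 'params': ",
         paste(unique(trials$cell[is.na(idx)]), collapse = ", "))
  par <- cell_par_matrix(params)
  .race_loglik_cpp(as.numeric(trials$rt_s),
                   as.integer(trials$choice == "aberrant"),
                   as.integer(idx) - 1L, par,
                   conv_arg(convention) == "truncated")
}

#' Simulate trials from the two-accumulator race
#'
#' Draws start points uniformly from `[0, A]` and drifts from the normal
#' distribution under the chosen convention, races the two accumulators,
#' and returns choices and reaction times. Trials in which no accumulator
#' finishes within the response window are flagged censored (their `rt` is
#' the window), not dropped.
#'
#' @param cell a [cell_params()] object.
#' @param n number of trials.
#' @param window response window in seconds (on-screen duration); finishing
#'   times beyond it are censored.
#' @inheritParams lba_cdf
#' @return A data frame with columns `choice`, `rt_s`, `censored`.
#' @examples
#' cl <- cell_params(A = 2, B = 2, t0 = 0.3,
#'                   mean_v_normative = 3, mean_v_aberrant = 0.5)
#' set.seed(1)
#' head(simulate_trials(cl, 5))
#' @export
simulate_trials <- function(cell, n, convention = "truncated",
                            window = 8) {
  stopifnot(inherits(cell, "cell_params"), n >= 1)
  truncated <- conv_arg(convention) == "truncated"
  times <- vapply(list(cell$normative, cell$aberrant), function(acc) {
    start <- stats::runif(n, 0, acc$A)
    v <- if (truncated) rtnorm_pos(n, acc$mean_v, acc$sv)
         else stats::rnorm(n, acc$mean_v, acc$sv)
    ft <- (acc$b - start) / v
    ft[v <= 0] <- Inf
    ft
  }, numeric(n))
  win <- max.col(-times)  # 1 = normative, 2 = aberrant
  tmin <- times[cbind(seq_len(n), win)]
  t0 <- cell$normative$t0
  rt <- t0 + tmin
  censored <- !is.finite(tmin) | rt > window
  rt[censored] <- window
  data.frame(choice = c("normative", "aberrant")[win],
             rt_s = rt, censored = censored,
             stringsAsFactors = FALSE)
}

# normal truncated to (0, Inf) by inverse-CDF; numerically safe for
# mean_v several sd below zero.
rtnorm_pos <- function(n, mean, sd, lower = 0) {
  plo <- stats::pnorm(lower, mean, sd)
  u <- plo + stats::runif(n) * (1 - plo)
  q <- stats::qnorm(pmin(u, 1 - 1e-16), mean, sd)
  pmax(q, lower + 1e-12)
}
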