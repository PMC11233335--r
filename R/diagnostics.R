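#' Gelman-Rubin potential scale reduction factor
#'
#' Classic two-part PSRF from between- and within-chain variances, with the
#' Brooks-Gelman sampling-variability correction: for `m` chains of `n`
#' draws, `R = sqrt(((n-1)/n) + (1 + 1/m) * B/(n*W))` where `B/n` is the
#' variance of chain means and `W` the mean within-chain variance. Values
#' near 1 indicate convergence; below 1.10 is the conventional
#' acceptability bound. Chains with zero within-chain variance everywhere
#' yield `NaN` with a warning. Split-chain R-hat is available behind
#' `split = TRUE`.
#'
#' @param chains a draws matrix, one row per chain, or an `lba_fit`.
#' @param split halve each chain before computing (detects within-chain
#'   drift).
#' @param ... unused.
#' @return For a matrix: the scalar R-hat. For a fit: a list with `rhat`
#'   (population parameters), `rhat_subject` (subjects x parameters
#'   matrix), `max_rhat`, and `max_rhat_subject` (per participant).
#' @examples
#' set.seed(1)
#' gelman_rubin(matrix(rnorm(8 * 500), 8))  # iid draws: close to 1
#' @export
gelman_rubin <- function(chains, split = FALSE, ...) {
  UseMethod("gelman_rubin")
}

#' @rdname gelman_rubin
#' @export
gelman_rubin.default <- function(chains, split = FALSE, ...) {
  x <- as.matrix(chains)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need at least 2 chains with at least 2 draws each")
  if (split) {
    h <- ncol(x) %/% 2L
    x <- rbind(x[, seq_len(h), drop = FALSE],
               x[, h + seq_len(h), drop = FALSE])
  }
  m <- nrow(x); n <- ncol(x)
  W <- mean(apply(x, 1, stats::var))
  B_over_n <- stats::var(rowMeans(x))
  if (!is.finite(W) || W == 0) {
    warning("zero within-chain variance; R-hat undefined")
    return(NaN)
  }
  sqrt((n - 1) / n + (1 + 1 / m) * B_over_n / W)
}

#' @rdname gelman_rubin
#' @export
gelman_rubin.lba_fit <- function(chains, split = FALSE, ...) {
  fit <- chains
  pop <- c(
    apply(fit$mu, 3, function(a) gr_quiet(a, split)),
    stats::setNames(apply(fit$sigma, 3, function(a) gr_quiet(a, split)),
                    paste0("sigma.", dimnames(fit$sigma)[[3]])))
  subjects <- dimnames(fit$theta)[[3]]
  pars <- dimnames(fit$theta)[[4]]
  rs <- matrix(NA_real_, length(subjects), length(pars),
               dimnames = list(subjects, pars))
  for (s in subjects) for (p in pars)
    rs[s, p] <- gr_quiet(fit$theta[, , s, p], split)
  list(rhat = pop, rhat_subject = rs,
       max_rhat = max(c(pop, rs), na.rm = TRUE),
       max_rhat_subject = apply(rs, 1, max, na.rm = TRUE))
}

gr_quiet <- function(a, split) {
  suppressWarnings(gelman_rubin.default(a, split = split))
}

#' @rdname gelman_rubin
#' @export
gelman_diag <- function(chains, split = FALSE, ...) {
  gelman_rubin(chains, split = split, ...)
}

#' Participant-level deviance information criterion
#'
#' For one participant, `DIC = Dbar + pD` with `Dbar` the posterior mean of
#' the deviance `-2 * log-likelihood` of that participant's trials under
#' their own subject-level parameter draws, and
#' `pD = Dbar - D(posterior mean)`. Population-level terms are excluded:
#' the score describes how well the subject-level model accounts for that
#' participant's data. `dic(fit)` returns the per-participant table and the
#' participant-summed total.
#'
#' @param fit an `lba_fit`.
#' @param participant a participant ID present in the fit; `NULL` for all.
#' @return For one participant, a list with `dic`, `mean_deviance`, `pD`.
#'   For all, a list with `table` (data frame per participant) and
#'   `total` (summed DIC).
#' @export
dic <- function(fit, participant = NULL) {
  stopifnot(inherits(fit, "lba_fit"))
  if (!is.null(participant)) return(dic_participant(fit, participant))
  tab <- do.call(rbind, lapply(fit$subjects, function(id) {
    d <- dic_participant(fit, id)
    data.frame(participant_id = id, dic = d$dic,
               mean_deviance = d$mean_deviance, pD = d$pD,
               stringsAsFactors = FALSE)
  }))
  list(table = tab, total = sum(tab$dic))
}

#' @rdname dic
#' @export
dic_participant <- function(fit, participant) {
  stopifnot(inherits(fit, "lba_fit"))
  id <- as.character(participant)
  if (!id %in% fit$subjects) stop("unknown participant: ", id)
  di <- fit$data[fit$data$participant_id == id, ]
  rt <- as.numeric(di$rt_s)
  winner <- as.integer(di$choice == "aberrant")
  cell <- match(di$cell, fit$spec$cells) - 1L
  truncated <- fit$convention == "truncated"
  dm <- dim(fit$theta)
  draws <- matrix(fit$theta[, , id, ], dm[1] * dm[2], dm[4])
  ll <- .race_loglik_rows_cpp(
    expand_theta_rows(fit$spec, draws, sv = fit$sv),
    rt, winner, cell, truncated)
  dbar <- mean(-2 * ll)
  ll_at_mean <- .race_loglik_rows_cpp(
    expand_theta_rows(fit$spec, matrix(colMeans(draws), 1), sv = fit$sv),
    rt, winner, cell, truncated)
  d_hat <- -2 * ll_at_mean
  if (!is.finite(d_hat))
    stop("non-finite deviance at the posterior mean for ", id)
  list(dic = 2 * dbar - d_hat, mean_deviance = dbar, pD = dbar - d_hat)
}

#' Compare two fitted models by participant-summed DIC
#'
#' Computes per-participant DIC under both fits (which must be fits of the
#' same preprocessed data), sums across participants, and prefers the model
#' with the lower total. A difference of at least 6 points is conventionally
#' taken as a real difference; the verdict reports whether the winning
#' margin clears it.
#'
#' @param fit_null,fit_core two `lba_fit` objects on identical data (by
#'   convention the null and core models, but any pair works).
#' @param threshold the decisive-difference convention (points).
#' @return An object of class `lba_comparison`: per-participant table,
#'   summed DICs, difference (null minus core; positive favours core),
#'   preferred model, and whether the margin is decisive.
#' @export
compare_models <- function(fit_null, fit_core, threshold = 6) {
  stopifnot(inherits(fit_null, "lba_fit"), inherits(fit_core, "lba_fit"))
  if (!identical(sort(fit_null$subjects), sort(fit_core$subjects)))
    stop("fits cover different participants")
  key <- function(f) {
    d <- f$data[order(f$data$participant_id, f$data$rt_s), ]
    list(d$participant_id, round(d$rt_s, 12), d$choice, d$cell)
  }
  if (!identical(key(fit_null), key(fit_core)))
    stop("fits were not computed on identical data")
  dn <- dic(fit_null)
  dc <- dic(fit_core)
  tab <- merge(dn$table[, c("participant_id", "dic")],
               dc$table[, c("participant_id", "dic")],
               by = "participant_id", suffixes = c("_null", "_core"))
  diff <- dn$total - dc$total
  preferred <- if (dc$total < dn$total) fit_core$spec$name
               else fit_null$spec$name
  structure(list(table = tab, total_null = dn$total, total_core = dc$total,
                 difference = diff, preferred = preferred,
                 decisive = abs(diff) >= threshold, threshold = threshold),
            class = "lba_comparison")
}

#' @export
print.lba_comparison <- function(x, ...) {
  cat(sprintf("Summed DIC: null %.2f, core %.2f (difference %.2f)\n",
              x$total_null, x$total_core, x$difference))
  cat(sprintf("Preferred model: %s (%sdecisive at the %g-point convention)\n",
              x$preferred, if (x$decisive) "" else "not ", x$threshold))
  invisible(x)
}
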