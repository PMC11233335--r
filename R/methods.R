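#' @export
print.lba_fit <- function(x, ...) {
  dm <- dim(x$theta)
  cat(sprintf("Hierarchical LBA fit ('%s' model, %s drifts)\n",
              x$spec$name, x$convention))
  cat(sprintf("  %d subjects, %d trials, %d free parameters per subject\n",
              dm[3], nrow(x$data), dm[4]))
  cat(sprintf("  %d chains x %d stored draws (burn-in %d, thin %d)\n",
              dm[1], dm[2], x$control$n_burn, x$control$thin))
  cat("Population-location posterior means:\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' Population-location posterior means
#'
#' @param object an `lba_fit`.
#' @param ... unused.
#' @return Named vector of posterior means of the population locations.
#' @export
coef.lba_fit <- function(object, ...) {
  apply(object$mu, 3, mean)
}

#' Summarise a hierarchical LBA fit
#'
#' Posterior means, SDs and central 95% credible intervals of the
#' population locations and scales, pooled over chains and post-thinning
#' draws, plus the maximum Gelman-Rubin statistic over parameters.
#'
#' @param object an `lba_fit`.
#' @param prob credible-interval mass.
#' @param ... unused.
#' @return An object of class `summary.lba_fit`.
#' @export
summary.lba_fit <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  smry <- function(arr) {
    t(apply(arr, 3, function(v)
      c(mean = mean(v), sd = stats::sd(v),
        lower = unname(stats::quantile(v, a)),
        upper = unname(stats::quantile(v, 1 - a)))))
  }
  gd <- gelman_diag(object)
  structure(list(location = smry(object$mu), scale = smry(object$sigma),
                 prob = prob, max_rhat = gd$max_rhat,
                 model = object$spec$name),
            class = "summary.lba_fit")
}

#' @export
print.summary.lba_fit <- function(x, ...) {
  cat(sprintf("Population locations ('%s' model), %d%% credible intervals:\n",
              x$model, round(100 * x$prob)))
  print(round(x$location, 3))
  cat("Population scales:\n")
  print(round(x$scale, 3))
  cat(sprintf("Max Gelman-Rubin over parameters: %.3f\n", x$max_rhat))
  invisible(x)
}

#' Posterior summary tables for a fit
#'
#' Pooled (over chains and draws) posterior means, SDs and credible
#' intervals for population locations and scales, and per-subject posterior
#' means of every free parameter — the input table for downstream
#' Bayes-factor analyses.
#'
#' @param fit an `lba_fit`.
#' @param prob credible-interval mass.
#' @return A list with `population` (data frame: parameter, level, mean,
#'   sd, lower, upper) and `subjects` (data frame of per-subject posterior
#'   means, one row per subject).
#' @export
posterior_summary <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "lba_fit"))
  a <- (1 - prob) / 2
  one <- function(arr, level) {
    do.call(rbind, lapply(dimnames(arr)[[3]], function(p) {
      v <- arr[, , p]
      data.frame(parameter = p, level = level, mean = mean(v),
                 sd = stats::sd(v),
                 lower = unname(stats::quantile(v, a)),
                 upper = unname(stats::quantile(v, 1 - a)),
                 stringsAsFactors = FALSE)
    }))
  }
  pop <- rbind(one(fit$mu, "location"), one(fit$sigma, "scale"))
  subj <- apply(fit$theta, c(3, 4), mean)
  subjects <- data.frame(participant_id = rownames(subj), subj,
                         row.names = NULL, check.names = FALSE,
                         stringsAsFactors = FALSE)
  list(population = pop, subjects = subjects)
}

#' Per-subject posterior means of one parameter family across cells
#'
#' Builds the participants x design-cells table consumed by
#' [rm_banova_bf()]: for the core model each cell's own parameter; for the
#' null model the shared parameter repeated (cells are then identical).
#'
#' @param fit an `lba_fit`.
#' @param family `"v_norm"`, `"v_ab"`, or `"B"`.
#' @return A numeric matrix, rows = participants, columns = the four
#'   design cells.
#' @export
subject_cell_table <- function(fit, family = c("v_norm", "v_ab", "B")) {
  stopifnot(inherits(fit, "lba_fit"))
  family <- match.arg(family)
  cells <- fit$spec$cells
  subj <- apply(fit$theta, c(3, 4), mean)
  cols <- if (fit$spec$name == "core") paste0(family, ".", cells)
          else rep(family, length(cells))
  if (!all(cols %in% colnames(subj)))
    stop("parameter family '", family, "' not present in this fit")
  out <- subj[, cols, drop = FALSE]
  colnames(out) <- cells
  out
}

#' Posterior-predictive simulation from a fitted model
#'
#' Draws parameter vectors from the pooled posterior of each subject and
#' simulates that subject's design (their observed cell counts) through the
#' LBA race.
#'
#' @param object an `lba_fit`.
#' @param nsim number of simulated datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` trial tables (columns `participant_id`,
#'   `cell`, `choice`, `rt_s`, `censored`).
#' @export
simulate.lba_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dm <- dim(object$theta)
  n_draw <- dm[1] * dm[2]
  counts <- table(object$data$participant_id, object$data$cell)
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    sims <- list()
    for (id in object$subjects) {
      i <- sample.int(n_draw, 1L)
      th <- matrix(object$theta[, , id, ], n_draw, dm[4])[i, ]
      cells <- expand_subject_params(object$spec, th, sv = object$sv)
      for (cl in object$spec$cells) {
        n <- counts[id, cl]
        if (n == 0) next
        tr <- simulate_trials(cells[[cl]], n,
                              convention = object$convention)
        tr$participant_id <- id
        tr$cell <- cl
        sims[[length(sims) + 1L]] <- tr
      }
    }
    out[[r]] <- do.call(rbind, sims)
  }
  out
}

#' Diagnostic plots for a hierarchical LBA fit
#'
#' Trace plots (one line per chain) and pooled posterior densities of the
#' population-location parameters.
#'
#' @param x an `lba_fit`.
#' @param pars parameter names (default: all population locations).
#' @param which `"trace"` or `"density"`.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.lba_fit <- function(x, pars = NULL,
                         which = c("trace", "density"), ...) {
  which <- match.arg(which)
  pars <- pars %||% dimnames(x$mu)[[3]]
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(pars)),
                       mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    draws <- x$mu[, , p]
    if (which == "trace") {
      graphics::matplot(t(draws), type = "l", lty = 1, main = p,
                        xlab = "draw", ylab = p, ...)
    } else {
      graphics::plot(stats::density(as.vector(draws)), main = p, ...)
    }
  }
  invisible(x)
}
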