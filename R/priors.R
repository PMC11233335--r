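#' Default priors on population-level parameter locations
#'
#' Normal priors (truncated to the parameter's support) on the population
#' locations of the subject-level LBA parameters. Defaults: `A ~ N(2, 0.6)`,
#' `B ~ N(2, 0.6)`, `t0 ~ N(0.3, 0.1)` (each truncated at 0), normative
#' drift `~ N(2, 0.8)` and aberrant drift `~ N(0.5, 0.8)` (unbounded). In
#' the core model the split parameters inherit the prior of their shared
#' counterpart in each cell. Population scales carry half-Normal(0, 1)
#' hyperpriors.
#'
#' @param spec a [model_spec()].
#' @return A data frame with one row per free parameter: `par`, `mean`,
#'   `sd`, `lower`.
#' @examples
#' default_priors(model_spec("null"))
#' @export
default_priors <- function(spec) {
  tab <- data.frame(
    family = c("A", "B", "t0", "v_norm", "v_ab"),
    mean = c(2, 2, 0.3, 2, 0.5),
    sd = c(0.6, 0.6, 0.1, 0.8, 0.8),
    stringsAsFactors = FALSE
  )
  fam <- sub("\\..*$", "", spec$par_names)
  i <- match(fam, tab$family)
  data.frame(par = spec$par_names, mean = tab$mean[i], sd = tab$sd[i],
             lower = spec$lower, stringsAsFactors = FALSE)
}

#' Sampler configuration for the hierarchical DE-MCMC fit
#'
#' Two named profiles are provided. `"desk"` (the default) uses scaled-down
#' settings suitable for simulation studies on a single CPU: 24 chains, 500
#' burn-in iterations, 1500 sampling iterations thinned by 3. `"paper"`
#' mirrors the full-scale settings of the original analysis: 42 chains,
#' 1000 burn-in, 8000 sampling iterations thinned by 12.
#'
#' @param n_chains number of interacting chains.
#' @param n_burn burn-in iterations (discarded).
#' @param n_sample post-burn-in iterations; every `thin`-th is stored.
#' @param thin thinning interval.
#' @param gamma differential-evolution step size; default
#'   `2.38 / sqrt(2 d)` for a `d`-dimensional block.
#' @param jitter_sd SD of the small normal jitter added to every proposal.
#' @param migration_prob probability of a chain-migration step per
#'   iteration during burn-in only.
#' @param n_inner kernel cycles per iteration: each iteration applies the
#'   full update cycle (subject passes, population blocks, recentring and
#'   shear moves) this many times. Raising it buys faster mixing per
#'   stored draw at proportional cost.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param profile `"desk"` or `"paper"`; explicit arguments override the
#'   profile's values.
#' @return A list of class `sampler_control`.
#' @examples
#' sampler_control(profile = "paper")$n_chains
#' @export
sampler_control <- function(n_chains = NULL, n_burn = NULL,
                            n_sample = NULL, thin = NULL, gamma = NULL,
                            jitter_sd = 1e-3, migration_prob = 0.05,
                            n_inner = 2L, seed = NULL,
                            profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  def <- if (profile == "paper")
    list(n_chains = 42L, n_burn = 1000L, n_sample = 8000L, thin = 12L)
  else
    list(n_chains = 24L, n_burn = 500L, n_sample = 1500L, thin = 3L)
  out <- list(
    n_chains = as.integer(n_chains %||% def$n_chains),
    n_burn = as.integer(n_burn %||% def$n_burn),
    n_sample = as.integer(n_sample %||% def$n_sample),
    thin = as.integer(thin %||% def$thin),
    gamma = gamma, jitter_sd = jitter_sd,
    migration_prob = migration_prob, n_inner = as.integer(n_inner),
    seed = seed, profile = profile)
  stopifnot(out$n_chains >= 4L, out$n_burn >= 0L, out$n_sample >= 1L,
            out$thin >= 1L, out$n_sample %% out$thin == 0L)
  class(out) <- "sampler_control"
  out
}

# log density of Normal(mean, sd) truncated to [lower, Inf); all of x, m,
# s may be matrices of the same shape, lower a vector recycled along rows.
log_dtnorm <- function(x, m, s, lower) {
  lo <- matrix(lower, nrow(as.matrix(x)), length(lower), byrow = TRUE)
  out <- stats::dnorm(x, m, s, log = TRUE) -
    stats::pnorm(lo, m, s, lower.tail = FALSE, log.p = TRUE)
  out[x < lo] <- -Inf
  out
}

# draw from Normal(m, s) truncated to [lower, Inf)
rtnorm_lower <- function(n, m, s, lower) {
  plo <- stats::pnorm(lower, m, s)
  u <- plo + stats::runif(n) * (1 - plo)
  pmax(stats::qnorm(pmin(u, 1 - 1e-16), m, s), lower + 1e-12)
}
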