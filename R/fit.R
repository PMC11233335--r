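#' Fit a hierarchical Bayesian LBA model by DE-MCMC
#'
#' Estimates subject-level LBA parameters jointly with a population-level
#' truncated-Normal distribution over subjects, by an ensemble MCMC
#' sampler in the differential-evolution family. The chain ensemble is
#' split into two halves updated alternately (proposals for one half use
#' donor differences from the other half only). Each iteration cycles
#' complementary moves: per-subject DE crossover (full vector and
#' correlated sub-blocks), shear moves along the non-decision-time/boundary
#' and start-range/boundary trade-offs, a global multiplicative move along
#' the boundary/drift scaling degeneracy, conditional updates of each
#' population location/scale pair (DE plus an independence proposal from
#' the approximate conditional), and a non-centred recentring move that
#' translates population parameters together with all subjects. During
#' burn-in only, occasional migration steps let stuck chains adopt the
#' state of better-placed ones. Acceptance rates per move are returned in
#' the fit (`$acceptance`). See the package vignette for the rationale
#' behind each move.
#'
#' @param data a coded trial table: columns `participant_id`, `choice`
#'   (`"normative"`/`"aberrant"`), `rt_s`, and either `cell` or both
#'   `pleasantness` and `difficulty`. Typically the output of
#'   [preprocess()].
#' @param model `"core"` (boundary and both drifts split over the four
#'   design cells) or `"null"` (all parameters shared); see [model_spec()].
#' @param priors priors on the population locations; defaults to
#'   [default_priors()] for the chosen model.
#' @param control a [sampler_control()] object.
#' @param convention drift-sign convention of the likelihood; see
#'   [lba_cdf()].
#' @param sv fixed across-trial drift SD (the scaling constraint).
#' @return An object of class `lba_fit` with per-chain, per-draw arrays of
#'   subject parameters (`theta`: chains x draws x subjects x parameters)
#'   and population locations/scales (`mu`, `sigma`: chains x draws x
#'   parameters), the model spec, priors, control settings, and the data.
#'   Use [summary.lba_fit()], [coef.lba_fit()], [gelman_diag()], [dic()].
#' @examples
#' \donttest{
#' cohort <- gen_dataset(generator_config(n_participants = 4), seed = 1)
#' d <- cohort$trials
#' d$choice <- code_response(d$picture_norm, d$report)
#' fit <- fit_lba(d, model = "null",
#'                control = sampler_control(n_chains = 12, n_burn = 100,
#'                                          n_sample = 200, thin = 2,
#'                                          seed = 1))
#' coef(fit)
#' }
#' @export
fit_lba <- function(data, model = c("core", "null"), priors = NULL,
                    control = sampler_control(),
                    convention = "truncated", sv = 1) {
  spec <- model_spec(match.arg(model))
  if (is.null(priors)) priors <- default_priors(spec)
  stopifnot(identical(priors$par, spec$par_names))
  convention <- conv_arg(convention)
  if (!"cell" %in% names(data)) {
    if (!all(c("pleasantness", "difficulty") %in% names(data)))
      stop("data needs a 'cell' column or 'pleasantness' + 'difficulty'")
    data$cell <- cell_label(data$pleasantness, data$difficulty)
  }
  if (!all(data$cell %in% spec$cells))
    stop("unknown design cell label(s) in data")
  if (!all(data$choice %in% c("normative", "aberrant")))
    stop("'choice' must be 'normative' or 'aberrant'")
  if (any(data$rt_s <= 0)) stop("non-positive reaction times in data")

  subjects <- sort(unique(as.character(data$participant_id)))
  S <- length(subjects)
  if (S < 2L) stop("hierarchical fitting needs at least 2 subjects")
  sdat <- lapply(subjects, function(id) {
    di <- data[data$participant_id == id, ]
    list(rt = as.numeric(di$rt_s),
         winner = as.integer(di$choice == "aberrant"),
         cell = match(di$cell, spec$cells) - 1L)
  })
  names(sdat) <- subjects

  if (!is.null(control$seed)) set.seed(control$seed)
  fit <- run_demcmc(sdat, spec, priors, control, convention, sv)
  structure(c(fit,
              list(subjects = subjects, spec = spec, priors = priors,
                   control = control, convention = convention, sv = sv,
                   data = data)),
            class = "lba_fit")
}

# ---- sampler internals ------------------------------------------------

run_demcmc <- function(sdat, spec, priors, control, convention, sv) {
  d <- spec$n_free
  S <- length(sdat)
  C <- control$n_chains
  truncated <- convention == "truncated"
  lower <- priors$lower
  gam_th <- control$gamma %||% (0.7 * 2.38 / sqrt(2 * d))
  gam_phi <- control$gamma %||% (0.7 * 2.38 / sqrt(2 * 2))
  jit <- control$jitter_sd
  n_inner <- control$n_inner %||% 1L

  loglik_s <- function(theta_mat, s) {
    .race_loglik_rows_cpp(expand_theta_rows(spec, theta_mat, sv = sv),
                          sdat[[s]]$rt, sdat[[s]]$winner, sdat[[s]]$cell,
                          truncated)
  }
  subj_lp <- function(theta_s, mu_m, sg_m) {
    rowSums(log_dtnorm(theta_s, mu_m, sg_m, lower))
  }
  # per-parameter pieces; sigma is clamped before the density calls so
  # invalid proposals yield -Inf without NaN warnings
  log_dtnorm_j <- function(th_j, mu_j, sg_j, lo) {
    bad <- !is.finite(sg_j) | sg_j <= 0
    sg <- ifelse(bad, 1, sg_j)
    out <- stats::dnorm(th_j, mu_j, sg, log = TRUE) -
      stats::pnorm(lo, mu_j, sg, lower.tail = FALSE, log.p = TRUE)
    out[th_j < lo] <- -Inf
    if (is.matrix(out)) out[bad, ] <- -Inf else out[bad] <- -Inf
    out
  }
  hyper_lp_j <- function(mu_j, sg_j, pm, ps, lo) {
    bad <- !is.finite(sg_j) | sg_j <= 0
    sg <- ifelse(bad, 1, sg_j)
    h <- stats::dnorm(mu_j, pm, ps, log = TRUE) -
      stats::pnorm(lo, pm, ps, lower.tail = FALSE, log.p = TRUE) +
      stats::dnorm(sg, 0, 1, log = TRUE) + log(2)
    h[mu_j < lo | bad] <- -Inf
    h
  }
  hyper_lp <- function(mu_m, sg_m) {
    h <- numeric(nrow(mu_m))
    for (j in seq_len(d))
      h <- h + hyper_lp_j(mu_m[, j], sg_m[, j], priors$mean[j],
                          priors$sd[j], lower[j])
    h
  }

  # initialization from the priors, with bounded retries per chain
  mu <- matrix(rtnorm_lower(C * d, rep(priors$mean, each = C),
                            rep(priors$sd, each = C),
                            rep(lower, each = C)), C, d)
  sigma <- matrix(abs(stats::rnorm(C * d, 0, 0.3)) + 0.02, C, d)
  theta <- array(NA_real_, c(C, S, d))
  ll <- matrix(NA_real_, C, S)
  for (s in seq_len(S)) {
    n_s <- length(sdat[[s]]$rt)
    th <- matrix(rtnorm_lower(C * d, as.vector(mu), as.vector(sigma),
                              rep(lower, each = C)), C, d)
    lls <- loglik_s(th, s)
    bad <- !is.finite(lls) | lls < -600 * n_s
    tries <- 0L
    while (any(bad) && tries < 200L) {
      tries <- tries + 1L
      nb <- sum(bad)
      th[bad, ] <- matrix(
        rtnorm_lower(nb * d, as.vector(mu[bad, , drop = FALSE]),
                     as.vector(sigma[bad, , drop = FALSE]),
                     rep(lower, each = nb)), nb, d)
      lls[bad] <- loglik_s(th[bad, , drop = FALSE], s)
      bad <- !is.finite(lls) | lls < -600 * n_s
    }
    if (any(bad))
      stop("chain initialization failed for subject ", names(sdat)[s])
    theta[, s, ] <- th
    ll[, s] <- lls
  }
  lp <- vapply(seq_len(S),
               function(s) subj_lp(theta[, s, , drop = TRUE], mu, sigma),
               numeric(C))
  hyp <- hyper_lp(mu, sigma)

  # the ensemble is split in two halves updated alternately; proposals for
  # one half use donor differences from the other half only, so each
  # half-update is a product of independent MH kernels (the parallel
  # red-black scheme) and fresher donor states speed relaxation
  halves <- list(seq_len(C %/% 2L), (C %/% 2L + 1L):C)
  donors <- function(H) {
    O <- setdiff(seq_len(C), H)
    nH <- length(H)
    r1 <- O[sample.int(length(O), nH, replace = TRUE)]
    r2 <- O[sample.int(length(O), nH, replace = TRUE)]
    clash <- which(r2 == r1)
    while (length(clash)) {
      r2[clash] <- O[sample.int(length(O), length(clash), replace = TRUE)]
      clash <- clash[r2[clash] == r1[clash]]
    }
    list(r1 = r1, r2 = r2)
  }

  # alternating sub-blocks for the second subject pass: the shared (A, t0)
  # pair, and per design cell the correlated trio of boundary gap and the
  # two drifts
  fam <- sub("\\..*$", "", spec$par_names)
  cell_of <- sub("^[^.]*\\.?", "", spec$par_names)
  sub_blocks <- c(list(which(fam %in% c("A", "t0"))),
                  unname(lapply(unique(cell_of[fam == "B"]), function(cl)
                    which(fam %in% c("B", "v_norm", "v_ab") &
                            cell_of == cl))))
  # recentring rotates over whole parameter families
  recenter_blocks <- list(which(fam %in% c("A", "t0", "B")),
                          which(fam == "v_norm"),
                          which(fam == "v_ab"))
  gam_rec <- vapply(recenter_blocks, function(J)
    2.38 / sqrt(2 * 2 * length(J)) / sqrt(S), numeric(1))
  jt_i <- which(fam == "t0")
  jA_i <- which(fam == "A")
  jB_i <- which(fam == "B")
  jv_i <- which(fam == "v_norm")   # same cell order as the B entries

  acc_n <- c(subject = 0, subject_block = 0, subject_shear = 0,
             population = 0, pop_gibbs = 0, recenter = 0, shear = 0,
             scale = 0)
  acc_d <- acc_n

  count <- function(move, acc) {
    acc_n[move] <<- acc_n[move] + sum(acc)
    acc_d[move] <<- acc_d[move] + length(acc)
  }

  # one MH step for subject s restricted to chains H, given a proposal
  # matrix for those chains
  subject_step <- function(s, H, prop, move) {
    lp_new <- subj_lp(prop, mu[H, , drop = FALSE],
                      sigma[H, , drop = FALSE])
    fin <- is.finite(lp_new)
    ll_new <- rep(-Inf, length(H))
    if (any(fin)) ll_new[fin] <- loglik_s(prop[fin, , drop = FALSE], s)
    acc <- log(stats::runif(length(H))) <
      (ll_new + lp_new) - (ll[H, s] + lp[H, s])
    acc <- acc & fin
    count(move, acc)
    if (any(acc)) {
      Ha <- H[acc]
      theta[Ha, s, ] <<- prop[acc, , drop = FALSE]
      ll[Ha, s] <<- ll_new[acc]
      lp[Ha, s] <<- lp_new[acc]
    }
  }

  n_iter <- control$n_burn + control$n_sample
  n_keep <- control$n_sample %/% control$thin
  theta_draws <- array(NA_real_, c(C, n_keep, S, d))
  mu_draws <- array(NA_real_, c(C, n_keep, d))
  sigma_draws <- array(NA_real_, c(C, n_keep, d))
  keep_i <- 0L

  for (it in seq_len(n_iter)) {
    in_burn <- it <= control$n_burn
    for (inner in seq_len(n_inner)) {
    for (H in halves) {
      nH <- length(H)
      # subject blocks: full-vector crossover, then a rotating correlated
      # sub-block, then a shear along the t0/boundary trade-off (raising
      # t0 while lowering each boundary gap by t0-shift times the cell's
      # normative drift leaves predicted RTs nearly unchanged; plain
      # coordinate moves never traverse that ridge)
      for (s in seq_len(S)) {
        r <- donors(H)
        th <- theta[H, s, , drop = TRUE]
        if (is.null(dim(th))) th <- matrix(th, nrow = nH)
        g <- gam_th * stats::runif(nH, 0.5, 1.5)
        prop <- th + g * (theta[r$r1, s, , drop = TRUE] -
                          theta[r$r2, s, , drop = TRUE]) +
          matrix(stats::rnorm(nH * d, 0, jit), nH, d)
        subject_step(s, H, prop, "subject")

        blk <- sub_blocks[[(it + s) %% length(sub_blocks) + 1L]]
        db <- length(blk)
        r <- donors(H)
        th <- theta[H, s, , drop = TRUE]
        prop <- th
        g <- (2.38 / sqrt(2 * db)) * stats::runif(nH, 0.5, 1.5)
        prop[, blk] <- th[, blk, drop = FALSE] +
          g * (theta[r$r1, s, blk, drop = TRUE] -
               theta[r$r2, s, blk, drop = TRUE]) +
          matrix(stats::rnorm(nH * db, 0, jit), nH, db)
        subject_step(s, H, prop, "subject_block")

        r <- donors(H)
        th <- theta[H, s, , drop = TRUE]
        prop <- th
        if ((it + inner) %% 2L == 0L) {
          delta <- stats::runif(nH, 0.5, 1.5) *
            (theta[r$r1, s, jt_i] - theta[r$r2, s, jt_i]) +
            stats::rnorm(nH, 0, jit)
          prop[, jt_i] <- th[, jt_i] + delta
          prop[, jB_i] <- th[, jB_i, drop = FALSE] -
            delta * th[, jv_i, drop = FALSE]
        } else {
          # complementary shear along the start-range/boundary trade-off:
          # b - A/2 (mean distance to boundary) is preserved
          delta <- stats::runif(nH, 0.5, 1.5) *
            (theta[r$r1, s, jA_i] - theta[r$r2, s, jA_i]) +
            stats::rnorm(nH, 0, jit)
          prop[, jA_i] <- th[, jA_i] + delta
          prop[, jB_i] <- th[, jB_i, drop = FALSE] - delta / 2
        }
        subject_step(s, H, prop, "subject_shear")
      }

      # population blocks: conditional on the subjects the (mu_j, sigma_j)
      # pairs factorize over parameters, so update each 2-dim block by DE
      for (j in seq_len(d)) {
        r <- donors(H)
        g <- gam_phi * stats::runif(nH, 0.5, 1.5)
        mu_n <- mu[H, j] + g * (mu[r$r1, j] - mu[r$r2, j]) +
          stats::rnorm(nH, 0, jit)
        sg_n <- sigma[H, j] + g * (sigma[r$r1, j] - sigma[r$r2, j]) +
          stats::rnorm(nH, 0, jit)
        th_j <- theta[H, , j, drop = TRUE]
        if (is.null(dim(th_j))) th_j <- matrix(th_j, nrow = nH)
        old_terms <- log_dtnorm_j(th_j, mu[H, j], sigma[H, j], lower[j])
        new_terms <- log_dtnorm_j(th_j, mu_n, sg_n, lower[j])
        hyp_old <- hyper_lp_j(mu[H, j], sigma[H, j], priors$mean[j],
                              priors$sd[j], lower[j])
        hyp_new <- hyper_lp_j(mu_n, sg_n, priors$mean[j], priors$sd[j],
                              lower[j])
        acc <- log(stats::runif(nH)) <
          (rowSums(new_terms) + hyp_new) - (rowSums(old_terms) + hyp_old)
        acc <- acc & is.finite(hyp_new) & is.finite(rowSums(new_terms))
        count("population", acc)
        if (any(acc)) {
          Ha <- H[acc]
          mu[Ha, j] <- mu_n[acc]
          sigma[Ha, j] <- sg_n[acc]
          lp[Ha, ] <- lp[Ha, , drop = FALSE] +
            (new_terms - old_terms)[acc, , drop = FALSE]
          hyp[Ha] <- hyp[Ha] + (hyp_new - hyp_old)[acc]
        }

        # second population pass: independence proposal from the
        # approximate conditional (Normal for the location, inverse-gamma
        # for the squared scale), with an exact Hastings correction for
        # the truncation and hyperprior terms. Mixes (mu_j, sigma_j)
        # nearly as well as a Gibbs step, at no likelihood cost.
        sum_th <- rowSums(th_j)
        pm <- priors$mean[j]; ps <- priors$sd[j]
        cond <- function(sg) {
          s2 <- sg^2
          prec <- S / s2 + 1 / ps^2
          list(m = (sum_th / s2 + pm / ps^2) / prec,
               sd = sqrt(1 / prec))
        }
        a_p <- 1 + S / 2
        ldinvg <- function(x2, b) a_p * log(b) - lgamma(a_p) -
          (a_p + 1) * log(x2) - b / x2
        cf <- cond(sigma[H, j])
        mu_n <- stats::rnorm(nH, cf$m, cf$sd)
        b_n <- 0.5 * rowSums((th_j - mu_n)^2) + 0.1
        sg2_n <- b_n / stats::rgamma(nH, a_p)
        sg_n <- sqrt(sg2_n)
        q_f <- stats::dnorm(mu_n, cf$m, cf$sd, log = TRUE) +
          ldinvg(sg2_n, b_n) + log(2 * sg_n)
        cr <- cond(sg_n)
        b_r <- 0.5 * rowSums((th_j - mu[H, j])^2) + 0.1
        q_r <- stats::dnorm(mu[H, j], cr$m, cr$sd, log = TRUE) +
          ldinvg(sigma[H, j]^2, b_r) + log(2 * sigma[H, j])
        new_terms <- log_dtnorm_j(th_j, mu_n, sg_n, lower[j])
        hyp_new <- hyper_lp_j(mu_n, sg_n, pm, ps, lower[j])
        old_terms <- log_dtnorm_j(th_j, mu[H, j], sigma[H, j], lower[j])
        hyp_old <- hyper_lp_j(mu[H, j], sigma[H, j], pm, ps, lower[j])
        acc <- log(stats::runif(nH)) <
          (rowSums(new_terms) + hyp_new) - (rowSums(old_terms) + hyp_old) +
          (q_r - q_f)
        acc <- acc & is.finite(hyp_new) & is.finite(rowSums(new_terms))
        count("pop_gibbs", acc)
        if (any(acc)) {
          Ha <- H[acc]
          mu[Ha, j] <- mu_n[acc]
          sigma[Ha, j] <- sg_n[acc]
          lp[Ha, ] <- lp[Ha, , drop = FALSE] +
            (new_terms - old_terms)[acc, , drop = FALSE]
          hyp[Ha] <- hyp[Ha] + (hyp_new - hyp_old)[acc]
        }
      }

      # non-centered recentring on one parameter family (rotating):
      # translate/rescale (mu_j, sigma_j) and every subject's theta_j
      # jointly, holding standardized residuals fixed; this breaks the
      # funnel between population scales and weakly identified subject
      # parameters
      {
        bi <- (it + inner - 1L) %% length(recenter_blocks) + 1L
        J <- recenter_blocks[[bi]]
        r <- donors(H)
        g <- gam_rec[bi] * stats::runif(nH, 0.5, 1.5)
        mu_n <- mu[H, J, drop = FALSE] +
          g * (mu[r$r1, J, drop = FALSE] - mu[r$r2, J, drop = FALSE]) +
          matrix(stats::rnorm(nH * length(J), 0, jit), nH)
        sg_n <- sigma[H, J, drop = FALSE] +
          g * (sigma[r$r1, J, drop = FALSE] -
                 sigma[r$r2, J, drop = FALSE]) +
          matrix(stats::rnorm(nH * length(J), 0, jit), nH)
        ok <- apply(is.finite(sg_n) & sg_n > 0, 1, all)
        ratio <- sg_n / sigma[H, J, drop = FALSE]
        ratio[!ok, ] <- 1
        th_n <- theta[H, , , drop = FALSE]
        dlp <- matrix(0, nH, S)
        dhyp <- numeric(nH)
        ljac <- numeric(nH)
        for (k in seq_along(J)) {
          j <- J[k]
          th_j <- theta[H, , j, drop = TRUE]
          if (is.null(dim(th_j))) th_j <- matrix(th_j, nrow = nH)
          th_j_n <- mu_n[, k] + ratio[, k] * (th_j - mu[H, j])
          ok <- ok & apply(th_j_n >= lower[j], 1, all)
          th_n[, , j] <- th_j_n
          dlp <- dlp +
            log_dtnorm_j(th_j_n, mu_n[, k], sg_n[, k], lower[j]) -
            log_dtnorm_j(th_j, mu[H, j], sigma[H, j], lower[j])
          dhyp <- dhyp +
            hyper_lp_j(mu_n[, k], sg_n[, k], priors$mean[j],
                       priors$sd[j], lower[j]) -
            hyper_lp_j(mu[H, j], sigma[H, j], priors$mean[j],
                       priors$sd[j], lower[j])
          ljac <- ljac + S * log(ratio[, k])
        }
        if (any(ok)) {
          ll_new <- matrix(-Inf, nH, S)
          for (s in seq_len(S)) {
            pm <- th_n[, s, , drop = TRUE]
            if (is.null(dim(pm))) pm <- matrix(pm, nrow = nH)
            ll_new[ok, s] <- loglik_s(pm[ok, , drop = FALSE], s)
          }
          dlog <- rowSums(ll_new - ll[H, , drop = FALSE]) + rowSums(dlp) +
            dhyp + ljac
          acc <- ok & log(stats::runif(nH)) < dlog
          count("recenter", acc)
          if (any(acc)) {
            Ha <- H[acc]
            for (k in seq_along(J)) {
              j <- J[k]
              theta[Ha, , j] <- th_n[acc, , j, drop = FALSE]
              mu[Ha, j] <- mu_n[acc, k]
              sigma[Ha, j] <- sg_n[acc, k]
            }
            ll[Ha, ] <- ll_new[acc, , drop = FALSE]
            lp[Ha, ] <- lp[Ha, , drop = FALSE] + dlp[acc, , drop = FALSE]
            hyp[Ha] <- hyp[Ha] + dhyp[acc]
          }
        }
      }

      # population-level shear along the same t0/boundary ridge, applied
      # to the locations and every subject jointly (unit-Jacobian map)
      {
        r <- donors(H)
        t0_mode <- (it + inner) %% 2L == 0L
        jref <- if (t0_mode) jt_i else jA_i
        delta <- stats::runif(nH, 0.5, 1.5) * 0.5 *
          (mu[r$r1, jref] - mu[r$r2, jref]) + stats::rnorm(nH, 0, jit)
        th_n <- theta[H, , , drop = FALSE]
        mu_n <- mu[H, , drop = FALSE]
        mu_n[, jref] <- mu_n[, jref] + delta
        tj <- theta[H, , jref, drop = TRUE]
        if (is.null(dim(tj))) tj <- matrix(tj, nrow = nH)
        th_n[, , jref] <- tj + delta
        for (k in seq_along(jB_i)) {
          tB <- theta[H, , jB_i[k], drop = TRUE]
          tv <- theta[H, , jv_i[k], drop = TRUE]
          if (is.null(dim(tB))) { tB <- matrix(tB, nrow = nH)
                                  tv <- matrix(tv, nrow = nH) }
          if (t0_mode) {
            mu_n[, jB_i[k]] <- mu_n[, jB_i[k]] - delta * mu[H, jv_i[k]]
            th_n[, , jB_i[k]] <- tB - delta * tv
          } else {
            mu_n[, jB_i[k]] <- mu_n[, jB_i[k]] - delta / 2
            th_n[, , jB_i[k]] <- tB - delta / 2
          }
        }
        Jmv <- c(jref, jB_i)
        ok <- rep(TRUE, nH)
        dlp <- matrix(0, nH, S)
        dhyp <- numeric(nH)
        for (j in Jmv) {
          th_j_n <- th_n[, , j, drop = TRUE]
          if (is.null(dim(th_j_n))) th_j_n <- matrix(th_j_n, nrow = nH)
          ok <- ok & apply(th_j_n >= lower[j], 1, all) &
            mu_n[, j] >= lower[j]
          th_j <- theta[H, , j, drop = TRUE]
          if (is.null(dim(th_j))) th_j <- matrix(th_j, nrow = nH)
          dlp <- dlp +
            log_dtnorm_j(th_j_n, mu_n[, j], sigma[H, j], lower[j]) -
            log_dtnorm_j(th_j, mu[H, j], sigma[H, j], lower[j])
          dhyp <- dhyp +
            hyper_lp_j(mu_n[, j], sigma[H, j], priors$mean[j],
                       priors$sd[j], lower[j]) -
            hyper_lp_j(mu[H, j], sigma[H, j], priors$mean[j],
                       priors$sd[j], lower[j])
        }
        if (any(ok)) {
          ll_new <- matrix(-Inf, nH, S)
          for (s in seq_len(S)) {
            pm <- th_n[, s, , drop = TRUE]
            if (is.null(dim(pm))) pm <- matrix(pm, nrow = nH)
            ll_new[ok, s] <- loglik_s(pm[ok, , drop = FALSE], s)
          }
          dlog <- rowSums(ll_new - ll[H, , drop = FALSE]) +
            rowSums(dlp) + dhyp
          acc <- ok & log(stats::runif(nH)) < dlog
          count("shear", acc)
          if (any(acc)) {
            Ha <- H[acc]
            for (j in Jmv) {
              theta[Ha, , j] <- th_n[acc, , j, drop = FALSE]
              mu[Ha, j] <- mu_n[acc, j]
            }
            ll[Ha, ] <- ll_new[acc, , drop = FALSE]
            lp[Ha, ] <- lp[Ha, , drop = FALSE] + dlp[acc, , drop = FALSE]
            hyp[Ha] <- hyp[Ha] + dhyp[acc]
          }
        }
      }

      # global scaling move along the boundary/drift degeneracy: with the
      # drift SD fixed at sv, multiplying A, the boundary gaps and both
      # drifts (with their population locations and scales) by a common
      # factor leaves all finishing times invariant and is constrained
      # only by choice probabilities — the classic LBA scaling ridge.
      # The map is multiplicative with log-Jacobian (S + 2) |jS| log(lam).
      {
        r <- donors(H)
        eps <- stats::runif(nH, 0.5, 1.5) * 0.5 *
          (log(mu[r$r1, jA_i]) - log(mu[r$r2, jA_i])) +
          stats::rnorm(nH, 0, jit)
        lam <- exp(eps)
        jS <- setdiff(seq_len(d), jt_i)
        th_n <- theta[H, , , drop = FALSE]
        mu_n <- mu[H, , drop = FALSE]
        sg_n <- sigma[H, , drop = FALSE]
        for (j in jS) {
          th_n[, , j] <- th_n[, , j] * lam
          mu_n[, j] <- mu_n[, j] * lam
          sg_n[, j] <- sg_n[, j] * lam
        }
        ok <- rep(TRUE, nH)
        dlp <- matrix(0, nH, S)
        dhyp <- numeric(nH)
        for (j in jS) {
          th_j_n <- th_n[, , j, drop = TRUE]
          if (is.null(dim(th_j_n))) th_j_n <- matrix(th_j_n, nrow = nH)
          th_j <- theta[H, , j, drop = TRUE]
          if (is.null(dim(th_j))) th_j <- matrix(th_j, nrow = nH)
          dlp <- dlp +
            log_dtnorm_j(th_j_n, mu_n[, j], sg_n[, j], lower[j]) -
            log_dtnorm_j(th_j, mu[H, j], sigma[H, j], lower[j])
          dhyp <- dhyp +
            hyper_lp_j(mu_n[, j], sg_n[, j], priors$mean[j],
                       priors$sd[j], lower[j]) -
            hyper_lp_j(mu[H, j], sigma[H, j], priors$mean[j],
                       priors$sd[j], lower[j])
        }
        ljac <- (S + 2) * length(jS) * eps
        ll_new <- matrix(-Inf, nH, S)
        for (s in seq_len(S)) {
          pm <- th_n[, s, , drop = TRUE]
          if (is.null(dim(pm))) pm <- matrix(pm, nrow = nH)
          ll_new[ok, s] <- loglik_s(pm[ok, , drop = FALSE], s)
        }
        dlog <- rowSums(ll_new - ll[H, , drop = FALSE]) +
          rowSums(dlp) + dhyp + ljac
        acc <- ok & log(stats::runif(nH)) < dlog
        count("scale", acc)
        if (any(acc)) {
          Ha <- H[acc]
          for (j in jS) {
            theta[Ha, , j] <- th_n[acc, , j, drop = FALSE]
            mu[Ha, j] <- mu_n[acc, j]
            sigma[Ha, j] <- sg_n[acc, j]
          }
          ll[Ha, ] <- ll_new[acc, , drop = FALSE]
          lp[Ha, ] <- lp[Ha, , drop = FALSE] + dlp[acc, , drop = FALSE]
          hyp[Ha] <- hyp[Ha] + dhyp[acc]
        }
      }
    }
    }

    # migration during burn-in: cyclic block exchanges between a random
    # chain subset let stuck chains adopt better-placed states. Subject
    # vectors and population pairs migrate separately under their
    # conditional posteriors.
    if (in_burn && stats::runif(1) < control$migration_prob && C >= 3L) {
      cyc <- function() {
        k <- sample(2:max(2L, C %/% 2L), 1L)
        idx <- sample.int(C, k)
        cbind(cur = idx, from = c(idx[k], idx[-k]))
      }
      for (s in seq_len(S)) {
        mv <- cyc()
        th_from <- theta[mv[, "from"], s, , drop = TRUE]
        if (is.null(dim(th_from))) th_from <- matrix(th_from, nrow = 1)
        lp_ad <- subj_lp(th_from, mu[mv[, "cur"], , drop = FALSE],
                         sigma[mv[, "cur"], , drop = FALSE])
        ll_ad <- ll[mv[, "from"], s]
        acc <- log(stats::runif(nrow(mv))) <
          (ll_ad + lp_ad) - (ll[mv[, "cur"], s] + lp[mv[, "cur"], s])
        for (i in which(acc)) {
          cur <- mv[i, "cur"]
          theta[cur, s, ] <- th_from[i, ]
          ll[cur, s] <- ll_ad[i]
          lp[cur, s] <- lp_ad[i]
        }
      }
      for (j in seq_len(d)) {
        mv <- cyc()
        mu_ad <- mu[mv[, "from"], j]
        sg_ad <- sigma[mv[, "from"], j]
        th_j <- theta[mv[, "cur"], , j, drop = TRUE]
        if (is.null(dim(th_j))) th_j <- matrix(th_j, nrow = 1)
        new_terms <- log_dtnorm_j(th_j, mu_ad, sg_ad, lower[j])
        old_terms <- log_dtnorm_j(th_j, mu[mv[, "cur"], j],
                                  sigma[mv[, "cur"], j], lower[j])
        dhyp <- hyper_lp_j(mu_ad, sg_ad, priors$mean[j], priors$sd[j],
                           lower[j]) -
          hyper_lp_j(mu[mv[, "cur"], j], sigma[mv[, "cur"], j],
                     priors$mean[j], priors$sd[j], lower[j])
        dlp <- new_terms - old_terms
        acc <- log(stats::runif(nrow(mv))) < rowSums(dlp) + dhyp
        for (i in which(acc)) {
          cur <- mv[i, "cur"]
          mu[cur, j] <- mu_ad[i]
          sigma[cur, j] <- sg_ad[i]
          lp[cur, ] <- lp[cur, ] + dlp[i, ]
          hyp[cur] <- hyp[cur] + dhyp[i]
        }
      }
    }

    if (!in_burn && (it - control$n_burn) %% control$thin == 0L) {
      keep_i <- keep_i + 1L
      theta_draws[, keep_i, , ] <- theta
      mu_draws[, keep_i, ] <- mu
      sigma_draws[, keep_i, ] <- sigma
    }
  }
  dimnames(theta_draws) <- list(NULL, NULL, names(sdat), spec$par_names)
  dimnames(mu_draws) <- list(NULL, NULL, spec$par_names)
  dimnames(sigma_draws) <- list(NULL, NULL, spec$par_names)
  list(theta = theta_draws, mu = mu_draws, sigma = sigma_draws,
       acceptance = ifelse(acc_d > 0, acc_n / acc_d, NA))
}

#' Joint log-posterior of the hierarchical LBA model
#'
#' Sum of the per-subject data log-likelihoods, the truncated-Normal
#' subject-level prior terms given the population parameters, and the
#' hyperprior terms (truncated-Normal priors on locations, half-Normal(0,1)
#' on scales). Returns `-Inf` outside the support. Exposed mainly for
#' testing and external diagnostics; [fit_lba()] uses the same terms
#' internally.
#'
#' @param theta_subjects matrix, one row per subject, columns in
#'   `spec$par_names` order.
#' @param mu,sigma population location and scale vectors.
#' @param data coded trial table (as in [fit_lba()], with `cell` labels).
#' @param spec a [model_spec()].
#' @param priors as in [fit_lba()].
#' @inheritParams fit_lba
#' @return The joint log density (scalar).
#' @export
log_posterior <- function(theta_subjects, mu, sigma, data, spec,
                          priors = default_priors(spec),
                          convention = "truncated", sv = 1) {
  if (any(sigma <= 0)) return(-Inf)
  lower <- priors$lower
  if (any(t(theta_subjects) < lower) || any(mu < lower)) return(-Inf)
  subjects <- rownames(theta_subjects) %||%
    as.character(sort(unique(data$participant_id)))
  truncated <- conv_arg(convention) == "truncated"
  ll <- 0
  for (i in seq_along(subjects)) {
    di <- data[data$participant_id == subjects[i], ]
    if (nrow(di)) {
      ll <- ll + .race_loglik_rows_cpp(
        expand_theta_rows(spec, theta_subjects[i, , drop = FALSE], sv = sv),
        as.numeric(di$rt_s), as.integer(di$choice == "aberrant"),
        match(di$cell, spec$cells) - 1L, truncated)
    }
    ll <- ll + sum(log_dtnorm(theta_subjects[i, , drop = FALSE],
                              matrix(mu, 1), matrix(sigma, 1), lower))
  }
  ll + sum(log_dtnorm(matrix(mu, 1), matrix(priors$mean, 1),
                      matrix(priors$sd, 1), lower)) +
    sum(stats::dnorm(sigma, 0, 1, log = TRUE) + log(2))
}
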