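# Shared fixtures, built in code at test time.

# small coded trial table with known per-step contaminants; aberrant
# drifts are set far below zero so the clean base triggers no filter and
# injected counts are exact
contaminated_cohort <- function(seed = 401) {
  # small drift SD makes clean decision times bounded (start-point range
  # only), so no clean trial can trip the RT-window or z-score filters
  # and the injected counts are exact by construction
  cfg <- generator_config(
    n_participants = 8,
    v_norm = c(unpleasant.easy = 4.5, unpleasant.difficult = 4.5,
               pleasant.easy = 4.5, pleasant.difficult = 4.5),
    v_ab = c(unpleasant.easy = -2, unpleasant.difficult = -2,
             pleasant.easy = -2, pleasant.difficult = -2),
    sv = 0.15, pop_scale = 0.1)
  cohort <- gen_dataset(cfg, seed = seed)
  d <- cohort$trials
  d$choice <- code_response(d$picture_norm, d$report)
  inject_contaminants(d, n_bad_participants = 2, n_bad_pictures = 3,
                      n_fast = 5, n_slow = 4, n_extreme = 6,
                      seed = seed + 1)
}

# deterministic mini trial table for hand-checked filter counts
tiny_trials <- function() {
  data.frame(
    participant_id = rep(c("p1", "p2"), each = 10),
    picture_id = rep(sprintf("pic%02d", 1:10), 2),
    pleasantness = rep(c("unpleasant", "pleasant"), 10),
    difficulty = "easy",
    choice = c(rep("aberrant", 6), rep("normative", 4),   # p1: 60% aberrant
               rep("normative", 8), rep("aberrant", 2)),  # p2: 20%
    rt_s = rep(1.5, 20),
    stringsAsFactors = FALSE
  )
}

a_cell <- function(vn = 3, va = 0.5, A = 2, B = 2, t0 = 0.3, sv = 1) {
  cell_params(A = A, B = B, t0 = t0, mean_v_normative = vn,
              mean_v_aberrant = va, sv = sv)
}

# pipeline config small enough for an end-to-end smoke run
default_config_for_tests <- function() {
  cfg <- read_config(NULL)
  cfg$generator$n_participants <- 3
  cfg$generator$blocks <- 1
  cfg$generator$trials_per_block <- 60
  cfg$banova$nsim <- 2e4
  cfg$sampler <- list(n_chains = 10, n_burn = 60, n_sample = 120,
                      thin = 3, n_inner = 1)
  cfg
}
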