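# hand-built session / cohort constructors used across the test files

# one subject's trials in a single market, all entered, outcomes given
make_session_df <- function(market, bids, accepted, subject_id = "s01") {
  n <- length(bids)
  data.frame(
    subject_id = rep(subject_id, n), market = market, block = seq_len(n),
    trial_in_market = seq_len(n), entered = TRUE, bid = bids,
    accepted = accepted, reward = ifelse(accepted, 10 - bids, 0),
    competitor_bid = NA_real_, stringsAsFactors = FALSE
  )
}

# random but valid multi-market session for property sweeps
random_session_df <- function(n_per_market = 5, subject_id = "s01", seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(c("SC", "NC", "BC"), function(m) {
    bids <- sample(bid_grid(), n_per_market, replace = TRUE)
    make_session_df(m, bids, accepted = runif(n_per_market) < 0.6,
                    subject_id = subject_id)
  }))
}

# small generated cohort at the study's generating defaults
small_cohort <- function(n_subjects = 4, n_blocks = 8, seed = 1, ...) {
  simulate_cohort(cohort_config(n_subjects = n_subjects, n_blocks = n_blocks,
                                ...), seed = seed)
}

# reference parameter sets used throughout
ffx_lepto <- c(alpha = 0.53, sigma_a = 0.70, sigma_r = 0.79,
               sigma_0 = 0.65, k = 0.39)
ffx_gauss <- c(alpha = 0.38, sigma = 1.09)
ffx_naive <- c(n_up = 0.20, n_down = 0.06, sigma_a = 1.06, sigma_r = 1.16)

example_params <- function(model) {
  switch(model,
    rw_coarse = c(alpha = 0.2, beta = 2),
    rw_fine = c(alpha = 0.2, beta = 2),
    counterfactual_rl = c(alpha = 0.1, beta = 1),
    dl_gauss = ffx_gauss,
    dl_naive = ffx_naive,
    dl_lepto = ffx_lepto,
    null = numeric(0))
}

# random in-bounds parameter draw for property sweeps
draw_params <- function(model) {
  spec <- bid_model(model)
  if (!length(spec$params)) return(numeric(0))
  stats::setNames(spec$lower + runif(length(spec$params)) *
                    (spec$upper - spec$lower), spec$params)
}
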