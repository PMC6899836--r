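#' Cohort configuration
#'
#' Bundles everything needed to simulate a synthetic cohort: cohort size,
#' schedule length, the opponent pools' truncated-Gaussian parameters, the
#' generating model and its parameters, and the per-market initial
#' preferred bids. Defaults emulate the study conditions: 27 subjects, 24
#' blocks of the three markets with a 1-in-6 lottery skip, stationary
#' opponents whose asks/bids are truncated Gaussians around market-specific
#' clearing prices chosen so that acceptance difficulty orders
#' SC < NC < BC (mean asks 3.5/3.5 in SC, 4.5 in NC, 4.0 in BC with a
#' competitor buyer centred at 5.5; sd 1, no drift), and the leptokurtic-DL
#' delta-rule agent at its aggregated-fit estimates.
#'
#' @param n_subjects Number of subjects.
#' @param n_blocks Blocks per session (each visits all three markets).
#' @param model Generating model name or spec.
#' @param params Generating parameters (named, within bounds).
#' @param init_bids Named per-market initial preferred bids (DL) — also used
#'   as the Beta-prior location for RL generators via [fit_beta_prior()]
#'   defaults when needed.
#' @param mu_ask Named list of per-market seller ask means (SC has two).
#' @param mu_comp Mean of the BC competitor buyer's bids.
#' @param sigma Spread of all opponent truncated Gaussians.
#' @param drift Linear drift of the opponent means per trial (MU/trial).
#' @param lottery One of `"one_in_six"` (exactly one skip per window of six)
#'   or `"none"` or `"all"` (degenerate overrides for testing).
#' @param seed Master seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 27L,
                          n_blocks = 24L,
                          model = "dl_lepto",
                          params = c(alpha = 0.53, sigma_a = 0.70,
                                     sigma_r = 0.79, sigma_0 = 0.65, k = 0.39),
                          init_bids = c(SC = 4.96, NC = 5.13, BC = 6.55),
                          mu_ask = list(SC = c(3.5, 3.5), NC = 4.5, BC = 4.0),
                          mu_comp = 5.5,
                          sigma = 1.0,
                          drift = 0.0,
                          lottery = c("one_in_six", "none", "all"),
                          seed = 1L) {
  if (n_subjects < 1L) stop("cohort_config: n_subjects must be >= 1")
  spec <- as_model_spec(model)
  params <- check_params(spec, params)
  if (sigma < 0) stop("cohort_config: sigma must be >= 0")
  mus <- c(unlist(mu_ask), mu_comp)
  if (any(mus < 0 | mus > 10))
    stop("cohort_config: opponent means must lie in [0, 10]")
  if (length(mu_ask$SC) != 2L || length(mu_ask$NC) != 1L || length(mu_ask$BC) != 1L)
    stop("cohort_config: mu_ask needs 2 SC values and 1 each for NC, BC")
  structure(list(
    n_subjects = as.integer(n_subjects), n_blocks = as.integer(n_blocks),
    model = spec, params = params, init_bids = init_bids,
    mu_ask = mu_ask, mu_comp = mu_comp, sigma = sigma, drift = drift,
    lottery = match.arg(lottery), seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @rdname cohort_config
#' @param path Path of a YAML file whose keys are `cohort_config()`
#'   arguments (`params`, `init_bids` and `mu_ask` given as named maps).
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$params)) y$params <- unlist(y$params)
  if (!is.null(y$init_bids)) y$init_bids <- unlist(y$init_bids)
  do.call(cohort_config, y)
}

# truncated-Gaussian draws on [0, 10] by inverse CDF; sigma = 0 degenerates
# to the (clamped) mean
rtrunc_gauss <- function(n, mu, sigma, lo = 0, hi = 10) {
  mu <- pmin(pmax(mu, lo), hi)
  if (sigma == 0) return(rep_len(mu, n))
  plo <- stats::pnorm(lo, mu, sigma)
  phi <- stats::pnorm(hi, mu, sigma)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mu, sigma)
}

#' Opponent pool for one subject
#'
#' Draws the per-market seller ask series (and the BC competitor-bid
#' series) the subject will face, one value per within-market trial,
#' i.i.d. truncated Gaussians around the configured clearing prices
#' (optionally drifting linearly in trial index). Reproducible from the
#' master seed and subject index.
#'
#' @param config A [cohort_config()].
#' @param subject_index Integer subject index (1-based).
#' @param n_trials Series length; defaults to the config's blocks count.
#' @return List of class `opponent_pool`: per market, an `asks` matrix
#'   (sellers x trials) and, for BC, a `comp` vector of competitor bids.
#' @export
make_opponent_pool <- function(config, subject_index, n_trials = config$n_blocks) {
  if (config$sigma <= 0 && config$sigma != 0)
    stop("make_opponent_pool: sigma must be positive (or 0 for degenerate)")
  pool <- list()
  with_preserved_seed(derive_seed(config$seed, subject_index, salt = 1L), {
    tt <- seq_len(n_trials) - 1L
    for (m in market_labels()) {
      mus <- config$mu_ask[[m]]
      asks <- t(vapply(mus, function(mu)
        vapply(tt, function(t1)
          rtrunc_gauss(1L, mu + config$drift * t1, config$sigma), numeric(1)),
        numeric(n_trials)))
      pool[[m]] <- list(asks = asks)
    }
    pool$BC$comp <- vapply(tt, function(t1)
      rtrunc_gauss(1L, config$mu_comp + config$drift * t1, config$sigma),
      numeric(1))
  })
  structure(list(markets = pool, seed = config$seed,
                 subject_index = subject_index), class = "opponent_pool")
}

#' Simulate one session
#'
#' Plays an initialized agent through a market/lottery schedule against an
#' opponent pool. On each entered trial the agent samples a grid bid from
#' its policy, the auction is resolved, and the agent's state is updated;
#' lottery-skipped trials leave the state untouched. The returned event
#' table includes the ground-truth asks (`ask1`, `ask2`), the disclosed
#' competitor bid, and the agent's pre-trial tracked preference
#' (`state_pref`: the preferred bid for DL agents, the value-maximizing bin
#' centre for RL agents) for posterior-predictive summaries.
#'
#' @param state An [init_state()] agent state.
#' @param pool An [make_opponent_pool()] pool.
#' @param schedule A [market_schedule()] data frame.
#' @param seed Integer seed driving policy sampling and tie-breaks.
#' @param subject_id Subject identifier stored in the log.
#' @return Data frame of trials (one session).
#' @export
simulate_session <- function(state, pool, schedule, seed = 1L,
                             subject_id = "s01") {
  n <- nrow(schedule)
  need <- vapply(market_labels(), function(m)
    sum(schedule$market == m), integer(1))
  avail <- vapply(market_labels(), function(m)
    ncol(pool$markets[[m]]$asks), integer(1))
  if (any(avail < need)) stop("simulate_session: opponent pool exhausted")
  g <- bid_grid()
  out <- data.frame(
    subject_id = rep(subject_id, n), market = schedule$market,
    block = schedule$block, trial_in_market = schedule$trial_in_market,
    entered = schedule$entered, bid = NA_real_, accepted = NA,
    reward = 0, competitor_bid = NA_real_,
    ask1 = NA_real_, ask2 = NA_real_, state_pref = NA_real_,
    stringsAsFactors = FALSE
  )
  with_preserved_seed(seed, {
    for (i in seq_len(n)) {
      m <- schedule$market[i]
      tm <- schedule$trial_in_market[i]
      out$state_pref[i] <- tracked_preference(state, m)
      if (!schedule$entered[i]) next
      bid <- sample(g, 1L, prob = policy_probs(state, m))
      asks <- pool$markets[[m]]$asks[, tm]
      comp <- if (m == "BC") pool$markets$BC$comp[tm] else numeric(0)
      res <- resolve_trial(m, bid, asks, comp)
      out$bid[i] <- bid
      out$accepted[i] <- res$accepted
      out$reward[i] <- res$reward
      out$competitor_bid[i] <- res$disclosed_competitor_bid
      out$ask1[i] <- asks[1]
      if (length(asks) > 1) out$ask2[i] <- asks[2]
      state <- update_state(state, m, bid, res$accepted, res$reward)
    }
  })
  out
}

# the quantity posterior-predictive curves track: preferred bid (DL) or the
# bin centre maximizing the action-value function (RL)
tracked_preference <- function(state, market) {
  if (state$model$family == "dl") return(state$A[[market]])
  if (state$model$family == "rl") {
    Q <- state$Q[[market]]
    at <- if (state$model$name == "rw_coarse") tile_centres() else bid_grid()
    return(at[which.max(Q)])
  }
  NA_real_
}

#' Simulate a synthetic cohort
#'
#' Generates `n_subjects` independent sessions under a [cohort_config()]:
#' each subject gets a market-sequence permutation (cycling through the six
#' orderings), an independently seeded lottery schedule, opponent pool and
#' policy stream, and a fresh agent initialized at the config's generating
#' model, parameters and initial preferred bids.
#'
#' @param config A [cohort_config()].
#' @param seed Optional master seed overriding `config$seed`.
#' @return Dataset: data frame of all subjects' trials, writable with
#'   [write_events_tsv()].
#' @export
simulate_cohort <- function(config, seed = NULL) {
  if (!inherits(config, "cohort_config")) stop("simulate_cohort: need a cohort_config")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  sessions <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    sched <- market_schedule(((s - 1L) %% 6L) + 1L, config$n_blocks,
                             seed = derive_seed(config$seed, s, salt = 2L))
    if (config$lottery == "none") sched$entered <- TRUE
    if (config$lottery == "all") sched$entered <- FALSE
    pool <- make_opponent_pool(config, s)
    st <- init_state(config$model, config$params,
                     init = if (config$model$family == "dl")
                       config$init_bids else NULL)
    sessions[[s]] <- simulate_session(
      st, pool, sched, seed = derive_seed(config$seed, s, salt = 3L),
      subject_id = sprintf("s%02d", s))
  }
  do.call(rbind, sessions)
}
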