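#' Negative log-likelihood of a dataset under a model
#'
#' Replays every subject's trials in chronological order, accumulating the
#' negative log-probability of each entered bid under the model's policy
#' and applying the model's update rule after each; lottery-skipped trials
#' contribute nothing and leave the state untouched. Fixed effects share
#' one parameter vector across subjects (the aggregated likelihood); the
#' per-subject decomposition is always returned.
#'
#' Initial conditions are taken from the data unless supplied: DL models
#' start each market at the cohort's mean first-trial bid, RL models at a
#' Beta prior fit per market to the pooled first-trial bids.
#'
#' @param model Model name or spec.
#' @param params Named parameter vector within bounds.
#' @param data Dataset (data frame of trials).
#' @param init Optional initial conditions, as in [init_state()].
#' @param engine `"compiled"` (the default fast path) or `"reference"`, a
#'   plain-R evaluation of the same likelihood used for validation.
#' @return List with `total` and per-subject vector `by_subject`.
#' @export
bids_nll <- function(model, params, data, init = NULL,
                     engine = c("compiled", "reference")) {
  spec <- as_model_spec(model)
  engine <- match.arg(engine)
  params <- check_params(spec, params)
  if (!any(!is.na(data$entered) & data$entered & !is.na(data$bid)))
    stop("bids_nll: dataset has no entered bid trials")
  init <- default_init(spec, data, init)
  preps <- lapply(split_subjects(data), prep_subject)
  by_subject <- if (engine == "compiled")
    nll_preps(spec, params, preps, init)
  else
    vapply(preps, function(p) nll_subject(spec, params, p, init), numeric(1))
  list(total = sum(by_subject), by_subject = by_subject)
}

# flatten per-subject replay structures into the stacked arrays the
# compiled likelihood consumes; `newseq` marks subject-market sequence starts
stack_preps <- function(preps) {
  subj <- market <- bid <- bididx <- acc <- rew <- new <- list()
  j <- 0L
  for (s in seq_along(preps)) {
    for (mi in 1:3) {
      p <- preps[[s]][[market_labels()[mi]]]
      nt <- length(p$bid)
      if (!nt) next
      j <- j + 1L
      subj[[j]] <- rep.int(s, nt)
      market[[j]] <- rep.int(mi, nt)
      bid[[j]] <- p$bid
      bididx[[j]] <- p$bid_idx
      acc[[j]] <- as.integer(p$accepted)
      rew[[j]] <- p$reward
      new[[j]] <- c(TRUE, rep.int(FALSE, nt - 1L))
    }
  }
  list(subj = unlist(subj), market = unlist(market), bid = unlist(bid),
       bididx = unlist(bididx), accepted = unlist(acc), reward = unlist(rew),
       newseq = unlist(new))
}

# per-subject NLL vector over pre-extracted replay structures (compiled path)
nll_preps <- function(spec, params, preps, init, stacked = NULL) {
  out <- stats::setNames(numeric(length(preps)), names(preps))
  if (spec$family == "null") {
    n <- vapply(preps, function(p)
      sum(vapply(p, function(q) length(q$bid), integer(1))), numeric(1))
    return(out + n * log(101))
  }
  st <- if (is.null(stacked)) stack_preps(preps) else stacked
  if (!length(st$subj)) return(out)
  if (spec$family == "dl") {
    mid <- match(spec$name, c("dl_gauss", "dl_naive", "dl_lepto"))
    res <- cpp_dl_nll(mid, unname(params[spec$params]), st$subj, st$market,
                      st$bid, st$bididx, st$accepted, st$reward, st$newseq,
                      unname(init[market_labels()]), length(preps))
  } else {
    mid <- match(spec$name, c("rw_coarse", "rw_fine", "counterfactual_rl"))
    at <- if (spec$name == "rw_coarse") tile_centres() else bid_grid()
    Q0 <- do.call(rbind, lapply(market_labels(), function(m)
      beta_prior_values(init[[m]], at)))
    res <- cpp_rl_nll(mid, unname(params[spec$params]), st$subj, st$market,
                      st$bid, st$bididx, st$accepted, st$reward, st$newseq,
                      Q0, tile_of_grid(), tile_sizes(), length(preps))
  }
  bump_floor_count(res$nfloor)
  out + res$nll
  }

# vectorized DL choice log-probabilities for stacked trials
dl_loglik_rows <- function(spec, params, A, last, bidx) {
  n <- length(A)
  g <- bid_grid()
  D <- outer(A, g, "-")                 # positive where grid < A
  below <- D > 0
  rows <- cbind(seq_len(n), bidx)
  if (spec$name == "dl_gauss") {
    W <- exp(-D^2 / (2 * params[["sigma"]]^2))
    pr <- W[rows] / rowSums(W)
  } else {
    key <- match(last, c("none", "accepted", "rejected"))
    sbs <- sus <- numeric(3)
    for (j in 1:3) {
      sc <- dl_side_scales(spec, params, c("none", "accepted", "rejected")[j])
      sbs[j] <- sc[["below"]]; sus[j] <- sc[["above"]]
    }
    sb <- sbs[key]; su <- sus[key]
    S <- ifelse(below, sb, su)          # column-major recycling keys sb/su by row
    W <- exp(-abs(D) / S) / (2 * S)     # Laplace density incl. side prefactor
    if (spec$name == "dl_naive") {
      pr <- W[rows] / rowSums(W)
    } else {
      kk <- ifelse(last == "none", 0.5, params[["k"]])
      sum_b <- rowSums(W * below)
      sum_a <- rowSums(W) - sum_b
      kk[sum_b == 0] <- 0
      pr <- ifelse(below[rows], kk * W[rows] / sum_b, (1 - kk) * W[rows] / sum_a)
    }
  }
  ll <- log(pr)
  low <- !is.finite(ll) | ll < LOGLIK_FLOOR
  bump_floor_count(sum(low))
  ll[low] <- LOGLIK_FLOOR
  ll
}

# initial conditions derived from the dataset (the study's convention)
default_init <- function(spec, data, init = NULL) {
  if (spec$family == "null") return(NULL)
  if (!is.null(init)) {
    if (inherits(init, "beta_prior"))
      init <- stats::setNames(rep(list(init), 3), market_labels())
    if (is.numeric(init) && is.null(names(init)) && length(init) == 3)
      names(init) <- market_labels()
    return(init)
  }
  if (spec$family == "dl") return(first_bid_means(data))
  first <- lapply(market_labels(), function(m) {
    bids <- unlist(lapply(split_subjects(data), function(s) {
      sm <- s[s$market == m & !is.na(s$entered) & s$entered & !is.na(s$bid), ,
              drop = FALSE]
      if (!nrow(sm)) return(NULL)
      sm$bid[which.min(sm$trial_in_market)]
    }))
    if (length(bids) >= 3) fit_beta_prior(bids) else beta_prior(2, 2, 10)
  })
  stats::setNames(first, market_labels())
}

# ---- fast per-subject likelihoods (vectorized over trials) ----------------

nll_subject <- function(spec, params, prep, init) {
  switch(spec$family,
    null = {
      n <- sum(vapply(prep, function(p) length(p$bid), integer(1)))
      n * log(101)
    },
    dl = nll_subject_dl(spec, params, prep, init),
    rl = nll_subject_rl(spec, params, prep, init)
  )
}

# DL: the preferred-bid trajectory depends only on the recorded outcomes,
# so it is rolled forward first and the per-trial choice likelihoods are
# then evaluated in one vectorized pass
nll_subject_dl <- function(spec, params, prep, init) {
  traj <- dl_trajectory(spec, params, prep, init)
  if (!length(traj$A_pre)) return(0)
  -sum(dl_loglik_rows(spec, params, traj$A_pre, traj$last_pre, traj$bid_idx))
}

# pre-update preferred bid, outcome memory and choices of one subject,
# stacked across markets (used by the likelihood and by enactment checks)
dl_trajectory <- function(spec, params, prep, init) {
  A_pre <- last_pre <- bid <- bid_idx <- acc <- rew <- market <- row <- NULL
  for (m in market_labels()) {
    p <- prep[[m]]
    nt <- length(p$bid)
    if (!nt) next
    A <- unname(init[[m]]); last <- "none"
    Av <- numeric(nt); Lv <- character(nt)
    for (t in seq_len(nt)) {
      Av[t] <- A; Lv[t] <- last
      if (spec$name == "dl_naive") {
        A <- if (p$accepted[t]) A - params[["n_up"]] else A + params[["n_down"]]
      } else {
        A <- if (p$accepted[t]) A + params[["alpha"]] * min(0, p$bid[t] - A)
             else A + params[["alpha"]] * (10 - A)
      }
      A <- min(10, max(0, A))
      last <- if (p$accepted[t]) "accepted" else "rejected"
    }
    A_pre <- c(A_pre, Av); last_pre <- c(last_pre, Lv)
    bid <- c(bid, p$bid); bid_idx <- c(bid_idx, p$bid_idx)
    acc <- c(acc, p$accepted); rew <- c(rew, p$reward)
    market <- c(market, rep(m, nt)); row <- c(row, p$row)
  }
  list(A_pre = A_pre, last_pre = last_pre, bid = bid, bid_idx = bid_idx,
       accepted = acc, reward = rew, market = market, row = row)
}

nll_subject_rl <- function(spec, params, prep, init) {
  alpha <- params[["alpha"]]; beta <- params[["beta"]]
  g <- bid_grid()
  tiles <- tile_of_grid(); sizes <- tile_sizes()
  at <- if (spec$name == "rw_coarse") tile_centres() else g
  nll <- 0; nfloor <- 0L
  for (m in market_labels()) {
    p <- prep[[m]]
    nt <- length(p$bid)
    if (!nt) next
    Q <- beta_prior_values(init[[m]], at)
    for (t in seq_len(nt)) {
      z <- beta * Q
      lse <- {mx <- max(z); mx + log(sum(exp(z - mx)))}
      idx <- p$bid_idx[t]
      if (spec$name == "rw_coarse") {
        j <- tiles[idx]
        ll <- z[j] - lse - log(sizes[j])
        Q[j] <- Q[j] + alpha * (p$reward[t] - Q[j])
      } else {
        ll <- z[idx] - lse
        if (spec$name == "counterfactual_rl") {
          if (p$accepted[t]) {
            sel <- idx:101L
            Q[sel] <- Q[sel] + alpha * ((10 - g[sel]) - Q[sel])
          } else {
            sel <- 1L:idx
            Q[sel] <- Q[sel] + alpha * (0 - Q[sel])
          }
        } else {
          Q[idx] <- Q[idx] + alpha * (p$reward[t] - Q[idx])
        }
      }
      if (!is.finite(ll) || ll < LOGLIK_FLOOR) { ll <- LOGLIK_FLOOR; nfloor <- nfloor + 1L }
      nll <- nll - ll
    }
  }
  bump_floor_count(nfloor)
  nll
}

# ---- BIC -------------------------------------------------------------------

#' Bayesian information criterion
#'
#' `2 * nll + n_params * log(n_obs)`, with `n_obs` the number of entered
#' bid trials contributing to the likelihood.
#'
#' @param nll_total Total negative log-likelihood.
#' @param n_params Number of free parameters.
#' @param n_obs Number of observations (>= 1).
#' @return The BIC score.
#' @export
bic_score <- function(nll_total, n_params, n_obs) {
  if (n_obs < 1) stop("bic_score: n_obs must be >= 1")
  2 * nll_total + n_params * log(n_obs)
}

n_bid_trials <- function(data) {
  sum(!is.na(data$entered) & data$entered & !is.na(data$bid))
}

# ---- basin-hopping bounded optimization -----------------------------------

#' Optimizer control for model fitting
#'
#' Bounded local quasi-Newton (L-BFGS-B) runs are wrapped in a
#' basin-hopping loop: after the seeded initial run, each hop perturbs the
#' current position by up to 10% of every parameter's bound range, runs a
#' fresh local minimization, and accepts or rejects the move by a
#' Metropolis rule at unit temperature; the best minimum ever seen is
#' returned.
#'
#' @param n_hops Number of basin hops after the initial run of each chain
#'   (>= 0; the default 10 matches the fitting procedure's minimum).
#' @param maxit Maximum L-BFGS-B iterations per local run.
#' @param factr L-BFGS-B convergence tolerance factor.
#' @param seed Integer seed making the whole fit deterministic.
#' @param restarts Independent basin-hopping chains from fresh random
#'   starts; the best minimum across chains is kept.
#' @return List of class `fit_control`.
#' @export
fit_control <- function(n_hops = 10L, maxit = 200L, factr = 1e8, seed = 1L,
                        restarts = 2L) {
  structure(list(n_hops = as.integer(n_hops), maxit = as.integer(maxit),
                 factr = factr, seed = as.integer(seed),
                 restarts = max(1L, as.integer(restarts))),
            class = "fit_control")
}

# minimize fn over a box with basin hopping; RNG already seeded by caller
basinhop <- function(fn, lower, upper, control) {
  np <- length(lower)
  localmin <- function(par) {
    res <- tryCatch(
      stats::optim(par, fn, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = control$maxit, factr = control$factr)),
      error = function(e) list(par = par, value = fn(par), convergence = 99L))
    if (!is.finite(res$value)) res$value <- Inf
    res
  }
  step <- 0.1 * (upper - lower)
  best <- NULL
  for (chain in seq_len(control$restarts)) {
    start <- lower + stats::runif(np) * (upper - lower)
    cur <- localmin(start)
    if (is.null(best) || cur$value < best$value) best <- cur
    for (h in seq_len(control$n_hops)) {
      cand0 <- cur$par + stats::runif(np, -1, 1) * step
      cand0 <- pmin(pmax(cand0, lower), upper)
      cand <- localmin(cand0)
      if (cand$value < best$value) best <- cand
      if (cand$value <= cur$value ||
          stats::runif(1) < exp(cur$value - cand$value)) cur <- cand
    }
  }
  # polish the best basin to a tight gradient tolerance
  pol <- tryCatch(
    stats::optim(best$par, fn, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500L, factr = 1e3, pgtol = 1e-8,
                                ndeps = rep(1e-6, np))),
    error = function(e) best)
  if (is.finite(pol$value) && pol$value <= best$value + 1e-10) best <- pol
  best
}

# projected finite-difference gradient norm at a box-constrained optimum
projected_grad_norm <- function(fn, par, lower, upper, h = 1e-5) {
  g <- vapply(seq_along(par), function(i) {
    hi <- pmin(par[i] + h, upper[i]); lo <- pmax(par[i] - h, lower[i])
    if (hi == lo) return(0)
    pu <- par; pu[i] <- hi; pl <- par; pl[i] <- lo
    (fn(pu) - fn(pl)) / (hi - lo)
  }, numeric(1))
  at_lo <- par <= lower + 1e-9
  at_hi <- par >= upper - 1e-9
  g[at_lo & g > 0] <- 0      # pushing outward against an active bound
  g[at_hi & g < 0] <- 0
  sqrt(sum(g^2))
}

# ---- the fitting front end -------------------------------------------------

#' Fit a bid-learning model by maximum likelihood
#'
#' Fits one of the registered models to an event dataset by minimizing the
#' aggregated negative log-likelihood, either with one parameter vector
#' yoked across all subjects (`mode = "ffx"`, the aggregated fixed-effects
#' likelihood) or separately per subject (`mode = "rfx"`; subjects whose
#' optimizer run converges — success flag and projected gradient norm below
#' 1e-5 — enter the reported mean and SEM). Optimization is bounded
#' L-BFGS-B wrapped in basin hopping ([fit_control()]).
#'
#' @param model Model name or spec.
#' @param data Dataset (data frame of trials).
#' @param mode `"ffx"` or `"rfx"`.
#' @param control A [fit_control()].
#' @param init Optional initial conditions, as in [bids_nll()].
#' @return Object of class `bidfit`; see [coef.bidfit()], [logLik.bidfit()],
#'   [simulate.bidfit()], [residuals.bidfit()], [plot.bidfit()].
#' @export
fit_bids <- function(model, data, mode = c("ffx", "rfx"),
                     control = fit_control(), init = NULL) {
  spec <- as_model_spec(model)
  mode <- match.arg(mode)
  init <- default_init(spec, data, init)
  subs <- split_subjects(data)
  preps <- lapply(subs, prep_subject)
  n_obs <- n_bid_trials(data)
  if (n_obs == 0) stop("fit_bids: dataset has no entered bid trials")
  np <- length(spec$params)
  n_subj <- length(subs)

  mk_obj <- function(idx) {
    stacked <- stack_preps(preps[idx])
    sub <- preps[idx]
    function(par) {
      names(par) <- spec$params
      sum(nll_preps(spec, par, sub, init, stacked = stacked))
    }
  }

  fit <- list(model = spec, mode = mode, n_obs = n_obs, n_subjects = n_subj,
              init = init, control = control, data = data, call = match.call())

  if (np == 0L) {
    fit$par <- stats::setNames(numeric(0), character(0))
    fit$nll_by_subject <- vapply(preps, function(p)
      nll_subject(spec, numeric(0), p, init), numeric(1))
    fit$nll_total <- sum(fit$nll_by_subject)
    fit$convergence <- 0L
  } else if (mode == "ffx") {
    obj <- mk_obj(seq_len(n_subj))
    res <- with_preserved_seed(control$seed, basinhop(obj, spec$lower, spec$upper, control))
    fit$par <- stats::setNames(res$par, spec$params)
    fit$nll_total <- res$value
    fit$nll_by_subject <- bids_nll(spec, fit$par, data, init = init)$by_subject
    fit$convergence <- res$convergence
  } else {
    pm <- matrix(NA_real_, n_subj, np, dimnames = list(names(subs), spec$params))
    nlls <- numeric(n_subj); conv <- logical(n_subj)
    for (s in seq_len(n_subj)) {
      obj <- mk_obj(s)
      res <- with_preserved_seed(derive_seed(control$seed, s, salt = 9L),
                                 basinhop(obj, spec$lower, spec$upper, control))
      pm[s, ] <- res$par
      nlls[s] <- res$value
      conv[s] <- identical(res$convergence, 0L) &&
        projected_grad_norm(obj, res$par, spec$lower, spec$upper) <= 1e-5
    }
    fit$par_by_subject <- pm
    fit$converged <- conv
    fit$par <- colMeans(pm[conv, , drop = FALSE])
    fit$par_sem <- apply(pm[conv, , drop = FALSE], 2, stats::sd) /
      sqrt(max(sum(conv), 1))
    fit$nll_by_subject <- nlls
    fit$nll_total <- sum(nlls)
  }
  fit$bic_total <- bic_score(fit$nll_total, np, n_obs)
  fit$bic_per_subject <- fit$bic_total / n_subj
  fit$nll_per_subject <- fit$nll_total / n_subj
  class(fit) <- "bidfit"
  fit
}

# ---- ranking ---------------------------------------------------------------

#' Fit and rank competing models by BIC
#'
#' Fits every requested model to the same dataset and ranks them by total
#' BIC (ascending), reporting per-subject NLL and BIC and the class-average
#' BICs for the directional-learning (DL) and reinforcement-learning (RL)
#' families.
#'
#' @param data Dataset.
#' @param models Character vector of model names, or `"all"`.
#' @param mode `"ffx"` or `"rfx"`.
#' @param control A [fit_control()].
#' @param init Optional family-specific initial conditions: a list with
#'   elements `dl` (per-market initial preferred bids) and/or `rl` (a
#'   [beta_prior()] or per-market list of priors); families without an
#'   entry use the data-derived defaults.
#' @return A data frame of class `bidrank` with one row per model, the
#'   fitted `bidfit` objects in `attr(, "fits")` and the class averages in
#'   `attr(, "class_bic")`.
#' @export
rank_bid_models <- function(data, models = "all", mode = "ffx",
                            control = fit_control(), init = NULL) {
  if (identical(models, "all")) models <- list_bid_models()
  if (length(models) < 2) stop("rank_bid_models: need at least 2 models")
  fits <- lapply(models, function(m)
    fit_bids(m, data, mode = mode,
             control = fit_control(control$n_hops, control$maxit,
                                   control$factr,
                                   derive_seed(control$seed, match(m, models),
                                               salt = 11L),
                                   restarts = control$restarts),
             init = init[[bid_model(m)$family]]))
  names(fits) <- models
  tab <- data.frame(
    model = models,
    class = vapply(models, model_class, character(1)),
    n_params = vapply(fits, function(f) length(f$model$params), integer(1)),
    nll_total = vapply(fits, function(f) f$nll_total, numeric(1)),
    nll_per_subject = vapply(fits, function(f) f$nll_per_subject, numeric(1)),
    bic_total = vapply(fits, function(f) f$bic_total, numeric(1)),
    bic_per_subject = vapply(fits, function(f) f$bic_per_subject, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab$rank <- rank(tab$bic_total, ties.method = "first")
  tab <- tab[order(tab$rank), ]
  class_bic <- tapply(tab$bic_total[tab$class != "null"],
                      tab$class[tab$class != "null"], mean)
  structure(tab, fits = fits, class_bic = class_bic, mode = mode,
            class = c("bidrank", "data.frame"))
}

# ---- parameter recovery ----------------------------------------------------

#' Simulate-and-refit parameter recovery
#'
#' Repeatedly simulates a cohort from a model at known parameters and
#' refits it by fixed-effects maximum likelihood, reporting per-parameter
#' bias, RMSE and the empirical 95% interval of the estimates.
#'
#' @param model Model name or spec.
#' @param true_params Generating parameters (named, within bounds).
#' @param config A [cohort_config()]; its model/params fields are replaced.
#' @param n_reps Number of simulate-fit replicates.
#' @param seed Master seed.
#' @param control A [fit_control()] for the refits.
#' @return List with `estimates` (n_reps x n_params matrix) and `summary`
#'   (data frame: parameter, true, mean, bias, rmse, sd, q2.5, q97.5).
#' @export
recover_parameters <- function(model, true_params, config = cohort_config(),
                               n_reps = 5L, seed = 1L,
                               control = fit_control()) {
  spec <- as_model_spec(model)
  true_params <- check_params(spec, true_params)
  config$model <- spec
  config$params <- true_params
  est <- matrix(NA_real_, n_reps, length(spec$params),
                dimnames = list(NULL, spec$params))
  for (r in seq_len(n_reps)) {
    dat <- simulate_cohort(config, seed = derive_seed(seed, r, salt = 13L))
    f <- fit_bids(spec, dat, mode = "ffx",
                  control = fit_control(control$n_hops, control$maxit,
                                        control$factr,
                                        derive_seed(seed, r, salt = 17L),
                                        restarts = control$restarts))
    est[r, ] <- f$par
  }
  summ <- data.frame(
    parameter = spec$params,
    true = unname(true_params),
    mean = colMeans(est),
    bias = colMeans(est) - unname(true_params),
    rmse = sqrt(colMeans((est - matrix(true_params, n_reps,
                                       length(true_params), byrow = TRUE))^2)),
    sd = apply(est, 2, stats::sd),
    q2.5 = apply(est, 2, stats::quantile, 0.025),
    q97.5 = apply(est, 2, stats::quantile, 0.975),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(estimates = est, summary = summ)
}
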