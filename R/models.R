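#' The model registry
#'
#' Seven models of trial-by-trial bid learning are implemented. Two families
#' plus a benchmark:
#'
#' * **Reinforcement learning (RL)** — an action-value vector per market,
#'   softmax policy with inverse temperature `beta`:
#'   `rw_coarse` (Rescorla-Wagner delta rule on an 11-tile binning of the
#'   grid), `rw_fine` (the same on the native 101-point grid) and
#'   `counterfactual_rl` (model-based: acceptance of bid *b* also updates
#'   every bid *i >= b* toward its counterfactual payoff `10 - i`; rejection
#'   updates every *i <= b* toward 0).
#' * **Directional learning (DL)** — a single continuous preferred bid `A`
#'   per market, nudged by the previous outcome: `dl_gauss` (delta rule on
#'   the preferred-bid value, Gaussian choice noise), `dl_naive` (fixed
#'   nudges `n_up`/`n_down`, asymmetric two-sided Laplace noise) and
#'   `dl_lepto` (delta rule plus asymmetric Laplace noise with an
#'   explorative-mass parameter `k`).
#' * **`null`** — uniform over the 101 bids, zero free parameters.
#'
#' @param name Model name.
#' @return `bid_model()` returns a model spec: list with `name`, `family`
#'   (`"rl"`, `"dl"` or `"null"`), `params`, `lower`, `upper`.
#' @export
#' @examples
#' bid_model("dl_lepto")$params
#' list_bid_models()
bid_model <- function(name) {
  name <- match.arg(name, list_bid_models())
  spec <- switch(name,
    rw_coarse = list(family = "rl",
      params = c("alpha", "beta"), lower = c(0, 0), upper = c(1, 50)),
    rw_fine = list(family = "rl",
      params = c("alpha", "beta"), lower = c(0, 0), upper = c(1, 50)),
    counterfactual_rl = list(family = "rl",
      params = c("alpha", "beta"), lower = c(0, 0), upper = c(1, 50)),
    dl_gauss = list(family = "dl",
      params = c("alpha", "sigma"), lower = c(0, 0.01), upper = c(1, 10)),
    dl_naive = list(family = "dl",
      params = c("n_up", "n_down", "sigma_a", "sigma_r"),
      lower = c(0, 0, 0.01, 0.01), upper = c(5, 5, 10, 10)),
    dl_lepto = list(family = "dl",
      params = c("alpha", "sigma_a", "sigma_r", "sigma_0", "k"),
      lower = c(0, 0.01, 0.01, 0.01, 0), upper = c(1, 10, 10, 10, 1)),
    null = list(family = "null",
      params = character(0), lower = numeric(0), upper = numeric(0))
  )
  spec$name <- name
  names(spec$lower) <- names(spec$upper) <- spec$params
  class(spec) <- "bid_model_spec"
  spec
}

#' @rdname bid_model
#' @export
list_bid_models <- function() {
  c("rw_coarse", "rw_fine", "counterfactual_rl",
    "dl_gauss", "dl_naive", "dl_lepto", "null")
}

#' @rdname bid_model
#' @param model A `bid_model_spec` or model name.
#' @export
model_class <- function(model) {
  spec <- as_model_spec(model)
  switch(spec$family, rl = "RL", dl = "DL", null = "null")
}

as_model_spec <- function(model) {
  if (inherits(model, "bid_model_spec")) model else bid_model(model)
}

check_params <- function(spec, params) {
  spec <- as_model_spec(spec)
  if (!length(spec$params)) return(numeric(0))
  if (is.null(names(params))) {
    if (length(params) != length(spec$params))
      stop(spec$name, ": expected ", length(spec$params), " parameters")
    names(params) <- spec$params
  }
  params <- params[spec$params]
  if (anyNA(params))
    stop(spec$name, ": missing parameter(s); expected ",
         paste(spec$params, collapse = ", "))
  out <- params < spec$lower - 1e-12 | params > spec$upper + 1e-12
  if (any(out))
    stop(spec$name, ": parameter(s) out of bounds: ",
         paste(spec$params[out], collapse = ", "))
  params
}

# ---- Beta prior on initial action values ----------------------------------

#' Beta-shaped prior on initial action values
#'
#' RL agents start from a prior action-value curve shaped like a Beta
#' density with its support rescaled from \[0, 1\] to the 0-10 MU bid range
#' and its range rescaled so that the maximum prior value equals the
#' amplitude `c` (in MU): `Q0(i) = c * f(i/10; a, b) / max f`.
#'
#' @param a,b Beta shape parameters (> 0).
#' @param c Amplitude in MU; the prior's maximum value. Default 10.
#' @return Object of class `beta_prior`.
#' @export
beta_prior <- function(a, b, c = 10) {
  if (a <= 0 || b <= 0) stop("beta_prior: shapes must be positive")
  structure(list(a = a, b = b, c = c), class = "beta_prior")
}

#' @rdname beta_prior
#' @param prior A `beta_prior`.
#' @param at Bid values (MU) at which to evaluate the prior.
#' @return `beta_prior_values()` returns the prior action values at `at`.
#' @export
beta_prior_values <- function(prior, at) {
  # clamp support points off the endpoints, where the density can be 0 or Inf
  x <- pmin(pmax(at / 10, 1e-3), 1 - 1e-3)
  d <- stats::dbeta(x, prior$a, prior$b)
  prior$c * d / max(d)
}

#' Fit a Beta prior to first-trial bids
#'
#' Maximum-likelihood fit of the two Beta shapes to a sample of bids
#' rescaled to \[0, 1\] (values clamped 1e-3 away from the endpoints). A
#' degenerate sample (near-zero variance) falls back to moment matching
#' with the variance floored at 1e-4.
#'
#' @param first_bids Numeric sample of bids in \[0, 10\], length >= 3.
#' @param c Amplitude of the resulting prior, default 10 MU.
#' @return A [beta_prior()].
#' @export
fit_beta_prior <- function(first_bids, c = 10) {
  if (length(first_bids) < 3) stop("fit_beta_prior: need at least 3 bids")
  if (any(first_bids < 0 | first_bids > 10))
    stop("fit_beta_prior: bids must lie in [0, 10]")
  x <- pmin(pmax(first_bids / 10, 1e-3), 1 - 1e-3)
  mm <- beta_moment_match(x)
  est <- tryCatch({
    f <- suppressWarnings(MASS::fitdistr(
      x, "beta", start = list(shape1 = mm[1], shape2 = mm[2]),
      lower = c(1e-2, 1e-2)))
    unname(f$estimate)
  }, error = function(e) mm)
  beta_prior(est[1], est[2], c)
}

beta_moment_match <- function(x) {
  m <- mean(x)
  v <- max(stats::var(x), 1e-4)
  v <- min(v, 0.9 * m * (1 - m))        # keep shapes positive
  k <- m * (1 - m) / v - 1
  c(max(m * k, 1e-2), max((1 - m) * k, 1e-2))
}

# ---- 11-tile binning of the grid ------------------------------------------

# tile j (j = 0..10) holds grid bids rounding half-up to j MU:
# sizes 5, 10 x 9, 6 (sums to 101)
tile_of_grid <- function() as.integer(floor(bid_grid() + 0.5)) + 1L
tile_sizes <- function() tabulate(tile_of_grid(), 11L)
tile_centres <- function() 0:10

# ---- agent state -----------------------------------------------------------

#' Initialize an agent's state
#'
#' RL models start from per-market action-value vectors evaluated from a
#' Beta prior at the bin centres (11 tiles for `rw_coarse`, the 101 grid
#' points otherwise). DL models start from per-market initial preferred
#' bids (the task's observed pooled first-trial means by default) with no
#' outcome history.
#'
#' @param model Model name or spec.
#' @param params Named parameter vector, within bounds.
#' @param init For RL models a [beta_prior()] (recycled across markets) or
#'   a named list of per-market priors; for DL models a named numeric vector
#'   of initial preferred bids. Defaults: `beta_prior(2, 2, 10)` and
#'   `c(SC = 4.96, NC = 5.13, BC = 6.55)`.
#' @return Object of class `agent_state`.
#' @export
init_state <- function(model, params = numeric(0), init = NULL) {
  spec <- as_model_spec(model)
  params <- check_params(spec, params)
  st <- list(model = spec, params = params)
  if (spec$family == "rl") {
    if (is.null(init)) init <- beta_prior(2, 2, 10)
    priors <- if (inherits(init, "beta_prior"))
      stats::setNames(rep(list(init), 3), market_labels()) else init
    at <- if (spec$name == "rw_coarse") tile_centres() else bid_grid()
    st$Q <- lapply(priors[market_labels()],
                   function(p) beta_prior_values(p, at))
  } else if (spec$family == "dl") {
    if (is.null(init)) init <- c(SC = 4.96, NC = 5.13, BC = 6.55)
    if (is.null(names(init)) && length(init) == 3) names(init) <- market_labels()
    if (!all(market_labels() %in% names(init)))
      stop("init_state: DL initial bids must be named SC, NC, BC")
    if (any(init < 0 | init > 10))
      stop("init_state: initial preferred bids must lie in [0, 10]")
    st$A <- init[market_labels()]
    st$last <- stats::setNames(rep("none", 3), market_labels())
  }
  class(st) <- "agent_state"
  st
}

# ---- policies --------------------------------------------------------------

# numerically stable softmax
softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# side scales and below-A mass of the leptokurtic policies, by last outcome.
# dl_naive: sides keyed to acceptance (below) / rejection (above) scales;
# neutral = their mean; mass follows the renormalized two-sided density.
# dl_lepto: outcome-matched side uses its own scale, the other side the
# neutral sigma_0; mass k strictly below A (explorative, profit-seeking
# side for a buyer), 1 - k at or above; first trial k = 0.5.
dl_side_scales <- function(spec, params, last) {
  if (spec$name == "dl_naive") {
    s0 <- mean(c(params[["sigma_a"]], params[["sigma_r"]]))
    switch(last,
      none = c(below = s0, above = s0),
      accepted = c(below = params[["sigma_a"]], above = params[["sigma_r"]]),
      rejected = c(below = params[["sigma_a"]], above = params[["sigma_r"]]))
  } else { # dl_lepto
    switch(last,
      none = c(below = params[["sigma_0"]], above = params[["sigma_0"]]),
      accepted = c(below = params[["sigma_a"]], above = params[["sigma_0"]]),
      rejected = c(below = params[["sigma_0"]], above = params[["sigma_r"]]))
  }
}

#' Policy distribution over the bid grid
#'
#' Returns the probability the agent assigns to each of the 101 grid bids
#' in the given market. RL models: softmax with inverse temperature `beta`
#' over bin values; a grid bid's probability is its bin's probability
#' divided by the bin's grid-point count. `dl_gauss`: Gaussian density
#' centred at the preferred bid, evaluated at the grid points and
#' renormalized. `dl_naive`: two-sided Laplace with side-specific scales,
#' renormalized. `dl_lepto`: mixture placing total mass `k` on grid bids
#' strictly below the preferred bid and `1 - k` at or above it, each side
#' following its Laplace density renormalized within the side (an empty
#' side's mass goes to the other side).
#'
#' @param state An [init_state()] agent state (possibly evolved).
#' @param market Market label.
#' @return Probability vector of length 101 summing to 1.
#' @export
policy_probs <- function(state, market) {
  if (!inherits(state, "agent_state")) stop("policy_probs: uninitialized state")
  spec <- state$model
  market <- match.arg(market, market_labels())
  p <- state$params
  if (spec$family == "null") return(rep(1 / 101, 101))
  if (spec$family == "rl") {
    pb <- softmax(p[["beta"]] * state$Q[[market]])
    if (spec$name == "rw_coarse") return(pb[tile_of_grid()] / tile_sizes()[tile_of_grid()])
    return(pb)
  }
  A <- state$A[[market]]
  g <- bid_grid()
  if (spec$name == "dl_gauss") {
    w <- exp(-(g - A)^2 / (2 * p[["sigma"]]^2))
    return(w / sum(w))
  }
  sc <- dl_side_scales(spec, p, state$last[[market]])
  below <- g < A
  w <- numeric(101)
  # Laplace densities with per-side scales; the 1/(2*sigma) prefactor sets
  # the relative side masses for dl_naive (it cancels within dl_lepto sides)
  w[below] <- exp(-(A - g[below]) / sc[["below"]]) / (2 * sc[["below"]])
  w[!below] <- exp(-(g[!below] - A) / sc[["above"]]) / (2 * sc[["above"]])
  if (spec$name == "dl_naive") return(w / sum(w))
  kk <- if (state$last[[market]] == "none") 0.5 else p[["k"]]
  if (!any(below)) kk <- 0          # A at the bottom of the grid: one side only
  out <- numeric(101)
  if (any(below)) out[below] <- kk * w[below] / sum(w[below])
  out[!below] <- (1 - kk) * w[!below] / sum(w[!below])
  out
}

# ---- update rules ----------------------------------------------------------

#' Advance an agent's state by one observed trial
#'
#' Applies the model's learning rule for a single entered trial and returns
#' the new state. RL models update action values with the delta rule
#' (`rw_*`: the chosen bin only; `counterfactual_rl`: the acceptance-implied
#' region of the grid toward counterfactual payoffs). DL models move the
#' preferred bid `A`: the delta-rule models (`dl_gauss`, `dl_lepto`) track
#' the preferred-bid value `V = 10 - A` asymmetrically — good news on
#' acceptance raises it, `V <- V + alpha * max(0, r - V)`, so an accepted
#' bid undercutting `A` pulls `A` down to it and acceptance never raises
#' `A`; rejection decays it, `V <- (1 - alpha) * V`, pushing `A` toward 10.
#' `dl_naive` applies fixed nudges: `A - n_up` on acceptance, `A + n_down`
#' on rejection. `A` is clamped to \[0, 10\] and the outcome is remembered
#' for the next trial's policy asymmetry.
#'
#' @inheritParams policy_probs
#' @param bid Chosen grid bid.
#' @param accepted Logical outcome.
#' @param reward Reward in MU; must equal `10 - bid` if accepted, else 0.
#' @return The updated `agent_state`.
#' @export
update_state <- function(state, market, bid, accepted, reward) {
  spec <- state$model
  market <- match.arg(market, market_labels())
  idx <- bid_index(bid)
  expected <- if (accepted) 10 - bid else 0
  if (abs(reward - expected) > 1e-9)
    stop("update_state: reward inconsistent with the acceptance rule")
  p <- state$params
  if (spec$family == "null") return(state)
  if (spec$family == "rl") {
    Q <- state$Q[[market]]
    if (spec$name == "counterfactual_rl") {
      g <- bid_grid()
      if (accepted) {
        sel <- idx:101L                       # i >= b would also be accepted
        Q[sel] <- Q[sel] + p[["alpha"]] * ((10 - g[sel]) - Q[sel])
      } else {
        sel <- 1L:idx                         # i <= b would also be rejected
        Q[sel] <- Q[sel] + p[["alpha"]] * (0 - Q[sel])
      }
    } else {
      j <- if (spec$name == "rw_coarse") tile_of_grid()[idx] else idx
      Q[j] <- Q[j] + p[["alpha"]] * (reward - Q[j])
    }
    state$Q[[market]] <- Q
    return(state)
  }
  A <- state$A[[market]]
  if (spec$name == "dl_naive") {
    A <- if (accepted) A - p[["n_up"]] else A + p[["n_down"]]
  } else {
    A <- if (accepted) A + p[["alpha"]] * min(0, bid - A)
         else A + p[["alpha"]] * (10 - A)
  }
  state$A[[market]] <- min(10, max(0, A))
  state$last[[market]] <- if (accepted) "accepted" else "rejected"
  state
}

# ---- log-likelihood of a single bid ---------------------------------------

# probabilities below exp(LOGLIK_FLOOR) are floored so degenerate scale
# parameters cannot yield -Inf objectives
LOGLIK_FLOOR <- -745

.bl_env <- new.env(parent = emptyenv())
.bl_env$floor_count <- 0L

#' @rdname log_lik_bid
#' @export
loglik_floor_count <- function() .bl_env$floor_count

#' @rdname log_lik_bid
#' @export
reset_loglik_floor_count <- function() {
  .bl_env$floor_count <- 0L
  invisible(0L)
}

bump_floor_count <- function(n) {
  if (n > 0L) .bl_env$floor_count <- .bl_env$floor_count + as.integer(n)
}

#' Log-likelihood of one bid under a model's policy
#'
#' The log of the grid bid's probability under [policy_probs()]; the null
#' model returns `-log(101)` for every bid. A zero-probability bid returns
#' the floored value -745 (the smallest log a double's probability can
#' carry) and increments a package-level counter, queryable with
#' `loglik_floor_count()` and cleared with `reset_loglik_floor_count()`.
#'
#' @inheritParams update_state
#' @return A single log-probability.
#' @export
log_lik_bid <- function(state, market, bid) {
  idx <- bid_index(bid)
  if (state$model$family == "null") return(-log(101))
  pr <- policy_probs(state, market)[idx]
  ll <- log(pr)
  if (!is.finite(ll) || ll < LOGLIK_FLOOR) {
    bump_floor_count(1L)
    ll <- LOGLIK_FLOOR
  }
  ll
}
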