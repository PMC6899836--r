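#' Market discrimination index
#'
#' Difference between a subject's mean bid in the buyer-competition market
#' and in the seller-competition market: `mean(BC bids) - mean(SC bids)`.
#' Buyers who discriminate markets more sharply bid higher under buyer
#' competition and lower under seller competition.
#'
#' @param session One subject's trials (data frame).
#' @return MDI in MU.
#' @export
mdi <- function(session) {
  bc <- session$bid[session$market == "BC" & !is.na(session$bid)]
  sc <- session$bid[session$market == "SC" & !is.na(session$bid)]
  if (!length(bc) || !length(sc))
    stop("mdi: need at least one bid in each of BC and SC")
  mean(bc) - mean(sc)
}

#' Directional-learning compliance
#'
#' For every bid trial with a preceding bid trial in the same market
#' (lottery-skipped trials are skipped over), the bid change
#' `db = b_t - b_{t-1}` is compliant with directional learning when the
#' previous bid was accepted and `db <= 0`, or rejected and `db >= 0`
#' (repeats count as compliant under both outcomes). Returns the compliant
#' fraction overall and split by the previous outcome.
#'
#' @param session One subject's trials.
#' @return List with `overall`, `after_acceptance`, `after_rejection`
#'   (fractions) and the corresponding `n_*` eligible-pair counts.
#' @export
dl_compliance <- function(session) {
  pairs <- eligible_pairs(session)
  if (!nrow(pairs)) stop("dl_compliance: no eligible trial pairs")
  comp <- ifelse(pairs$prev_accepted, pairs$db <= 0, pairs$db >= 0)
  acc <- pairs$prev_accepted
  list(
    overall = mean(comp),
    after_acceptance = if (any(acc)) mean(comp[acc]) else NA_real_,
    after_rejection = if (any(!acc)) mean(comp[!acc]) else NA_real_,
    n_pairs = nrow(pairs), n_after_acceptance = sum(acc),
    n_after_rejection = sum(!acc)
  )
}

# consecutive entered-bid-trial pairs within subject and market
eligible_pairs <- function(data) {
  out <- list()
  for (s in split_subjects(data)) {
    prep <- prep_subject(s)
    for (m in market_labels()) {
      p <- prep[[m]]
      nt <- length(p$bid)
      if (nt < 2) next
      out[[length(out) + 1L]] <- data.frame(
        subject_id = rep(s$subject_id[1], nt - 1L), market = m,
        db = diff(p$bid), prev_accepted = p$accepted[-nt],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(subject_id = character(0), market = character(0),
                      db = numeric(0), prev_accepted = logical(0)))
  do.call(rbind, out)
}

#' Transaction rates and profit
#'
#' `transaction_rates()` returns the fraction of entered trials accepted,
#' per market; `profit()` the summed reward of a session (MU).
#'
#' @param data Dataset.
#' @return Named numeric vector of per-market acceptance fractions, with
#'   counts in `attr(, "counts")`.
#' @export
transaction_rates <- function(data) {
  ent <- !is.na(data$entered) & data$entered & !is.na(data$bid)
  counts <- t(vapply(market_labels(), function(m) {
    e <- sum(ent & data$market == m)
    a <- sum(ent & data$market == m & !is.na(data$accepted) & data$accepted)
    c(accepted = a, entered = e)
  }, numeric(2)))
  rates <- counts[, "accepted"] / counts[, "entered"]
  attr(rates, "counts") <- counts
  rates
}

#' @rdname transaction_rates
#' @param session One subject's trials.
#' @export
profit <- function(session) sum(session$reward, na.rm = TRUE)

#' First-bid summary and one-way ANOVA
#'
#' Compares each subject's first entered bid across the three markets:
#' group means and the standard one-way F statistic with (k-1, N-k)
#' degrees of freedom (via [stats::aov()]).
#'
#' @param data Dataset with >= 2 subjects.
#' @return List with `means` (per market), `F`, `df` and `p`.
#' @export
first_bid_summary <- function(data) {
  subs <- split_subjects(data)
  if (length(subs) < 2) stop("first_bid_summary: need >= 2 subjects")
  rows <- do.call(rbind, lapply(subs, function(s) {
    do.call(rbind, lapply(market_labels(), function(m) {
      sm <- s[s$market == m & !is.na(s$entered) & s$entered & !is.na(s$bid), ,
              drop = FALSE]
      if (!nrow(sm)) return(NULL)
      data.frame(market = m, bid = sm$bid[which.min(sm$trial_in_market)])
    }))
  }))
  if (length(unique(rows$market)) < 3) stop("first_bid_summary: empty market group")
  wvar <- tapply(rows$bid, rows$market, stats::var)
  means <- tapply(rows$bid, rows$market, mean)[market_labels()]
  if (all(wvar == 0) && stats::var(means) > 0)
    stop("first_bid_summary: zero within-group variance, F undefined")
  fit <- stats::aov(bid ~ market, data = rows)
  tab <- summary(fit)[[1]]
  list(means = means,
       F = tab[1, "F value"], df = c(tab[1, "Df"], tab[2, "Df"]),
       p = tab[1, "Pr(>F)"])
}

#' Bid-increment distribution conditioned on the previous outcome
#'
#' Pools the within-market bid changes `db` over all subjects, keeps those
#' following the requested previous outcome, and summarizes them as a
#' fixed 0.1-wide histogram with quartiles and moment skewness.
#'
#' @param data Dataset.
#' @param previous One of `"accepted"`, `"rejected"`, `"all"`.
#' @return List with `db`, `breaks`, `mids`, `counts`, `median`, `q1`,
#'   `q3`, `skewness`, `n`.
#' @export
increment_distribution <- function(data, previous = c("all", "accepted", "rejected")) {
  previous <- match.arg(previous)
  pairs <- eligible_pairs(data)
  db <- switch(previous,
               all = pairs$db,
               accepted = pairs$db[pairs$prev_accepted],
               rejected = pairs$db[!pairs$prev_accepted])
  breaks <- seq(-10.05, 10.05, by = 0.1)
  h <- graphics::hist(db, breaks = breaks, plot = FALSE)
  list(db = db, breaks = breaks, mids = h$mids, counts = h$counts,
       median = stats::median(db),
       q1 = unname(stats::quantile(db, 0.25)),
       q3 = unname(stats::quantile(db, 0.75)),
       skewness = if (length(db) > 2 && stats::sd(db) > 0)
         e1071::skewness(db) else NA_real_,
       n = length(db))
}

#' Per-subject bid-trend slopes
#'
#' Ordinary least-squares slope of bid on within-market trial index for
#' every subject and market, with a group-level one-sample t test of the
#' slopes against zero per market. (A deliberate simplification of a
#' mixed-effects trend model: per-subject OLS plus a group t.)
#'
#' @param data Dataset; every subject needs >= 3 bid trials per market.
#' @return List with `slopes` (subject x market data frame) and `tests`
#'   (per-market t, df, p, mean slope).
#' @export
trend_slopes <- function(data) {
  subs <- split_subjects(data)
  slopes <- do.call(rbind, lapply(subs, function(s) {
    row <- lapply(market_labels(), function(m) {
      sm <- s[s$market == m & !is.na(s$entered) & s$entered & !is.na(s$bid), ,
              drop = FALSE]
      if (nrow(sm) < 3) stop("trend_slopes: need >= 3 bid trials per market")
      if (stats::var(sm$trial_in_market) == 0)
        stop("trend_slopes: constant trial index")
      unname(stats::coef(stats::lm(bid ~ trial_in_market, data = sm))[2])
    })
    data.frame(subject_id = s$subject_id[1],
               SC = row[[1]], NC = row[[2]], BC = row[[3]],
               stringsAsFactors = FALSE)
  }))
  rownames(slopes) <- NULL
  tests <- do.call(rbind, lapply(market_labels(), function(m) {
    x <- slopes[[m]]
    if (length(x) >= 2 && stats::sd(x) > 0) {
      tt <- stats::t.test(x)
      data.frame(market = m, mean_slope = mean(x),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stringsAsFactors = FALSE)
    } else {
      data.frame(market = m, mean_slope = mean(x), t = NA_real_,
                 df = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    }
  }))
  list(slopes = slopes, tests = tests)
}

#' Pearson correlation between per-subject quantities
#'
#' Standard product-moment correlation with `t = r * sqrt((n-2)/(1-r^2))`,
#' `df = n - 2` and the Fisher-z 95% confidence interval (via
#' [stats::cor.test()]).
#'
#' @param x,y Numeric vectors, length >= 3, nonzero variance.
#' @return List with `r`, `t`, `df`, `p`, `ci`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y))
    stop("pearson_r: need paired vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_r: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value,
       ci = if (!is.null(ct$conf.int)) as.numeric(ct$conf.int) else c(NA, NA))
}

#' Posterior-predictive preference curves
#'
#' Re-simulates fitted (or given) agents against fresh opponent pools and
#' averages the tracked quantity — the preferred bid for DL agents, the
#' value-maximizing bin centre for RL agents — within each trial index and
#' market, across subjects and replicates.
#'
#' @param model A `bidfit` or a model name/spec.
#' @param params Parameters (ignored when `model` is a fit).
#' @param config A [cohort_config()] for the simulation environment.
#' @param n_reps Number of replicate cohorts.
#' @param seed Integer seed.
#' @return Data frame: `market`, `trial`, `mean_pref`, `sem`, `n`.
#' @export
posterior_predictive <- function(model, params = NULL, config = NULL,
                                 n_reps = 5L, seed = 1L) {
  if (inherits(model, "bidfit")) {
    params <- model$par
    if (is.null(config)) config <- cohort_config()
    if (model$model$family == "dl") config$init_bids <- model$init
    model <- model$model
  }
  spec <- as_model_spec(model)
  if (is.null(config)) config <- cohort_config()
  config$model <- spec
  config$params <- check_params(spec, params)
  acc <- list()
  for (r in seq_len(n_reps)) {
    dat <- simulate_cohort(config, seed = derive_seed(seed, r, salt = 29L))
    acc[[r]] <- dat[, c("market", "trial_in_market", "state_pref")]
  }
  all <- do.call(rbind, acc)
  agg <- stats::aggregate(state_pref ~ market + trial_in_market, data = all,
                          FUN = function(v) c(mean(v), stats::sd(v) / sqrt(length(v)),
                                              length(v)))
  out <- data.frame(market = agg$market, trial = agg$trial_in_market,
                    mean_pref = agg$state_pref[, 1], sem = agg$state_pref[, 2],
                    n = agg$state_pref[, 3], stringsAsFactors = FALSE)
  out[order(match(out$market, market_labels()), out$trial), ]
}
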