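# Straight-line reimplementation of the replay likelihood, written directly
# from the model definitions with base-R density calls and explicit
# normalization. Shares no code with the package internals; used as the
# independent oracle for the likelihood equivalence checks.

oracle_grid <- seq(0, 10, by = 0.1)

oracle_policy <- function(model, params, A = NULL, last = NULL, Q = NULL) {
  g <- oracle_grid
  if (model == "null") return(rep(1 / 101, 101))
  if (model %in% c("rw_coarse", "rw_fine", "counterfactual_rl")) {
    if (model == "rw_coarse") {
      tile <- floor(g + 0.5) + 1          # half-up rounding to whole MU
      e <- exp(params[["beta"]] * (Q - max(Q)))
      pb <- e / sum(e)
      sizes <- as.vector(table(tile))
      return(pb[tile] / sizes[tile])
    }
    e <- exp(params[["beta"]] * (Q - max(Q)))
    return(e / sum(e))
  }
  if (model == "dl_gauss") {
    w <- stats::dnorm(g, mean = A, sd = params[["sigma"]])
    return(w / sum(w))
  }
  # leptokurtic family: two-sided Laplace with outcome-contingent scales
  if (model == "dl_naive") {
    if (last == "none") {
      sb <- su <- (params[["sigma_a"]] + params[["sigma_r"]]) / 2
    } else {
      sb <- params[["sigma_a"]]; su <- params[["sigma_r"]]
    }
    w <- numeric(101)
    w[g < A] <- stats::dexp((A - g)[g < A], rate = 1 / sb)
    w[g >= A] <- stats::dexp((g - A)[g >= A], rate = 1 / su)
    return(w / sum(w))
  }
  # dl_lepto
  sb <- if (identical(last, "accepted")) params[["sigma_a"]] else params[["sigma_0"]]
  su <- if (identical(last, "rejected")) params[["sigma_r"]] else params[["sigma_0"]]
  k <- if (identical(last, "none")) 0.5 else params[["k"]]
  below <- g < A
  p <- numeric(101)
  if (any(below)) {
    wb <- stats::dexp(A - g[below], rate = 1 / sb)
    p[below] <- k * wb / sum(wb)
  } else k <- 0
  wa <- stats::dexp(g[!below] - A, rate = 1 / su)
  p[!below] <- (1 - k) * wa / sum(wa)
  p
}

oracle_update <- function(model, params, A = NULL, Q = NULL, bid, accepted, reward) {
  if (model %in% c("rw_coarse", "rw_fine")) {
    j <- if (model == "rw_coarse") floor(bid + 0.5) + 1 else round(bid * 10) + 1
    Q[j] <- Q[j] + params[["alpha"]] * (reward - Q[j])
    return(Q)
  }
  if (model == "counterfactual_rl") {
    g <- oracle_grid
    if (accepted) {
      sel <- g >= bid - 1e-12
      Q[sel] <- Q[sel] + params[["alpha"]] * ((10 - g[sel]) - Q[sel])
    } else {
      sel <- g <= bid + 1e-12
      Q[sel] <- Q[sel] * (1 - params[["alpha"]])
    }
    return(Q)
  }
  if (model == "dl_naive") {
    A <- if (accepted) A - params[["n_up"]] else A + params[["n_down"]]
  } else {
    A <- if (accepted) A + params[["alpha"]] * min(0, bid - A)
         else A + params[["alpha"]] * (10 - A)
  }
  min(10, max(0, A))
}

# full replay NLL; init = list(A0 = named bids) or list(Q0 = 3 x nbins matrix
# rows SC, NC, BC)
oracle_nll <- function(model, params, data, init) {
  total <- 0
  for (sid in unique(data$subject_id)) {
    for (m in c("SC", "NC", "BC")) {
      rows <- data[data$subject_id == sid & data$market == m &
                     !is.na(data$entered) & data$entered & !is.na(data$bid), ,
                   drop = FALSE]
      rows <- rows[order(rows$trial_in_market), , drop = FALSE]
      if (!nrow(rows)) next
      A <- init$A0[[m]]; last <- "none"
      Q <- if (!is.null(init$Q0)) init$Q0[m, ] else NULL
      for (i in seq_len(nrow(rows))) {
        pv <- oracle_policy(model, params, A = A, last = last, Q = Q)
        pb <- pv[round(rows$bid[i] * 10) + 1]
        total <- total - max(log(pb), -745)
        if (model %in% c("dl_gauss", "dl_naive", "dl_lepto")) {
          A <- oracle_update(model, params, A = A, bid = rows$bid[i],
                             accepted = rows$accepted[i], reward = rows$reward[i])
          last <- if (rows$accepted[i]) "accepted" else "rejected"
        } else if (model != "null") {
          Q <- oracle_update(model, params, Q = Q, bid = rows$bid[i],
                             accepted = rows$accepted[i], reward = rows$reward[i])
        }
      }
    }
  }
  total
}
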