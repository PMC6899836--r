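tile_idx <- function() floor(bid_grid() + 0.5) + 1

test_that("the registry exposes the seven models with their parameter counts", {
  counts <- c(rw_coarse = 2, rw_fine = 2, counterfactual_rl = 2,
              dl_gauss = 2, dl_naive = 4, dl_lepto = 5, null = 0)
  for (m in names(counts))
    expect_length(bid_model(m)$params, counts[[m]])
  expect_equal(model_class("dl_lepto"), "DL")
  expect_equal(model_class("counterfactual_rl"), "RL")
  expect_error(init_state("dl_gauss", c(alpha = 2, sigma = 1)), "bounds")
})

test_that("initial states honour priors and initial preferred bids", {
  st <- init_state("dl_lepto", ffx_lepto,
                   init = c(SC = 4.96, NC = 5.13, BC = 6.55))
  expect_equal(unname(st$A), c(4.96, 5.13, 6.55))
  expect_equal(unname(st$last), rep("none", 3))

  # flat Beta prior: every action value equals the amplitude
  st <- init_state("rw_coarse", c(alpha = 0.1, beta = 1),
                   init = beta_prior(1, 1, 10))
  expect_equal(unname(st$Q$NC), rep(10, 11))

  # symmetric prior: values symmetric about the central bin
  st <- init_state("rw_coarse", c(alpha = 0.1, beta = 1),
                   init = beta_prior(2, 2, 10))
  expect_equal(st$Q$SC, rev(st$Q$SC))
  expect_equal(which.max(st$Q$SC), 6)  # peak at 5 MU
})

test_that("Beta prior fitting is consistent and matches sample moments", {
  set.seed(11)
  x <- 10 * rbeta(1e4, 2, 2)
  pr <- fit_beta_prior(x)
  expect_lt(abs(pr$a - 2), 0.1)
  expect_lt(abs(pr$b - 2), 0.1)
  expect_lt(abs(pr$a - pr$b), 0.1)                      # symmetric sample
  expect_lt(abs(10 * pr$a / (pr$a + pr$b) - mean(x)), 0.1)

  # degenerate sample falls back to moment matching with a variance floor
  pr0 <- fit_beta_prior(rep(5, 10))
  expect_true(is.finite(pr0$a) && pr0$a > 0)
  expect_lt(abs(10 * pr0$a / (pr0$a + pr0$b) - 5), 0.2)
  expect_error(fit_beta_prior(c(1, 2)), "at least 3")
  expect_error(fit_beta_prior(c(1, 2, 11)), "0, 10")
})

test_that("softmax policies match closed forms and bin sharing", {
  # beta = 0: all bins equiprobable, interior-tile grid bids get 1/110
  st <- init_state("rw_coarse", c(alpha = 0.1, beta = 0))
  p <- policy_probs(st, "NC")
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p[51], 1 / 110)          # bid 5.0 sits in a 10-point tile
  expect_equal(p[1], 1 / (11 * 5))      # tile 0 holds 5 grid bids

  # two-value softmax closed form exp(1)/(exp(1)+1) on the bin scale
  st <- init_state("rw_coarse", c(alpha = 0.5, beta = 1),
                   init = beta_prior(1, 1, 1))
  st$Q$NC <- c(1, rep(0, 10))
  p <- policy_probs(st, "NC")
  p_bin1 <- sum(p[tile_idx() == 1])
  expect_equal(p_bin1 / (p_bin1 + sum(p[tile_idx() == 2])),
               exp(1) / (exp(1) + 1), tolerance = 1e-12)
})

test_that("the Gaussian DL policy matches brute-force grid renormalization", {
  st <- init_state("dl_gauss", c(alpha = 0.5, sigma = 1),
                   init = c(SC = 5, NC = 5, BC = 5))
  p <- policy_probs(st, "NC")
  w <- dnorm(bid_grid(), 5, 1)
  expect_equal(p, w / sum(w), tolerance = 1e-10)
  expect_equal(which.max(p), 51)
})

test_that("update rules reproduce the stated arithmetic", {
  # bid at the preferred bid is a fixed point under acceptance
  st <- init_state("dl_lepto", ffx_lepto, init = c(SC = 6, NC = 6, BC = 6))
  st2 <- update_state(st, "NC", 6.0, TRUE, 4.0)
  expect_equal(unname(st2$A[["NC"]]), 6.0)
  expect_equal(unname(st2$last[["NC"]]), "accepted")

  # rejection pushes the preferred bid toward 10 with gain alpha
  st <- init_state("dl_lepto", c(alpha = 0.5, sigma_a = 0.7, sigma_r = 0.79,
                                 sigma_0 = 0.65, k = 0.39),
                   init = c(SC = 6, NC = 6, BC = 6))
  st2 <- update_state(st, "NC", 6.0, FALSE, 0)
  expect_equal(unname(st2$A[["NC"]]), 8.0)

  # fixed nudges for the naive DL, clamped to the bid range
  st <- init_state("dl_naive", ffx_naive, init = c(SC = 0.1, NC = 5, BC = 9.99))
  st2 <- update_state(st, "SC", 0.1, TRUE, 9.9)
  expect_equal(unname(st2$A[["SC"]]), 0)     # 0.1 - 0.2 clamps at 0
  st2 <- update_state(st, "NC", 5.0, FALSE, 0)
  expect_equal(unname(st2$A[["NC"]]), 5.06)

  # counterfactual region update from a flat value function
  st <- init_state("counterfactual_rl", c(alpha = 0.2, beta = 1),
                   init = beta_prior(1, 1, 3))   # Q identically 3
  st2 <- update_state(st, "NC", 5.0, TRUE, 5.0)
  Q <- st2$Q$NC
  expect_equal(Q[1:50], rep(3, 49 + 1))          # i < 5.0 untouched exactly
  expect_equal(Q[51], 3 + 0.2 * (5 - 3))         # chosen bid toward 10 - b
  expect_equal(Q[101], 3 + 0.2 * (0 - 3))        # bid 10 toward payoff 0

  expect_error(update_state(st, "NC", 5.0, TRUE, 3.0), "inconsistent")
})

test_that("counterfactual updated/untouched index sets partition the grid exactly", {
  # flat prior off the counterfactual-payoff grid, so every true update
  # changes the value and every untouched entry stays bit-identical
  for (i in seq_len(101)) {
    b <- bid_grid()[i]
    st <- init_state("counterfactual_rl", c(alpha = 0.5, beta = 1),
                     init = beta_prior(1, 1, 7.03))
    upd_acc <- update_state(st, "SC", b, TRUE, 10 - b)$Q$SC != 7.03
    expect_identical(which(upd_acc), seq(i, 101L))
    upd_rej <- update_state(st, "SC", b, FALSE, 0)$Q$SC != 7.03
    expect_identical(which(upd_rej), seq(1L, i))
  }
})

test_that("bid log-likelihoods are consistent with the policy and floored", {
  st <- init_state("null")
  expect_equal(log_lik_bid(st, "NC", 3.3), -log(101), tolerance = 1e-12)

  st <- init_state("dl_lepto", ffx_lepto)
  p <- policy_probs(st, "BC")
  expect_equal(exp(log_lik_bid(st, "BC", 4.2)), p[43], tolerance = 1e-12)

  # near-degenerate scale far from the preferred bid hits the floor
  reset_loglik_floor_count()
  st <- init_state("dl_gauss", c(alpha = 0.5, sigma = 0.01),
                   init = c(SC = 9, NC = 9, BC = 9))
  expect_equal(log_lik_bid(st, "NC", 0.0), -745)
  expect_gte(loglik_floor_count(), 1)
})

test_that("every policy normalizes to 1 across random parameters and states", {
  set.seed(202)
  for (m in setdiff(list_bid_models(), "null")) {
    for (rep in 1:8) {
      params <- draw_params(m)
      st <- init_state(m, params)
      # push the state through a random outcome history
      for (t in 1:6) {
        mk <- sample(c("SC", "NC", "BC"), 1)
        b <- sample(bid_grid(), 1)
        acc <- runif(1) < 0.5
        st <- update_state(st, mk, b, acc, if (acc) 10 - b else 0)
        for (mk2 in c("SC", "NC", "BC")) {
          p <- policy_probs(st, mk2)
          expect_true(all(p >= 0))
          expect_lt(abs(sum(p) - 1), 1e-9)
        }
      }
    }
  }
})

test_that("states stay bounded under arbitrary update sequences", {
  set.seed(77)
  for (m in c("dl_gauss", "dl_naive", "dl_lepto", "rw_fine", "counterfactual_rl")) {
    params <- draw_params(m)
    st <- init_state(m, params)
    q0 <- if (!is.null(st$Q)) range(unlist(st$Q)) else NULL
    for (t in 1:60) {
      mk <- sample(c("SC", "NC", "BC"), 1)
      b <- sample(bid_grid(), 1)
      acc <- runif(1) < 0.5
      st <- update_state(st, mk, b, acc, if (acc) 10 - b else 0)
    }
    if (!is.null(st$A))
      expect_true(all(st$A >= 0 & st$A <= 10))
    if (!is.null(st$Q))
      expect_true(all(unlist(st$Q) >= min(0, q0[1]) &
                        unlist(st$Q) <= max(10, q0[2])))
  }
})

test_that("DL preferred bids move with, never against, the outcome direction", {
  set.seed(31)
  for (m in c("dl_gauss", "dl_naive", "dl_lepto")) {
    for (rep in 1:10) {
      params <- draw_params(m)
      A0 <- runif(1, 0.5, 9.5)
      st <- init_state(m, params, init = c(SC = A0, NC = A0, BC = A0))
      p <- policy_probs(st, "NC")
      dA_acc <- vapply(seq_len(101), function(i) {
        b <- bid_grid()[i]
        update_state(st, "NC", b, TRUE, 10 - b)$A[["NC"]] - A0
      }, numeric(1))
      dA_rej <- vapply(seq_len(101), function(i)
        update_state(st, "NC", bid_grid()[i], FALSE, 0)$A[["NC"]] - A0,
        numeric(1))
      expect_lte(sum(p * dA_acc), 1e-12)   # expected move after acceptance
      expect_gte(sum(p * dA_rej), -1e-12)  # expected move after rejection
    }
  }
})
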