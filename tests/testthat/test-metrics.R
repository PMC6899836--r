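test_that("the market discrimination index is the BC-SC mean-bid gap", {
  d <- rbind(make_session_df("BC", rep(6, 4), rep(TRUE, 4)),
             make_session_df("SC", rep(4, 4), rep(TRUE, 4)))
  expect_equal(mdi(d), 2.0)
  d2 <- rbind(make_session_df("BC", rep(5, 3), rep(TRUE, 3)),
              make_session_df("SC", rep(5, 3), rep(TRUE, 3)))
  expect_equal(mdi(d2), 0.0)
  # invariant under within-market permutation
  d3 <- rbind(make_session_df("BC", c(7, 5, 6), rep(TRUE, 3)),
              make_session_df("SC", c(3, 4, 5), rep(TRUE, 3)))
  d4 <- rbind(make_session_df("BC", c(6, 7, 5), rep(TRUE, 3)),
              make_session_df("SC", c(5, 3, 4), rep(TRUE, 3)))
  expect_equal(mdi(d3), mdi(d4))
  expect_error(mdi(make_session_df("NC", 5, TRUE)), "BC and SC")
})

test_that("DL compliance matches exhaustive enumeration on a known pattern", {
  # 6 NC trials: outcomes and bid moves chosen so compliance is countable
  d <- make_session_df("NC", c(5.0, 4.5, 4.7, 4.7, 5.5, 5.0),
                       accepted = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  # pairs: (acc,-0.5)C (rej,+0.2)C (acc,0)C (acc,+0.8)N (rej,-0.5)N
  cp <- dl_compliance(d)
  expect_equal(cp$n_pairs, 5)
  expect_equal(cp$overall, 3 / 5)
  expect_equal(cp$after_acceptance, 2 / 3)
  expect_equal(cp$after_rejection, 1 / 2)

  # accept then lower bid: compliant; reject then lower: not
  d <- make_session_df("NC", c(5, 4), accepted = c(TRUE, TRUE))
  expect_equal(dl_compliance(d)$overall, 1)
  d <- make_session_df("NC", c(5, 4), accepted = c(FALSE, TRUE))
  expect_equal(dl_compliance(d)$overall, 0)
  expect_error(dl_compliance(make_session_df("NC", 5, TRUE)), "eligible")
})

test_that("zero-noise naive-DL bidders are perfectly DL-compliant", {
  # nudges dominate a near-degenerate policy: every move follows the rule
  cfg <- cohort_config(n_subjects = 4, n_blocks = 12, model = "dl_naive",
                       params = c(n_up = 0.5, n_down = 0.5,
                                  sigma_a = 0.01, sigma_r = 0.01))
  d <- simulate_cohort(cfg, seed = 2)
  expect_equal(dl_compliance(d)$overall, 1.0)
})

test_that("compliance pairs skip lottery gaps but not market interleaving", {
  d <- make_session_df("NC", c(5, 4, 4.5), accepted = c(TRUE, TRUE, TRUE))
  gap <- d[1, ]; gap$entered <- FALSE; gap$bid <- NA; gap$accepted <- NA
  gap$reward <- 0; gap$trial_in_market <- 1.5   # lottery trial between bids
  d2 <- rbind(d[1, ], gap, d[2:3, ])
  expect_equal(dl_compliance(d2)$n_pairs, 2)
})

test_that("transaction rates and profits count exactly", {
  d <- make_session_df("NC", rep(5, 24), accepted = rep(c(TRUE, FALSE), 12))
  expect_equal(unname(transaction_rates(d)[["NC"]]), 0.5)
  d <- make_session_df("SC", c(4, 5, 6), accepted = c(TRUE, TRUE, FALSE))
  expect_equal(profit(d), 11.0)
  expect_equal(unname(transaction_rates(d)[["SC"]]), 2 / 3)
})

test_that("first-bid ANOVA matches the textbook F formula", {
  set.seed(9)
  d <- simulate_cohort(cohort_config(n_subjects = 12, n_blocks = 4), seed = 9)
  fb <- first_bid_summary(d)
  # independent computation from the group decomposition
  firsts <- do.call(rbind, lapply(split(d, d$subject_id), function(s)
    do.call(rbind, lapply(c("SC", "NC", "BC"), function(m) {
      sm <- s[s$market == m & s$entered & !is.na(s$bid), ]
      data.frame(g = m, y = sm$bid[which.min(sm$trial_in_market)])
    }))))
  k <- 3; N <- nrow(firsts)
  gm <- mean(firsts$y)
  ssb <- sum(tapply(firsts$y, firsts$g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(firsts$y, firsts$g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(fb$F, f_oracle, tolerance = 1e-9)
  expect_equal(fb$df, c(k - 1, N - k))
  expect_equal(unname(fb$means["SC"]),
               mean(firsts$y[firsts$g == "SC"]))

  # three identical groups: F = 0
  d0 <- rbind(make_session_df("SC", 5, TRUE, "a"), make_session_df("NC", 6, TRUE, "a"),
              make_session_df("BC", 7, TRUE, "a"),
              make_session_df("SC", 6, TRUE, "b"), make_session_df("NC", 7, TRUE, "b"),
              make_session_df("BC", 5, TRUE, "b"),
              make_session_df("SC", 7, TRUE, "c"), make_session_df("NC", 5, TRUE, "c"),
              make_session_df("BC", 6, TRUE, "c"))
  expect_equal(first_bid_summary(d0)$F, 0, tolerance = 1e-12)

  # degenerate: zero within-group variance with distinct means
  dd <- rbind(make_session_df("SC", 4, TRUE, "a"), make_session_df("NC", 5, TRUE, "a"),
              make_session_df("BC", 6, TRUE, "a"),
              make_session_df("SC", 4, TRUE, "b"), make_session_df("NC", 5, TRUE, "b"),
              make_session_df("BC", 6, TRUE, "b"))
  expect_error(first_bid_summary(dd), "variance")
})

test_that("bid-increment distributions split by previous outcome", {
  d <- make_session_df("NC", rep(5, 6), accepted = rep(TRUE, 6))
  inc <- increment_distribution(d)
  expect_equal(inc$n, 5)
  expect_true(all(inc$db == 0))
  expect_equal(sum(inc$counts), 5)                 # point mass at zero
  expect_equal(inc$median, 0)

  d <- simulate_cohort(cohort_config(n_subjects = 10, n_blocks = 16), seed = 15)
  up <- increment_distribution(d, previous = "rejected")
  dn <- increment_distribution(d, previous = "accepted")
  expect_gte(up$median, 0)                          # reject -> move up
  expect_lte(dn$median, 0)                          # accept -> stay or down
  expect_equal(up$n + dn$n, increment_distribution(d)$n)
  expect_equal(sum(up$counts), up$n)
})

test_that("bid-trend slopes recover linear drifts and group tests", {
  mk <- function(bids, market, sid) make_session_df(market, bids, rep(TRUE, length(bids)), sid)
  lin <- snap_to_grid(seq(1, 3.3, length.out = 24))
  d <- do.call(rbind, lapply(c("a", "b", "c"), function(sid)
    rbind(mk(lin, "SC", sid), mk(rep(5, 24), "NC", sid), mk(rev(lin), "BC", sid))))
  ts <- trend_slopes(d)
  expect_equal(ts$slopes$SC, rep(0.1, 3), tolerance = 1e-9)
  expect_equal(ts$slopes$NC, rep(0, 3), tolerance = 1e-12)
  expect_equal(ts$slopes$BC, rep(-0.1, 3), tolerance = 1e-9)
  expect_equal(ts$tests$mean_slope[ts$tests$market == "SC"], 0.1,
               tolerance = 1e-9)

  # BC-hard opponents push the generating agent's bids upward over time
  d <- simulate_cohort(cohort_config(n_subjects = 12, n_blocks = 24), seed = 19)
  ts <- trend_slopes(d)
  expect_gt(ts$tests$mean_slope[ts$tests$market == "BC"], 0)
})

test_that("Pearson correlations match the direct formula", {
  x <- c(1, 2, 3, 5, 8); y <- c(2.1, 2.9, 4.2, 5.0, 8.5)
  pr <- pearson_r(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pr$r, r_hand, tolerance = 1e-12)
  expect_equal(pr$t, r_hand * sqrt(3 / (1 - r_hand^2)), tolerance = 1e-12)
  expect_equal(pr$df, 3)
  expect_equal(pearson_r(1:5, (1:5) * 2 + 1)$r, 1.0)
  expect_equal(pearson_r(1:5, -(1:5))$r, -1.0)
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
})

test_that("market discrimination aligns with profit in a synthetic cohort", {
  d <- simulate_cohort(cohort_config(), seed = 27)
  subs <- split(d, d$subject_id)
  mdis <- vapply(subs, mdi, numeric(1))
  profits <- vapply(subs, profit, numeric(1))
  expect_gt(mean(mdis), 0)
  expect_gt(pearson_r(mdis, profits)$r, 0)
})

test_that("posterior-predictive curves track the agents' preferences", {
  # frozen nudge-free agent: flat curve at the initial preferred bids
  pp <- posterior_predictive("dl_naive",
                             params = c(n_up = 0, n_down = 0,
                                        sigma_a = 0.5, sigma_r = 0.5),
                             config = cohort_config(n_subjects = 3, n_blocks = 8,
                                                    model = "dl_naive",
                                                    params = c(n_up = 0, n_down = 0,
                                                               sigma_a = 0.5, sigma_r = 0.5)),
                             n_reps = 2, seed = 3)
  expect_equal(unique(pp$mean_pref[pp$market == "NC"]), 5.13)
  expect_equal(sum(pp$market == "SC"), 8)

  pp <- posterior_predictive("dl_lepto", ffx_lepto,
                             config = cohort_config(n_subjects = 6, n_blocks = 24),
                             n_reps = 2, seed = 5)
  expect_equal(sum(pp$market == "BC"), 24)
  late <- pp[pp$trial > 14, ]
  expect_gt(mean(late$mean_pref[late$market == "BC"]),
            mean(late$mean_pref[late$market == "SC"]))
})
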