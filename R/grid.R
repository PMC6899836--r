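#' The bid grid
#'
#' Bids in the double-auction task live on a fixed 101-point grid: 0.0 to
#' 10.0 monetary units (MU) in steps of 0.1. All agents' policies are
#' probability vectors over this grid, and all recorded bids must lie on it.
#'
#' @return Numeric vector of length 101, strictly increasing from 0 to 10.
#' @export
#' @examples
#' g <- bid_grid()
#' length(g)   # 101
#' g[38]       # 3.7
bid_grid <- function() {
  seq(0L, 100L, by = 1L) / 10
}

#' @rdname bid_grid
#' @return `n_bids()` returns the grid size, 101.
#' @export
n_bids <- function() 101L

#' Snap a value to the bid grid
#'
#' Rounds a value in \[0, 10\] to the nearest grid bid. Exact half-steps
#' (e.g. 3.15) round up.
#'
#' @param x Numeric vector of values in \[0, 10\].
#' @return Grid bids of the same length.
#' @export
#' @examples
#' snap_to_grid(c(3.14, 3.15, 10))   # 3.1 3.2 10.0
snap_to_grid <- function(x) {
  if (!is.numeric(x) || anyNA(x)) stop("snap_to_grid: 'x' must be numeric and non-missing")
  if (any(x < 0 | x > 10)) stop("snap_to_grid: values must lie in [0, 10]")
  # half-up rounding at 0.1 resolution; tiny epsilon guards binary representation
  floor(x * 10 + 0.5 + 1e-9) / 10
}

# index of a grid bid in bid_grid(); errors on off-grid values
bid_index <- function(bid) {
  idx <- as.integer(round(bid * 10)) + 1L
  on <- !is.na(bid) & abs(bid * 10 - round(bid * 10)) < 1e-9 & idx >= 1L & idx <= 101L
  if (any(!on)) stop("bid off the 0.1-step grid: ", paste(bid[!on], collapse = ", "))
  idx
}

#' Market types
#'
#' The three market types of the task: `SC` (seller competition: two sellers,
#' one buyer), `NC` (no competition: one seller, one buyer) and `BC` (buyer
#' competition: one seller, two buyers, one of them the subject).
#'
#' @param label One of `"SC"`, `"NC"`, `"BC"`.
#' @return A list with elements `label`, `n_sellers`, `n_competitor_buyers`.
#' @export
#' @examples
#' market_type("SC")$n_sellers   # 2
market_type <- function(label) {
  label <- match.arg(label, c("SC", "NC", "BC"))
  switch(label,
    SC = list(label = "SC", n_sellers = 2L, n_competitor_buyers = 0L),
    NC = list(label = "NC", n_sellers = 1L, n_competitor_buyers = 0L),
    BC = list(label = "BC", n_sellers = 1L, n_competitor_buyers = 1L)
  )
}

#' @rdname market_type
#' @export
market_labels <- function() c("SC", "NC", "BC")

#' Resolve one auction trial
#'
#' Applies the double-auction transaction rule: the highest buyer bid is
#' pitted against the lowest seller ask; the transaction is consummated
#' unless the highest bid is strictly lower than the lowest ask (equality
#' transacts). The subject transacts only if their bid is the highest buyer
#' bid; an exact tie with a competitor buyer is broken by a fair coin drawn
#' from the current RNG stream. On acceptance the subject earns `10 - bid`
#' MU, otherwise 0. In BC, a competitor bid strictly above the subject's is
#' disclosed (as in the task's feedback screen).
#'
#' @param market Market label (`"SC"`, `"NC"`, `"BC"`) or a [market_type()].
#' @param bid Subject's bid, on the grid.
#' @param asks Numeric vector of seller asks; length must equal the market's
#'   seller count.
#' @param competitor_bids Numeric vector of competitor buyer bids; length
#'   must equal the market's competitor count.
#' @return List with `accepted` (logical), `reward` (MU) and
#'   `disclosed_competitor_bid` (MU or `NA`).
#' @export
#' @examples
#' resolve_trial("NC", 4.0, asks = 4.0)           # accepted, reward 6
#' resolve_trial("SC", 4.0, asks = c(4.5, 3.5))   # accepted, reward 6
resolve_trial <- function(market, bid, asks, competitor_bids = numeric(0)) {
  mt <- if (is.character(market)) market_type(market) else market
  bid <- bid_grid()[bid_index(bid)]
  if (length(asks) != mt$n_sellers)
    stop("resolve_trial: expected ", mt$n_sellers, " ask(s) for market ", mt$label)
  if (length(competitor_bids) != mt$n_competitor_buyers)
    stop("resolve_trial: expected ", mt$n_competitor_buyers,
         " competitor bid(s) for market ", mt$label)

  top_comp <- if (length(competitor_bids)) max(competitor_bids) else -Inf
  subject_highest <-
    if (bid > top_comp) TRUE
    else if (bid < top_comp) FALSE
    else stats::runif(1) < 0.5           # exact tie: seeded fair coin
  accepted <- subject_highest && max(bid, top_comp) >= min(asks)
  disclosed <- if (is.finite(top_comp) && top_comp > bid) top_comp else NA_real_
  list(accepted = accepted,
       reward = if (accepted) 10 - bid else 0,
       disclosed_competitor_bid = disclosed)
}

# the six orderings of (SC, NC, BC), in lexicographic order
market_sequences <- function() {
  list(c("SC", "NC", "BC"), c("SC", "BC", "NC"),
       c("NC", "SC", "BC"), c("NC", "BC", "SC"),
       c("BC", "SC", "NC"), c("BC", "NC", "SC"))
}

#' Market and lottery schedule for one session
#'
#' Markets are looped block-wise in one of the six fixed permutations of
#' (SC, NC, BC), repeated `n_blocks` times. A lottery excludes the subject
#' from one in every six trials: each consecutive window of six scheduled
#' trials contains exactly one skip, at a position uniform within the window
#' (a trailing partial window contains none). With 24 blocks this yields 72
#' trials, 24 per market, and exactly 12 skips.
#'
#' @param sequence_id Integer 1..6 selecting the market permutation.
#' @param n_blocks Number of blocks (each block visits all three markets).
#' @param seed Integer seed for the lottery draw.
#' @return Data frame with columns `trial`, `block`, `market`,
#'   `trial_in_market`, `entered`.
#' @export
market_schedule <- function(sequence_id, n_blocks = 24L, seed = 1L) {
  if (length(sequence_id) != 1L || is.na(sequence_id) ||
      !(sequence_id %in% 1:6))
    stop("market_schedule: 'sequence_id' must be an integer in 1..6")
  if (n_blocks < 1L) stop("market_schedule: 'n_blocks' must be >= 1")
  perm <- market_sequences()[[sequence_id]]
  market <- rep(perm, times = n_blocks)
  n <- length(market)
  entered <- rep(TRUE, n)
  with_preserved_seed(seed, {
    for (w in seq_len(n %/% 6L)) {
      skip <- (w - 1L) * 6L + sample.int(6L, 1L)
      entered[skip] <- FALSE
    }
  })
  data.frame(
    trial = seq_len(n),
    block = rep(seq_len(n_blocks), each = 3L),
    market = market,
    trial_in_market = stats::ave(seq_len(n), market, FUN = seq_along),
    entered = entered,
    stringsAsFactors = FALSE
  )
}

# evaluate `expr` under `seed`, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, index, salt = 0L) {
  as.integer((as.numeric(seed) %% 1e6 * 2039 + index * 104729 + salt * 7919) %%
               2147483647) + 1L
}
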