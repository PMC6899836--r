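#' Event-table input and output
#'
#' Sessions are stored as tab-separated event tables, one row per trial,
#' BIDS `events.tsv` style: header row, `"n/a"` for missing values, UTF-8.
#' Canonical columns are `subject_id`, `market`, `block`, `trial_in_market`,
#' `entered`, `bid`, `accepted`, `reward`, `competitor_bid`; optional
#' columns (`onset`, `duration`, ground-truth asks `ask1`/`ask2` from
#' simulation logs, ...) pass through untouched. External dialects with
#' different column names are adapted with a column-mapping config.
#'
#' @param path File path.
#' @param col_map Optional column mapping: a named character vector or list
#'   mapping canonical names to the file's names (e.g.
#'   `c(subject_id = "subj")`), or the path of a YAML file holding such a
#'   mapping.
#' @param snap Logical; if `TRUE`, off-grid bids are snapped to the nearest
#'   grid value ([snap_to_grid()]) instead of rejected.
#' @return `read_events_tsv()` returns a data frame of trials (a dataset);
#'   `write_events_tsv()` returns `path` invisibly.
#' @export
read_events_tsv <- function(path, col_map = NULL, snap = FALSE) {
  dat <- utils::read.delim(path, sep = "\t", na.strings = "n/a",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    if (is.character(col_map) && length(col_map) == 1L && file.exists(col_map))
      col_map <- unlist(yaml::read_yaml(col_map))
    col_map <- unlist(col_map)
    for (canon in names(col_map)) {
      ext <- col_map[[canon]]
      if (!ext %in% names(dat))
        stop("read_events_tsv: mapped column '", ext, "' not found")
      names(dat)[names(dat) == ext] <- canon
    }
  }
  required <- c("subject_id", "market", "block", "trial_in_market",
                "entered", "bid", "accepted", "reward")
  missing <- setdiff(required, names(dat))
  if (length(missing))
    stop("read_events_tsv: missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!"competitor_bid" %in% names(dat)) dat$competitor_bid <- NA_real_
  if (!is.numeric(dat$bid))
    stop("read_events_tsv: column 'bid' must be numeric")
  bad <- setdiff(unique(dat$market), market_labels())
  if (length(bad))
    stop("read_events_tsv: unknown market label(s): ", paste(bad, collapse = ", "))
  dat$entered <- as.logical(dat$entered)
  dat$accepted <- as.logical(dat$accepted)
  dat$subject_id <- as.character(dat$subject_id)
  has_bid <- !is.na(dat$bid)
  off <- has_bid & abs(dat$bid * 10 - round(dat$bid * 10)) >= 1e-9
  if (any(off)) {
    if (!snap)
      stop("read_events_tsv: ", sum(off),
           " bid(s) off the 0.1-step grid; set snap = TRUE to snap them")
    dat$bid[off] <- snap_to_grid(dat$bid[off])
  }
  validate_events(dat)
  dat
}

#' @param data Dataset (data frame of trials), e.g. from [simulate_cohort()].
#' @rdname read_events_tsv
#' @export
write_events_tsv <- function(data, path) {
  out <- data
  num <- vapply(out, is.numeric, logical(1))
  # %.12g round-trips the grid exactly and continuous asks to ~1e-12
  out[num] <- lapply(out[num],
                     function(x) ifelse(is.na(x), NA, sprintf("%.12g", x)))
  lg <- vapply(data, is.logical, logical(1))
  out[lg] <- lapply(data[lg],
                    function(x) ifelse(is.na(x), NA, ifelse(x, "1", "0")))
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "n/a",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# structural checks shared by the reader and the simulator
validate_events <- function(data) {
  ent <- !is.na(data$entered) & data$entered
  if (any(ent & is.na(data$bid)))
    stop("events: entered trials must carry a bid")
  acc <- ent & !is.na(data$accepted) & data$accepted
  if (any(abs(data$reward[acc] - (10 - data$bid[acc])) > 1e-9))
    stop("events: accepted trials must have reward = 10 - bid")
  rej <- !ent | (!is.na(data$accepted) & !data$accepted)
  if (any(abs(data$reward[rej]) > 1e-9, na.rm = TRUE))
    stop("events: non-accepted trials must have reward 0")
  invisible(data)
}

# split a dataset into per-subject chronological chunks (stable order)
split_subjects <- function(data) {
  split(data, factor(data$subject_id, levels = unique(data$subject_id)))
}

# per-subject, per-market sequences of entered bid trials, in market order;
# this is the replay structure shared by the likelihood and the enactment
prep_subject <- function(data_s) {
  out <- list()
  for (m in market_labels()) {
    idx <- which(data_s$market == m)
    idx <- idx[order(data_s$trial_in_market[idx])]
    idx <- idx[!is.na(data_s$entered[idx]) & data_s$entered[idx] &
                 !is.na(data_s$bid[idx])]
    out[[m]] <- list(
      bid = data_s$bid[idx],
      bid_idx = if (length(idx)) bid_index(data_s$bid[idx]) else integer(0),
      accepted = as.logical(data_s$accepted[idx]),
      reward = data_s$reward[idx],
      row = idx
    )
  }
  out
}

# per-market mean first entered bids of a dataset (DL initial preferred bids)
first_bid_means <- function(data) {
  vapply(market_labels(), function(m) {
    firsts <- vapply(split_subjects(data), function(s) {
      sm <- s[s$market == m & !is.na(s$entered) & s$entered & !is.na(s$bid), ,
              drop = FALSE]
      if (!nrow(sm)) return(NA_real_)
      sm$bid[which.min(sm$trial_in_market)]
    }, numeric(1))
    mean(firsts, na.rm = TRUE)
  }, numeric(1))
}
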