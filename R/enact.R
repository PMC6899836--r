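#' Enact a fitted DL model through observed sessions
#'
#' Forced-choice replay: the agent is marched through each subject's
#' recorded trials, its choice forced to the recorded bid and its state
#' updated from the recorded outcome — exactly the state evolution used by
#' the likelihood. Before each update the trial-level learning signals are
#' recorded:
#'
#' * `PBV_pre` — the preferred-bid value `10 - A` before the update (the
#'   model's reward expectation entering the trial);
#' * `DS` — the directional signature, +1 for accepted, -1 for rejected;
#' * `pseudo_RPE` — `reward - PBV_pre`, the prediction-error analogue whose
#'   expectation term is the preferred bid's value.
#'
#' Each signal also gets a pooled z-scored duplicate (`*_z`), standardized
#' across all subjects' trials. `onset`/`duration` columns, when present,
#' pass through for downstream design-matrix tools.
#'
#' @param model A DL model name/spec, or a `bidfit` object (in which case
#'   `params`, `data` and `init` default to the fit's).
#' @param params Named parameter vector.
#' @param data Dataset with recorded outcomes.
#' @param init Optional per-market initial preferred bids.
#' @return Data frame of class `enactment_trace`, one row per entered bid
#'   trial.
#' @export
enact <- function(model, params = NULL, data = NULL, init = NULL) {
  if (inherits(model, "bidfit")) {
    if (is.null(params)) params <- model$par
    if (is.null(data)) data <- model$data
    if (is.null(init)) init <- model$init
    model <- model$model
  }
  spec <- as_model_spec(model)
  if (spec$family != "dl")
    stop("enact: the preferred-bid value is only defined for DL models")
  params <- check_params(spec, params)
  init <- default_init(spec, data, init)
  rows <- list()
  for (s in split_subjects(data)) {
    prep <- prep_subject(s)
    if (any(vapply(prep, function(p) any(is.na(p$accepted)), logical(1))))
      stop("enact: entered trial with missing outcome")
    st <- init_state(spec, params, init = init)
    for (m in market_labels()) {
      p <- prep[[m]]
      for (t in seq_along(p$bid)) {
        A_pre <- st$A[[m]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s$subject_id[p$row[t]], market = m,
          block = s$block[p$row[t]],
          trial_in_market = s$trial_in_market[p$row[t]],
          onset = if ("onset" %in% names(s)) s$onset[p$row[t]] else NA_real_,
          duration = if ("duration" %in% names(s)) s$duration[p$row[t]] else NA_real_,
          bid = p$bid[t], accepted = p$accepted[t], reward = p$reward[t],
          PBV_pre = 10 - A_pre,
          DS = if (p$accepted[t]) 1 else -1,
          pseudo_RPE = p$reward[t] - (10 - A_pre),
          stringsAsFactors = FALSE
        )
        st <- update_state(st, m, p$bid[t], p$accepted[t], p$reward[t])
      }
    }
  }
  trace <- do.call(rbind, rows)
  if (!any(!is.na(trace$onset))) trace$onset <- NULL
  if (!any(!is.na(trace$duration))) trace$duration <- NULL
  for (sig in c("PBV_pre", "DS", "pseudo_RPE"))
    trace <- zscore_pooled(trace, sig)
  class(trace) <- c("enactment_trace", "data.frame")
  trace
}

#' Pooled z-scoring of a regressor column
#'
#' Standardizes a signal across all subjects' trials: `(x - mean) / sd`,
#' with the mean and the population SD (n divisor) pooled over the whole
#' trace, appended as `<signal>_z`. The population convention makes the
#' standardized column's pooled moments exactly (0, 1).
#'
#' @param trace Data frame holding the signal.
#' @param signal Column name.
#' @return `trace` with the standardized column added (or replaced).
#' @export
zscore_pooled <- function(trace, signal) {
  x <- trace[[signal]]
  if (is.null(x)) stop("zscore_pooled: no column '", signal, "'")
  s <- sqrt(mean((x - mean(x))^2))
  if (!is.finite(s) || s == 0)
    stop("zscore_pooled: signal '", signal, "' is degenerate (zero variance)")
  trace[[paste0(signal, "_z")]] <- (x - mean(x)) / s
  trace
}

#' Write / read an enactment trace as TSV
#'
#' One row per entered bid trial, tab-separated, `"n/a"` for missing,
#' stable column order; the round trip reproduces the trace.
#'
#' @param trace An [enact()] trace.
#' @param path File path.
#' @export
write_regressor_tsv <- function(trace, path) {
  if (!nrow(trace)) stop("write_regressor_tsv: empty trace")
  out <- as.data.frame(trace)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num],
                     function(x) ifelse(is.na(x), NA, sprintf("%.12g", x)))
  lg <- vapply(trace, is.logical, logical(1))
  out[lg] <- lapply(as.data.frame(trace)[lg],
                    function(x) ifelse(is.na(x), NA, ifelse(x, "1", "0")))
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "n/a",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_regressor_tsv
#' @export
read_regressor_tsv <- function(path) {
  dat <- utils::read.delim(path, sep = "\t", na.strings = "n/a",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if ("accepted" %in% names(dat)) dat$accepted <- as.logical(dat$accepted)
  dat
}
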