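#' @export
print.bid_model_spec <- function(x, ...) {
  cat("<bid model> ", x$name, " (", model_class(x), " class, ",
      length(x$params), " free parameter",
      if (length(x$params) != 1) "s", ")\n", sep = "")
  if (length(x$params)) {
    b <- data.frame(parameter = x$params, lower = unname(x$lower),
                    upper = unname(x$upper))
    print(b, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.bidfit <- function(x, digits = 4, ...) {
  cat("Bid-learning model fit:", x$model$name,
      sprintf("(%s, %d subject%s, %d bid trials)\n", toupper(x$mode),
              x$n_subjects, if (x$n_subjects != 1) "s" else "", x$n_obs))
  if (length(x$par)) {
    cat("Estimates",
        if (x$mode == "rfx") " (mean over converged subjects)", ":\n", sep = "")
    print(round(x$par, digits))
  } else cat("No free parameters.\n")
  cat(sprintf("NLL: %.*f total, %.*f per subject;  BIC: %.*f total, %.*f per subject\n",
              digits, x$nll_total, digits, x$nll_per_subject,
              digits, x$bic_total, digits, x$bic_per_subject))
  invisible(x)
}

#' Summaries and extractors for fitted models
#'
#' `coef()` returns the fixed-effects estimates (RFX: the mean over
#' converged subjects); `logLik()` the maximized log-likelihood with
#' `df` and `nobs` attributes; `residuals()` the trial-level pseudo
#' reward-prediction errors from forced-choice enactment (DL models only);
#' `simulate()` posterior-predictive cohorts re-simulated at the fitted
#' parameters; `predict()` the probability the fitted policy assigns to
#' each observed bid.
#'
#' @param object A `bidfit`.
#' @param ... Unused.
#' @export
summary.bidfit <- function(object, ...) {
  s <- list(model = object$model$name, mode = object$mode,
            par = object$par, par_sem = object$par_sem,
            converged = object$converged,
            nll_total = object$nll_total,
            nll_per_subject = object$nll_per_subject,
            bic_total = object$bic_total,
            bic_per_subject = object$bic_per_subject,
            n_obs = object$n_obs, n_subjects = object$n_subjects,
            nll_by_subject = object$nll_by_subject)
  class(s) <- "summary.bidfit"
  s
}

#' @export
print.summary.bidfit <- function(x, digits = 4, ...) {
  cat("Model:", x$model, " mode:", toupper(x$mode), "\n")
  est <- data.frame(estimate = x$par)
  if (!is.null(x$par_sem)) est$sem <- x$par_sem
  print(round(est, digits))
  if (!is.null(x$converged))
    cat(sum(x$converged), "of", length(x$converged), "subjects converged\n")
  cat(sprintf("NLL per subject: %.*f   BIC per subject: %.*f   (n = %d bid trials)\n",
              digits, x$nll_per_subject, digits, x$bic_per_subject, x$n_obs))
  invisible(x)
}

#' @rdname summary.bidfit
#' @export
coef.bidfit <- function(object, ...) object$par

#' @rdname summary.bidfit
#' @export
logLik.bidfit <- function(object, ...) {
  structure(-object$nll_total, df = length(object$model$params),
            nobs = object$n_obs, class = "logLik")
}

#' @rdname summary.bidfit
#' @export
residuals.bidfit <- function(object, ...) {
  tr <- enact(object)
  stats::setNames(tr$pseudo_RPE, tr$subject_id)
}

#' @rdname summary.bidfit
#' @param newdata Dataset to score; defaults to the training data.
#' @export
predict.bidfit <- function(object, newdata = NULL, ...) {
  data <- if (is.null(newdata)) object$data else newdata
  # per-trial probabilities via replay with the public per-trial API
  out <- numeric(0)
  for (s in split_subjects(data)) {
    prep <- prep_subject(s)
    st <- init_state(object$model, object$par, init = object$init)
    for (m in market_labels()) {
      p <- prep[[m]]
      for (t in seq_along(p$bid)) {
        out <- c(out, exp(log_lik_bid(st, m, p$bid[t])))
        st <- update_state(st, m, p$bid[t], p$accepted[t], p$reward[t])
      }
    }
  }
  out
}

#' @rdname summary.bidfit
#' @param nsim Number of cohorts to simulate.
#' @param seed Integer seed.
#' @param config A [cohort_config()] giving the opponent environment;
#'   defaults to the package's study conditions with the fit's model,
#'   parameters and initial bids substituted.
#' @export
simulate.bidfit <- function(object, nsim = 1, seed = 1L, config = NULL, ...) {
  if (is.null(config)) config <- cohort_config()
  config$model <- object$model
  config$params <- object$par
  if (object$model$family == "dl") config$init_bids <- object$init
  out <- lapply(seq_len(nsim), function(r)
    simulate_cohort(config, seed = derive_seed(seed, r, salt = 23L)))
  if (nsim == 1) out[[1]] else out
}

#' @rdname summary.bidfit
#' @param x A `bidfit`.
#' @param n_reps Posterior-predictive replicates to average.
#' @export
plot.bidfit <- function(x, n_reps = 5, seed = 1L, config = NULL, ...) {
  pp <- posterior_predictive(x, config = config, n_reps = n_reps, seed = seed)
  cols <- c(SC = "#1b9e77", NC = "#d95f02", BC = "#7570b3")
  plot(NULL, xlim = range(pp$trial), ylim = c(0, 10),
       xlab = "trial within market", ylab = "tracked preferred bid (MU)",
       main = paste("Posterior predictive:", x$model$name))
  for (m in market_labels()) {
    pm <- pp[pp$market == m, ]
    graphics::lines(pm$trial, pm$mean_pref, col = cols[[m]], lwd = 2)
  }
  graphics::legend("bottomright", legend = market_labels(),
                   col = cols[market_labels()], lwd = 2, bty = "n")
  invisible(pp)
}

#' @export
print.bidrank <- function(x, digits = 2, ...) {
  cat("Model comparison by BIC (", toupper(attr(x, "mode") %||% "ffx"),
      " fits, ascending):\n", sep = "")
  df <- as.data.frame(x)
  df[c("nll_total", "nll_per_subject", "bic_total", "bic_per_subject")] <-
    round(df[c("nll_total", "nll_per_subject", "bic_total", "bic_per_subject")],
          digits)
  print(df, row.names = FALSE)
  cb <- attr(x, "class_bic")
  if (!is.null(cb)) {
    cat("Class-average BIC:",
        paste(names(cb), round(cb, digits), sep = " = ", collapse = ",  "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
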