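#' Splice observed events with a permuted replicate
#'
#' Produces the alternating case/control dataset on which the stratified
#' partial likelihood is fitted: row `2k - 1` is observed event `k`, row
#' `2k` its lone accompanying non-event, both sharing index, day,
#' apparatus, time and event clock.
#'
#' @param events Observed event table.
#' @param nonevents Permuted replicate, row-aligned with `events`.
#' @return Data frame with `2 * nrow(events)` rows and an `is_observed`
#'   flag.
#' @export
splice <- function(events, nonevents) {
  n <- nrow(events)
  if (nrow(nonevents) != n) stop("events and nonevents are misaligned")
  ii <- rep(seq_len(n), each = 2)
  out <- data.frame(
    index = events$index[ii],
    day = events$day[ii],
    apparatus = events$apparatus[ii],
    start_time = events$start_time[ii],
    clock = events$index[ii] / 1000,
    is_observed = rep(c(TRUE, FALSE), n),
    source = character(2 * n),
    target = character(2 * n),
    arrival_latency = numeric(2 * n),
    duration = numeric(2 * n),
    stringsAsFactors = FALSE)
  obs <- out$is_observed
  for (col in c("source", "target", "arrival_latency", "duration")) {
    out[[col]][obs] <- events[[col]]
    out[[col]][!obs] <- nonevents[[col]]
  }
  out
}

#' Fit the stratified partial likelihood on paired event/non-event rows
#'
#' With each observed event matched to exactly one non-event sharing its
#' stratum and time, the stratified Cox partial likelihood reduces exactly
#' to the matched conditional-logistic log-likelihood
#' \deqn{\sum_k \left[ x_k^{(1)}\beta - \log(e^{x_k^{(1)}\beta} +
#'   e^{x_k^{(0)}\beta}) \right],}
#' a logistic likelihood in the within-pair covariate differences. It is
#' maximised by Newton iteration with analytic gradient and Hessian
#' (convergence when the largest absolute score falls below `1e-8`, at most
#' `max_iter` iterations). Terms with no within-pair variance are flagged
#' and returned as `NA`; separation (a term whose nonzero within-pair
#' differences all share one sign and which diverges) is reported as
#' non-convergence naming the offending term.
#'
#' @param design Spliced design rows from [build_design()], or a list with
#'   elements `case` and `control` (numeric matrices of covariates).
#' @param keep Optional logical vector selecting event pairs (defaults to
#'   the design's `"keep"` attribute).
#' @param max_iter Newton iteration cap.
#' @param tol Score convergence tolerance.
#' @return List with `coef` (named, `NA` for non-estimable terms),
#'   `converged`, `flagged` (zero-variance terms), `separated` (terms
#'   implicated in separation), `loglik` and `iterations`.
#' @export
fit_partial_likelihood <- function(design, keep = NULL, max_iter = 50,
                                   tol = 1e-8) {
  if (is.data.frame(design)) {
    terms <- attr(design, "terms")
    if (is.null(terms))
      terms <- setdiff(names(design),
                       c("index", "stratum", "apparatus", "clock",
                         "is_observed"))
    obs <- design$is_observed
    Xc <- as.matrix(design[obs, terms, drop = FALSE])
    Xn <- as.matrix(design[!obs, terms, drop = FALSE])
    if (is.null(keep)) keep <- attr(design, "keep")
  } else {
    Xc <- as.matrix(design$case)
    Xn <- as.matrix(design$control)
    terms <- colnames(Xc)
    if (is.null(terms)) terms <- paste0("x", seq_len(ncol(Xc)))
  }
  if (!is.null(keep)) {
    Xc <- Xc[keep, , drop = FALSE]
    Xn <- Xn[keep, , drop = FALSE]
  }
  D <- Xc - Xn
  p <- ncol(D)
  flagged <- colSums(D != 0) == 0
  est <- which(!flagged)
  coefs <- setNames(rep(NA_real_, p), terms)
  if (!length(est))
    return(list(coef = coefs, converged = TRUE, flagged = terms[flagged],
                separated = character(0), loglik = -nrow(D) * log(2),
                iterations = 0L))
  Dk <- D[, est, drop = FALSE]
  beta <- rep(0, length(est))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(Dk %*% beta)
    pr <- stats::plogis(eta)
    score <- drop(crossprod(Dk, 1 - pr))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    w <- pr * (1 - pr)
    H <- crossprod(Dk * w, Dk)
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) break
    # dampen wild steps to keep the ascent stable
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    beta <- beta + step
    if (max(abs(beta)) > 30) break  # diverging: separation
  }
  # separation: a diverging coefficient whose within-pair differences all
  # share one sign (the score can underflow to "convergence" at the
  # boundary, so this is checked even after apparent convergence)
  mono <- vapply(seq_len(ncol(Dk)), function(j) {
    dj <- Dk[, j]
    nz <- dj[dj != 0]
    length(nz) > 0 && (all(nz > 0) || all(nz < 0))
  }, logical(1))
  separated <- terms[est][(mono & abs(beta) > 15) | abs(beta) >= 30]
  if (length(separated)) converged <- FALSE
  coefs[est] <- beta
  eta <- drop(Dk %*% beta)
  list(coef = coefs, converged = converged, flagged = terms[flagged],
       separated = separated,
       loglik = sum(stats::plogis(eta, log.p = TRUE)), iterations = iter)
}

#' Fit a permuted Relational Event Model
#'
#' The core estimator. For each of `n_replicates` permuted replicates the
#' observed events are paired with permutation-generated non-events
#' ([permute_events()], [splice()]), time-varying covariates are computed
#' from the observed history ([build_design()]), and the stratified partial
#' likelihood is maximised ([fit_partial_likelihood()]). The per-term
#' coefficient distribution across replicates is summarised by its median
#' (point estimate), quantile confidence interval at the model's CI level
#' (95%, widened to 97.5% for the two individual-level models as a
#' multiple-testing correction), the implied incidence rate ratios
#' (`IRR = exp(coef)`), and a significance call by zero-crossing of the
#' coefficient-scale interval. Non-converged replicates are dropped and
#' counted; more than 10% triggers a warning.
#'
#' @param events Observed event table (from [extract_events()],
#'   [read_events()] or [simulate_market()]).
#' @param individuals Data frame with `id` and `class`.
#' @param model Model id `"M1"`--`"M8"` (see [prem_models()]) or a custom
#'   spec list.
#' @param n_replicates Number of permuted replicates (>= 2). 10,000 matches
#'   the full design; 200 is a fast desk mode.
#' @param seed Integer seed (mandatory; replicate `r` depends only on
#'   `(seed, r)`).
#' @param variant Override the model's permutation variant.
#' @param ci_level Override the model's CI level.
#' @param min_common Joint-event threshold defining a common associate
#'   (M8).
#' @param hours_per_day Session hours per day, used for the baseline
#'   events-per-hour rate (default 4).
#' @return An object of class `prem`.
#' @export
prem <- function(events, individuals, model = "M3", n_replicates = 200,
                 seed, variant = NULL, ci_level = NULL, min_common = 1,
                 hours_per_day = 4) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  spec <- if (is.character(model)) prem_models()[[model]] else model
  if (is.null(spec)) stop("unknown model id")
  if (!is.null(variant)) spec$variant <- variant
  if (!is.null(ci_level)) spec$ci_level <- ci_level
  plan <- permutation_plan(spec$variant,
                           weight = if (!is.null(spec$weight)) spec$weight
                                    else "duration")
  seeds <- replicate_seeds(seed, n_replicates)
  p <- length(spec$terms)
  coefs <- matrix(NA_real_, n_replicates, p,
                  dimnames = list(NULL, spec$terms))
  conv <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(seeds[r])
    perm <- permute_events(events, plan)
    des <- build_design(events, perm, spec, individuals,
                        min_common = min_common)
    fit <- fit_partial_likelihood(des)
    conv[r] <- fit$converged
    if (fit$converged) coefs[r, ] <- fit$coef
  }
  n_dropped <- sum(!conv)
  if (n_dropped > 0.1 * n_replicates)
    warning(sprintf("%d of %d replicates failed to converge (> 10%%)",
                    n_dropped, n_replicates))
  alpha <- 1 - spec$ci_level
  probs <- c(alpha / 2, 1 - alpha / 2)
  med <- apply(coefs, 2, stats::median, na.rm = TRUE)
  ci <- t(apply(coefs, 2, stats::quantile, probs = probs, na.rm = TRUE,
                names = FALSE))
  colnames(ci) <- c("lower", "upper")
  n_days <- length(unique(events$day))
  structure(list(
    model = spec$id, level = spec$level, terms = spec$terms,
    variant = spec$variant, ci_level = spec$ci_level,
    coef_samples = coefs, median = med, ci = ci,
    irr = exp(med), irr_ci = exp(ci),
    significant = ci[, "lower"] > 0 | ci[, "upper"] < 0,
    n_replicates = n_replicates, n_dropped = n_dropped,
    n_events = nrow(events),
    baseline_rate = nrow(events) / (n_days * hours_per_day),
    seed = seed, call = match.call()),
    class = "prem")
}

#' @export
print.prem <- function(x, digits = 4, ...) {
  cat(sprintf("Permuted relational event model %s (%s level)\n",
              x$model, x$level))
  cat(sprintf("  %d events, %d replicates (%s permutation), %g%% CI\n",
              x$n_events, x$n_replicates, x$variant, 100 * x$ci_level))
  tab <- data.frame(IRR = round(x$irr, digits),
                    lower = round(x$irr_ci[, 1], digits),
                    upper = round(x$irr_ci[, 2], digits),
                    signif = ifelse(x$significant, "*", ""),
                    row.names = x$terms)
  print(tab)
  invisible(x)
}

#' @export
summary.prem <- function(object, ...) {
  structure(list(prem = object), class = "summary.prem")
}

#' @export
print.summary.prem <- function(x, ...) {
  p <- x$prem
  print(p)
  cat(sprintf("Baseline rate: %.3g events/hour\n", p$baseline_rate))
  if (p$n_dropped > 0)
    cat(sprintf("Dropped replicates (non-convergence): %d of %d\n",
                p$n_dropped, p$n_replicates))
  cat("Coefficient scale summary:\n")
  print(t(apply(p$coef_samples, 2, stats::quantile,
                probs = c(.025, .25, .5, .75, .975), na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.prem <- function(object, ...) object$median

#' @export
confint.prem <- function(object, parm, level = NULL, ...) {
  ci <- object$ci
  if (!is.null(level)) {
    alpha <- 1 - level
    ci <- t(apply(object$coef_samples, 2, stats::quantile,
                  probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                  names = FALSE))
    colnames(ci) <- c("lower", "upper")
  }
  rownames(ci) <- object$terms
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predicted event rates from a fitted pREM
#'
#' Multiplies a baseline rate of events per hour by the incidence rate
#' ratio implied by a covariate profile, propagating the full coefficient
#' distribution: `rate = baseline * exp(profile . beta)` per replicate,
#' summarised as median and 95% prediction interval.
#'
#' @param object A fitted [prem()] object.
#' @param profile Named numeric vector of covariate values; names must be
#'   model terms.
#' @param baseline_rate Events per hour (defaults to the rate estimated at
#'   fit time).
#' @return List with `median`, `lower`, `upper` and the replicate `samples`.
#' @export
predict_rates <- function(object, profile, baseline_rate = NULL) {
  stopifnot(inherits(object, "prem"))
  if (is.null(baseline_rate)) baseline_rate <- object$baseline_rate
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  unknown <- setdiff(names(profile), object$terms)
  if (length(unknown))
    stop("unknown term(s) in profile: ", paste(unknown, collapse = ", "))
  beta <- object$coef_samples[, names(profile), drop = FALSE]
  samples <- baseline_rate * exp(drop(beta %*% profile))
  qs <- stats::quantile(samples, c(.025, .5, .975), na.rm = TRUE,
                        names = FALSE)
  list(median = qs[2], lower = qs[1], upper = qs[3], samples = samples)
}

#' @rdname predict_rates
#' @param ... Passed through to [predict_rates()].
#' @export
predict.prem <- function(object, profile, baseline_rate = NULL, ...) {
  predict_rates(object, profile, baseline_rate)
}

#' Forest plot of incidence rate ratios
#'
#' @param x A fitted [prem()] object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.prem <- function(x, ...) {
  p <- length(x$terms)
  ylim <- c(0.5, p + 0.5)
  xlim <- range(c(x$irr_ci, 1), finite = TRUE)
  graphics::plot(x$irr, seq_len(p), log = "x", xlim = xlim, ylim = ylim,
                 pch = 19, yaxt = "n", xlab = "Incidence rate ratio",
                 ylab = "", panel.first = graphics::abline(v = 1, lty = 2),
                 ...)
  graphics::segments(x$irr_ci[, 1], seq_len(p), x$irr_ci[, 2], seq_len(p))
  graphics::axis(2, at = seq_len(p), labels = x$terms, las = 1)
  invisible(x)
}
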