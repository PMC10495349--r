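#' Permutation null interval for the success proportion
#'
#' Compares the observed percentage of successful (same-class) events with
#' the 2.5% and 97.5% quantiles of the same percentage recomputed from
#' permuted datasets (class match of the permuted source/target labels).
#'
#' @param events Observed event table.
#' @param individuals Data frame with `id` and `class`.
#' @param replicates List of permuted event tables (from
#'   [generate_replicates()] with the `joint_labels` variant).
#' @return An object of class `null_envelope` with the observed percentage,
#'   replicate percentages, median, bounds and an `exceeds` flag (observed
#'   above the upper bound).
#' @export
success_proportion_test <- function(events, individuals, replicates) {
  if (nrow(events) == 0) stop("no events")
  cls <- setNames(individuals$class, individuals$id)
  pct <- function(src, tgt) 100 * mean(cls[src] == cls[tgt])
  observed <- pct(events$source, events$target)
  reps <- vapply(replicates, function(r) pct(r$source, r$target), numeric(1))
  qs <- stats::quantile(reps, c(.025, .975), names = FALSE)
  structure(list(statistic = "success percentage", observed = observed,
                 replicates = reps, median = stats::median(reps),
                 lower = qs[1], upper = qs[2],
                 exceeds = observed > qs[2]),
            class = "null_envelope")
}

#' Cumulative success/fail differential with permutation envelope
#'
#' For each day, the number of successful minus unsuccessful events; the
#' cumulative sum of these daily differentials tracks how the balance of
#' event types changed over the experiment. The same series is recomputed
#' from each permuted replicate (outcomes re-derived from permuted labels
#' via class match) to give a pointwise median and 95% envelope.
#'
#' @inheritParams success_proportion_test
#' @return A `null_envelope` whose `observed`, `median`, `lower`, `upper`
#'   and `exceeds` elements are daily series (named by day).
#' @export
cumulative_differential <- function(events, individuals, replicates) {
  cls <- setNames(individuals$class, individuals$id)
  days <- sort(unique(events$day))
  daily_cum <- function(src, tgt) {
    same <- cls[src] == cls[tgt]
    diff <- vapply(days, function(d) {
      sel <- events$day == d
      sum(same[sel]) - sum(!same[sel])
    }, numeric(1))
    cumsum(diff)
  }
  observed <- setNames(daily_cum(events$source, events$target), days)
  reps <- vapply(replicates, function(r) daily_cum(r$source, r$target),
                 numeric(length(days)))
  reps <- matrix(reps, nrow = length(days))
  lower <- apply(reps, 1, stats::quantile, probs = .025, names = FALSE)
  upper <- apply(reps, 1, stats::quantile, probs = .975, names = FALSE)
  med <- apply(reps, 1, stats::median)
  structure(list(statistic = "cumulative success/fail differential",
                 day = days, observed = observed,
                 replicates = t(reps), median = setNames(med, days),
                 lower = setNames(lower, days),
                 upper = setNames(upper, days),
                 exceeds = observed > upper | observed < lower),
            class = "null_envelope")
}

#' @export
print.null_envelope <- function(x, ...) {
  cat("<null_envelope>", x$statistic, "\n")
  if (length(x$observed) == 1) {
    cat(sprintf("  observed %.2f vs null (%.2f, %.2f); exceeds: %s\n",
                x$observed, x$lower, x$upper, x$exceeds))
  } else {
    cat(sprintf("  %d-point series; observed outside envelope at %d point(s)\n",
                length(x$observed), sum(x$exceeds)))
  }
  invisible(x)
}

#' Plot a permutation null envelope
#'
#' For series envelopes, draws the observed cumulative differential over
#' the permuted median and 95% envelope; for scalar envelopes, a histogram
#' of replicate statistics with the observed value marked.
#'
#' @param x A `null_envelope`.
#' @param ... Passed to the underlying plot call.
#' @export
plot.null_envelope <- function(x, ...) {
  if (length(x$observed) > 1) {
    ylim <- range(c(x$observed, x$lower, x$upper))
    graphics::plot(x$day, x$observed, type = "n", ylim = ylim,
                   xlab = "Day", ylab = x$statistic, ...)
    graphics::polygon(c(x$day, rev(x$day)), c(x$lower, rev(x$upper)),
                      col = grDevices::adjustcolor("red", 0.2), border = NA)
    graphics::lines(x$day, x$median, col = "red")
    graphics::lines(x$day, x$observed, lwd = 2)
  } else {
    graphics::hist(x$replicates, main = x$statistic, xlab = "replicate value",
                   ...)
    graphics::abline(v = x$observed, lwd = 2)
  }
  invisible(x)
}

#' Binomial test of event share against dyad share
#'
#' Tests whether a subset of dyads (e.g. affiliated pairs) accounts for a
#' disproportionate share of events: the exact binomial tail probability of
#' observing at least `k_events` of `n_events` events from the subset if
#' each event independently involved a subset dyad with probability
#' `k_dyads / n_dyads`.
#'
#' @param k_events,n_events Events from the subset, and total events.
#' @param k_dyads,n_dyads Dyads in the subset, and total dyads.
#' @param alternative `"greater"` (default; over-representation) or
#'   `"two.sided"`.
#' @return List with `event_share`, `dyad_share` (proportions), `p_value`
#'   and (for the one-sided test) `log10_p`, which survives underflow.
#' @export
binomial_share_test <- function(k_events, n_events, k_dyads, n_dyads,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_events <= 0 || n_dyads <= 0) stop("totals must be positive")
  if (k_events < 0 || k_events > n_events || k_dyads < 0 ||
      k_dyads > n_dyads) stop("counts must satisfy 0 <= k <= n")
  rate <- k_dyads / n_dyads
  log_p <- NA_real_
  p <- if (alternative == "greater") {
    # log-scale tail survives underflow for extreme over-representation
    log_p <- stats::pbinom(k_events - 1, n_events, rate, lower.tail = FALSE,
                           log.p = TRUE)
    exp(log_p)
  } else {
    stats::binom.test(k_events, n_events, rate,
                      alternative = "two.sided")$p.value
  }
  list(event_share = k_events / n_events, dyad_share = rate, p_value = p,
       log10_p = log_p / log(10), alternative = alternative)
}
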