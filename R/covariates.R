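#' Incremental network state over an event history
#'
#' Maintains, as observed events are applied in order, the symmetric matrix
#' of prior joint-event counts per dyad (from which partner multisets,
#' per-class experience counts and triadic-closure statistics derive) and a
#' running event clock. Non-events never enter the state.
#'
#' @param individuals Data frame with columns `id` and `class`.
#' @return An environment of class `network_state`.
#' @export
network_state <- function(individuals) {
  st <- new.env(parent = emptyenv())
  st$ids <- individuals$id
  st$class <- individuals$class
  st$idx <- setNames(seq_along(st$ids), st$ids)
  st$pc <- matrix(0L, length(st$ids), length(st$ids))
  st$n_events <- 0L
  class(st) <- "network_state"
  st
}

#' Apply observed events to a network state
#'
#' @param state A [network_state()].
#' @param source,target Individual ids (vectors apply events in order).
#' @return The state, invisibly (modified in place).
#' @export
apply_event <- function(state, source, target) {
  i <- state$idx[source]; j <- state$idx[target]
  if (anyNA(i) || anyNA(j)) stop("unknown individual id")
  for (k in seq_along(i)) {
    state$pc[i[k], j[k]] <- state$pc[i[k], j[k]] + 1L
    state$pc[j[k], i[k]] <- state$pc[i[k], j[k]]
  }
  state$n_events <- state$n_events + length(i)
  invisible(state)
}

#' Bin a dyad's prior-association count into experience levels
#'
#' Zero prior associations map to `none`, one to five to `low`, six or more
#' to `high`.
#'
#' @param prior_count Non-negative integer vector.
#' @return Character vector in `{"none","low","high"}`.
#' @export
bin_experience <- function(prior_count) {
  if (any(prior_count < 0)) stop("prior_count must be non-negative")
  ifelse(prior_count == 0, "none", ifelse(prior_count <= 5, "low", "high"))
}

#' Count partners an individual has associated with repeatedly
#'
#' Number of distinct partners with at least two prior joint events,
#' restricted to partners of the individual's own class (`"same"`) or of
#' the other class (`"different"`).
#'
#' @param state A [network_state()].
#' @param id Individual id.
#' @param class_filter `"same"` or `"different"`.
#' @param min_events Repetition threshold (default 2).
#' @return Integer count.
#' @export
repeated_partner_count <- function(state, id, class_filter = c("same", "different"),
                                   min_events = 2) {
  class_filter <- match.arg(class_filter)
  i <- state$idx[[id]]
  match_cls <- if (class_filter == "same") state$class == state$class[i]
               else state$class != state$class[i]
  sum(state$pc[i, ] >= min_events & match_cls & seq_along(state$ids) != i)
}

#' Count common associates of a dyad
#'
#' Number of third parties with at least `min_events` prior joint events
#' with *both* members of the dyad (the dyad members themselves excluded).
#' With `same_class_only = TRUE` -- defined only for same-class dyads -- the
#' count is restricted to third parties sharing the treatment class of both
#' members.
#'
#' @param state A [network_state()].
#' @param id1,id2 The dyad members (distinct).
#' @param same_class_only Restrict to third parties of the dyad's class.
#' @param min_events Minimum prior joint events with each member (default 1).
#' @return Integer count.
#' @export
common_associates <- function(state, id1, id2, same_class_only = FALSE,
                              min_events = 1) {
  if (id1 == id2) stop("dyad members must be distinct")
  i <- state$idx[[id1]]; j <- state$idx[[id2]]
  if (same_class_only && state$class[i] != state$class[j])
    stop("same_class_only is undefined for a different-class dyad")
  ok <- state$pc[i, ] >= min_events & state$pc[j, ] >= min_events
  ok[c(i, j)] <- FALSE
  if (same_class_only) ok <- ok & state$class == state$class[i]
  sum(ok)
}

#' Model registry for the pREM analyses
#'
#' Eight model specifications reconstructed from the analysis design:
#' individual-level performance (M1: cumulative same-/different-class
#' event counts; M2: counts of repeated same-/different-class partners,
#' both fitted on successful events against independently role-shuffled
#' non-events, 97.5% CIs), dyad-level association (M3: class match and its
#' per-1000-events trend; M4/M5: experience-by-class-match for
#' non-affiliate/affiliate dyads; jointly shuffled labels, 95% CIs),
#' within-dyad coordination (M6 arrival latency, M7 duration; edge-weight
#' permutation) and network-level triadic closure (M8: common associates of
#' any class and of the dyad's class, each with a per-1000-events trend).
#'
#' @return Named list of model specifications.
#' @export
prem_models <- function() {
  list(
    M1 = list(id = "M1", level = "individual", variant = "independent_labels",
              ci_level = 0.975, subset = "success",
              terms = c("same_class_experience", "diff_class_experience")),
    M2 = list(id = "M2", level = "individual", variant = "independent_labels",
              ci_level = 0.975, subset = "success",
              terms = c("repeated_same_partners", "repeated_diff_partners")),
    M3 = list(id = "M3", level = "dyad", variant = "joint_labels",
              ci_level = 0.95, subset = "all",
              terms = c("same_class", "same_class_clock")),
    M4 = list(id = "M4", level = "dyad", variant = "joint_labels",
              ci_level = 0.95, subset = "nonaffiliate",
              terms = c("exp_low", "exp_high", "exp_low_same", "exp_high_same")),
    M5 = list(id = "M5", level = "dyad", variant = "joint_labels",
              ci_level = 0.95, subset = "affiliate",
              terms = c("exp_low", "exp_high", "exp_low_same", "exp_high_same")),
    M6 = list(id = "M6", level = "coordination", variant = "edge_weights",
              ci_level = 0.95, subset = "all", weight = "arrival_latency",
              terms = c("latency_same")),
    M7 = list(id = "M7", level = "coordination", variant = "edge_weights",
              ci_level = 0.95, subset = "all", weight = "duration",
              terms = c("duration_same")),
    M8 = list(id = "M8", level = "network", variant = "joint_labels",
              ci_level = 0.95, subset = "same_class_pairs",
              terms = c("common_any", "common_same", "common_any_clock",
                        "common_same_clock")))
}

#' Build the pREM design rows for events and their paired non-events
#'
#' For each observed event and its permuted non-event, computes the model's
#' time-varying covariates from the network state accumulated over strictly
#' earlier *observed* events (non-events never update the state). Rows are
#' returned in spliced order (event k, then non-event k), sharing index,
#' day, apparatus and event clock.
#'
#' @param events Observed event table.
#' @param nonevents Permuted replicate, row-aligned with `events` (columns
#'   `source`, `target`, and the weight column for edge-weight variants).
#' @param model Model id (`"M1"` to `"M8"`) or a spec from [prem_models()].
#' @param individuals Data frame with `id` and `class`.
#' @param min_common Minimum joint events defining a common associate.
#' @return Data frame with `index`, `stratum`, `is_observed` and one column
#'   per model term; attribute `"keep"` marks pairs in the model's event
#'   subset.
#' @export
build_design <- function(events, nonevents, model, individuals,
                         min_common = 1) {
  spec <- if (is.character(model)) prem_models()[[model]] else model
  if (is.null(spec)) stop("unknown model id")
  n <- nrow(events)
  if (nrow(nonevents) != n) stop("events and nonevents are misaligned")
  clock <- events$index / 1000
  cls <- setNames(individuals$class, individuals$id)
  same_obs <- cls[events$source] == cls[events$target]
  same_non <- cls[nonevents$source] == cls[nonevents$target]

  keep <- switch(spec$subset,
    all = rep(TRUE, n),
    success = events$outcome == "success",
    affiliate = events$is_affiliate,
    nonaffiliate = !events$is_affiliate,
    same_class_pairs = rep(TRUE, n))

  if (spec$id %in% c("M3", "M6", "M7")) {
    Xo <- Xn <- matrix(0, n, length(spec$terms),
                       dimnames = list(NULL, spec$terms))
    if (spec$id == "M3") {
      Xo[, 1] <- same_obs;            Xn[, 1] <- same_non
      Xo[, 2] <- same_obs * clock;    Xn[, 2] <- same_non * clock
    } else {
      w_obs <- events[[spec$weight]]
      w_non <- nonevents[[spec$weight]]
      Xo[, 1] <- w_obs * same_obs
      Xn[, 1] <- w_non * same_obs  # labels untouched under edge permutation
    }
  } else {
    st <- network_state(individuals)
    idx <- st$idx
    so <- idx[events$source]; to <- idx[events$target]
    sn <- idx[nonevents$source]; tn <- idx[nonevents$target]
    if (anyNA(sn) || anyNA(tn)) stop("unknown id in nonevents")
    classv <- st$class
    p <- length(spec$terms)
    Xo <- Xn <- matrix(0, n, p, dimnames = list(NULL, spec$terms))
    samev <- outer(classv, classv, "==")
    for (k in seq_len(n)) {
      Xo[k, ] <- history_covariates(spec, st$pc, classv, samev,
                                    so[k], to[k], clock[k], min_common)
      Xn[k, ] <- history_covariates(spec, st$pc, classv, samev,
                                    sn[k], tn[k], clock[k], min_common)
      st$pc[so[k], to[k]] <- st$pc[so[k], to[k]] + 1L
      st$pc[to[k], so[k]] <- st$pc[so[k], to[k]]
    }
  }

  des <- data.frame(
    index = rep(events$index, each = 2),
    stratum = rep(events$day, each = 2),
    apparatus = rep(events$apparatus, each = 2),
    clock = rep(clock, each = 2),
    is_observed = rep(c(TRUE, FALSE), n))
  X <- matrix(0, 2 * n, ncol(Xo), dimnames = list(NULL, colnames(Xo)))
  X[des$is_observed, ] <- Xo
  X[!des$is_observed, ] <- Xn
  des <- cbind(des, as.data.frame(X))
  attr(des, "keep") <- keep
  attr(des, "terms") <- spec$terms
  des
}

# history-dependent covariates for a single dyad (integer indices) at the
# state held in the prior-count matrix pc
history_covariates <- function(spec, pc, classv, samev, s, t, clock,
                               min_common) {
  nn <- length(classv)
  switch(spec$id,
    M1 = {
      same_s <- samev[s, ]; same_t <- samev[t, ]
      cs <- sum(pc[s, same_s]) + sum(pc[t, same_t])
      cd <- sum(pc[s, !same_s]) + sum(pc[t, !same_t])
      c(cs, cd)
    },
    M2 = {
      rs <- sum(pc[s, ] >= 2 & samev[s, ] & seq_len(nn) != s) +
            sum(pc[t, ] >= 2 & samev[t, ] & seq_len(nn) != t)
      rd <- sum(pc[s, ] >= 2 & !samev[s, ] & seq_len(nn) != s) +
            sum(pc[t, ] >= 2 & !samev[t, ] & seq_len(nn) != t)
      c(rs, rd)
    },
    M4 = ,
    M5 = {
      prior <- pc[s, t]
      same <- samev[s, t]
      lo <- prior >= 1 && prior <= 5
      hi <- prior >= 6
      c(lo, hi, lo && same, hi && same)
    },
    M8 = {
      ok <- pc[s, ] >= min_common & pc[t, ] >= min_common
      ok[c(s, t)] <- FALSE
      any_ct <- sum(ok)
      same_ct <- if (samev[s, t]) sum(ok & samev[s, ]) else 0
      c(any_ct, same_ct, any_ct * clock, same_ct * clock)
    },
    stop("unknown model id: ", spec$id))
}
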