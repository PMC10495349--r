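#' Plan for data-stream permutation of an event list
#'
#' Randomization is applied independently within subsets of the data
#' defined by each day-by-feeder combination, so permuted datasets can
#' never move an individual outside the sessions in which it was observed
#' (juveniles entering mid-experiment therefore never appear early).
#' Four variants are available:
#' \describe{
#'   \item{`independent_labels`}{source and target labels shuffled
#'     separately; each individual's per-role event counts within the
#'     subset are preserved (used for individual-level models).}
#'   \item{`joint_labels`}{all `2n` labels of the subset pooled and
#'     redistributed over the `2n` slots; each individual's total
#'     participation is preserved but not its roles (dyad- and
#'     network-level models).}
#'   \item{`edge_weights`}{only an edge-weight column (duration or arrival
#'     latency) is shuffled among the subset's events; labels untouched
#'     (coordination models).}
#'   \item{`target_only`}{only the target column shuffled; experimental.}
#' }
#' Shuffles producing loops (the same individual as both source and
#' target) are re-drawn up to `max_reshuffles` times; if loops persist,
#' constrained pairwise label swaps remove them ([resolve_loops()]).
#'
#' @param variant One of the four variants above.
#' @param max_reshuffles Maximum full re-randomizations before falling back
#'   to constrained swaps (default 10000).
#' @param weight For `edge_weights`, the column to shuffle
#'   (`"duration"` or `"arrival_latency"`).
#' @return An object of class `permutation_plan`.
#' @export
permutation_plan <- function(variant = c("independent_labels", "joint_labels",
                                         "edge_weights", "target_only"),
                             max_reshuffles = 10000,
                             weight = "duration") {
  variant <- match.arg(variant)
  if (max_reshuffles < 1) stop("max_reshuffles must be >= 1")
  structure(list(variant = variant, max_reshuffles = max_reshuffles,
                 weight = weight),
            class = "permutation_plan")
}

# one shuffle draw for a subset (no loop handling)
shuffle_subset <- function(src, tgt, variant) {
  n <- length(src)
  switch(variant,
    independent_labels = list(source = src[sample.int(n)],
                              target = tgt[sample.int(n)]),
    joint_labels = {
      pool <- c(src, tgt)[sample.int(2 * n)]
      list(source = pool[seq_len(n)], target = pool[n + seq_len(n)])
    },
    target_only = list(source = src, target = tgt[sample.int(n)]),
    stop("shuffle_subset does not apply to variant ", variant))
}

#' Permute one day-by-feeder subset
#'
#' Draws a label (or weight) shuffle for the subset under the plan's
#' variant, re-drawing up to `max_reshuffles` times while loops are present
#' and falling back to constrained pairwise swaps ([resolve_loops()]) if
#' the re-shuffle limit is exhausted.
#'
#' @param subset Data frame with `source`, `target` and any weight columns.
#' @param plan A [permutation_plan()].
#' @return The subset with permuted labels (or weights); guaranteed
#'   loop-free for label variants.
#' @export
permute_subset <- function(subset, plan) {
  n <- nrow(subset)
  if (n == 0) stop("subset must be non-empty")
  if (plan$variant == "edge_weights") {
    subset[[plan$weight]] <- subset[[plan$weight]][sample.int(n)]
    return(subset)
  }
  sh <- permute_labels(subset$source, subset$target, plan)
  subset$source <- sh$source
  subset$target <- sh$target
  subset
}

# loop-free label permutation of one subset: re-shuffle until clean or the
# limit is reached, then constrained swaps
permute_labels <- function(src, tgt, plan) {
  for (try in seq_len(plan$max_reshuffles)) {
    sh <- shuffle_subset(src, tgt, plan$variant)
    if (!any(sh$source == sh$target)) return(sh)
  }
  resolve_loops(sh)
}

#' Remove loops from a permuted subset by constrained pairwise swaps
#'
#' For each loop in turn, another row not featuring the looped individual
#' in either role is drawn at random, and either the source or the target
#' label (chosen at random) is swapped between the two rows, creating two
#' valid non-loop rows. The per-subset label multiset is preserved.
#'
#' @param sh List or data frame with `source` and `target` vectors.
#' @param max_sweeps Bound on full passes over remaining loops.
#' @return `sh` with zero loops.
#' @export
resolve_loops <- function(sh, max_sweeps = 100) {
  src <- sh$source; tgt <- sh$target
  n <- length(src)
  for (sweep in seq_len(max_sweeps)) {
    loops <- which(src == tgt)
    if (!length(loops)) break
    for (l in loops) {
      if (src[l] != tgt[l]) next  # may have been fixed by an earlier swap
      elig <- which(src != src[l] & tgt != src[l])
      if (!length(elig))
        stop("cannot resolve loop for individual ", src[l],
             ": no row without that individual exists in the subset")
      other <- elig[if (length(elig) > 1) sample.int(length(elig), 1) else 1L]
      if (stats::runif(1) < 0.5) {
        tmp <- src[l]; src[l] <- src[other]; src[other] <- tmp
      } else {
        tmp <- tgt[l]; tgt[l] <- tgt[other]; tgt[other] <- tmp
      }
    }
  }
  if (any(src == tgt)) stop("loops remain after ", max_sweeps, " swap sweeps")
  sh$source <- src; sh$target <- tgt
  sh
}

#' Permute a full event list under a plan
#'
#' Applies [permute_subset()] independently to every day-by-feeder subset.
#' Timestamps, strata, per-subset event counts and (for label variants)
#' weight columns are never altered.
#'
#' @param events Event table.
#' @param plan A [permutation_plan()].
#' @return The event table with permuted labels or weights.
#' @export
permute_events <- function(events, plan) {
  key <- paste(events$day, events$apparatus, sep = "\r")
  idx_by <- split(seq_len(nrow(events)), key)
  if (plan$variant == "edge_weights") {
    w <- events[[plan$weight]]
    if (is.null(w)) stop("unknown weight column: ", plan$weight)
    for (rows in idx_by) w[rows] <- w[rows][sample.int(length(rows))]
    events[[plan$weight]] <- w
    return(events)
  }
  src <- events$source
  tgt <- events$target
  for (rows in idx_by) {
    sh <- permute_labels(src[rows], tgt[rows], plan)
    src[rows] <- sh$source
    tgt[rows] <- sh$target
  }
  events$source <- src
  events$target <- tgt
  events
}

#' Generate permuted replicates of an event list
#'
#' Each replicate permutes every day-by-feeder subset independently using a
#' replicate-specific substream of the seeded generator, so replicate `r`
#' is reproducible from `(seed, r)` alone.
#'
#' @param events Event table.
#' @param plan A [permutation_plan()].
#' @param n_replicates Number of replicates.
#' @param seed Integer seed.
#' @return List of `n_replicates` permuted event tables.
#' @export
generate_replicates <- function(events, plan, n_replicates, seed) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  seeds <- replicate_seeds(seed, n_replicates)
  lapply(seq_len(n_replicates), function(r) {
    set.seed(seeds[r])
    permute_events(events, plan)
  })
}

replicate_seeds <- function(seed, n_replicates) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n_replicates)
}
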