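#' Configuration for the dual-feeder market simulation
#'
#' Builds the configuration for [simulate_market()], an agent-based
#' emulation of a feeder-based "biological market" experiment: two treatment
#' classes whose same-class dyads are rewarded and different-class dyads
#' penalised, affiliated dyads (mates, parent-offspring, siblings) with
#' elevated co-visitation, fission-fusion visitation in day-by-feeder
#' sessions, and mid-experiment entry of juveniles.
#'
#' Defaults describe a desk-scale study: 60 individuals visiting two feeder
#' units over 20 four-hour morning sessions, producing on the order of 1,500
#' dyadic association events.
#'
#' @param n_individuals Total number of individuals (adults plus juveniles).
#' @param n_mate_pairs Number of mated adult pairs.
#' @param n_sibling_groups Number of juvenile sibling broods (two fledglings
#'   each), entering at `juvenile_entry_day`.
#' @param n_parent_offspring_links Number of parent-offspring affiliation
#'   edges (parents drawn from mated adults, offspring from juveniles).
#' @param n_regulars Number of unpaired adults treated as regular feeder
#'   users (class-balanced by supervised randomization).
#' @param n_days Number of daily sessions.
#' @param n_feeders Number of two-perch feeder units.
#' @param session_length Session length in seconds (default 4 h).
#' @param arrival_rate Expected visits per individual per session.
#' @param stay_mean Mean perch-visit duration in seconds.
#' @param learning_rate Weight (lambda) on the cumulative net reward
#'   experienced with a partner (+1 per successful, -1 per unsuccessful
#'   joint event) in the log-odds of joining that partner.
#' @param affiliate_weight Log-odds bonus (theta) for joining an affiliate.
#' @param pair_follow Probability that an arriving individual is followed a
#'   few seconds later by one of its affiliates (correlated pair movement;
#'   set 0 for independent arrivals).
#' @param min_success_access Minimum seconds of high-quality reward access.
#' @param lockout_duration Lockout length in seconds.
#' @param gap_tolerance Seconds bridged when merging dyad co-occupancy into
#'   events; the simulator keeps re-visits farther apart than this so that
#'   event extraction recovers its ground truth exactly.
#' @param juvenile_entry_day Day index (1-based) on which juveniles enter;
#'   defaults to the session midpoint.
#' @param seed Mandatory integer seed.
#' @return An object of class `market_config`.
#' @export
market_config <- function(n_individuals = 60,
                          n_mate_pairs = 8,
                          n_sibling_groups = 3,
                          n_parent_offspring_links = 6,
                          n_regulars = 10,
                          n_days = 20,
                          n_feeders = 2,
                          session_length = 14400,
                          arrival_rate = 5,
                          stay_mean = 30,
                          learning_rate = 0.1,
                          affiliate_weight = 4,
                          pair_follow = 0.15,
                          min_success_access = 15,
                          lockout_duration = 120,
                          gap_tolerance = 2,
                          juvenile_entry_day = NULL,
                          seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(n_individuals = n_individuals, n_mate_pairs = n_mate_pairs,
              n_sibling_groups = n_sibling_groups,
              n_parent_offspring_links = n_parent_offspring_links,
              n_regulars = n_regulars, n_days = n_days, n_feeders = n_feeders,
              session_length = session_length, arrival_rate = arrival_rate,
              stay_mean = stay_mean, learning_rate = learning_rate,
              affiliate_weight = affiliate_weight,
              pair_follow = pair_follow,
              min_success_access = min_success_access,
              lockout_duration = lockout_duration,
              gap_tolerance = gap_tolerance,
              juvenile_entry_day = if (is.null(juvenile_entry_day))
                ceiling(n_days / 2) + 1L else as.integer(juvenile_entry_day),
              seed = as.integer(seed))
  counts <- cfg[c("n_individuals", "n_days", "n_feeders", "session_length")]
  if (any(unlist(counts) <= 0)) stop("counts must be positive")
  if (cfg$learning_rate < 0) stop("learning_rate must be non-negative")
  n_juv <- 2 * n_sibling_groups
  if (2 * n_mate_pairs + n_regulars + n_juv > n_individuals)
    stop("n_individuals too small for the requested pairs, regulars and broods")
  if (n_parent_offspring_links > 0 && n_juv == 0)
    stop("parent-offspring links require at least one sibling group")
  class(cfg) <- "market_config"
  cfg
}

#' Assign treatment classes
#'
#' Supervised randomization for listed pairs (half the pairs, rounded down,
#' same-class with AA and BB in as equal numbers as possible; the rest
#' different-class) and for regular users (split equally between classes);
#' unsupervised randomization (an independent fair coin) for everyone else.
#'
#' @param ids Character vector of all individual ids.
#' @param pair_list List of length-2 character vectors (e.g. mated pairs);
#'   members must be disjoint across pairs.
#' @param regular_list Character vector of regular users without a listed
#'   partner (disjoint from pair members).
#' @return Named character vector of classes (`"A"`/`"B"`) over `ids`.
#' @export
assign_classes <- function(ids, pair_list = list(), regular_list = character()) {
  pair_members <- unlist(pair_list)
  if (anyDuplicated(pair_members))
    stop("duplicate individual appears in two pairs")
  if (!all(c(pair_members, regular_list) %in% ids))
    stop("pair/regular members must be in ids")
  if (any(regular_list %in% pair_members))
    stop("regular_list must be disjoint from pair members")
  cls <- setNames(rep(NA_character_, length(ids)), ids)
  np <- length(pair_list)
  if (np > 0) {
    n_same <- np %/% 2
    n_aa <- n_same %/% 2
    n_bb <- n_same - n_aa
    if (n_same %% 2 == 1 && stats::runif(1) < 0.5) { n_aa <- n_bb; n_bb <- n_same - n_aa }
    ord <- sample.int(np)
    kind <- rep("AB", np)
    kind[ord[seq_len(n_aa)]] <- "AA"
    if (n_bb > 0) kind[ord[n_aa + seq_len(n_bb)]] <- "BB"
    for (k in seq_len(np)) {
      pr <- pair_list[[k]]
      cls[pr] <- switch(kind[k],
                        AA = c("A", "A"),
                        BB = c("B", "B"),
                        AB = sample(c("A", "B")))
    }
  }
  nr <- length(regular_list)
  if (nr > 0) {
    ord <- sample(regular_list)
    half <- nr %/% 2
    extra <- nr - 2 * half  # odd: one extra goes to a random class
    nA <- half + if (extra && stats::runif(1) < 0.5) 1L else 0L
    cls[ord] <- c(rep("A", nA), rep("B", nr - nA))
  }
  rest <- names(cls)[is.na(cls)]
  cls[rest] <- ifelse(stats::runif(length(rest)) < 0.5, "A", "B")
  cls
}

# Build the synthetic population: ids, classes, entry days, affiliation edges.
build_population <- function(cfg) {
  n <- cfg$n_individuals
  ids <- sprintf("J%03d", seq_len(n))
  n_juv <- 2L * cfg$n_sibling_groups
  juv <- if (n_juv > 0) ids[(n - n_juv + 1L):n] else character()
  adults <- setdiff(ids, juv)
  pair_list <- list()
  aff <- list()
  mates <- character()
  if (cfg$n_mate_pairs > 0) {
    mates <- adults[seq_len(2 * cfg$n_mate_pairs)]
    for (k in seq_len(cfg$n_mate_pairs)) {
      pr <- mates[c(2 * k - 1, 2 * k)]
      pair_list[[k]] <- pr
      aff[[length(aff) + 1L]] <- data.frame(id1 = pr[1], id2 = pr[2],
                                            relation = "mate")
    }
  }
  regulars <- setdiff(adults, mates)
  regulars <- regulars[seq_len(min(cfg$n_regulars, length(regulars)))]
  if (cfg$n_sibling_groups > 0) {
    for (g in seq_len(cfg$n_sibling_groups)) {
      br <- juv[c(2 * g - 1, 2 * g)]
      aff[[length(aff) + 1L]] <- data.frame(id1 = br[1], id2 = br[2],
                                            relation = "sibling")
    }
  }
  if (cfg$n_parent_offspring_links > 0) {
    parents <- if (length(mates) > 0) mates else adults
    kids <- rep_len(juv, cfg$n_parent_offspring_links)
    pars <- rep_len(parents, cfg$n_parent_offspring_links)
    for (k in seq_len(cfg$n_parent_offspring_links))
      aff[[length(aff) + 1L]] <- data.frame(id1 = pars[k], id2 = kids[k],
                                            relation = "parent_offspring")
  }
  affiliations <- if (length(aff)) do.call(rbind, aff) else
    data.frame(id1 = character(), id2 = character(), relation = character())
  cls <- assign_classes(ids, pair_list, regulars)
  individuals <- data.frame(
    id = ids,
    class = unname(cls[ids]),
    entry_day = ifelse(ids %in% juv, cfg$juvenile_entry_day, 1L),
    is_regular = ids %in% regulars,
    stringsAsFactors = FALSE)
  list(individuals = individuals, affiliations = affiliations)
}

#' Simulate the dual-feeder market experiment
#'
#' Agent-based simulation with known ground truth. Per day-by-feeder
#' session, individuals arrive by a Poisson process (each active individual
#' makes on average `arrival_rate` visits per session at uniform times).
#' An arriving individual chooses among the feeders with a single current
#' occupant `j` -- joining with weight `exp(theta * affiliate(i,j) +
#' lambda * q[i,j])`, where `q[i,j]` is the cumulative net reward the pair
#' has experienced together -- and solo foraging at an empty feeder (weight
#' 1), a softmax partner-choice rule. Joining creates a dyadic association
#' event whose outcome is success if and only if the two share a treatment
#' class; outcomes update `q` by +1/-1. Each feeder runs the four-state
#' reward task ([step_task_state()]) and the state at each event onset is
#' recorded. Juveniles never appear before their entry day.
#'
#' Feeder task state is tracked independently per feeder unit.
#'
#' @param config A [market_config()].
#' @param emit_visits If `TRUE` (default) also return the per-second visit
#'   records from which [extract_events()] can recover the ground-truth
#'   event list exactly.
#' @return A list of class `market_sim` with elements `events` (the
#'   ground-truth ordered event table), `individuals`, `affiliations`,
#'   `visits` (per-second records, or `NULL`), and `config`.
#' @export
simulate_market <- function(config, emit_visits = TRUE) {
  stopifnot(inherits(config, "market_config"))
  cfg <- config
  set.seed(cfg$seed)
  pop <- build_population(cfg)
  ind <- pop$individuals
  n <- nrow(ind)
  idx <- setNames(seq_len(n), ind$id)
  cls <- ind$class
  entry <- ind$entry_day

  affmat <- matrix(FALSE, n, n)
  if (nrow(pop$affiliations) > 0) {
    i1 <- idx[pop$affiliations$id1]; i2 <- idx[pop$affiliations$id2]
    affmat[cbind(i1, i2)] <- TRUE; affmat[cbind(i2, i1)] <- TRUE
  }
  q <- matrix(0, n, n)  # cumulative net reward per dyad

  ev_day <- ev_feeder <- ev_src <- ev_tgt <- integer(0)
  ev_start <- ev_lat <- ev_dur <- integer(0)
  ev_state <- character(0)
  vis <- list()

  for (day in seq_len(cfg$n_days)) {
    active <- which(entry <= day)
    n_act <- length(active)
    if (n_act == 0) next
    n_arr <- stats::rpois(1, n_act * cfg$arrival_rate)
    n_arr <- min(n_arr, cfg$session_length - 1L)
    times <- sort(sample.int(cfg$session_length - 1L, n_arr))
    who <- active[sample.int(n_act, n_arr, replace = TRUE)]
    if (cfg$pair_follow > 0 && n_arr > 0) {
      # correlated pair movement: an affiliate may follow shortly after
      f_t <- f_w <- integer(0)
      for (a in seq_len(n_arr)) {
        partners <- which(affmat[who[a], ] & entry <= day)
        if (length(partners) && stats::runif(1) < cfg$pair_follow) {
          pt <- times[a] + sample(3:15, 1)
          pw <- partners[if (length(partners) > 1)
            sample.int(length(partners), 1) else 1L]
          f_t <- c(f_t, pt); f_w <- c(f_w, pw)
        }
      }
      if (length(f_t)) {
        all_t <- c(times, f_t); all_w <- c(who, f_w)
        keep <- !duplicated(all_t) & all_t < cfg$session_length
        o <- order(all_t[keep])
        times <- all_t[keep][o]; who <- all_w[keep][o]
        n_arr <- length(times)
      }
    }

    # per-feeder occupancy: occupant index, perch, arrival, departure
    occ_id <- matrix(0L, cfg$n_feeders, 2)
    occ_arr <- matrix(0L, cfg$n_feeders, 2)
    occ_dep <- matrix(0L, cfg$n_feeders, 2)
    refrac <- matrix(0L, n, cfg$n_feeders)
    present_until <- integer(n)
    fstate <- replicate(cfg$n_feeders, task_state(), simplify = FALSE)
    fstate_t <- numeric(cfg$n_feeders)
    pending_end <- numeric(cfg$n_feeders)  # end time of the open/last event

    for (a in seq_len(n_arr)) {
      t <- times[a]; i <- who[a]
      if (present_until[i] > t) next  # already on a perch somewhere
      gone <- occ_dep <= t
      occ_id[gone] <- 0L
      # candidate joins: feeders with exactly one present occupant (not i,
      # still there beyond t, and i not refractory at that feeder)
      nocc <- rowSums(occ_id != 0L)
      join_f <- which(nocc == 1L)
      w_join <- numeric(0)
      join_j <- integer(0)
      if (length(join_f)) {
        keep <- logical(length(join_f))
        jj <- integer(length(join_f))
        for (k in seq_along(join_f)) {
          f <- join_f[k]
          p <- which(occ_id[f, ] != 0L)
          j <- occ_id[f, p]
          keep[k] <- j != i && occ_dep[f, p] > t + 1L && refrac[i, f] <= t
          jj[k] <- j
        }
        join_f <- join_f[keep]; join_j <- jj[keep]
        if (length(join_f)) {
          eta <- cfg$affiliate_weight * affmat[cbind(join_j, rep(i, length(join_j)))] +
            cfg$learning_rate * q[cbind(join_j, rep(i, length(join_j)))]
          w_join <- exp(pmin(eta, 20))
        }
      }
      solo_f <- which(nocc == 0L & refrac[i, ] <= t)
      opts <- length(w_join) + (length(solo_f) > 0)
      if (opts == 0) next
      w <- c(w_join, if (length(solo_f)) 1 else numeric(0))
      pick <- sample.int(length(w), 1, prob = w)

      stay <- max(1L, as.integer(round(stats::rexp(1, 1 / cfg$stay_mean))))
      dep <- min(t + stay, cfg$session_length)
      if (dep <= t) next

      if (pick <= length(w_join)) {            # join occupant j at feeder f
        f <- join_f[pick]; jpos <- which(occ_id[f, ] != 0L)
        j <- occ_id[f, jpos]
        perch <- 3L - jpos
        end <- min(dep, occ_dep[f, jpos])
        same <- cls[i] == cls[j]
        # drive the reward task: dissolve the previous dyad at its end
        # time, elapse to t, then the new dyad forms
        if (pending_end[f] > fstate_t[f]) {
          st0 <- step_task_state(fstate[[f]], "solo",
                                 dt = pending_end[f] - fstate_t[f],
                                 lockout_duration = cfg$lockout_duration,
                                 min_success_access = cfg$min_success_access)
          fstate[[f]] <- st0$state; fstate_t[f] <- pending_end[f]
        }
        st <- step_task_state(fstate[[f]], "dyad", class_match = same,
                              dt = t - fstate_t[f],
                              lockout_duration = cfg$lockout_duration,
                              min_success_access = cfg$min_success_access)
        fstate[[f]] <- st$state; fstate_t[f] <- t
        pending_end[f] <- end
        ev_day <- c(ev_day, day); ev_feeder <- c(ev_feeder, f)
        ev_src <- c(ev_src, j); ev_tgt <- c(ev_tgt, i)
        ev_start <- c(ev_start, t)
        ev_lat <- c(ev_lat, t - occ_arr[f, jpos])
        ev_dur <- c(ev_dur, end - t)
        ev_state <- c(ev_state, st$state$state)
        d <- if (same) 1 else -1
        q[i, j] <- q[i, j] + d; q[j, i] <- q[i, j]
      } else {                                  # solo at an empty feeder
        f <- solo_f[if (length(solo_f) > 1) sample.int(length(solo_f), 1) else 1L]
        perch <- sample.int(2L, 1)
      }
      occ_id[f, perch] <- i
      occ_arr[f, perch] <- t
      occ_dep[f, perch] <- dep
      present_until[i] <- dep
      refrac[i, f] <- dep + cfg$gap_tolerance + 1L
      if (emit_visits)
        vis[[length(vis) + 1L]] <- c(i, day, f, perch, t, dep)
    }
  }

  ord <- order(ev_day, ev_start, ev_feeder)
  events <- data.frame(
    index = seq_along(ord),
    day = ev_day[ord],
    apparatus = ev_feeder[ord],
    source = ind$id[ev_src[ord]],
    target = ind$id[ev_tgt[ord]],
    start_time = ev_start[ord],
    arrival_latency = ev_lat[ord],
    duration = ev_dur[ord],
    outcome = ifelse(cls[ev_src[ord]] == cls[ev_tgt[ord]], "success", "fail"),
    is_same_class = cls[ev_src[ord]] == cls[ev_tgt[ord]],
    is_affiliate = affmat[cbind(ev_src[ord], ev_tgt[ord])],
    task_state = ev_state[ord],
    stringsAsFactors = FALSE)

  visits <- NULL
  if (emit_visits && length(vis)) {
    vm <- do.call(rbind, vis)
    lens <- vm[, 6] - vm[, 5]
    visits <- data.frame(
      tag_id = rep(ind$id[vm[, 1]], lens),
      day = rep(vm[, 2], lens),
      feeder = rep(vm[, 3], lens),
      perch = rep(vm[, 4], lens),
      time = sequence(lens, from = vm[, 5]),
      stringsAsFactors = FALSE)
    visits <- visits[order(visits$day, visits$feeder, visits$perch,
                           visits$time), , drop = FALSE]
    rownames(visits) <- NULL
  }

  structure(list(events = events, individuals = ind,
                 affiliations = pop$affiliations, visits = visits,
                 config = cfg),
            class = "market_sim")
}

#' @export
print.market_sim <- function(x, ...) {
  cat("<market_sim>", nrow(x$individuals), "individuals,",
      nrow(x$events), "events over", x$config$n_days, "days\n")
  cat(sprintf("  success rate %.1f%%; affiliate events %.1f%%\n",
              100 * mean(x$events$outcome == "success"),
              100 * mean(x$events$is_affiliate)))
  invisible(x)
}

#' Write simulated visit and individual tables as CSV
#'
#' Visit records are one row per occupied second (`tag_id, day, feeder,
#' perch, time`); the individuals table and the affiliation edge list are
#' written alongside.
#'
#' @param sim A `market_sim` object with visits.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_market_csv <- function(sim, dir) {
  stopifnot(inherits(sim, "market_sim"))
  if (is.null(sim$visits)) stop("simulation was run with emit_visits = FALSE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("visits.csv", "individuals.csv",
                            "affiliations.csv", "events.csv"))
  utils::write.csv(sim$visits, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$individuals, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$affiliations, paths[3], row.names = FALSE, quote = FALSE)
  write_events(sim$events, paths[4])
  invisible(paths)
}
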