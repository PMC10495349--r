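# brute-force oracles recomputing statistics from a raw event list
brute_pair_count <- function(events, a, b) {
  sum((events$source == a & events$target == b) |
        (events$source == b & events$target == a))
}
brute_repeated <- function(events, ind, id, filter) {
  cls <- setNames(ind$class, ind$id)
  partners <- setdiff(ind$id, id)
  hits <- vapply(partners, function(p) brute_pair_count(events, id, p) >= 2,
                 logical(1))
  match_cls <- if (filter == "same") cls[partners] == cls[id]
               else cls[partners] != cls[id]
  sum(hits & match_cls)
}
brute_common <- function(events, ind, a, b, same_only = FALSE, min_events = 1) {
  cls <- setNames(ind$class, ind$id)
  third <- setdiff(ind$id, c(a, b))
  hits <- vapply(third, function(p)
    brute_pair_count(events, a, p) >= min_events &&
      brute_pair_count(events, b, p) >= min_events, logical(1))
  if (same_only) hits <- hits & cls[third] == cls[a]
  sum(hits)
}

random_history <- function(ind, n, seed) {
  set.seed(seed)
  src <- tgt <- character(n)
  for (k in seq_len(n)) {
    pair <- sample(ind$id, 2)
    src[k] <- pair[1]; tgt[k] <- pair[2]
  }
  make_event_table(src, tgt, ind)
}

test_that("experience bins match the defined thresholds", {
  expect_equal(bin_experience(c(0, 1, 5, 6, 40)),
               c("none", "low", "low", "high", "high"))
  expect_error(bin_experience(-1), "non-negative")
})

test_that("repeated-partner counts match a brute-force recount", {
  ind <- make_individuals(rep(c("A", "B"), 4))
  ev <- random_history(ind, 60, seed = 2)
  st <- network_state(ind)
  apply_event(st, ev$source, ev$target)
  for (id in ind$id) {
    expect_equal(repeated_partner_count(st, id, "same"),
                 brute_repeated(ev, ind, id, "same"))
    expect_equal(repeated_partner_count(st, id, "different"),
                 brute_repeated(ev, ind, id, "different"))
  }
  # empty history and a single repeated partner
  st0 <- network_state(ind)
  expect_equal(repeated_partner_count(st0, "I01", "same"), 0)
  apply_event(st0, c("I01", "I01"), c("I03", "I03"))  # both class A
  expect_equal(repeated_partner_count(st0, "I01", "same"), 1)
  expect_equal(repeated_partner_count(st0, "I01", "different"), 0)
})

test_that("common-associate counts match brute-force set intersection", {
  ind <- make_individuals(c("A", "A", "A", "B", "B", "A"))
  # triangle history {I01-I02, I01-I03, I02-I03}, all class A
  st <- network_state(ind)
  apply_event(st, c("I01", "I01", "I02"), c("I02", "I03", "I03"))
  expect_equal(common_associates(st, "I01", "I02", same_class_only = TRUE), 1)
  expect_equal(common_associates(st, "I01", "I02"), 1)
  expect_error(common_associates(st, "I01", "I04", same_class_only = TRUE),
               "different-class")
  expect_equal(common_associates(network_state(ind), "I01", "I02"), 0)

  ev <- random_history(ind, 80, seed = 5)
  st2 <- network_state(ind)
  apply_event(st2, ev$source, ev$target)
  cls <- setNames(ind$class, ind$id)
  combos <- combn(ind$id, 2)
  for (k in seq_len(ncol(combos))) {
    a <- combos[1, k]; b <- combos[2, k]
    expect_equal(common_associates(st2, a, b),
                 brute_common(ev, ind, a, b))
    if (cls[a] == cls[b]) {
      cs <- common_associates(st2, a, b, same_class_only = TRUE)
      expect_equal(cs, brute_common(ev, ind, a, b, same_only = TRUE))
      expect_lte(cs, common_associates(st2, a, b))
    }
  }
})

test_that("incremental state equals a from-scratch rebuild at every prefix", {
  ind <- make_individuals(rep(c("A", "B"), 5))
  ev <- random_history(ind, 40, seed = 7)
  st <- network_state(ind)
  for (k in seq_len(nrow(ev))) {
    apply_event(st, ev$source[k], ev$target[k])
    if (k %% 10 == 0) {
      fresh <- network_state(ind)
      apply_event(fresh, ev$source[seq_len(k)], ev$target[seq_len(k)])
      expect_identical(st$pc, fresh$pc)
      expect_identical(st$n_events, fresh$n_events)
    }
  }
})

test_that("the first event of an experiment carries zero history covariates", {
  ind <- make_individuals(c("A", "A", "B", "B"))
  ev <- make_event_table("I01", "I02", ind)
  non <- data.frame(source = "I02", target = "I03")  # different-class pair
  for (m in c("M1", "M2", "M4", "M5", "M8")) {
    des <- build_design(ev, non, m, ind)
    expect_true(all(des[, attr(des, "terms")] == 0))
  }
  des3 <- build_design(ev, non, "M3", ind)
  expect_equal(des3$same_class, c(1, 0))
})

test_that("the event clock is scaled per 1000 events", {
  ind <- make_individuals(c("A", "A"))
  n <- 1000
  ev <- make_event_table(rep("I01", n), rep("I02", n), ind,
                         start = seq_len(n))
  non <- data.frame(source = rep("I01", n), target = rep("I02", n))
  des <- build_design(ev, non, "M3", ind)
  last <- des[des$index == 1000 & des$is_observed, ]
  expect_equal(last$clock, 1)
  expect_equal(last$same_class_clock, 1)
})

test_that("design covariates equal a non-incremental recomputation (all models)", {
  ind <- make_individuals(rep(c("A", "B"), 6))
  ev <- random_history(ind, 50, seed = 11)
  ev$is_affiliate <- rep(c(TRUE, FALSE), 25)
  set.seed(12)
  non <- data.frame(source = sample(ev$source), target = sample(ev$target),
                    arrival_latency = sample(ev$arrival_latency),
                    duration = sample(ev$duration))
  bad <- which(non$source == non$target)
  non$target[bad] <- ifelse(non$source[bad] == "I01", "I02", "I01")
  cls <- setNames(ind$class, ind$id)

  oracle_row <- function(model, s, t, k) {
    hist <- ev[seq_len(k - 1), , drop = FALSE]
    clock <- k / 1000
    switch(model,
      M1 = {
        cnt <- function(id, same) {
          sum(vapply(setdiff(ind$id, id), function(p) {
            m <- brute_pair_count(hist, id, p)
            if ((cls[p] == cls[id]) == same) m else 0L
          }, numeric(1)))
        }
        c(cnt(s, TRUE) + cnt(t, TRUE), cnt(s, FALSE) + cnt(t, FALSE))
      },
      M2 = c(brute_repeated(hist, ind, s, "same") +
               brute_repeated(hist, ind, t, "same"),
             brute_repeated(hist, ind, s, "different") +
               brute_repeated(hist, ind, t, "different")),
      M4 = {
        prior <- brute_pair_count(hist, s, t)
        same <- cls[s] == cls[t]
        lo <- prior >= 1 && prior <= 5; hi <- prior >= 6
        as.numeric(c(lo, hi, lo && same, hi && same))
      },
      M8 = {
        any_ct <- brute_common(hist, ind, s, t)
        same_ct <- if (cls[s] == cls[t])
          brute_common(hist, ind, s, t, same_only = TRUE) else 0
        c(any_ct, same_ct, any_ct * clock, same_ct * clock)
      })
  }

  for (m in c("M1", "M2", "M4", "M8")) {
    des <- build_design(ev, non, m, ind)
    terms <- attr(des, "terms")
    for (k in c(1, 7, 25, 50)) {
      obs <- as.numeric(des[des$index == k & des$is_observed, terms])
      ctr <- as.numeric(des[des$index == k & !des$is_observed, terms])
      expect_equal(obs, unname(oracle_row(m, ev$source[k], ev$target[k], k)),
                   info = paste(m, "observed", k))
      expect_equal(ctr, unname(oracle_row(m, non$source[k], non$target[k], k)),
                   info = paste(m, "non-event", k))
    }
  }

  # edge-weight models: covariate is weight x same-class of observed labels
  des6 <- build_design(ev, non, "M6", ind)
  same <- unname(cls[ev$source] == cls[ev$target])
  expect_equal(des6$latency_same[des6$is_observed],
               ev$arrival_latency * same)
  expect_equal(des6$latency_same[!des6$is_observed],
               non$arrival_latency * same)
})

test_that("non-events share stratum and clock with their paired event", {
  sim <- simulate_market(market_config(seed = 19, n_days = 4),
                         emit_visits = FALSE)
  plan <- permutation_plan("joint_labels")
  set.seed(4)
  perm <- permute_events(sim$events, plan)
  des <- build_design(sim$events, perm, "M3", sim$individuals)
  for (col in c("stratum", "apparatus", "clock"))
    expect_equal(des[[col]][des$is_observed], des[[col]][!des$is_observed])
})
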