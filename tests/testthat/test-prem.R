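# independent grid-search maximiser of the paired conditional-logistic
# log-likelihood (one covariate)
grid_mle <- function(d) {
  ll <- function(beta) sum(stats::plogis(d * beta, log.p = TRUE))
  coarse <- seq(-8, 8, by = 0.01)
  b0 <- coarse[which.max(vapply(coarse, ll, numeric(1)))]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-6)
  fine[which.max(vapply(fine, ll, numeric(1)))]
}

test_that("splicing produces a strict event/non-event alternation", {
  ind <- make_individuals(c("A", "B", "A"))
  ev <- make_event_table(c("I01", "I02", "I01"), c("I02", "I03", "I03"), ind)
  non <- data.frame(source = c("I02", "I01", "I02"),
                    target = c("I03", "I03", "I01"),
                    arrival_latency = c(1, 2, 3), duration = c(4, 5, 6))
  sp <- splice(ev, non)
  expect_equal(nrow(sp), 6)
  expect_equal(sp$index, c(1, 1, 2, 2, 3, 3))
  expect_equal(sp$is_observed, rep(c(TRUE, FALSE), 3))
  expect_equal(sp$day[sp$is_observed], sp$day[!sp$is_observed])
  expect_error(splice(ev, non[1:2, ]), "misaligned")
  sp1 <- splice(ev[1, ], non[1, ])
  expect_equal(sp1$is_observed, c(TRUE, FALSE))
})

test_that("every spliced pair shares its day stratum on simulated data", {
  sim <- simulate_market(market_config(seed = 37, n_days = 4),
                         emit_visits = FALSE)
  set.seed(1)
  perm <- permute_events(sim$events, permutation_plan("joint_labels"))
  sp <- splice(sim$events, perm)
  odd <- sp[seq(1, nrow(sp), 2), ]
  even <- sp[seq(2, nrow(sp), 2), ]
  expect_equal(odd$day, even$day)
  expect_equal(odd$start_time, even$start_time)
})

test_that("the matched-pair fit equals the discordant-ratio closed form", {
  # 3 pairs case-exposed/control-unexposed, 1 pair the reverse: beta = ln 3
  D <- list(case = matrix(c(1, 1, 1, 0), ncol = 1),
            control = matrix(c(0, 0, 0, 1), ncol = 1))
  fit <- fit_partial_likelihood(D)
  expect_true(fit$converged)
  expect_equal(unname(fit$coef), log(3), tolerance = 1e-6)
})

test_that("a covariate identical within every pair is flagged, not estimated", {
  D <- list(case = matrix(c(1, 2, 3, 1, 0, 1), ncol = 2,
                          dimnames = list(NULL, c("same", "varies"))),
            control = matrix(c(1, 2, 3, 0, 1, 0), ncol = 2,
                             dimnames = list(NULL, c("same", "varies"))))
  fit <- fit_partial_likelihood(D)
  expect_true(is.na(fit$coef["same"]))
  expect_equal(fit$flagged, "same")
  expect_false(is.na(fit$coef["varies"]))
})

test_that("separation is reported as non-convergence naming the term", {
  D <- list(case = matrix(rep(1, 6), ncol = 1,
                          dimnames = list(NULL, "exposed")),
            control = matrix(rep(0, 6), ncol = 1,
                             dimnames = list(NULL, "exposed")))
  fit <- fit_partial_likelihood(D)
  expect_false(fit$converged)
  expect_equal(fit$separated, "exposed")
})

test_that("Newton fits match an independent grid-search maximiser", {
  for (s in 1:5) {
    set.seed(s)
    d <- matrix(round(stats::rnorm(50), 1), ncol = 1)
    if (all(d == 0) || all(d >= 0) || all(d <= 0)) next
    fit <- fit_partial_likelihood(list(case = d,
                                       control = matrix(0, 50, 1)))
    expect_true(fit$converged)
    expect_equal(unname(fit$coef), grid_mle(drop(d)), tolerance = 1e-5)
  }
})

test_that("the fit agrees with a general stratified Cox solver", {
  skip_if_not_installed("survival")
  set.seed(8)
  n <- 120
  x1 <- stats::rnorm(n); x0 <- stats::rnorm(n)
  z1 <- stats::rbinom(n, 1, 0.5); z0 <- stats::rbinom(n, 1, 0.5)
  fit <- fit_partial_likelihood(list(case = cbind(x = x1, z = z1),
                                     control = cbind(x = x0, z = z0)))
  df <- data.frame(y = rep(c(1, 0), n), pair = rep(seq_len(n), each = 2),
                   x = as.vector(rbind(x1, x0)),
                   z = as.vector(rbind(z1, z0)))
  cox <- survival::coxph(survival::Surv(rep(1, 2 * n), y) ~ x + z +
                           survival::strata(pair), data = df,
                         ties = "exact")
  expect_equal(unname(fit$coef), unname(stats::coef(cox)), tolerance = 1e-6)
})

test_that("within-pair differencing absorbs constant covariate shifts", {
  set.seed(9)
  case <- cbind(x = stats::rnorm(30))
  control <- cbind(x = stats::rnorm(30))
  f1 <- fit_partial_likelihood(list(case = case, control = control))
  shift <- stats::rnorm(30)
  f2 <- fit_partial_likelihood(list(case = case + shift,
                                    control = control + shift))
  expect_equal(f1$coef, f2$coef, tolerance = 1e-10)
})

test_that("prem aggregates replicate coefficients into median IRRs and CIs", {
  sim <- simulate_market(market_config(seed = 41, n_days = 6),
                         emit_visits = FALSE)
  fit <- prem(sim$events, sim$individuals, model = "M3",
              n_replicates = 30, seed = 2)
  expect_s3_class(fit, "prem")
  expect_equal(dim(fit$coef_samples), c(30, 2))
  expect_equal(unname(fit$irr), unname(exp(fit$median)))
  expect_true(all(fit$median >= fit$ci[, "lower"] &
                    fit$median <= fit$ci[, "upper"]))
  expect_equal(unname(fit$significant),
               unname(fit$ci[, "lower"] > 0 | fit$ci[, "upper"] < 0))
  # determinism
  fit2 <- prem(sim$events, sim$individuals, model = "M3",
               n_replicates = 30, seed = 2)
  expect_identical(fit$coef_samples, fit2$coef_samples)
  # quantile CIs widen monotonically with the level
  ci95 <- confint(fit, level = 0.95)
  ci975 <- confint(fit, level = 0.975)
  expect_true(all(ci975[, "lower"] <= ci95[, "lower"]))
  expect_true(all(ci975[, "upper"] >= ci95[, "upper"]))
})

test_that("model registry carries the permutation variant and CI mapping", {
  reg <- prem_models()
  expect_equal(reg$M1$variant, "independent_labels")
  expect_equal(reg$M2$variant, "independent_labels")
  for (m in c("M3", "M4", "M5", "M8"))
    expect_equal(reg[[m]]$variant, "joint_labels")
  for (m in c("M6", "M7"))
    expect_equal(reg[[m]]$variant, "edge_weights")
  expect_equal(reg$M1$ci_level, 0.975)
  expect_equal(reg$M2$ci_level, 0.975)
  expect_equal(reg$M3$ci_level, 0.95)
})

test_that("rate predictions propagate the coefficient distribution", {
  sim <- simulate_market(market_config(seed = 43, n_days = 4),
                         emit_visits = FALSE)
  fit <- prem(sim$events, sim$individuals, model = "M3",
              n_replicates = 20, seed = 3)
  # degenerate at IRR 1: zero profile leaves the baseline untouched
  pr0 <- predict_rates(fit, c(same_class = 0), baseline_rate = 1.75)
  expect_equal(pr0$median, 1.75)
  expect_equal(pr0$lower, 1.75)
  # brute-force per-sample exponentiation
  prof <- c(same_class = 1, same_class_clock = 0.5)
  pr <- predict_rates(fit, prof, baseline_rate = 3.62)
  manual <- 3.62 * exp(fit$coef_samples %*% prof)
  expect_equal(sort(pr$samples), sort(drop(manual)))
  expect_equal(pr$median, unname(stats::quantile(manual, 0.5)))
  expect_error(predict_rates(fit, c(bogus = 1)), "unknown term")
  expect_error(predict_rates(fit, c(same_class = 1), baseline_rate = 0),
               "positive")
})
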