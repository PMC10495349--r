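---
title: "Permuted relational event models for dynamic partner choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permuted relational event models for dynamic partner choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premnet)
```

## The problem

In a social-network-manipulation experiment, wild corvids carrying RFID leg
tags visit paired automated feeders. Each bird is randomly assigned to one
of two treatment classes, A or B. When two birds occupy the two perches of
a feeder unit simultaneously they form a dyadic *association event*: a
same-class dyad is rewarded (access to a high-quality food), a
different-class dyad is penalised (the feeder locks out). The scientific
questions are whether individuals *learn* to choose compatible (same-class)
partners, whether long-term relationships (mates, parent–offspring,
siblings — "affiliates") constrain that plasticity, and whether individual
partner choice produces network-level clustering of compatible birds.

`premnet` implements the full analysis chain for such data — event
extraction from perch-visit streams, constrained data-stream permutations,
time-varying network covariates, and stratified partial-likelihood fitting
— together with an agent-based simulator of the experiment that provides
known ground truth for validation.

## The estimator

A relational event model (REM) treats the stream of timestamped dyadic
events as a time-to-event process: covariates computed from the interaction
history up to each event predict which interactions occur. Conventional REM
inference samples "non-events" uniformly from all possible dyads, but that
is invalid here: individuals differ enormously in visitation, birds that
fledged mid-experiment exist only in later sessions, and co-presence is
structured by fission–fusion dynamics. Instead, non-events are generated by
*data-stream permutation*: within each day-by-feeder subset of the observed
events, participant labels are shuffled, so the permuted data preserve
exactly who was active, where, when, and how often.

Three permutation variants serve different hypotheses (a fourth,
target-only shuffling, is included as experimental):

* **independent label shuffling** — source and target columns shuffled
  separately, preserving each individual's per-role counts (used for
  individual-level models M1–M2);
* **joint label shuffling** — all `2n` labels pooled and redistributed,
  preserving total participation but not roles (dyad- and network-level
  models M3–M5, M8);
* **edge-weight shuffling** — only latency or duration values permuted
  (coordination models M6–M7).

Label shuffles can create *loops* (an individual paired with itself); a
subset is re-shuffled until loop-free, up to 10,000 times, after which
constrained pairwise swaps repair the remaining loops: for each loop, a
random other row not featuring the looped individual is drawn and one role
label (chosen at random) is exchanged, producing two valid rows. Swaps are
a fallback because constrained swapping can randomize less thoroughly than
re-shuffling.

Each observed event is spliced with its single permuted counterpart and the
pair shares its stratum (day) and time. For this 1:1 case–control design
the stratified Cox partial likelihood collapses *exactly* to the matched
conditional-logistic likelihood

$$\ell(\beta) = \sum_k \left[ x^{(1)}_k \beta -
  \log\!\left(e^{x^{(1)}_k \beta} + e^{x^{(0)}_k \beta}\right)\right]
  = \sum_k \log \sigma\!\left((x^{(1)}_k - x^{(0)}_k)\beta\right),$$

which `fit_partial_likelihood()` maximises by Newton iteration with
analytic gradient and Hessian (convergence at max |score| < 1e−8, at most
50 iterations). We implement this reduction directly rather than calling a
general Cox solver because it is exact, fast enough to refit thousands of
replicates, and free of tie-handling ambiguity; the test suite cross-checks
it against `survival::coxph` with exact ties, against the closed form
β = ln(discordant ratio) for a binary covariate, and against a grid-search
maximiser.

Fitting one model per permuted replicate yields a distribution of
coefficients for each term. The median is the point estimate, quantile
intervals (2.5%/97.5%, or 1.25%/98.75% for the two individual-level models,
a Bonferroni-style widening for their shared dataset) give the confidence
interval, and a term is significant when its coefficient-scale interval
excludes zero. Exponentiated values are reported as incidence rate ratios
(IRR): how many times more or less likely an event with that covariate
profile is, relative to the permutation baseline.

## The model registry

Exact covariate lists for the original eight models are reconstructed from
the reported results rather than copied from a published registry, and are
marked as such:

| id | level | covariates | variant | CI |
|----|-------|-----------|---------|----|
| M1 | individual | cumulative same-/different-class event counts of the two participants | independent | 97.5% |
| M2 | individual | counts of same-/different-class partners associated with repeatedly (≥2 events) | independent | 97.5% |
| M3 | dyad | class-match indicator; class-match × events/1000 | joint | 95% |
| M4 | dyad (non-affiliates) | experience bins (1–5, 6+) and their class-match interactions | joint | 95% |
| M5 | dyad (affiliates) | as M4 | joint | 95% |
| M6 | coordination | arrival latency (s) × class match | edge weights | 95% |
| M7 | coordination | association duration (s) × class match | edge weights | 95% |
| M8 | network | common associates (any class / dyad's class), each × events/1000 | joint | 95% |

Design choices made where the original specification is open:

* M1/M2 are fitted on the successful-event subset (the individual-level
  hypothesis concerns future *success*) with each event carrying the
  summed covariates of its two participants; this is configurable.
* M4 and M5 are separate subset models, not one interaction model, because
  their results are reported separately.
* A "common associate" requires at least one prior joint event with each
  dyad member (`min_common`, configurable); the class-restricted count is
  defined only for same-class dyads and is zero otherwise.
* The per-1000-events clock counts observed events globally across
  feeders; event `k` carries clock `k/1000`.
* Non-events inherit the clock and stratum of their paired event and
  never update the network state, so covariates for any event depend only
  on strictly earlier *observed* events.

## The simulator

`simulate_market()` is an agent-based emulation of the dual-feeder
experiment with known ground truth. Its defaults define the package's
reference desk-scale conditions: 60 individuals (8 mated pairs, 3
two-fledgling sibling broods entering at the session midpoint, 6
parent–offspring links, 10 class-balanced regulars), 20 four-hour daily
sessions, two feeder units, a mean perch stay of 30 s, and about five
visits per bird per session — producing on the order of 1,500 events,
roughly the per-month event rate of the field experiment it emulates.

Behaviour follows a softmax partner-choice rule, invented here because the
field protocol defines only the task, not a generative behaviour model: an
arriving bird `i` joins a feeder currently occupied by a single bird `j`
with weight $\exp(\theta\,\mathrm{affil}(i,j) + \lambda\, q_{ij})$ against
weight 1 for foraging solo, where `q_ij` is the cumulative net reward the
pair has experienced (+1 per success, −1 per failure, the exponent capped
at 20 for numerical safety). λ (`learning_rate`) is the class-learning
dial; θ (`affiliate_weight`) the affiliate-retention dial. With
λ = θ = 0 partner choice is uniform and the same-class event fraction
converges to the closed-form random-mixing expectation
(`expected_same_class_fraction()`), which the test suite verifies.

Two further features mirror the field system:

* **Correlated pair movement.** With probability `pair_follow` (default
  0.15) an arriving bird is trailed by one of its affiliates a few seconds
  later. This reproduces the strong over-representation of affiliate
  dyads among events (about 10% of events from under 2% of dyads at the
  defaults, against 20.8% from 2.4% in the field data) without touching
  the choice rule. θ defaults to 4 so that a bird encountering its
  affiliate on a perch almost always joins it.
* **The four-state reward task.** Each feeder runs the full state machine
  (`step_task_state()`): default, lockout (≥120 s, restarted by further
  unsuccessful dyads), success (both rewards, the high-quality reward held
  open for at least 15 s from onset), and lockout-override (high-quality
  reward only). All eight transitions are exercised and the state at each
  event onset is recorded. Lockout state is tracked independently per
  feeder unit; how lockouts couple across the two units of one apparatus
  is not documented for the original hardware, so independence is assumed
  and flagged here.

Visit records are emitted as one row per occupied second per perch,
exactly the RFID logger format, and `extract_events()` recovers the
simulated ground-truth event list from them bit-for-bit (a round-trip the
tests enforce). Re-visits are kept farther apart than the event-merging
gap tolerance (2 s, bridging single missed reads) so the recovery is
exact. Simultaneous arrivals are resolved by taking the lexicographically
smaller id as source; the simulator avoids ties altogether by drawing
arrival seconds without replacement within a session.

What the simulator does *not* emulate: spatial movement and neophobia,
food-preference differences, sex or age structure beyond entry day, the
RFID duration-correction procedure applied to the original loggers
(extraction instead uses the stated gap-bridging rule), and weather- or
season-driven visitation trends. Passing calibration and recovery tests on
synthetic streams therefore demonstrates correctness of the inference
machinery under the generative model, not the field realism of that model.

## Numerical and procedural choices

* Quantiles everywhere use R's default linear interpolation (type 7).
* Replicate `r` of a permutation run draws its RNG substream from a seed
  vector generated once from the user seed, so results are reproducible
  from `(seed, r)` and independent of how many replicates run before `r`.
* Separation in a replicate fit is detected as a diverging coefficient
  (|β| > 15) whose within-pair differences share one sign; such replicates
  are dropped from the coefficient distribution and counted, with a hard
  warning above 10%. Terms with no within-pair variance are returned as
  `NA` and flagged rather than reported as zero.
* `resolve_loops()` scans loops in subset order, draws swap partners
  uniformly among eligible rows and errors with a diagnostic if none
  exists (only possible for degenerate subsets that valid field data
  cannot produce).
* The baseline event rate attached to fitted models is events per hour of
  session time; rate predictions (`predict_rates()`) multiply a baseline
  by `exp(profile · β)` per replicate and summarise with a 95% prediction
  interval.

## Reference desk scale

The package's own validation experiments (reported by the test suite and
`scripts/acceptance.R`) use the default simulator scale — 60 individuals
and roughly 1,500 events per stream — with 200 permuted replicates per fit
and 200 independent runs for calibration claims. These sizes give stable
95% quantile intervals while keeping a full calibration experiment in the
minutes range; the full-scale design (10,000 replicates) is a single
argument change.

Under the clean null (λ = θ = 0, independent arrivals) the dyad-level
class-match term is significant in about 5% of runs and the observed
success proportion falls inside the permuted 95% interval in about 95% of
runs. With correlated pair arrivals switched on, repeated-dyad
overdispersion makes the permutation test mildly anti-conservative — a
known property of label-permutation nulls when the observed stream repeats
dyads more than the permuted ones do, and worth remembering when
interpreting borderline field results.

## Data-density requirements of the experience models

The experience-bin models (M4, M5) compare each event's dyad history to
that of its permuted counterpart. They are only estimable when permuted
non-events regularly land on dyads that themselves have prior history —
i.e. when the stream repeats dyads densely (the field data average ~4
events per observed dyad). At the default desk scale events are spread
thinly (~1.6 per dyad), permuted controls almost never carry experience,
the within-pair differences become one-signed, and the fit correctly
reports separation and drops the replicate. A denser configuration (e.g.
24 individuals, 30 days, `arrival_rate = 10`, ~5.6 events per dyad) fits
cleanly and reproduces the qualitative published pattern: strong positive
experience-by-class-match interactions for non-affiliate dyads, and very
large experience main effects with class-null interactions for affiliate
dyads. The dyad-level trend model (M3), the coordination models (M6–M7)
and the triadic-closure model (M8) are estimable at the default scale.

## Known limitations

* The covariate lists of the eight models are reconstructions from
  reported results, not a copy of the original specification.
* The identity of the fourth permutation variant in the original toolchain
  is not documented; `target_only` is a placeholder and should not be used
  for inference.
* The triadic-closure statistic counts distinct common associates; a
  sum-over-triads variant of the original network statistic may differ by
  multiplicity. The threshold defining an "associate" is configurable.
* The unconditional triad-composition expectation ignores degree
  heterogeneity; a degree-conditioned null would be tighter but is out of
  scope.
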