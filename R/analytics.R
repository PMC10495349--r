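#' Expected fraction of same-class dyads under random assignment
#'
#' Probability that a uniformly random dyad drawn from `n_A + n_B`
#' individuals is single-class:
#' \deqn{[\binom{n_A}{2} + \binom{n_B}{2}] / \binom{n_A + n_B}{2}.}
#' With equal class sizes `n_A = n_B = n` this equals `(n - 1)/(2n - 1) <
#' 1/2`: same-class dyads are rarer than different-class dyads by chance.
#' These are null oracles under sampling blind to visitation rates, not
#' fitted quantities.
#'
#' @param n_A,n_B Class sizes (non-negative; at least 2 individuals total).
#' @return Probability in `[0, 1]`.
#' @export
expected_same_class_fraction <- function(n_A, n_B) {
  if (n_A < 0 || n_B < 0) stop("class sizes must be non-negative")
  if (n_A + n_B < 2) stop("need at least 2 individuals")
  (choose(n_A, 2) + choose(n_B, 2)) / choose(n_A + n_B, 2)
}

#' Expected fraction of single-class triads under random assignment
#'
#' Probability that a uniformly random triad is single-class:
#' \deqn{[\binom{n_A}{3} + \binom{n_B}{3}] / \binom{n_A + n_B}{3}.}
#' With balanced classes the value is below 1/4 for all finite sizes and
#' tends to 1/4 as the group grows, so single-class triads are expected
#' less often than mixed-composition triads under a random process.
#'
#' @param n_A,n_B Class sizes (at least 3 individuals total).
#' @return Probability in `[0, 1]`.
#' @export
expected_uniform_triad_fraction <- function(n_A, n_B) {
  if (n_A < 0 || n_B < 0) stop("class sizes must be non-negative")
  if (n_A + n_B < 3) stop("need at least 3 individuals")
  (choose(n_A, 3) + choose(n_B, 3)) / choose(n_A + n_B, 3)
}
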