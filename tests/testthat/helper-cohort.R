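# Cohort fixtures built in code.

# Cohort whose metric equals the given values (carried on f_bw, f_rw = 0).
cohort_from_metrics <- function(metrics, eligible = NULL) {
  d <- tibble::tibble(
    id = sprintf("p%03d", seq_along(metrics)),
    f_bw = metrics, f_rw = 0
  )
  if (!is.null(eligible)) d$eligible <- eligible
  as_cohort(d)
}

# Exhaustive threshold-accuracy oracle: best achievable training accuracy of
# the ">= t -> ineligible" rule over every candidate cutoff (all midpoints
# and sentinels), computed directly.
best_threshold_accuracy <- function(values, eligible) {
  v <- sort(unique(values))
  cand <- c(v[1] - 1, if (length(v) > 1) (head(v, -1) + tail(v, -1)) / 2,
            v[length(v)] + 1)
  max(vapply(cand, function(t) {
    mean((values >= t) == !eligible)
  }, numeric(1)))
}

# Exact two-sided rank-sum p-value by enumerating every assignment of the
# pooled observations to group A (small n only).
exact_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  sums <- apply(idx, 2, function(ii) sum(r[ii]))
  obs <- sum(r[seq_len(n1)])
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}
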