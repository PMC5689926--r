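#' Single-threshold eligibility classifier
#'
#' The classifier has one parameter: a scalar cutoff on one feature (the
#' combined overlap metric by default). A patient is predicted
#' *ineligible* iff the feature value is greater than or equal to the
#' threshold; the boundary is inclusive.
#'
#' @param threshold Scalar cutoff (>= 0 for overlap features).
#' @param feature One of `"metric"`, `"f_bw"`, `"f_rw"`, `"ptv_volume_cc"`.
#' @return A `threshold_model` object.
#' @export
threshold_model <- function(threshold, feature = "metric") {
  feature <- match.arg(feature, c("metric", "f_bw", "f_rw", "ptv_volume_cc"))
  if (!is.finite(threshold)) ot_abort("Threshold must be finite.", "domain_error")
  structure(list(threshold = as.numeric(threshold), feature = feature),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> ineligible iff %s >= %g\n", x$feature, x$threshold))
  if (!is.null(attr(x, "train_accuracy"))) {
    cat(sprintf("  training accuracy %.3f (n = %d)\n",
                attr(x, "train_accuracy"), attr(x, "n_train")))
  }
  invisible(x)
}

#' Apply the threshold rule
#'
#' @param values Numeric feature values.
#' @param model A [threshold_model()] (or scalar threshold).
#' @return Factor with levels `eligible`, `ineligible`; a value is
#'   `ineligible` iff it is `>=` the threshold.
#' @export
classify_threshold <- function(values, model) {
  t <- if (inherits(model, "threshold_model")) model$threshold else as.numeric(model)
  if (any(!is.finite(values))) ot_abort("Feature values must be finite.", "domain_error")
  factor(ifelse(values >= t, "ineligible", "eligible"),
         levels = c("eligible", "ineligible"))
}

# Candidate cutoffs: midpoints between consecutive distinct sorted values,
# plus one sentinel below the minimum and one above the maximum.
threshold_candidates <- function(values) {
  v <- sort(unique(values))
  d <- if (length(v) > 1) stats::median(diff(v)) / 2 else 1
  c(v[1] - d, if (length(v) > 1) (head(v, -1) + tail(v, -1)) / 2, v[length(v)] + d)
}

#' Fit the threshold by exhaustive cutoff search
#'
#' Scans every candidate cutoff (midpoints between consecutive distinct
#' feature values plus sentinels below/beyond the data range) and returns the
#' one maximizing training accuracy under the rule "ineligible iff value >=
#' threshold". Ties resolve to the smallest optimal cutoff, which flags more
#' patients as ineligible — the conservative choice for triage. The fit is
#' deterministic.
#'
#' @param data Labelled cohort tibble (see [as_cohort()]); both classes must
#'   be present.
#' @param feature Feature column to threshold; default the combined metric.
#' @return A [threshold_model()] with `train_accuracy` and `n_train`
#'   attributes.
#' @examples
#' d <- tibble::tibble(id = as.character(1:4), f_bw = 0, f_rw = 0,
#'                     metric = c(0.1, 0.2, 0.4, 0.5),
#'                     eligible = c(TRUE, TRUE, FALSE, FALSE))
#' fit_threshold(d) # threshold 0.3
#' @export
fit_threshold <- function(data, feature = "metric") {
  data <- labelled_cohort(data)
  v <- feature_values(data, feature)
  elig <- data$eligible
  cand <- threshold_candidates(v)
  ev <- sort(v[elig]); iv <- sort(v[!elig])
  # accuracy(t) = (#eligible below t + #ineligible at/above t) / n
  n_e_below <- findInterval(cand, ev)            # ev < t (candidates never tie data)
  n_i_above <- length(iv) - findInterval(cand, iv)
  acc <- (n_e_below + n_i_above) / length(v)
  best <- which(acc >= max(acc) - 1e-12)[1]      # smallest optimal candidate
  m <- threshold_model(cand[best], feature)
  attr(m, "train_accuracy") <- acc[best]
  attr(m, "n_train") <- length(v)
  m
}

#' @export
tidy.threshold_model <- function(x, ...) {
  tibble(feature = x$feature, threshold = x$threshold)
}

#' @export
glance.threshold_model <- function(x, ...) {
  tibble(feature = x$feature, threshold = x$threshold,
         train_accuracy = attr(x, "train_accuracy") %||% NA_real_,
         n_train = attr(x, "n_train") %||% NA_integer_)
}

#' Serialize / load a threshold model as JSON
#' @param model A [threshold_model()].
#' @param path File path.
#' @export
write_threshold_json <- function(model, path) {
  jsonlite::write_json(list(feature = model$feature, threshold = model$threshold),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_threshold_json
#' @export
read_threshold_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  threshold_model(obj$threshold, obj$feature)
}

#' Confusion counts and rates for a fitted threshold
#'
#' The positive class is *eligible*: true positives are eligible patients
#' correctly classified eligible, true negatives are ineligible patients
#' correctly classified ineligible. Sensitivity = tp/(tp+fn), specificity =
#' tn/(tn+fp), accuracy = (tp+tn)/n.
#'
#' @param data Labelled cohort tibble (a single class is allowed here).
#' @param model A [threshold_model()].
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`, `n`.
#' @export
evaluate_threshold <- function(data, model) {
  data <- labelled_cohort(data, require_both = FALSE)
  pred <- classify_threshold(feature_values(data, model$feature), model)
  pred_elig <- pred == "eligible"
  tp <- sum(data$eligible & pred_elig)
  fn <- sum(data$eligible & !pred_elig)
  tn <- sum(!data$eligible & !pred_elig)
  fp <- sum(!data$eligible & pred_elig)
  n <- nrow(data)
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / n,
    n = n
  )
}

#' Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sided rank-sum test with mid-ranks for ties, tie-corrected variance
#' and continuity correction — the test used to compare feature
#' distributions between eligible and ineligible patients.
#'
#' @param group_a,group_b Nonempty numeric vectors.
#' @return One-row tibble with the z `statistic` and two-sided `p.value`.
#' @export
rank_sum_test <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 1 || n2 < 1) ot_abort("Both groups need at least one observation.", "domain_error")
  r <- rank(c(group_a, group_b))
  n <- n1 + n2
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    z <- 0
  } else {
    cc <- sign(u - mu) * 0.5
    z <- (u - mu - cc) / sqrt(sigma2)
  }
  tibble(statistic = z, p.value = min(1, 2 * pnorm(-abs(z))))
}

#' Compare feature distributions between eligibility groups
#'
#' Runs the rank-sum test per feature between eligible and ineligible
#' patients, the group-comparison report accompanying the classifier.
#'
#' @param data Labelled cohort tibble.
#' @param features Feature columns to compare (defaults to all present among
#'   `ptv_volume_cc`, `f_bw`, `f_rw`, `metric`).
#' @return Tibble with one row per feature: group medians, z statistic,
#'   p-value.
#' @export
compare_groups <- function(data, features = NULL) {
  data <- labelled_cohort(data)
  if (is.null(features)) {
    features <- intersect(c("ptv_volume_cc", "f_bw", "f_rw", "metric"), names(data))
  }
  purrr::map_dfr(features, function(f) {
    v <- feature_values(data, f)
    res <- rank_sum_test(v[data$eligible], v[!data$eligible])
    tibble(
      feature = f,
      median_eligible = stats::median(v[data$eligible]),
      median_ineligible = stats::median(v[!data$eligible]),
      statistic = res$statistic,
      p.value = res$p.value
    )
  })
}
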