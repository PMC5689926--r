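#' Stratified random half-split of a labelled cohort
#'
#' Splits a labelled cohort into two folds containing equal proportions of
#' eligible and ineligible patients: each class is randomly halved between
#' the folds, and for odd class counts the extra patient lands in either fold
#' with equal probability. The folds always partition the cohort. Draws use
#' the current RNG state; seed upstream (e.g. [withr::with_seed()]) for
#' reproducibility.
#'
#' @param data Labelled cohort tibble; each class needs at least 2 members.
#' @return List with tibbles `a` and `b`.
#' @export
stratified_split <- function(data) {
  data <- labelled_cohort(data)
  counts <- table(data$eligible)
  if (any(counts < 2)) {
    ot_abort("Each eligibility class needs at least 2 patients to stratify.",
             "stratification_error")
  }
  in_a <- logical(nrow(data))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(data$eligible == cls)
    n <- length(idx)
    n_a <- n %/% 2 + if (n %% 2 == 1) rbinom(1, 1, 0.5) else 0L
    in_a[sample(idx, n_a)] <- TRUE
  }
  list(a = data[in_a, ], b = data[!in_a, ])
}

#' Repeated stratified two-fold cross-validation
#'
#' The evaluation protocol for the threshold classifier: per repetition the
#' cohort is split into two stratified folds; the threshold is fitted on
#' fold A and evaluated on fold B, then the folds swap roles. Sensitivity,
#' specificity, accuracy (as percentages) and the fitted threshold are
#' aggregated as mean and standard deviation over all `2 * n_repetitions`
#' fold evaluations. Fully reproducible from `seed`.
#'
#' @param data Labelled cohort tibble.
#' @param feature Feature to threshold (default the combined metric).
#' @param n_repetitions Number of repeated splits (protocol default 1000).
#' @param seed Integer seed driving all random splits.
#' @return A `cv_report`: list with `summary` (per-statistic mean/sd),
#'   `folds` (per-fold audit records) and `config`.
#' @export
cross_validate <- function(data, feature = "metric", n_repetitions = 1000, seed = 1) {
  data <- labelled_cohort(data)
  if (n_repetitions < 1) ot_abort("`n_repetitions` must be >= 1.", "domain_error")
  rows <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(n_repetitions), function(rep) {
      folds <- stratified_split(data)
      purrr::map_dfr(1:2, function(half) {
        train <- if (half == 1) folds$a else folds$b
        test <- if (half == 1) folds$b else folds$a
        model <- fit_threshold(train, feature)
        ev <- evaluate_threshold(test, model)
        tibble(repetition = rep, fold = half, threshold = model$threshold,
               sensitivity = ev$sensitivity, specificity = ev$specificity,
               accuracy = ev$accuracy)
      })
    })
  })
  summary <- tibble(
    statistic = c("sensitivity", "specificity", "accuracy", "threshold"),
    mean = c(mean(rows$sensitivity) * 100, mean(rows$specificity) * 100,
             mean(rows$accuracy) * 100, mean(rows$threshold)),
    sd = c(sd(rows$sensitivity) * 100, sd(rows$specificity) * 100,
           sd(rows$accuracy) * 100, sd(rows$threshold)),
    unit = c("%", "%", "%", "feature units")
  )
  structure(
    list(summary = summary, folds = rows,
         config = list(feature = feature, n_repetitions = n_repetitions,
                       n_folds = 2L, seed = as.integer(seed),
                       n_folds_evaluated = 2L * as.integer(n_repetitions))),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> feature '%s', %d repetitions (%d fold evaluations), seed %d\n",
              x$config$feature, x$config$n_repetitions,
              x$config$n_folds_evaluated, x$config$seed))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %8.3f (%.3f)\n", s$statistic[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) x$summary

#' @export
glance.cv_report <- function(x, ...) {
  s <- x$summary
  tibble(
    feature = x$config$feature,
    n_repetitions = x$config$n_repetitions,
    n_folds_evaluated = x$config$n_folds_evaluated,
    mean_sensitivity_pct = s$mean[s$statistic == "sensitivity"],
    mean_specificity_pct = s$mean[s$statistic == "specificity"],
    mean_accuracy_pct = s$mean[s$statistic == "accuracy"],
    mean_threshold = s$mean[s$statistic == "threshold"]
  )
}

#' Write cross-validation reports
#'
#' `write_cv_json()` stores one report (summary, per-fold records, config).
#' `cv_table()` lays one or more reports out like the published efficacy
#' table: rows sensitivity/specificity/accuracy/threshold, one column per
#' feature, cells "mean (sd)"; `write_cv_csv()` writes it.
#'
#' @param report A `cv_report` (or list of them for `cv_table`).
#' @param path Output path.
#' @export
write_cv_json <- function(report, path) {
  jsonlite::write_json(
    list(summary = report$summary, config = report$config, folds = report$folds),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_cv_json
#' @param reports List of `cv_report` objects (one per feature).
#' @export
cv_table <- function(reports) {
  if (inherits(reports, "cv_report")) reports <- list(reports)
  cols <- purrr::map(reports, function(r) {
    s <- r$summary
    stats::setNames(sprintf("%.1f (%.1f)", s$mean, s$sd), s$statistic)
  })
  out <- tibble(statistic = c("sensitivity", "specificity", "accuracy", "threshold"))
  for (i in seq_along(reports)) {
    s <- reports[[i]]$summary
    fmt <- ifelse(out$statistic == "threshold",
                  sprintf("%.3f (%.3f)", s$mean[match(out$statistic, s$statistic)],
                          s$sd[match(out$statistic, s$statistic)]),
                  sprintf("%.1f (%.1f)", s$mean[match(out$statistic, s$statistic)],
                          s$sd[match(out$statistic, s$statistic)]))
    out[[reports[[i]]$config$feature]] <- fmt
  }
  out
}

#' @rdname write_cv_json
#' @export
write_cv_csv <- function(reports, path) {
  readr::write_csv(cv_table(reports), path)
  invisible(path)
}
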