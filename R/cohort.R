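#' Quadrature overlap metric
#'
#' Combines the bladder-wall and rectal-wall fractional overlaps into the
#' single-valued metric `sqrt(f_bw^2 + f_rw^2)` — the radial distance of the
#' patient's point from the origin of the (f_BW, f_RW) plane. Both inputs
#' must lie in `[0, 1]`, so the metric lies in `[0, sqrt(2)]` and always
#' dominates each component.
#'
#' @param f_bw,f_rw Fractional overlaps in `[0, 1]` (vectorized).
#' @return Numeric vector of metric values.
#' @examples
#' overlap_metric(0.3, 0.4) # 0.5
#' @export
overlap_metric <- function(f_bw, f_rw) {
  if (any(!is.finite(f_bw)) || any(!is.finite(f_rw)) ||
      any(f_bw < 0 | f_bw > 1) || any(f_rw < 0 | f_rw > 1)) {
    ot_abort("Fractional overlaps must be finite and in [0, 1].", "domain_error")
  }
  sqrt(f_bw^2 + f_rw^2)
}

#' Assemble and validate a patient cohort
#'
#' A cohort is a tibble with one row per patient: `id` (nonempty, unique),
#' fractional overlaps `f_bw` and `f_rw`, the derived `metric` (computed if
#' absent), and optionally `ptv_volume_cc` and a logical `eligible` label
#' (`TRUE` = dosimetrically eligible, i.e. the plan can meet the accepted
#' dose constraints).
#'
#' @param data Data frame with at least `id`, `f_bw`, `f_rw`.
#' @return A validated tibble with a `metric` column.
#' @export
as_cohort <- function(data) {
  data <- as_tibble(data)
  need <- c("id", "f_bw", "f_rw")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    ot_abort(paste0("Cohort is missing column(s): ", paste(miss, collapse = ", ")),
             "domain_error")
  }
  data$id <- as.character(data$id)
  if (any(is.na(data$id) | data$id == "") || anyDuplicated(data$id)) {
    ot_abort("Patient ids must be nonempty and unique.", "domain_error")
  }
  if (!"metric" %in% names(data)) {
    data$metric <- overlap_metric(data$f_bw, data$f_rw)
  }
  if ("eligible" %in% names(data)) data$eligible <- as.logical(data$eligible)
  data
}

#' Read / write a cohort CSV
#'
#' Columns: `id`, `f_bw`, `f_rw`, optional `ptv_volume_cc`, optional
#' `eligible` (true/false/empty); header required.
#'
#' @param path File path.
#' @return `read_cohort_csv()` returns a cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  as_cohort(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_cohort_csv
#' @param data Cohort tibble.
#' @export
write_cohort_csv <- function(data, path) {
  readr::write_csv(as_cohort(data), path)
  invisible(path)
}

# Drop unlabelled patients (with a warning) and require both classes.
labelled_cohort <- function(data, require_both = TRUE) {
  data <- as_cohort(data)
  if (!"eligible" %in% names(data)) {
    ot_abort("Cohort has no `eligible` labels.", "degenerate_cohort_error")
  }
  n_na <- sum(is.na(data$eligible))
  if (n_na > 0) {
    warn(sprintf("Excluding %d patient(s) with missing eligibility labels.", n_na))
    data <- data[!is.na(data$eligible), ]
  }
  if (nrow(data) == 0) {
    ot_abort("No labelled patients in cohort.", "degenerate_cohort_error")
  }
  if (require_both && length(unique(data$eligible)) < 2) {
    ot_abort("Cohort must contain both eligible and ineligible patients.",
             "degenerate_cohort_error")
  }
  data
}

feature_values <- function(data, feature) {
  feature <- match.arg(feature, c("metric", "f_bw", "f_rw", "ptv_volume_cc"))
  if (!feature %in% names(data)) {
    ot_abort(sprintf("Cohort has no `%s` column.", feature), "domain_error")
  }
  v <- data[[feature]]
  if (any(!is.finite(v))) {
    ot_abort(sprintf("Non-finite values in feature `%s`.", feature), "domain_error")
  }
  v
}
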