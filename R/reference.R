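#' Reference cohort summary
#'
#' Headline counts from the published 150-patient institutional planning
#' cohort from which the tool's shipped defaults (decision radii, protocol
#' margins) were derived: total size, eligible/ineligible class sizes, and
#' the per-zone census under the reference boundaries. Shipped so that
#' summary rates (ineligibility rate, zone occupancy) can be recomputed
#' without patient-level data; the patient-level measurements themselves
#' were never published.
#'
#' @return One-row tibble with columns `n`, `n_eligible`, `n_ineligible`,
#'   `n_feasible_zone`, `n_uncertain_zone`, `n_not_feasible_zone`,
#'   `n_uncertain_eligible`.
#' @export
reference_cohort_summary <- function() {
  tibble(
    n = 150L, n_eligible = 106L, n_ineligible = 44L,
    n_feasible_zone = 95L, n_uncertain_zone = 25L, n_not_feasible_zone = 30L,
    n_uncertain_eligible = 11L
  )
}

#' Summary rates from cohort counts
#'
#' Derives the ineligibility rate and per-zone occupancy percentages from a
#' cohort summary row (totals and zone census), as produced by
#' [reference_cohort_summary()] or assembled from [zone_census()].
#'
#' @param counts One-row tibble shaped like [reference_cohort_summary()].
#' @return Tibble of named percentage rates.
#' @export
cohort_rates <- function(counts = reference_cohort_summary()) {
  with(counts, tibble(
    rate = c("ineligible_pct", "feasible_zone_pct", "uncertain_zone_pct",
             "not_feasible_zone_pct"),
    value = 100 * c(n_ineligible / n, n_feasible_zone / n,
                    n_uncertain_zone / n, n_not_feasible_zone / n)
  ))
}
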