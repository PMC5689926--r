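#' Protocol dose-constraint sets
#'
#' The hypofractionation (6000 cGy / 20 fraction) protocol constrains, per
#' structure, the dose Dx received by x% of the volume. Plans were expected
#' to at least meet the *accepted* set; eligibility labelling uses it. The
#' stricter *preferred* set is shipped as a named alternative. Organ-at-risk
#' and femur limits are upper bounds; the CTV/PTV D99 limits are coverage
#' minima (lower bounds).
#'
#' @param set `"accepted"` (default) or `"preferred"`.
#' @return Tibble with columns `structure`, `x_percent`, `limit_cgy`,
#'   `direction`.
#' @export
profit_constraints <- function(set = c("accepted", "preferred")) {
  set <- match.arg(set)
  limits <- switch(set,
    accepted = c(4710, 3790, 4710, 3790, 4400, 6000, 5700),
    preferred = c(4600, 3700, 4600, 3700, 4300, 6000, 5700)
  )
  tibble(
    structure = c("rectal_wall", "rectal_wall", "bladder_wall", "bladder_wall",
                  "femur", "ctv", "ptv"),
    x_percent = c(30, 50, 30, 50, 5, 99, 99),
    limit_cgy = limits,
    direction = c("upper", "upper", "upper", "upper", "upper", "lower", "lower")
  )
}

# Validate one structure's cumulative DVH: strictly increasing doses,
# non-increasing fractional volumes, full volume at dose 0.
validate_dvh <- function(dose, volume, structure = "?") {
  if (length(dose) < 1 || any(!is.finite(dose)) || any(!is.finite(volume))) {
    ot_abort(sprintf("DVH for '%s' contains non-finite values.", structure), "domain_error")
  }
  if (any(diff(dose) <= 0)) {
    ot_abort(sprintf("DVH doses for '%s' must be strictly increasing.", structure), "domain_error")
  }
  if (any(diff(volume) > 1e-9)) {
    ot_abort(sprintf("DVH volumes for '%s' must be non-increasing.", structure), "domain_error")
  }
  if (abs(dose[1]) > 1e-9 || abs(volume[1] - 1) > 1e-9) {
    ot_abort(sprintf("DVH for '%s' must start at (dose 0, volume 1).", structure), "domain_error")
  }
  if (any(volume < -1e-9 | volume > 1 + 1e-9)) {
    ot_abort(sprintf("DVH volumes for '%s' must lie in [0, 1].", structure), "domain_error")
  }
  invisible(TRUE)
}

#' Dose received by x% of a structure (Dx)
#'
#' Reads Dx off a cumulative DVH: the largest dose `d` such that the
#' fractional volume receiving at least `d` is `>= x/100`, with linear
#' interpolation between tabulated points.
#'
#' @param data Cumulative DVH tibble for a single structure, columns
#'   `dose_cgy` (strictly increasing, starting at 0) and `fractional_volume`
#'   (non-increasing, starting at 1).
#' @param x_percent Volume percentage in `(0, 100]`.
#' @return Dose in cGy.
#' @export
dose_at_volume <- function(data, x_percent) {
  if (!is.finite(x_percent) || x_percent <= 0 || x_percent > 100) {
    ot_abort("`x_percent` must lie in (0, 100].", "domain_error")
  }
  dose <- data$dose_cgy
  vol <- data$fractional_volume
  validate_dvh(dose, vol, data$structure[1] %||% "?")
  v <- x_percent / 100
  if (vol[length(vol)] >= v) return(dose[length(dose)])
  i <- max(which(vol >= v))          # exists: vol[1] = 1 >= v
  dose[i] + (dose[i + 1] - dose[i]) * (vol[i] - v) / (vol[i] - vol[i + 1])
}

#' Read / write DVH CSV
#'
#' Columns `structure`, `dose_cgy`, `fractional_volume`; one file may hold
#' several structures.
#'
#' @param path File path.
#' @export
read_dvh_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("structure", "dose_cgy", "fractional_volume")
  if (!all(need %in% names(d))) {
    ot_abort("DVH CSV needs columns structure, dose_cgy, fractional_volume.", "io_error")
  }
  as_tibble(d)
}

#' @rdname read_dvh_csv
#' @param data DVH tibble.
#' @export
write_dvh_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Check dosimetric eligibility against a constraint set
#'
#' Evaluates each constraint's Dx on the matching structure's cumulative DVH
#' and passes it iff `Dx <= limit` (upper) or `Dx >= limit` (lower), with
#' exact equality passing in both directions. A patient is dosimetrically
#' eligible iff every constraint passes.
#'
#' @param dvhs DVH tibble (columns `structure`, `dose_cgy`,
#'   `fractional_volume`) covering every structure named in the constraints.
#' @param constraints Constraint tibble, default [profit_constraints()]
#'   ("accepted").
#' @return An `eligibility_check`: list with logical `eligible` and a
#'   `report` tibble (one row per constraint: `dose_cgy`, `limit_cgy`,
#'   `margin_cgy`, `pass`).
#' @export
check_eligibility <- function(dvhs, constraints = profit_constraints()) {
  dvhs <- as_tibble(dvhs)
  missing <- setdiff(unique(constraints$structure), unique(dvhs$structure))
  if (length(missing)) {
    ot_abort(paste0("No DVH for structure(s): ", paste(missing, collapse = ", ")),
             "missing_structure_error")
  }
  report <- purrr::pmap_dfr(constraints, function(structure, x_percent, limit_cgy, direction) {
    dvh <- dvhs[dvhs$structure == structure, ]
    dx <- dose_at_volume(dvh, x_percent)
    pass <- if (direction == "upper") dx <= limit_cgy else dx >= limit_cgy
    tibble(structure = structure, x_percent = x_percent,
           direction = direction, dose_cgy = dx, limit_cgy = limit_cgy,
           margin_cgy = if (direction == "upper") limit_cgy - dx else dx - limit_cgy,
           pass = pass)
  })
  structure(list(eligible = all(report$pass), report = report),
            class = "eligibility_check")
}

#' @export
print.eligibility_check <- function(x, ...) {
  cat(sprintf("<eligibility_check> %s (%d/%d constraints met)\n",
              if (x$eligible) "ELIGIBLE" else "INELIGIBLE",
              sum(x$report$pass), nrow(x$report)))
  print(x$report)
  invisible(x)
}

#' @export
tidy.eligibility_check <- function(x, ...) x$report

#' @export
glance.eligibility_check <- function(x, ...) {
  tibble(eligible = x$eligible,
         n_constraints = nrow(x$report),
         n_pass = sum(x$report$pass),
         worst_margin_cgy = min(x$report$margin_cgy))
}
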