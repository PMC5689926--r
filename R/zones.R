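#' Radial decision-zone boundaries
#'
#' Two radii partition the first quadrant of the (f_BW, f_RW) plane into
#' three zones by the patient's overlap metric (radial distance from the
#' origin): *feasible* below `r_inner`, *not feasible* beyond `r_outer`,
#' *uncertain* between; points exactly on a boundary are uncertain.
#'
#' @param r_inner Feasible/uncertain boundary radius (>= 0).
#' @param r_outer Uncertain/not-feasible boundary radius (>= 0). If
#'   `r_inner > r_outer` the radii are swapped and the `separable` flag set
#'   (the training cohort was perfectly separated).
#' @param source Free-text provenance tag stored with the boundaries.
#' @param separable Logical separable-cohort flag.
#' @return A `zone_boundaries` object.
#' @export
zone_boundaries <- function(r_inner, r_outer, source = "user", separable = FALSE) {
  if (!is.finite(r_inner) || !is.finite(r_outer) || r_inner < 0 || r_outer < 0) {
    ot_abort("Zone radii must be finite and >= 0.", "domain_error")
  }
  if (r_inner > r_outer) {
    tmp <- r_inner; r_inner <- r_outer; r_outer <- tmp
    separable <- TRUE
  }
  structure(list(r_inner = as.numeric(r_inner), r_outer = as.numeric(r_outer),
                 source = source, separable = isTRUE(separable)),
            class = "zone_boundaries")
}

#' @export
print.zone_boundaries <- function(x, ...) {
  cat(sprintf("<zone_boundaries> feasible < %g <= uncertain <= %g < not feasible [%s]%s\n",
              x$r_inner, x$r_outer, x$source,
              if (x$separable) " (separable cohort)" else ""))
  invisible(x)
}

#' Reference decision boundaries
#'
#' The default radii shipped with the tool, derived from a published
#' 150-patient institutional planning cohort: the inner radius is the
#' smallest overlap metric observed among ineligible patients (0.274), the
#' outer radius the largest observed among eligible patients (0.305).
#' Centres should refit boundaries on local data with [derive_zones()], as
#' optimal cutoffs depend on local planning and contouring practice.
#'
#' @return A `zone_boundaries` object with radii (0.274, 0.305).
#' @export
reference_zone_boundaries <- function() {
  zone_boundaries(0.274, 0.305, source = "reference-cohort-default")
}

#' Derive zone boundaries from a labelled cohort
#'
#' `r_inner` is the minimum overlap metric among ineligible patients and
#' `r_outer` the maximum among eligible patients; by construction no
#' ineligible patient then lies strictly inside the feasible zone and no
#' eligible patient strictly beyond the not-feasible boundary. If the cohort
#' is perfectly separated the raw radii invert; they are swapped and flagged.
#'
#' @param data Labelled cohort tibble with both classes present.
#' @return A [zone_boundaries()] object.
#' @export
derive_zones <- function(data) {
  data <- labelled_cohort(data)
  m <- feature_values(data, "metric")
  zone_boundaries(min(m[!data$eligible]), max(m[data$eligible]),
                  source = "fitted")
}

#' Classify overlap metrics into decision zones
#'
#' @param metric Numeric overlap metric values (vectorized).
#' @param boundaries A [zone_boundaries()] object.
#' @return Factor with levels `feasible`, `uncertain`, `not_feasible`;
#'   boundary values map to `uncertain`.
#' @export
zone_of <- function(metric, boundaries) {
  if (any(!is.finite(metric)) || any(metric < 0)) {
    ot_abort("Overlap metric must be finite and >= 0.", "domain_error")
  }
  lab <- ifelse(metric < boundaries$r_inner, "feasible",
                ifelse(metric > boundaries$r_outer, "not_feasible", "uncertain"))
  factor(lab, levels = c("feasible", "uncertain", "not_feasible"))
}

#' @rdname zone_of
#' @param data Cohort tibble (a `metric` column is computed if absent).
#' @return `classify_zones()` returns `data` with a `zone` column appended.
#' @export
classify_zones <- function(data, boundaries = reference_zone_boundaries()) {
  data <- as_cohort(data)
  data$zone <- zone_of(data$metric, boundaries)
  data
}

#' Zone census of a labelled cohort
#'
#' Counts patients per zone with the eligible/ineligible breakdown. Counts
#' always partition the cohort.
#'
#' @param data Labelled cohort tibble.
#' @param boundaries A [zone_boundaries()] object.
#' @return Tibble with one row per zone: `n`, `n_eligible`, `n_ineligible`.
#' @export
zone_census <- function(data, boundaries) {
  data <- classify_zones(labelled_cohort(data), boundaries)
  out <- dplyr::summarise(
    dplyr::group_by(data, zone = .data$zone, .drop = FALSE),
    n = dplyr::n(),
    n_eligible = sum(.data$eligible),
    n_ineligible = sum(!.data$eligible),
    .groups = "drop"
  )
  out
}

quarter_arc <- function(r, n = 181) {
  th <- seq(0, pi / 2, length.out = n)
  data.frame(x = r * cos(th), y = r * sin(th))
}

annulus_poly <- function(r0, r1) {
  outer <- quarter_arc(r1)
  if (r0 <= 0) {
    rbind(data.frame(x = 0, y = 0), outer)
  } else {
    inner <- quarter_arc(r0)
    rbind(outer, inner[rev(seq_len(nrow(inner))), ])
  }
}

#' Decision-support plot
#'
#' Renders the first-quadrant (f_BW, f_RW) plane split by quarter-circle
#' arcs at the two boundary radii into green (feasible), yellow (uncertain)
#' and red (not feasible) regions, with the patient plotted as a square
#' marker whose radial distance from the origin equals the overlap metric.
#'
#' @param object A [zone_boundaries()] object.
#' @param f_bw,f_rw Optional patient fractional overlaps to mark.
#' @param cohort Optional labelled cohort tibble drawn as background points.
#' @param zone_colors Named colors for the three zones (override for
#'   accessibility).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zone_boundaries <- function(object, f_bw = NULL, f_rw = NULL,
                                     cohort = NULL,
                                     zone_colors = c(feasible = "#2ca25f",
                                                     uncertain = "#ffd92f",
                                                     not_feasible = "#e34a33"),
                                     ...) {
  rmax <- max(object$r_outer * 1.4, 0.5,
              if (!is.null(f_bw)) sqrt(max(f_bw)^2 + max(f_rw)^2) * 1.15,
              if (!is.null(cohort)) max(as_cohort(cohort)$metric) * 1.15)
  regions <- rbind(
    cbind(annulus_poly(0, object$r_inner), zone = "feasible"),
    cbind(annulus_poly(object$r_inner, object$r_outer), zone = "uncertain"),
    cbind(annulus_poly(object$r_outer, rmax * sqrt(2)), zone = "not_feasible")
  )
  regions$zone <- factor(regions$zone, levels = names(zone_colors))
  p <- ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = regions,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$zone),
      alpha = 0.6, color = NA
    ) +
    ggplot2::scale_fill_manual(values = zone_colors, name = "zone") +
    ggplot2::coord_cartesian(xlim = c(0, rmax), ylim = c(0, rmax), expand = FALSE) +
    ggplot2::labs(
      x = expression(f[BW] ~ "(bladder wall-PTV fractional overlap)"),
      y = expression(f[RW] ~ "(rectal wall-PTV fractional overlap)")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(cohort)) {
    ch <- labelled_cohort(cohort)
    p <- p + ggplot2::geom_point(
      data = ch,
      ggplot2::aes(x = .data$f_bw, y = .data$f_rw, shape = .data$eligible),
      size = 1.6, color = "grey25"
    ) +
      ggplot2::scale_shape_manual(values = c(`TRUE` = 1, `FALSE` = 4),
                                  name = "eligible")
  }
  if (!is.null(f_bw)) {
    p <- p + ggplot2::geom_point(
      data = data.frame(x = f_bw, y = f_rw),
      ggplot2::aes(x = .data$x, y = .data$y),
      shape = 15, size = 3, color = "black"
    )
  }
  p
}

#' @rdname autoplot.zone_boundaries
#' @param boundaries A [zone_boundaries()] object.
#' @export
plot_decision <- function(f_bw, f_rw, boundaries = reference_zone_boundaries(),
                          cohort = NULL, ...) {
  autoplot(boundaries, f_bw = f_bw, f_rw = f_rw, cohort = cohort, ...)
}

#' Write the decision-support plot to file
#'
#' @inheritParams plot_decision
#' @param path Output file path.
#' @param format `"png"` (default) or `"svg"`.
#' @param width,height,dpi Device size in inches and resolution.
#' @return `path`, invisibly.
#' @export
render_decision_plot <- function(f_bw, f_rw,
                                 boundaries = reference_zone_boundaries(),
                                 path = "decision_plot.png",
                                 format = c("png", "svg"),
                                 cohort = NULL, width = 6, height = 5, dpi = 150) {
  format <- match.arg(format)
  p <- plot_decision(f_bw, f_rw, boundaries, cohort = cohort)
  ok <- try(ggplot2::ggsave(path, p, device = format, width = width,
                            height = height, dpi = dpi), silent = TRUE)
  if (inherits(ok, "try-error") || !file.exists(path) || file.size(path) == 0) {
    ot_abort(sprintf("Could not write decision plot to '%s'.", path), "io_error")
  }
  invisible(path)
}

#' Zone boundaries JSON I/O
#'
#' Stored as `{"r_inner": ..., "r_outer": ..., "source": ..., "separable": ...}`.
#'
#' @param boundaries A [zone_boundaries()] object.
#' @param path File path.
#' @export
write_zones_json <- function(boundaries, path) {
  jsonlite::write_json(
    list(r_inner = boundaries$r_inner, r_outer = boundaries$r_outer,
         source = boundaries$source, separable = boundaries$separable),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_zones_json
#' @export
read_zones_json <- function(path) {
  obj <- try(jsonlite::fromJSON(path), silent = TRUE)
  if (inherits(obj, "try-error") || is.null(obj$r_inner) || is.null(obj$r_outer)) {
    ot_abort(sprintf("Invalid zone-boundaries file '%s'.", path), "config_error")
  }
  zone_boundaries(obj$r_inner, obj$r_outer,
                  source = obj$source %||% "file",
                  separable = isTRUE(obj$separable))
}
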