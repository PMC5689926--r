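#' 3D binary structure masks
#'
#' A `structure_mask` represents a contoured anatomical structure (CTV, PTV,
#' rectal wall, bladder wall, ...) as a 3D logical voxel grid with physical
#' spacing, origin and explicit anatomical axis labels. All geometric
#' operations in the package (margin expansion, wall extraction, fractional
#' overlap) act on this type.
#'
#' Physical coordinates are in millimetres. The centre of voxel `(i, j, k)`
#' (1-based indices) sits at `origin + (c(i, j, k) - 1) * spacing`. Axis
#' labels give the anatomical direction of *increasing* index along each grid
#' axis using the single-letter codes `R`/`L` (right/left), `A`/`P`
#' (anterior/posterior), `S`/`I` (superior/inferior); the default `c("R",
#' "A", "S")` is the RAS convention used by NIfTI. Directional operations
#' (e.g. the posterior margin) are resolved from these labels, never from
#' array order.
#'
#' @param voxels 3D logical (or coercible 0/1 numeric) array.
#' @param spacing Numeric length-3, voxel spacing in mm along each grid axis;
#'   all strictly positive.
#' @param origin Numeric length-3, physical coordinate (mm) of the centre of
#'   voxel (1, 1, 1).
#' @param axis_labels Character length-3; anatomical direction of increasing
#'   index per axis. Must contain one of `R`/`L`, one of `A`/`P` and one of
#'   `S`/`I`.
#' @return A `structure_mask` object.
#' @examples
#' m <- structure_mask(array(TRUE, c(10, 10, 10)), spacing = c(1, 1, 1))
#' structure_volume(m) # 1 cc
#' @export
structure_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                           axis_labels = c("R", "A", "S")) {
  if (is.numeric(voxels)) voxels <- voxels >= 0.5
  if (!is.logical(voxels) || length(dim(voxels)) != 3L) {
    ot_abort("`voxels` must be a 3D logical array.", "domain_error")
  }
  voxels[is.na(voxels)] <- FALSE
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    ot_abort("`spacing` must be three strictly positive values (mm).", "domain_error")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    ot_abort("`origin` must be three finite values (mm).", "domain_error")
  }
  check_axis_labels(axis_labels)
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         axis_labels = as.character(axis_labels)),
    class = "structure_mask"
  )
}

axis_pairs <- list(c("R", "L"), c("A", "P"), c("S", "I"))

check_axis_labels <- function(axis_labels) {
  if (length(axis_labels) != 3L ||
      !all(axis_labels %in% unlist(axis_pairs))) {
    ot_abort("`axis_labels` must be three of R/L, A/P, S/I.", "domain_error")
  }
  covered <- vapply(axis_pairs, function(p) sum(axis_labels %in% p), integer(1))
  if (!all(covered == 1L)) {
    ot_abort("`axis_labels` must cover each anatomical axis exactly once.", "domain_error")
  }
  invisible(axis_labels)
}

opposite_label <- function(lab) {
  c(R = "L", L = "R", A = "P", P = "A", S = "I", I = "S")[[lab]]
}

#' @export
print.structure_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<structure_mask> %d x %d x %d voxels, spacing %s mm, %d true (%.2f cc)\n",
    d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
    sum(x$voxels), structure_volume(x)
  ))
  invisible(x)
}

#' @export
dim.structure_mask <- function(x) dim(x$voxels)

#' Physical voxel-centre coordinates along each grid axis
#' @param mask A `structure_mask`.
#' @return List of three numeric vectors (mm).
#' @keywords internal
#' @export
voxel_centers <- function(mask) {
  d <- dim(mask$voxels)
  lapply(1:3, function(a) mask$origin[a] + (seq_len(d[a]) - 1) * mask$spacing[a])
}

#' Test whether two masks share the same grid
#'
#' Two masks are co-registered iff their grid dimensions, spacings, origins
#' and axis labels are identical. Voxelwise operations (overlap) require
#' co-registration.
#'
#' @param a,b `structure_mask` objects.
#' @return Logical scalar.
#' @export
is_coregistered <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    isTRUE(all(abs(a$spacing - b$spacing) < 1e-9)) &&
    isTRUE(all(abs(a$origin - b$origin) < 1e-9)) &&
    identical(a$axis_labels, b$axis_labels)
}

stop_unless_coregistered <- function(a, b) {
  if (!is_coregistered(a, b)) {
    ot_abort("Masks are not co-registered (grid, spacing, origin and axis labels must match).",
             "registration_error")
  }
  invisible(TRUE)
}

stop_if_empty <- function(mask, what = "structure") {
  if (!any(mask$voxels)) {
    ot_abort(sprintf("Empty %s mask.", what), "empty_structure_error")
  }
  invisible(TRUE)
}

#' Structure volume in cc
#'
#' True-voxel count times the physical voxel volume, converted from mm^3 to
#' cubic centimetres.
#'
#' @param mask A `structure_mask`.
#' @return Volume in cc (>= 0).
#' @export
structure_volume <- function(mask) {
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

#' Fractional overlap of an OAR with the PTV
#'
#' The fraction of an organ-at-risk wall that intersects the planning target
#' volume: `|OAR intersect PTV| / |OAR|` by true-voxel counts. This is the
#' anatomical feature (f_BW for the bladder wall, f_RW for the rectal wall)
#' from which the eligibility metric is built.
#'
#' @param oar OAR `structure_mask` (nonempty).
#' @param ptv PTV `structure_mask`, co-registered with `oar`.
#' @return A value in `[0, 1]`.
#' @export
fractional_overlap <- function(oar, ptv) {
  stop_unless_coregistered(oar, ptv)
  n_oar <- sum(oar$voxels)
  if (n_oar == 0) {
    ot_abort("Fractional overlap is undefined for an empty OAR mask.",
             "empty_structure_error")
  }
  sum(oar$voxels & ptv$voxels) / n_oar
}
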