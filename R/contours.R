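#' Planar contour stacks
#'
#' Contoured structures exported from a planning system often arrive as
#' stacks of closed planar polygons, one set per axial slice. A
#' `contour_stack` holds, per slice, the slice z-position (mm) and a list of
#' polygons; each polygon is an n-by-2 matrix of (x, y) vertices in mm with
#' closure implied (the first vertex is not repeated).
#'
#' @param structure Structure name.
#' @param slices List of `list(z = <mm>, polygons = <list of n x 2 matrices>)`,
#'   with strictly increasing `z`.
#' @return A `contour_stack` object.
#' @export
contour_stack <- function(structure, slices) {
  z <- vapply(slices, function(s) as.numeric(s$z), numeric(1))
  if (length(z) > 1 && any(diff(z) <= 0)) {
    ot_abort("Slice z-positions must be strictly increasing.", "invalid_contour_error")
  }
  slices <- lapply(slices, function(s) {
    polys <- lapply(s$polygons, function(p) {
      p <- as.matrix(p)
      if (nrow(p) < 3 || ncol(p) != 2 || any(!is.finite(p))) {
        ot_abort("Each contour polygon needs >= 3 finite (x, y) vertices.",
                 "invalid_contour_error")
      }
      storage.mode(p) <- "double"
      unname(p)
    })
    list(z = as.numeric(s$z), polygons = polys)
  })
  structure(list(structure = as.character(structure), slices = slices),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  np <- sum(vapply(x$slices, function(s) length(s$polygons), integer(1)))
  cat(sprintf("<contour_stack> '%s': %d slice(s), %d polygon(s)\n",
              x$structure, length(x$slices), np))
  invisible(x)
}

#' Read / write the contour-stack JSON dialect
#'
#' The on-disk form is
#' `{"structure": name, "slices": [{"z": mm, "polygons": [[[x,y],...], ...]}]}`.
#'
#' @param path File path.
#' @return `read_contour_json()` returns a [contour_stack()];
#'   `write_contour_json()` returns `path` invisibly.
#' @export
read_contour_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  slices <- lapply(obj$slices, function(s) {
    polys <- lapply(s$polygons, function(p) {
      do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
    })
    list(z = as.numeric(s$z), polygons = polys)
  })
  contour_stack(obj$structure, slices)
}

#' @rdname read_contour_json
#' @param stack A [contour_stack()].
#' @export
write_contour_json <- function(stack, path) {
  obj <- list(
    structure = stack$structure,
    slices = lapply(stack$slices, function(s) {
      list(z = s$z, polygons = lapply(s$polygons, identity))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Even-odd (crossing-count) point-in-polygon, vectorized over points, with
# points lying exactly on an edge counted inside (closed boundary).
point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xin <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
      hit <- inside[crosses]
      flip <- px[crosses] < xin
      inside[crosses] <- xor(hit, flip)
    }
    # on-segment test
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - x1) * dx + (py - y1) * dy) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
      on_edge <- on_edge | d2 <= eps^2
    } else {
      on_edge <- on_edge | ((px - x1)^2 + (py - y1)^2 <= eps^2)
    }
    j <- i
  }
  inside | on_edge
}

#' Rasterize a contour stack onto a mask grid
#'
#' A voxel is set iff its centre lies inside any polygon of the slice nearest
#' to its plane (even-odd rule, boundary inclusive); each contour slice is
#' matched to the nearest voxel z-plane within half a voxel z-spacing.
#'
#' @param stack A [contour_stack()].
#' @param grid_template A `structure_mask` supplying spacing, origin, extent
#'   and axis labels (its voxel values are ignored).
#' @return A `structure_mask` on the template grid.
#' @export
rasterize_contours <- function(stack, grid_template) {
  tmpl <- grid_template
  d <- dim(tmpl$voxels)
  centers <- voxel_centers(tmpl)
  out <- array(FALSE, d)
  half <- tmpl$spacing / 2
  lo <- tmpl$origin - half
  hi <- tmpl$origin + (d - 1) * tmpl$spacing + half
  px <- rep(centers[[1]], times = d[2])
  py <- rep(centers[[2]], each = d[1])
  for (s in stack$slices) {
    if (s$z < lo[3] - 1e-9 || s$z > hi[3] + 1e-9) {
      ot_abort(sprintf("Contour slice at z = %g mm lies outside the grid extent.", s$z),
               "extent_error")
    }
    k <- which.min(abs(centers[[3]] - s$z))
    plane <- out[, , k]
    for (p in s$polygons) {
      if (any(p[, 1] < lo[1] - 1e-9) || any(p[, 1] > hi[1] + 1e-9) ||
          any(p[, 2] < lo[2] - 1e-9) || any(p[, 2] > hi[2] + 1e-9)) {
        ot_abort("Contour polygon lies outside the grid extent.", "extent_error")
      }
      plane <- plane | matrix(point_in_polygon(px, py, p), d[1], d[2])
    }
    out[, , k] <- plane
  }
  structure_mask(out, tmpl$spacing, tmpl$origin, tmpl$axis_labels)
}
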