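#' Directional CTV-to-PTV margins
#'
#' Six non-negative margins in mm, one per anatomical half-axis. The shipped
#' default is the hypofractionation protocol margin: 10 mm in all directions
#' except 7 mm posteriorly, protecting the rectum.
#'
#' @param right,left,anterior,posterior,inferior,superior Margins in mm, each
#'   `>= 0`.
#' @return A named numeric vector of class `margin_spec`.
#' @examples
#' default_ptv_margins()
#' @export
margin_spec <- function(right = 10, left = 10, anterior = 10, posterior = 7,
                        inferior = 10, superior = 10) {
  m <- c(right = right, left = left, anterior = anterior,
         posterior = posterior, inferior = inferior, superior = superior)
  if (any(!is.finite(m)) || any(m < 0)) {
    ot_abort("All six margins must be finite and >= 0 mm.", "domain_error")
  }
  structure(as.numeric(m), names = names(m), class = "margin_spec")
}

#' @rdname margin_spec
#' @export
default_ptv_margins <- function() margin_spec()

margin_for_label <- function(margins, lab) {
  key <- c(R = "right", L = "left", A = "anterior", P = "posterior",
           S = "superior", I = "inferior")[[lab]]
  unname(margins[[key]])
}

# Piecewise-ellipsoidal margin kernel on the mask's grid: an offset d (mm,
# grid-axis components) is inside the margin iff sum_i (d_i / m_i)^2 <= 1,
# where m_i is the margin of the half-axis matching the sign of d_i (resolved
# through the mask's anatomical axis labels). Reduces to a ball for isotropic
# margins. Closed boundary (<=).
margin_kernel <- function(spacing, axis_labels, margins) {
  terms <- vector("list", 3)
  for (a in 1:3) {
    lab_pos <- axis_labels[a]
    m_pos <- margin_for_label(margins, lab_pos)
    m_neg <- margin_for_label(margins, opposite_label(lab_pos))
    n <- ceiling(max(m_pos, m_neg) / spacing[a])
    d <- (-n:n) * spacing[a]
    t <- numeric(length(d))
    pos <- d > 0; neg <- d < 0
    t[pos] <- if (m_pos > 0) (d[pos] / m_pos)^2 else Inf
    t[neg] <- if (m_neg > 0) (d[neg] / m_neg)^2 else Inf
    terms[[a]] <- t
  }
  q <- outer(outer(terms[[1]], terms[[2]], `+`), terms[[3]], `+`)
  q <= 1 + 1e-9
}

# Full 3D linear convolution via FFT, cropped so out[p] = sum_o x[p - o] k[o]
# with k indexed by offsets -r..r. Used for binary dilation/erosion counts.
conv3d_sum <- function(x, k) {
  dx <- dim(x); dk <- dim(k)
  pad <- vapply(dx + dk - 1L, function(n) stats::nextn(n, c(2, 3, 5)), numeric(1))
  xp <- array(0, pad); xp[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <- x
  kp <- array(0, pad); kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  cc <- Re(fft(fft(xp) * fft(kp), inverse = TRUE)) / prod(pad)
  r <- (dk - 1L) %/% 2L
  cc[r[1] + seq_len(dx[1]), r[2] + seq_len(dx[2]), r[3] + seq_len(dx[3]),
     drop = FALSE]
}

#' Expand a CTV into a PTV by directional margins
#'
#' Dilates the CTV mask with a piecewise-ellipsoidal kernel: a voxel centre
#' `p` belongs to the PTV iff some CTV voxel centre `c` satisfies
#' `sum_i ((p - c)_i / m_i)^2 <= 1`, where each component picks the margin of
#' the anatomical half-axis matching its sign. With isotropic margins this is
#' expansion by a ball; margins of zero collapse to the identity. The PTV
#' always contains the CTV.
#'
#' @param ctv Nonempty CTV `structure_mask`.
#' @param margins A [margin_spec()]; defaults to the protocol margins
#'   (10 mm, 7 mm posterior).
#' @return PTV `structure_mask` on the same grid.
#' @export
expand_margin <- function(ctv, margins = default_ptv_margins()) {
  stop_if_empty(ctv, "CTV")
  if (!inherits(margins, "margin_spec")) margins <- do.call(margin_spec, as.list(margins))
  k <- margin_kernel(ctv$spacing, ctv$axis_labels, margins)
  out <- conv3d_sum(ctv$voxels, k) > 0.5
  structure_mask(out, ctv$spacing, ctv$origin, ctv$axis_labels)
}

#' Extract an organ wall from a solid organ mask
#'
#' The wall is the organ minus its erosion by a ball of the given physical
#' radius: `wall = organ \\ erode(organ, thickness)`. The wall is always a
#' subset of the organ; a thickness at or above the organ's inradius returns
#' the whole organ.
#'
#' @param organ Nonempty solid `structure_mask`.
#' @param thickness_mm Wall thickness in mm (> 0). Default 3 mm.
#' @return Wall `structure_mask` on the same grid.
#' @export
wall_from_solid <- function(organ, thickness_mm = 3) {
  stop_if_empty(organ, "organ")
  if (!is.finite(thickness_mm) || thickness_mm <= 0) {
    ot_abort("`thickness_mm` must be > 0.", "domain_error")
  }
  n <- ceiling(thickness_mm / organ$spacing)
  off <- lapply(1:3, function(a) (-n[a]:n[a]) * organ$spacing[a])
  q <- outer(outer(off[[1]]^2, off[[2]]^2, `+`), off[[3]]^2, `+`)
  ball <- q <= thickness_mm^2 + 1e-9
  eroded <- conv3d_sum(organ$voxels, ball) > sum(ball) - 0.5
  structure_mask(organ$voxels & !eroded, organ$spacing, organ$origin,
                 organ$axis_labels)
}
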