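# Geometry fixtures and independent brute-force oracles.

# Digitized sphere: voxel centers within radius r of `center`, on an
# isotropic grid padded by `pad` mm, shared across all calls with the same
# span so masks are co-registered.
grid_mask <- function(span, spacing, predicate) {
  cs <- seq(-span, span, by = spacing)
  q <- predicate(cs)
  structure_mask(q, rep(spacing, 3), rep(-span, 3))
}

sphere_on_grid <- function(r, center = c(0, 0, 0), span = 40, spacing = 1) {
  grid_mask(span, spacing, function(cs) {
    outer(outer((cs - center[1])^2, (cs - center[2])^2, `+`),
          (cs - center[3])^2, `+`) <= r^2
  })
}

# Analytic volume of the lens-shaped intersection of spheres (r1, r2) with
# centres d apart (0 < d < r1 + r2), via spherical caps.
lens_volume <- function(r1, r2, d) {
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * r2 - 3 * r2^2 + 2 * d * r1 + 6 * r1 * r2 - 3 * r1^2) / (12 * d)
}

# Brute-force margin expansion: direct evaluation of the piecewise
# ellipsoidal predicate over (every voxel) x (every true CTV voxel),
# independent of the FFT implementation.
brute_expand <- function(ctv, margins) {
  d <- dim(ctv$voxels)
  centers <- voxel_centers(ctv)
  true_idx <- which(ctv$voxels, arr.ind = TRUE)
  # margin of the half-axis matching the displacement sign, per grid axis
  mpos <- numeric(3); mneg <- numeric(3)
  key <- c(R = "right", L = "left", A = "anterior", P = "posterior",
           S = "superior", I = "inferior")
  opp <- c(R = "L", L = "R", A = "P", P = "A", S = "I", I = "S")
  for (a in 1:3) {
    lab <- ctv$axis_labels[a]
    mpos[a] <- margins[[key[[lab]]]]
    mneg[a] <- margins[[key[[opp[[lab]]]]]]
  }
  term <- function(dd, a) {
    t <- numeric(length(dd))
    p <- dd > 0; n <- dd < 0
    t[p] <- if (mpos[a] > 0) (dd[p] / mpos[a])^2 else Inf
    t[n] <- if (mneg[a] > 0) (dd[n] / mneg[a])^2 else Inf
    t
  }
  out <- array(FALSE, d)
  all_i <- rep(seq_len(d[1]), times = d[2] * d[3])
  all_j <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  all_k <- rep(seq_len(d[3]), each = d[1] * d[2])
  px <- centers[[1]][all_i]; py <- centers[[2]][all_j]; pz <- centers[[3]][all_k]
  acc <- logical(length(px))
  for (v in seq_len(nrow(true_idx))) {
    cx <- centers[[1]][true_idx[v, 1]]
    cy <- centers[[2]][true_idx[v, 2]]
    cz <- centers[[3]][true_idx[v, 3]]
    q <- term(px - cx, 1) + term(py - cy, 2) + term(pz - cz, 3)
    acc <- acc | (q <= 1 + 1e-9)
  }
  array(acc, d)
}

# Winding-number (angle-sum) point-in-polygon: an algorithm independent of
# the crossing-count implementation. Boundary points included via the same
# on-segment test.
winding_pip <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  total <- numeric(length(px))
  on_edge <- logical(length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1] - px; ay <- poly[i, 2] - py
    bx <- poly[j, 1] - px; by <- poly[j, 2] - py
    total <- total + atan2(ax * by - ay * bx, ax * bx + ay * by)
    dx <- poly[j, 1] - poly[i, 1]; dy <- poly[j, 2] - poly[i, 2]
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, (-ax * dx - ay * dy) / len2)) else 0
    d2 <- (ax + t * dx)^2 + (ay + t * dy)^2
    on_edge <- on_edge | d2 <= eps^2
  }
  (abs(total) > pi) | on_edge
}

brute_rasterize <- function(stack, tmpl) {
  d <- dim(tmpl$voxels)
  centers <- voxel_centers(tmpl)
  out <- array(FALSE, d)
  px <- rep(centers[[1]], times = d[2])
  py <- rep(centers[[2]], each = d[1])
  for (s in stack$slices) {
    k <- which.min(abs(centers[[3]] - s$z))
    for (p in s$polygons) {
      out[, , k] <- out[, , k] | matrix(winding_pip(px, py, p), d[1], d[2])
    }
  }
  out
}

# Random small blob CTV for property tests.
random_blob <- function(dims = c(20, 20, 20), n_seeds = 3, spacing = c(1, 1, 1)) {
  v <- array(FALSE, dims)
  for (s in seq_len(n_seeds)) {
    c0 <- sapply(dims, function(n) sample(seq(4, n - 3), 1))
    r <- runif(1, 1.5, 4)
    cs <- lapply(1:3, function(a) (seq_len(dims[a]) - c0[a]) * spacing[a])
    q <- outer(outer(cs[[1]]^2, cs[[2]]^2, `+`), cs[[3]]^2, `+`)
    v <- v | (q <= r^2)
  }
  structure_mask(v, spacing, c(0, 0, 0))
}
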