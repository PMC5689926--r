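#' Read and write structure masks
#'
#' Masks are exchanged as NIfTI (`.nii` / `.nii.gz`, via RNifti) or NRRD
#' (`.nrrd`, raw encoding) volumes. Values are binarized at 0.5 on load.
#' Only axis-aligned orientations are supported; the anatomical axis labels
#' are derived from (and written into) the image orientation, with the
#' package's physical coordinates measured along the grid axes.
#'
#' @param path File path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `read_mask()` returns a [structure_mask()]; `write_mask()` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    read_mask_nifti(path)
  } else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    read_mask_nrrd(path)
  } else {
    ot_abort("Unsupported mask format (use .nii, .nii.gz or .nrrd).", "io_error")
  }
}

#' @rdname read_mask
#' @param mask A [structure_mask()].
#' @export
write_mask <- function(mask, path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    write_mask_nifti(mask, path)
  } else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_mask_nrrd(mask, path)
  } else {
    ot_abort("Unsupported mask format (use .nii, .nii.gz or .nrrd).", "io_error")
  }
  invisible(path)
}

# Signed-permutation matrix mapping grid axes to world RAS axes.
axis_matrix <- function(axis_labels) {
  world_axis <- c(R = 1, L = 1, A = 2, P = 2, S = 3, I = 3)
  world_sign <- c(R = 1, L = -1, A = 1, P = -1, S = 1, I = -1)
  P <- matrix(0, 3, 3)
  for (a in 1:3) P[world_axis[[axis_labels[a]]], a] <- world_sign[[axis_labels[a]]]
  P
}

labels_from_matrix <- function(P) {
  labs <- character(3)
  names_pos <- c("R", "A", "S"); names_neg <- c("L", "P", "I")
  for (a in 1:3) {
    w <- which(abs(P[, a]) > 1e-6)
    if (length(w) != 1) {
      ot_abort("Only axis-aligned mask orientations are supported.", "io_error")
    }
    labs[a] <- if (P[w, a] > 0) names_pos[w] else names_neg[w]
  }
  labs
}

write_mask_nifti <- function(mask, path) {
  P <- axis_matrix(mask$axis_labels)
  affine <- diag(4)
  affine[1:3, 1:3] <- P %*% diag(mask$spacing)
  affine[1:3, 4] <- as.vector(P %*% mask$origin)
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim(mask$voxels)))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  M <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  if (any(spacing <= 0)) ot_abort("Degenerate NIfTI affine.", "io_error")
  P <- sweep(M, 2, spacing, "/")
  labs <- labels_from_matrix(P)
  origin <- as.vector(t(P) %*% aff[1:3, 4])
  structure_mask(as.array(img) >= 0.5, spacing, origin, labs)
}

write_mask_nrrd <- function(mask, path) {
  d <- dim(mask$voxels)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# binary structure mask",
    "type: uint8",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
            mask$spacing[1], mask$spacing[2], mask$spacing[3]),
    sprintf("space origin: (%.9g,%.9g,%.9g)",
            mask$origin[1], mask$origin[2], mask$origin[3]),
    sprintf("axis labels:=%s", paste(mask$axis_labels, collapse = " ")),
    ""
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.raw(as.integer(mask$voxels)), con)
  invisible(path)
}

read_mask_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) ot_abort("Truncated NRRD header.", "io_error")
    if (ln == "") break
    lines <- c(lines, ln)
  }
  if (!grepl("^NRRD", lines[1])) ot_abort("Not an NRRD file.", "io_error")
  field <- function(name) {
    ln <- grep(paste0("^", name, ":"), lines, value = TRUE)
    if (length(ln) == 0) return(NULL)
    sub(paste0("^", name, ":=?\\s*"), "", ln[1])
  }
  if (!identical(field("encoding"), "raw")) {
    ot_abort("Only raw-encoded NRRD is supported.", "io_error")
  }
  type <- field("type")
  if (!type %in% c("uint8", "unsigned char")) {
    ot_abort("Only uint8 NRRD masks are supported.", "io_error")
  }
  d <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  nums <- function(s) as.numeric(regmatches(s, gregexpr("-?[0-9.eE+]+", s))[[1]])
  dirs <- nums(field("space directions"))
  spacing <- c(dirs[1], dirs[5], dirs[9])
  origin <- nums(field("space origin"))
  labs_field <- field("axis labels")
  labs <- if (!is.null(labs_field)) strsplit(labs_field, "\\s+")[[1]] else c("R", "A", "S")
  raw <- readBin(con, "raw", n = prod(d))
  if (length(raw) < prod(d)) ot_abort("Truncated NRRD data.", "io_error")
  structure_mask(array(as.integer(raw) >= 1, d), spacing, origin, labs)
}
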