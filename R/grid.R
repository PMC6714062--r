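# Volume grids, masks and NIfTI I/O.
#
# A volume_grid is the shared spatial frame of a study: an integer 3-vector of
# voxel counts plus a 4x4 affine taking 0-based voxel indices to mm in RAS+
# orientation. Every mask and 4D run in an analysis must live on one grid.

#' Create a volume grid
#'
#' A grid couples a 3D array shape to an affine transform mapping 0-based
#' voxel indices to millimetre coordinates (RAS+ convention: +x right,
#' +y anterior, +z superior).
#'
#' @param shape Integer vector of length 3, voxels along x, y, z.
#' @param affine 4x4 numeric matrix, voxel index (0-based) to mm. If `NULL`,
#'   an isotropic grid of `voxel_size_mm` centred on the origin is built.
#' @param voxel_size_mm Voxel edge length in mm, used when `affine` is `NULL`.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, affine = NULL, voxel_size_mm = 3) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size_mm, 3), 1))
    # centre of the grid sits at mm (0,0,0)
    affine[1:3, 4] <- -voxel_size_mm * (shape - 1) / 2
  }
  stopifnot(length(affine) == 16L)
  affine <- matrix(as.numeric(affine), 4L, 4L)
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("grid affine is singular", call. = FALSE)
  structure(list(shape = shape, affine = affine), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$shape, collapse = " x "),
      " voxels; voxel->mm affine:\n", sep = "")
  print(round(x$affine, 4))
  invisible(x)
}

#' @export
format.volume_grid <- function(x, ...) {
  paste0(paste(x$shape, collapse = "x"), " grid")
}

grids_equal <- function(a, b, tol = 1e-5) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

#' Voxel indices of a grid (or mask) in canonical order
#'
#' Canonical order is R's array linear order: the x index varies fastest,
#' then y, then z. All V x T matrices, fingerprints and labelings in the
#' package index voxels this way.
#'
#' @param grid A `volume_grid`.
#' @param mask Optional logical array on the grid; if given, only voxels
#'   inside the mask are returned (still in canonical order).
#' @return Integer matrix with columns `i, j, k` (0-based voxel indices).
#' @export
voxel_indices <- function(grid, mask = NULL) {
  if (is.null(mask)) {
    idx <- arrayInd(seq_len(prod(grid$shape)), grid$shape)
  } else {
    check_mask(mask, grid)
    idx <- which(mask, arr.ind = TRUE)
    idx <- idx[order(idx[, 3], idx[, 2], idx[, 1]), , drop = FALSE]
  }
  idx <- idx - 1L
  colnames(idx) <- c("i", "j", "k")
  idx
}

#' Convert 0-based voxel indices to mm coordinates
#'
#' @param idx Integer matrix (n x 3) of 0-based voxel indices.
#' @param grid A `volume_grid`.
#' @return Numeric matrix (n x 3) of mm coordinates, columns `x, y, z`.
#' @export
voxel_to_mm <- function(idx, grid) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  mm <- cbind(idx, 1) %*% t(grid$affine)
  mm <- mm[, 1:3, drop = FALSE]
  colnames(mm) <- c("x", "y", "z")
  mm
}

check_mask <- function(mask, grid, name = "mask") {
  if (!is.array(mask) || !identical(dim(mask), as.integer(grid$shape)))
    stop(name, " does not match the grid shape ",
         paste(grid$shape, collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

#' Spherical seed mask on a grid
#'
#' A voxel belongs to the sphere iff the Euclidean distance from its centre
#' (in mm, through the grid affine) to `center_mm` is at most `radius_mm`.
#'
#' @param center_mm Numeric length-3, sphere centre in mm.
#' @param radius_mm Sphere radius in mm (default 8, the usual DMN-hub seed).
#' @param grid A `volume_grid`.
#' @return Logical array on the grid.
#' @export
sphere_mask <- function(center_mm, grid, radius_mm = 8) {
  stopifnot(radius_mm > 0, length(center_mm) == 3)
  mm <- voxel_to_mm(voxel_indices(grid), grid)
  d2 <- (mm[, 1] - center_mm[1])^2 + (mm[, 2] - center_mm[2])^2 +
    (mm[, 3] - center_mm[3])^2
  m <- array(d2 <= radius_mm^2, dim = grid$shape)
  if (!any(m))
    stop("sphere at (", paste(center_mm, collapse = ", "),
         ") mm, radius ", radius_mm, " mm contains no voxel", call. = FALSE)
  m
}

#' Read a NIfTI volume bound to a grid
#'
#' @param path Path to a NIfTI-1 file (3D or 4D).
#' @param grid Optional `volume_grid` the volume must match (shape of the
#'   first three dimensions and affine within 1e-5); a mismatch is an error
#'   naming the file.
#' @return A list with `data` (array), `grid` (`volume_grid`), and for 4D
#'   input `tr_seconds` read from the header.
#' @export
read_volume <- function(path, grid = NULL) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  dm <- dim(img)
  g <- volume_grid(dm[1:3], affine = aff)
  if (!is.null(grid) && !grids_equal(grid, g))
    stop("grid mismatch: ", path, " does not match the reference grid ",
         "(shape ", paste(g$shape, collapse = "x"), " vs ",
         paste(grid$shape, collapse = "x"), " or affine differs > 1e-5)",
         call. = FALSE)
  out <- list(data = unclass(img)[drop = FALSE], grid = g)
  attributes(out$data) <- list(dim = dm)
  if (length(dm) == 4L) {
    pd <- RNifti::pixdim(img)
    out$tr_seconds <- if (length(pd) >= 4) pd[4] else NA_real_
  }
  out
}

#' Write an array to NIfTI on a grid
#'
#' Integer-valued label volumes round-trip exactly; floating-point maps
#' round-trip to single precision.
#'
#' @param data 3D or 4D array (first three dims must equal the grid shape).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param grid A `volume_grid` supplying the affine.
#' @param tr_seconds For 4D data, the repetition time stored in the header.
#' @param datatype NIfTI datatype; `"auto"` picks int16 for integer-valued
#'   label data and float32 otherwise.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, grid, tr_seconds = NULL,
                         datatype = "auto") {
  stopifnot(identical(as.integer(dim(data)[1:3]), grid$shape))
  if (identical(datatype, "auto")) {
    datatype <- if (is.logical(data) ||
                    (is.numeric(data) && all(data == round(data)) &&
                     max(abs(data)) < 32767)) "int16" else "float"
  }
  vox <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  pd <- c(1, vox, if (!is.null(tr_seconds)) tr_seconds else 0, 0, 0, 0)
  hdr <- RNifti::niftiHeader(list(
    pixdim = pd,
    srow_x = grid$affine[1, ], srow_y = grid$affine[2, ],
    srow_z = grid$affine[3, ],
    sform_code = 2L, qform_code = 0L, xyzt_units = 10L))
  img <- RNifti::asNifti(data + 0, hdr, datatype = datatype)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' A single subject's BOLD run bound to a mask
#'
#' Stores the time series of the voxels inside `mask` as a V x T matrix in
#' canonical voxel order, together with the grid and repetition time.
#' Non-finite samples make a voxel invalid: such voxels are dropped from the
#' mask with a record rather than silently.
#'
#' @param data V x T numeric matrix (V = number of mask voxels), or a 4D
#'   array on the grid from which mask voxels are extracted.
#' @param mask Logical array on `grid`.
#' @param grid A `volume_grid`.
#' @param tr_seconds Repetition time in seconds.
#' @param subject Subject identifier.
#' @return An object of class `bold_run` with elements `data`, `mask`,
#'   `grid`, `tr_seconds`, `subject`, `dropped_voxels`.
#' @export
bold_run <- function(data, mask, grid, tr_seconds, subject = NA_character_) {
  check_mask(mask, grid)
  if (length(dim(data)) == 4L) {
    stopifnot(identical(as.integer(dim(data)[1:3]), grid$shape))
    tdim <- dim(data)[4]
    data <- t(apply(data, 4, function(v) v[mask]))
    data <- matrix(data, ncol = sum(mask))  # T x V
    data <- t(data)
  }
  data <- as.matrix(data)
  if (nrow(data) != sum(mask))
    stop("data has ", nrow(data), " rows but mask has ", sum(mask),
         " voxels", call. = FALSE)
  if (ncol(data) < 2L) stop("a BOLD run needs at least 2 volumes",
                            call. = FALSE)
  bad <- !apply(is.finite(data), 1, all)
  dropped <- integer(0)
  if (any(bad)) {
    keep_idx <- which(mask)[!bad]
    dropped <- which(mask)[bad]
    newmask <- array(FALSE, dim = grid$shape)
    newmask[keep_idx] <- TRUE
    mask <- newmask
    data <- data[!bad, , drop = FALSE]
  }
  structure(list(data = data, mask = mask, grid = grid,
                 tr_seconds = as.numeric(tr_seconds),
                 subject = subject, dropped_voxels = dropped),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat("<bold_run> subject ", x$subject, ": ", nrow(x$data), " voxels x ",
      ncol(x$data), " volumes, TR ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

#' Rebuild a 3D (or 4D) array from masked values
#'
#' @param values Vector of length V, or V x T matrix, in canonical mask order.
#' @param mask Logical array.
#' @param fill Value outside the mask.
#' @return 3D array (vector input) or 4D array (matrix input).
#' @export
unmask <- function(values, mask, fill = 0) {
  if (is.matrix(values)) {
    out <- array(fill, dim = c(dim(mask), ncol(values)))
    flat <- matrix(out, nrow = prod(dim(mask)))
    flat[which(mask), ] <- values
    array(flat, dim = c(dim(mask), ncol(values)))
  } else {
    out <- array(fill, dim = dim(mask))
    out[mask] <- values
    out
  }
}
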