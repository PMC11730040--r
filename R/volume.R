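#' Volumetric image container
#'
#' A `cmb_volume` is a light wrapper around a 3D array carrying the voxel
#' geometry needed for lesion measurement: voxel dimensions in mm and a 4x4
#' voxel-to-world affine. It is the carrier for binary CMB masks, probabilistic
#' atlases, label maps and scalar images throughout the package.
#'
#' Voxel indices are 1-based (R convention); the affine follows the NIfTI
#' convention and maps 0-based voxel coordinates to world mm, so the world
#' position of voxel `(i, j, k)` is `affine %*% c(i - 1, j - 1, k - 1, 1)`.
#'
#' @param data A 3D numeric/integer/logical array.
#' @param voxel_dims Length-3 positive numeric, voxel size in mm per axis.
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal scaling by
#'   `voxel_dims`.
#' @param dtype One of `"binary"`, `"probability"`, `"label"`, `"intensity"`.
#'   Binary volumes must contain only 0 and 1; probability volumes values in
#'   `[0, 1]` (unit scale) or `[0, 100]` (percent scale); label volumes
#'   non-negative integers.
#' @param scale For probability volumes, `"unit"` or `"percent"`. Detected from
#'   the data maximum when `NULL` (max > 1.5 implies percent).
#'
#' @return A `cmb_volume` object: a list with elements `data`, `voxel_dims`,
#'   `affine`, `dtype` and `scale`.
#' @export
#' @examples
#' v <- cmb_volume(array(0, c(8, 8, 8)), voxel_dims = c(0.9, 0.9, 0.9),
#'                 dtype = "binary")
#' v
cmb_volume <- function(data, voxel_dims = c(1, 1, 1), affine = NULL,
                       dtype = c("intensity", "binary", "probability", "label"),
                       scale = NULL) {
  dtype <- match.arg(dtype)
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort_validation("`data` must be a 3D array.")
  }
  if (is.logical(data)) data <- data * 1L
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) || any(voxel_dims <= 0)) {
    abort_validation("`voxel_dims` must be three positive mm values.")
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_dims, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine))) {
    abort_geometry("`affine` must be a finite 4x4 matrix.")
  }
  vals_ok <- switch(dtype,
    binary = {
      u <- unique(as.vector(data))
      bad <- setdiff(u, c(0, 1))
      if (length(bad)) {
        abort_validation(paste0(
          "binary volume contains values outside {0, 1}: ",
          paste(utils::head(bad, 5), collapse = ", ")))
      }
      TRUE
    },
    probability = {
      mx <- max(data, na.rm = TRUE)
      if (is.null(scale)) scale <- if (isTRUE(mx > 1.5)) "percent" else "unit"
      lim <- if (scale == "percent") 100 else 1
      if (min(data, na.rm = TRUE) < 0 || mx > lim) {
        abort_validation(sprintf(
          "probability volume (scale '%s') has values outside [0, %g].", scale, lim))
      }
      TRUE
    },
    label = {
      if (any(data < 0) || any(data != round(data))) {
        abort_validation("label volume must contain non-negative integers.")
      }
      TRUE
    },
    TRUE
  )
  stopifnot(isTRUE(vals_ok))
  structure(
    list(data = data, voxel_dims = voxel_dims, affine = affine,
         dtype = dtype, scale = if (dtype == "probability") scale else NULL),
    class = "cmb_volume"
  )
}

#' @export
print.cmb_volume <- function(x, ...) {
  cat(sprintf("<cmb_volume> %s, %s voxels, %s mm/voxel\n",
              x$dtype,
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$voxel_dims, 4), collapse = " x ")))
  if (x$dtype == "binary") {
    cat(sprintf("  foreground voxels: %d\n", sum(x$data == 1)))
  }
  invisible(x)
}

is_cmb_volume <- function(x) inherits(x, "cmb_volume")

assert_volume <- function(x, dtype = NULL, arg = "volume") {
  if (!is_cmb_volume(x)) abort_validation(sprintf("`%s` must be a cmb_volume.", arg))
  if (!is.null(dtype) && x$dtype != dtype) {
    abort_validation(sprintf("`%s` must have dtype '%s' (got '%s').", arg, dtype, x$dtype))
  }
  invisible(x)
}

# geometry equality between two volumes
same_geometry <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$voxel_dims - b$voxel_dims)) < tol
}

assert_same_geometry <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b)) {
    abort_geometry(sprintf(
      "%s have mismatched geometry: %s @ (%s) vs %s @ (%s).", what,
      paste(dim(a$data), collapse = "x"), paste(signif(a$voxel_dims, 4), collapse = ","),
      paste(dim(b$data), collapse = "x"), paste(signif(b$voxel_dims, 4), collapse = ",")))
  }
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Loads a `.nii` / `.nii.gz` file, canonicalises its orientation (see
#' [canonicalise_orientation()]) and validates the values against the expected
#' volume kind. Voxel dimensions come from the header `pixdim`, the affine
#' from the sform/qform.
#'
#' @param path Path to a NIfTI-1 file.
#' @param expect Expected volume kind, as in [cmb_volume()].
#' @param canonical Reorient to the canonical (RAS-aligned) axis order on load.
#' @return A [cmb_volume()].
#' @export
read_volume <- function(path,
                        expect = c("intensity", "binary", "probability", "label"),
                        canonical = TRUE) {
  expect <- match.arg(expect)
  if (!file.exists(path)) abort_format(sprintf("file does not exist: %s", path))
  img <- tryCatch(RNifti::readNifti(path, internal = FALSE),
                  error = function(e) {
                    abort_format(sprintf("cannot read '%s' as NIfTI-1: %s",
                                         path, conditionMessage(e)))
                  })
  data <- as.array(img)
  dm <- dim(data)
  if (length(dm) > 3L) {
    if (prod(dm[-(1:3)]) != 1L) {
      abort_format(sprintf("'%s' is %dD; only 3D volumes are supported.",
                           path, length(dm)))
    }
    dim(data) <- dm[1:3]
  }
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  vd <- abs(RNifti::pixdim(img))[1:3]
  attributes(data) <- list(dim = dim(data))
  vol <- cmb_volume(data, voxel_dims = vd, affine = affine, dtype = expect)
  if (canonical) vol <- canonicalise_orientation(vol) else vol
}

#' Write a volume as NIfTI-1
#'
#' Writes the grid with its affine in both sform and qform. Binary and label
#' volumes are stored as 32-bit integers so that save/load round-trips are
#' voxelwise exact.
#'
#' @param vol A [cmb_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  assert_volume(vol)
  if (any(!is.finite(vol$data))) {
    abort_validation("volume contains non-finite values; refusing to write.")
  }
  data <- vol$data
  if (vol$dtype %in% c("binary", "label")) storage.mode(data) <- "integer"
  hdr <- RNifti::niftiHeader(data)
  hdr$sform_code <- 2L
  hdr$qform_code <- 0L
  hdr$srow_x <- vol$affine[1, ]
  hdr$srow_y <- vol$affine[2, ]
  hdr$srow_z <- vol$affine[3, ]
  hdr$pixdim[2:4] <- vol$voxel_dims
  img <- RNifti::asNifti(data, reference = hdr)
  ok <- tryCatch({RNifti::writeNifti(img, path); TRUE},
                 error = function(e) {
                   abort_format(sprintf("failed to write '%s': %s",
                                        path, conditionMessage(e)))
                 })
  invisible(path)
}

#' Reorient a volume to the canonical axis order
#'
#' Permutes and flips the voxel axes so that each voxel axis aligns with the
#' anatomical axis it predominantly points along (the right-handed RAS
#' convention of MNI standard space), as derived from the affine's dominant
#' directions. World coordinates of every voxel centre are preserved, the
#' foreground count of masks is unchanged, and the operation is idempotent.
#'
#' @param vol A [cmb_volume()] with an invertible affine.
#' @return The reoriented [cmb_volume()].
#' @export
canonicalise_orientation <- function(vol) {
  assert_volume(vol)
  M <- vol$affine[1:3, 1:3]
  if (abs(det(M)) < 1e-12) abort_geometry("affine is singular; cannot orient.")
  A <- abs(M)
  perm <- integer(3)   # perm[w] = voxel axis feeding world axis w
  usedv <- usedw <- logical(3)
  for (step in 1:3) {
    A2 <- A
    A2[usedw, ] <- -Inf
    A2[, usedv] <- -Inf
    ix <- arrayInd(which.max(A2), c(3L, 3L))
    w <- ix[1L]; v <- ix[2L]
    perm[w] <- v
    usedw[w] <- TRUE; usedv[v] <- TRUE
  }
  sgn <- vapply(1:3, function(w) sign(M[w, perm[w]]), numeric(1))
  sgn[sgn == 0] <- 1
  if (all(perm == 1:3) && all(sgn > 0)) return(vol)

  dm <- dim(vol$data)
  data <- aperm(vol$data, perm)
  idx <- lapply(1:3, function(w) if (sgn[w] < 0) rev(seq_len(dm[perm[w]])) else seq_len(dm[perm[w]]))
  data <- data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]

  # voxel-coordinate map: old0 = P %*% new0 + t (0-based)
  P <- matrix(0, 4, 4); P[4, 4] <- 1
  for (w in 1:3) {
    P[perm[w], w] <- sgn[w]
    if (sgn[w] < 0) P[perm[w], 4] <- dm[perm[w]] - 1
  }
  affine <- vol$affine %*% P
  cmb_volume(data, voxel_dims = vol$voxel_dims[perm], affine = affine,
             dtype = vol$dtype, scale = vol$scale)
}

#' World coordinates of voxel centres
#'
#' @param vol A [cmb_volume()].
#' @param idx An n x 3 matrix of 1-based voxel indices (real-valued allowed).
#' @return An n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(vol, idx) {
  assert_volume(vol)
  idx <- rbind_matrix(idx)
  w <- vol$affine %*% rbind(t(idx - 1), 1)
  t(w[1:3, , drop = FALSE])
}

# coerce vector/matrix to n x 3 matrix
rbind_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3L) else as.matrix(x)
}
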