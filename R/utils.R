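# shared internal helpers

abort_validation <- function(msg, ...) abort(msg, class = "cmb_error_validation", ...)
abort_format     <- function(msg, ...) abort(msg, class = "cmb_error_format", ...)
abort_geometry   <- function(msg, ...) abort(msg, class = "cmb_error_geometry", ...)

#' Round half away from zero
#'
#' Rounds to the nearest integer with exact halves going away from zero
#' (so 5.5 -> 6, -5.5 -> -6), the convention used when snapping lesion
#' centroids to voxel indices. Base R's `round()` rounds halves to even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @export
#' @examples
#' round_half_away(c(5.49, 5.5, -5.5))
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# 1-based (i,j,k) matrix -> linear index, column-major
lin_index <- function(coords, dm) {
  (coords[, 3L] - 1) * (dm[1L] * dm[2L]) + (coords[, 2L] - 1) * dm[1L] + coords[, 1L]
}

# neighbour offsets for a 3D connectivity scheme
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    abort_validation("`connectivity` must be one of 6, 18 or 26.")
  }
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6"  = ord == 1,
    "18" = ord >= 1 & ord <= 2,
    "26" = ord >= 1
  )
  unname(g[keep, , drop = FALSE])
}

# in-bounds filter for 1-based coords
in_bounds <- function(coords, dm) {
  coords[, 1L] >= 1 & coords[, 1L] <= dm[1L] &
    coords[, 2L] >= 1 & coords[, 2L] <= dm[2L] &
    coords[, 3L] >= 1 & coords[, 3L] <= dm[3L]
}
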