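#' MARS structure lookup table
#'
#' The default structure table of the Microbleed Anatomical Rating Scale:
#' thirteen structures grouped into the three MARS regions, each with the
#' source atlas family it is usually taken from, the probability threshold (on
#' the percent scale) used to binarise probabilistic sources, and whether the
#' mask is dilated during assembly (the cortical lobes are, to pull the
#' grey-white junction into the lobar region).
#'
#' Regions: brainstem and cerebellum are infratentorial; basal ganglia,
#' thalamus, internal/external capsule, corpus callosum and deep white matter
#' are deep; frontal, parietal, temporal, occipital and insula are lobar.
#' Discrete label sources (MNI structural lobes and cerebellum, JHU white
#' matter labels) carry no threshold.
#'
#' @return A tibble with columns `code`, `name`, `region`, `source`,
#'   `threshold`, `dilate`.
#' @export
#' @examples
#' mars_lut()
mars_lut <- function() {
  tibble(
    code = 1:13,
    name = c("brainstem", "cerebellum",
             "basal_ganglia", "thalamus", "internal_capsule",
             "external_capsule", "corpus_callosum", "deep_white_matter",
             "frontal", "parietal", "temporal", "occipital", "insula"),
    region = c(rep("infratentorial", 2), rep("deep", 6), rep("lobar", 5)),
    source = c("harvard_oxford_subcortical", "mni_structural",
               "harvard_oxford_subcortical", "harvard_oxford_subcortical",
               "jhu_icbm_dti81", "jhu_icbm_dti81", "jhu_icbm_dti81",
               "harvard_oxford_subcortical",
               rep("mni_structural", 5)),
    threshold = c(50, NA, 50, 50, NA, NA, NA, 60, NA, NA, NA, NA, NA),
    dilate = c(rep(FALSE, 8), rep(TRUE, 5))
  )
}

mars_region_names <- function() c("infratentorial", "deep", "lobar")

# structures whose own label wins over deep white matter (the exclusion rule)
dwm_excluded_structures <- function() {
  c("internal_capsule", "external_capsule", "corpus_callosum")
}

# assembly priority class, smaller = stronger claim
structure_priority <- function(lut) {
  dplyr::case_when(
    lut$region == "infratentorial" ~ 1L,
    lut$region == "deep" & lut$name != "deep_white_matter" ~ 2L,
    lut$name == "deep_white_matter" ~ 3L,
    TRUE ~ 4L
  )
}

validate_lut <- function(lut) {
  need <- c("code", "name", "region", "source", "threshold", "dilate")
  if (!all(need %in% names(lut))) {
    abort_validation(paste0("LUT must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(duplicated(lut$code)) || any(lut$code <= 0)) {
    abort_validation("LUT codes must be unique positive integers (0 is background).")
  }
  bad <- setdiff(unique(lut$region), mars_region_names())
  if (length(bad)) {
    abort_validation(paste0("unknown MARS region(s): ", paste(bad, collapse = ", ")))
  }
  thr <- lut$threshold[!is.na(lut$threshold)]
  if (any(thr <= 0 | thr > 100)) {
    abort_validation("LUT thresholds must lie in (0, 100].")
  }
  invisible(lut)
}

#' Read / write a structure lookup table
#'
#' CSV with columns `code, name, region, source, threshold, dilate`. A copy of
#' the default table ships in `inst/extdata/mars_lut.csv`.
#'
#' @param path CSV path.
#' @return `read_lut()` returns the validated LUT tibble; `write_lut()`
#'   returns `path` invisibly.
#' @export
read_lut <- function(path) {
  lut <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           code = "i", name = "c", region = "c",
                           source = "c", threshold = "d", dilate = "l"))
  validate_lut(lut)
}

#' @rdname read_lut
#' @param lut A LUT tibble.
#' @export
write_lut <- function(lut, path) {
  validate_lut(lut)
  readr::write_csv(lut, path)
  invisible(path)
}

#' Binarise a probabilistic structure map
#'
#' Foreground where probability >= threshold. The comparison is inclusive, the
#' common atlas-tool convention, so a uniform map at exactly the threshold is
#' all foreground. The threshold is given on the percent scale (0, 100] and is
#' rescaled automatically for unit-scale volumes.
#'
#' @param prob A probability [cmb_volume()].
#' @param threshold_percent Threshold in (0, 100].
#' @return A binary [cmb_volume()] with the same geometry.
#' @export
binarise_structure <- function(prob, threshold_percent) {
  assert_volume(prob, "probability", "prob")
  if (!is.numeric(threshold_percent) || length(threshold_percent) != 1L ||
      !is.finite(threshold_percent) ||
      threshold_percent <= 0 || threshold_percent > 100) {
    abort_validation("`threshold_percent` must be a single value in (0, 100].")
  }
  thr <- if (identical(prob$scale, "unit")) threshold_percent / 100 else threshold_percent
  cmb_volume((prob$data >= thr) * 1L, prob$voxel_dims, prob$affine, dtype = "binary")
}

#' Morphological dilation of a binary mask
#'
#' Dilates with a 3D structuring element of the given width. Shapes: `"box"`
#' (a size^3 cube, the default reading of "an element of size 3"), `"ball"`
#' (Euclidean radius `(size-1)/2`) or `"cross"` (city-block radius
#' `(size-1)/2`). Output always contains the input.
#'
#' @param mask A binary [cmb_volume()].
#' @param size Odd element width in voxels, >= 1.
#' @param shape Element shape.
#' @return The dilated binary [cmb_volume()].
#' @export
dilate_mask <- function(mask, size = 3, shape = c("box", "ball", "cross")) {
  assert_volume(mask, "binary", "mask")
  shape <- match.arg(shape)
  if (!is.numeric(size) || length(size) != 1L || size < 1 || size != round(size)) {
    abort_validation("`size` must be a positive integer.")
  }
  if (size %% 2 == 0) abort_validation("`size` must be odd (element is centred).")
  r <- (size - 1) / 2
  if (r == 0) return(mask)
  off <- as.matrix(expand.grid(di = -r:r, dj = -r:r, dk = -r:r))
  keep <- switch(shape,
    box = rep(TRUE, nrow(off)),
    ball = sqrt(rowSums(off^2)) <= r + 1e-9,
    cross = rowSums(abs(off)) <= r
  )
  off <- off[keep, , drop = FALSE]
  out <- shift_union(mask$data == 1, off)
  cmb_volume(out * 1L, mask$voxel_dims, mask$affine, dtype = "binary")
}

# OR of a logical array shifted by each offset row (zero padding)
shift_union <- function(bin, off) {
  dm <- dim(bin)
  out <- array(FALSE, dm)
  for (r in seq_len(nrow(off))) {
    d <- off[r, ]
    src_i <- max(1, 1 - d[1]):min(dm[1], dm[1] - d[1])
    src_j <- max(1, 1 - d[2]):min(dm[2], dm[2] - d[2])
    src_k <- max(1, 1 - d[3]):min(dm[3], dm[3] - d[3])
    if (!length(src_i) || !length(src_j) || !length(src_k)) next
    out[src_i + d[1], src_j + d[2], src_k + d[3]] <-
      out[src_i + d[1], src_j + d[2], src_k + d[3]] | bin[src_i, src_j, src_k]
  }
  out
}

#' MARS atlas object
#'
#' An integer label volume plus the structure lookup table; `space` records
#' whether the labels live in the template or an individual subject's grid.
#' Label 0 is reserved for unclassified/background, and every nonzero label
#' appearing in the volume must be a `code` in the LUT.
#'
#' @param labels A label [cmb_volume()].
#' @param lut A LUT tibble, see [mars_lut()].
#' @param space `"template"` or `"subject"`.
#' @return A `mars_atlas` object.
#' @export
mars_atlas <- function(labels, lut = mars_lut(), space = c("template", "subject")) {
  assert_volume(labels, "label", "labels")
  validate_lut(lut)
  space <- match.arg(space)
  present <- setdiff(unique(as.vector(labels$data)), 0)
  orphan <- setdiff(present, lut$code)
  if (length(orphan)) {
    abort_validation(paste0("label volume contains codes absent from the LUT: ",
                            paste(orphan, collapse = ", ")))
  }
  structure(list(labels = labels, lut = lut, space = space), class = "mars_atlas")
}

#' @export
print.mars_atlas <- function(x, ...) {
  cat(sprintf("<mars_atlas> %s space, %s voxels, %d structures labelled\n",
              x$space, paste(dim(x$labels$data), collapse = " x "),
              length(setdiff(unique(as.vector(x$labels$data)), 0))))
  invisible(x)
}

#' Assemble the MARS label volume from per-structure masks
#'
#' Merges binary structure masks into a single label volume under the MARS
#' assembly rules:
#'
#' 1. lobar (cortical) masks flagged `dilate` in the LUT are dilated, pulling
#'    the grey-white junction into the lobar region;
#' 2. internal capsule, external capsule and corpus callosum voxels are
#'    removed from the deep white matter mask (they are rated separately);
#' 3. overlaps across priority classes resolve as infratentorial > named deep
#'    structures > deep white matter > dilated lobar > background, so the
#'    lobar dilation only extends the cortex outward and never annexes deep
#'    or infratentorial tissue;
#' 4. overlaps within a class go to the structure whose *undilated* mask is
#'    nearest the voxel (Euclidean distance in mm); exact ties to the lower
#'    structure code, making assembly deterministic.
#'
#' @param structures Named list of binary [cmb_volume()] masks; names must be
#'   LUT structure names and all masks must share geometry.
#' @param lut Structure table, see [mars_lut()].
#' @param dilate Apply rule 1. Turned off when re-assembling masks that were
#'   already dilated (e.g. after resampling in [transform_atlas()]).
#' @param dilate_size,dilate_shape Structuring element for rule 1, see
#'   [dilate_mask()].
#' @param space Space tag for the returned atlas.
#' @return A [mars_atlas()].
#' @export
assemble_atlas <- function(structures, lut = mars_lut(), dilate = TRUE,
                           dilate_size = 3, dilate_shape = "box",
                           space = "template") {
  validate_lut(lut)
  if (length(structures) == 0L) abort_validation("no structure masks supplied.")
  if (is.null(names(structures)) || any(!nzchar(names(structures)))) {
    abort_validation("`structures` must be a named list of binary masks.")
  }
  unknown <- setdiff(names(structures), lut$name)
  if (length(unknown)) {
    abort_validation(paste0("structures absent from the LUT: ",
                            paste(unknown, collapse = ", ")))
  }
  ref <- structures[[1]]
  bad_geom <- names(structures)[!vapply(structures, function(s) {
    assert_volume(s, "binary"); same_geometry(s, ref)
  }, logical(1))]
  if (length(bad_geom)) {
    abort_geometry(paste0("structure masks with mismatched geometry: ",
                          paste(bad_geom, collapse = ", ")))
  }

  masks <- lapply(structures, function(s) s$data == 1)
  undilated <- masks
  info <- lut[match(names(masks), lut$name), ]
  prio <- structure_priority(info)

  if (dilate) {
    for (nm in names(masks)[info$dilate]) {
      masks[[nm]] <- dilate_mask(structures[[nm]], dilate_size, dilate_shape)$data == 1
    }
  }

  excl <- dwm_excluded_structures()
  if ("deep_white_matter" %in% names(masks)) {
    for (nm in intersect(excl, names(masks))) {
      masks[["deep_white_matter"]] <- masks[["deep_white_matter"]] & !masks[[nm]]
    }
  }

  dm <- dim(ref$data)
  label <- array(0L, dm)
  for (p in sort(unique(prio), decreasing = TRUE)) {   # weakest class first
    idx <- which(prio == p)
    idx <- idx[order(info$code[idx])]
    claim <- Reduce(`+`, lapply(masks[idx], function(m) m * 1L))
    for (i in idx) label[masks[[i]]] <- info$code[i]
    contested <- which(claim >= 2)
    if (length(contested)) {
      label[contested] <- resolve_ties(contested, idx, masks, undilated,
                                       info, ref)
    }
  }
  mars_atlas(cmb_volume(label, ref$voxel_dims, ref$affine, dtype = "label"),
             lut = lut, space = space)
}

# nearest-undilated-structure tie break for same-priority overlaps
resolve_ties <- function(contested, idx, masks, undilated, info, ref) {
  dm <- dim(ref$data)
  cc <- arrayInd(contested, dm)
  cc_mm <- sweep(cc, 2L, ref$voxel_dims, `*`)
  best_code <- integer(length(contested))
  best_dist <- rep(Inf, length(contested))
  for (i in idx) {
    claims <- masks[[i]][contested]
    if (!any(claims)) next
    src <- arrayInd(which(undilated[[i]]), dm)
    if (nrow(src) == 0L) src <- arrayInd(which(masks[[i]]), dm)
    src_mm <- sweep(src, 2L, ref$voxel_dims, `*`)
    d <- chunked_min_dist(cc_mm[claims, , drop = FALSE], src_mm)
    sel <- which(claims)
    better <- d < best_dist[sel] - 1e-9
    best_dist[sel[better]] <- d[better]
    best_code[sel[better]] <- info$code[i]
    # exact tie: lower code wins; idx is iterated in code order so keep first
  }
  best_code
}

chunked_min_dist <- function(a, b, chunk = 2048L) {
  out <- numeric(nrow(a))
  for (s in seq(1L, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    blk <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rep(1, nrow(b))) +
      outer(rep(1, nrow(blk)), rowSums(b^2)) - 2 * blk %*% t(b)
    out[s:e] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' Transfer a MARS atlas into subject space
#'
#' Resamples each structure's binary mask into the target grid by pulling
#' values through the inverse of the supplied affine with trilinear
#' interpolation, thresholds the interpolated probabilities at 0.5, and
#' re-assembles the masks under the standard priority rules (without
#' re-dilating: the lobes were dilated before transfer).
#'
#' @param atlas A [mars_atlas()] in template space.
#' @param affine 4x4 matrix mapping template-space world coordinates to
#'   subject-space world coordinates (see [read_affine()] for the FSL-style
#'   matrix dialect).
#' @param target A [cmb_volume()] defining the subject grid geometry.
#' @param threshold Interpolated-mask threshold, default 0.5.
#' @return A [mars_atlas()] in subject space.
#' @export
transform_atlas <- function(atlas, affine, target, threshold = 0.5) {
  if (!inherits(atlas, "mars_atlas")) abort_validation("`atlas` must be a mars_atlas.")
  assert_volume(target, arg = "target")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12) {
    abort_geometry("`affine` must be an invertible 4x4 matrix.")
  }
  codes <- sort(setdiff(unique(as.vector(atlas$labels$data)), 0))
  masks <- list()
  for (cd in codes) {
    src <- cmb_volume((atlas$labels$data == cd) * 1L, atlas$labels$voxel_dims,
                      atlas$labels$affine, dtype = "intensity")
    res <- resample_volume(src, affine, target)
    nm <- atlas$lut$name[atlas$lut$code == cd]
    masks[[nm]] <- cmb_volume((res$data >= threshold) * 1L, target$voxel_dims,
                              target$affine, dtype = "binary")
  }
  assemble_atlas(masks, lut = atlas$lut, dilate = FALSE, space = "subject")
}

#' Resample a volume through an affine
#'
#' Pull-back resampling: each target voxel centre is mapped to subject world
#' coordinates via the target affine, back to source world coordinates via
#' the inverse of `affine` (source world -> target world), then into source
#' voxel coordinates where the value is interpolated trilinearly (zero
#' outside the source grid).
#'
#' @param vol Source [cmb_volume()].
#' @param affine 4x4 world-to-world matrix (source to target space).
#' @param target [cmb_volume()] supplying the output geometry.
#' @return An intensity [cmb_volume()] on the target grid.
#' @export
resample_volume <- function(vol, affine, target) {
  assert_volume(vol); assert_volume(target, arg = "target")
  dm_t <- dim(target$data)
  idx0 <- arrayInd(seq_len(prod(dm_t)), dm_t) - 1      # 0-based target voxels
  map <- solve(vol$affine) %*% solve(affine) %*% target$affine
  src0 <- map %*% rbind(t(idx0), 1)
  p <- t(src0[1:3, , drop = FALSE]) + 1                # 1-based source coords
  vals <- sample_trilinear(vol$data, p)
  out <- array(vals, dm_t)
  cmb_volume(out, target$voxel_dims, target$affine, dtype = "intensity")
}

sample_trilinear <- function(arr, p) {
  dm <- dim(arr)
  f <- floor(p); w <- p - f
  out <- numeric(nrow(p))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ci <- f[, 1] + dx; cj <- f[, 2] + dy; ck <- f[, 3] + dz
    wt <- (if (dx == 1) w[, 1] else 1 - w[, 1]) *
          (if (dy == 1) w[, 2] else 1 - w[, 2]) *
          (if (dz == 1) w[, 3] else 1 - w[, 3])
    ok <- ci >= 1 & ci <= dm[1] & cj >= 1 & cj <= dm[2] & ck >= 1 & ck <= dm[3] & wt > 0
    if (!any(ok)) next
    lin <- (ck[ok] - 1) * dm[1] * dm[2] + (cj[ok] - 1) * dm[1] + ci[ok]
    out[ok] <- out[ok] + wt[ok] * arr[lin]
  }
  out
}

#' Read an affine transform matrix
#'
#' Reads a whitespace-delimited 4x4 matrix. `convention = "world"` expects a
#' matrix acting on world (mm) coordinates, mapping template space to subject
#' space. `convention = "fsl"` converts the FLIRT dialect, which acts on
#' scaled-voxel coordinates (voxel index times voxel size, with the x axis
#' mirrored for grids whose sform has positive determinant); the source and
#' target volumes are then required to recover the world-to-world map.
#'
#' @param path Text file with 4 rows of 4 numbers.
#' @param convention `"world"` or `"fsl"`.
#' @param source,target [cmb_volume()]s defining the grids the FSL matrix was
#'   estimated between (ignored for `"world"`).
#' @return A 4x4 matrix mapping template world to subject world coordinates.
#' @export
read_affine <- function(path, convention = c("world", "fsl"),
                        source = NULL, target = NULL) {
  convention <- match.arg(convention)
  vals <- scan(path, quiet = TRUE)
  if (length(vals) != 16L) {
    abort_format(sprintf("'%s' does not hold a 4x4 matrix (found %d values).",
                         path, length(vals)))
  }
  m <- matrix(vals, 4, 4, byrow = TRUE)
  if (abs(det(m)) < 1e-12) abort_geometry("affine matrix is singular.")
  if (convention == "world") return(m)
  if (is.null(source) || is.null(target)) {
    abort_validation("FSL convention requires `source` and `target` volumes.")
  }
  fsl_of <- function(vol) {
    S <- diag(c(vol$voxel_dims, 1))
    if (det(vol$affine[1:3, 1:3]) > 0) {
      flip <- diag(4)
      flip[1, 1] <- -1
      flip[1, 4] <- dim(vol$data)[1] - 1
      S <- S %*% flip
    }
    S
  }
  # world_target <- A_tgt inv(F_tgt) M F_src inv(A_src) world_source
  target$affine %*% solve(fsl_of(target)) %*% m %*%
    fsl_of(source) %*% solve(source$affine)
}

#' Write a MARS atlas
#'
#' Writes the label volume as NIfTI-1 plus a sidecar LUT CSV.
#'
#' @param atlas A [mars_atlas()].
#' @param path Label volume output path (`.nii`/`.nii.gz`).
#' @param lut_path Sidecar LUT path; defaults to `<path>.lut.csv`.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path, lut_path = NULL) {
  if (!inherits(atlas, "mars_atlas")) abort_validation("`atlas` must be a mars_atlas.")
  write_volume(atlas$labels, path)
  lut_path <- lut_path %||% paste0(sub("\\.nii(\\.gz)?$", "", path), ".lut.csv")
  write_lut(atlas$lut, lut_path)
  invisible(path)
}
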