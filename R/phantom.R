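#' Phantom specification
#'
#' Describes a fully synthetic test scene: the grid, a set of geometric
#' structure primitives standing in for MARS structures, and a set of
#' spherical lesions with known centres, diameters and intended structures.
#' Everything downstream (probabilistic atlases, label maps, CMB masks,
#' degraded predictions) is generated from this spec, so tests need no
#' external data.
#'
#' @param grid_shape Integer triple, grid size in voxels.
#' @param voxel_dims mm per voxel. The default 64^3 grid at 0.9 mm isotropic
#'   is large enough to hold all thirteen structures as disjoint primitives
#'   while keeping per-test runtimes well under a second.
#' @param structures Tibble with columns `name`, `shape` (`"ball"` or
#'   `"box"`), `cx`, `cy`, `cz` (centre, voxel coordinates) and `rx`, `ry`,
#'   `rz` (radius / half-extents in voxels; balls use `rx`).
#' @param lesions Tibble with columns `cx`, `cy`, `cz` (centre, voxel
#'   coordinates, may be half-integer), `diameter_mm` in `[1, 12]` and
#'   `structure` (intended structure name, or NA for free-floating lesions).
#' @param perturbation List describing how a degraded "predicted" mask is
#'   derived: `kind` in `"none"`, `"jitter"`, `"drop"`, `"split_merge"`, plus
#'   `sigma_mm` (jitter) or `p` (drop / split_merge probability).
#' @param seed Integer seed; all phantom randomness flows through it.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_dims = c(0.9, 0.9, 0.9),
                         structures = default_phantom_structures(),
                         lesions = default_phantom_lesions(),
                         perturbation = list(kind = "none"),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L)) {
    abort_validation("`grid_shape` must be three integers >= 4.")
  }
  if (any(voxel_dims <= 0)) abort_validation("`voxel_dims` must be positive.")
  if (nrow(structures)) {
    need <- c("name", "shape", "cx", "cy", "cz", "rx", "ry", "rz")
    if (!all(need %in% names(structures))) {
      abort_validation(paste0("`structures` needs columns: ", paste(need, collapse = ", ")))
    }
    if (any(!structures$shape %in% c("ball", "box"))) {
      abort_validation("structure shapes must be 'ball' or 'box'.")
    }
    if (any(structures$rx <= 0 | structures$ry <= 0 | structures$rz <= 0)) {
      abort_validation("structure primitives must be non-degenerate (extents > 0).")
    }
  }
  if (nrow(lesions)) {
    need <- c("cx", "cy", "cz", "diameter_mm", "structure")
    if (!all(need %in% names(lesions))) {
      abort_validation(paste0("`lesions` needs columns: ", paste(need, collapse = ", ")))
    }
    if (any(lesions$diameter_mm < 1 | lesions$diameter_mm > 12)) {
      abort_validation("lesion diameters must lie in [1, 12] mm.")
    }
    inside <- lesions$cx >= 1 & lesions$cx <= grid_shape[1] &
      lesions$cy >= 1 & lesions$cy <= grid_shape[2] &
      lesions$cz >= 1 & lesions$cz <= grid_shape[3]
    if (any(!inside)) abort_validation("lesion centres must lie inside the grid.")
    tgt <- lesions$structure[!is.na(lesions$structure)]
    missing <- setdiff(tgt, structures$name)
    if (length(missing)) {
      abort_validation(paste0("intended structures absent from the phantom: ",
                              paste(unique(missing), collapse = ", ")))
    }
  }
  kinds <- c("none", "jitter", "drop", "split_merge")
  if (!is.list(perturbation) || !perturbation$kind %in% kinds) {
    abort_validation(paste0("`perturbation$kind` must be one of: ",
                            paste(kinds, collapse = ", ")))
  }
  structure(list(grid_shape = grid_shape, voxel_dims = as.numeric(voxel_dims),
                 structures = structures, lesions = lesions,
                 perturbation = perturbation, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_phantom_structures <- function() {
  tibble::tribble(
    ~name,               ~shape, ~cx, ~cy, ~cz, ~rx, ~ry, ~rz,
    "brainstem",         "ball",  32,  20,  10,   5,   5,   5,
    "cerebellum",        "ball",  32,  44,  10,   6,   6,   6,
    "deep_white_matter", "box",   32,  32,  32,  18,  18,   6,
    "basal_ganglia",     "ball",  22,  22,  32,   4,   4,   4,
    "thalamus",          "ball",  42,  22,  32,   4,   4,   4,
    "internal_capsule",  "box",   22,  42,  32,   4,   4,   4,
    "external_capsule",  "box",   42,  42,  32,   4,   4,   4,
    "corpus_callosum",   "box",   32,  32,  32,   4,   4,   4,
    "frontal",           "ball",  14,  16,  52,   6,   6,   6,
    "parietal",          "ball",  14,  48,  52,   6,   6,   6,
    "temporal",          "ball",  32,  16,  52,   6,   6,   6,
    "occipital",         "ball",  32,  48,  52,   6,   6,   6,
    "insula",            "ball",  50,  32,  52,   5,   5,   5
  )
}

#' @rdname phantom_spec
#' @export
default_phantom_lesions <- function() {
  s <- default_phantom_structures()
  ctr <- s[match(c("brainstem", "cerebellum", "basal_ganglia", "thalamus",
                   "internal_capsule", "external_capsule", "corpus_callosum",
                   "frontal", "parietal", "temporal", "occipital", "insula"),
                 s$name), ]
  les <- tibble(cx = ctr$cx, cy = ctr$cy, cz = ctr$cz,
                diameter_mm = c(2.7, 4.5, 2.7, 2.7, 2.7, 2.7, 2.7,
                                6.3, 4.5, 4.5, 2.7, 2.7),
                structure = ctr$name)
  # one deep-white-matter lesion away from the embedded deep structures
  bind_rows(les, tibble(cx = 22, cy = 32, cz = 32, diameter_mm = 4.5,
                        structure = "deep_white_matter"))
}

# distance (voxel units) from each grid voxel centre to the primitive surface,
# negative/zero inside
primitive_outside_distance <- function(grid_shape, row) {
  dm <- grid_shape
  idx <- arrayInd(seq_len(prod(dm)), dm)
  d <- sweep(idx, 2L, c(row$cx, row$cy, row$cz))
  out <- if (row$shape == "ball") {
    sqrt(rowSums(d^2)) - row$rx
  } else {
    ex <- pmax(abs(d[, 1]) - row$rx, 0)
    ey <- pmax(abs(d[, 2]) - row$ry, 0)
    ez <- pmax(abs(d[, 3]) - row$rz, 0)
    outside <- sqrt(ex^2 + ey^2 + ez^2)
    inside <- pmax(abs(d[, 1]) - row$rx, abs(d[, 2]) - row$ry, abs(d[, 3]) - row$rz)
    ifelse(outside > 0, outside, inside)
  }
  array(out, dm)
}

#' Synthetic atlas phantom
#'
#' Renders each structure primitive as a percent-scale probability map (100
#' inside, falling off linearly to 0 over two voxels outside the surface, so
#' binarising at threshold 50 recovers the primitive to within one voxel) and
#' assembles the ground-truth MARS label map from the exact binary
#' primitives.
#'
#' @param spec A [phantom_spec()].
#' @param lut Structure table used for assembly.
#' @param dilate Dilate lobar masks during ground-truth assembly.
#' @return A list: `prob_maps` (named list of probability [cmb_volume()]s),
#'   `atlas` (ground-truth [mars_atlas()]), `masks` (exact binary
#'   primitives).
#' @export
make_atlas_phantom <- function(spec, lut = mars_lut(), dilate = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  aff <- diag(c(spec$voxel_dims, 1))
  prob_maps <- list(); masks <- list()
  for (r in seq_len(nrow(spec$structures))) {
    row <- spec$structures[r, ]
    dist <- primitive_outside_distance(dm, row)
    p <- pmin(pmax(100 * (1 - dist / 2), 0), 100)
    p[dist <= 0] <- 100
    prob_maps[[row$name]] <- cmb_volume(array(p, dm), spec$voxel_dims, aff,
                                        dtype = "probability", scale = "percent")
    masks[[row$name]] <- cmb_volume((dist <= 0) * 1L, spec$voxel_dims, aff,
                                    dtype = "binary")
  }
  atlas <- if (length(masks)) {
    assemble_atlas(masks, lut = lut, dilate = dilate)
  } else {
    mars_atlas(cmb_volume(array(0L, dm), spec$voxel_dims, aff, dtype = "label"),
               lut = lut)
  }
  list(prob_maps = prob_maps, atlas = atlas, masks = masks)
}

#' Synthetic CMB mask with ground truth
#'
#' Renders each lesion as a digitised ball: a voxel belongs to the lesion when
#' its centre lies within `diameter_mm / 2` of the lesion centre, distances
#' measured in mm. Centres may sit between voxels (half-integer coordinates),
#' which produces even axis extents — a 5.4 mm lesion on a 0.9 mm grid spans
#' 6 voxels along each axis through its centre.
#'
#' @param spec A [phantom_spec()].
#' @return A list: `mask` (binary [cmb_volume()]) and `truth` (tibble:
#'   `lesion_id`, centre, `diameter_mm`, `structure`). Overlapping lesions
#'   are a validation error.
#' @export
make_lesion_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  aff <- diag(c(spec$voxel_dims, 1))
  total <- array(0L, dm)
  for (r in seq_len(nrow(spec$lesions))) {
    les <- spec$lesions[r, ]
    total <- total + render_ball_mm(dm, spec$voxel_dims,
                                    c(les$cx, les$cy, les$cz), les$diameter_mm / 2)
  }
  if (any(total > 1L)) abort_validation("phantom lesions overlap; adjust the spec.")
  truth <- spec$lesions |>
    mutate(lesion_id = dplyr::row_number(), .before = 1)
  list(mask = cmb_volume(total, spec$voxel_dims, aff, dtype = "binary"),
       truth = truth)
}

render_ball_mm <- function(dm, voxel_dims, centre_voxel, radius_mm) {
  rv <- ceiling(radius_mm / voxel_dims) + 1
  rng <- lapply(1:3, function(a) {
    max(1, floor(centre_voxel[a] - rv[a])):min(dm[a], ceiling(centre_voxel[a] + rv[a]))
  })
  idx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  d_mm <- sweep(sweep(idx, 2L, centre_voxel), 2L, voxel_dims, `*`)
  hit <- sqrt(rowSums(d_mm^2)) <= radius_mm + 1e-9
  out <- array(0L, dm)
  if (any(hit)) out[lin_index(idx[hit, , drop = FALSE], dm)] <- 1L
  out
}

#' Degrade a phantom mask into a synthetic "prediction"
#'
#' Emulates segmentation failure modes on a per-lesion basis: `jitter` shifts
#' each lesion by a Gaussian mm offset (rounded to voxels), `drop` deletes
#' each lesion with probability `p` (creating false negatives),
#' `split_merge` erodes or dilates each lesion with probability `p`
#' (changing its size). Deterministic for a fixed seed.
#'
#' @param mask Binary [cmb_volume()] (the phantom ground-truth mask).
#' @param perturbation As in [phantom_spec()]; overrides the spec's field.
#' @param seed Integer seed.
#' @param connectivity Connectivity used to split the mask into lesions.
#' @return The degraded binary [cmb_volume()].
#' @export
perturb_mask <- function(mask, perturbation = list(kind = "none"), seed = 1L,
                         connectivity = 26) {
  assert_volume(mask, "binary", "mask")
  kind <- perturbation$kind %||% "none"
  if (!kind %in% c("none", "jitter", "drop", "split_merge")) {
    abort_validation("unknown perturbation kind.")
  }
  if (kind == "none") return(mask)
  p <- perturbation$p %||% 0.3
  sigma <- perturbation$sigma_mm %||% 1
  if (!is.numeric(p) || p < 0 || p > 1) abort_validation("`p` must be in [0, 1].")
  if (!is.numeric(sigma) || sigma < 0) abort_validation("`sigma_mm` must be >= 0.")

  lesions <- label_components(mask, connectivity)
  dm <- dim(mask$data)
  out <- array(0L, dm)
  withr::with_seed(seed, {
    for (r in seq_len(nrow(lesions))) {
      vx <- lesions$voxels[[r]]
      keep <- TRUE
      if (kind == "drop") keep <- runif(1) >= p
      if (!keep) next
      if (kind == "jitter") {
        shift <- round_half_away(rnorm(3, 0, sigma) / mask$voxel_dims)
        vx <- sweep(vx, 2L, -shift)
        vx <- vx[in_bounds(vx, dm), , drop = FALSE]
      }
      if (kind == "split_merge" && runif(1) < p) {
        vx <- if (runif(1) < 0.5) erode_voxels(vx, dm) else dilate_voxels(vx, dm)
      }
      if (nrow(vx)) out[lin_index(vx, dm)] <- 1L
    }
  })
  cmb_volume(out, mask$voxel_dims, mask$affine, dtype = "binary")
}

erode_voxels <- function(vx, dm) {
  lin <- lin_index(vx, dm)
  off <- connectivity_offsets(6L)
  keep <- rep(TRUE, nrow(vx))
  for (r in seq_len(nrow(off))) {
    nb <- sweep(vx, 2L, -off[r, ])
    ok <- in_bounds(nb, dm)
    keep <- keep & ok & (lin_index(nb, dm) %in% lin)
  }
  if (!any(keep)) vx[which.min(rowSums(sweep(vx, 2L, colMeans(vx))^2)), , drop = FALSE]
  else vx[keep, , drop = FALSE]
}

dilate_voxels <- function(vx, dm) {
  off <- rbind(c(0, 0, 0), connectivity_offsets(26L))
  all <- do.call(rbind, lapply(seq_len(nrow(off)), function(r) sweep(vx, 2L, -off[r, ])))
  all <- unique(all[in_bounds(all, dm), , drop = FALSE])
  all
}

#' Calibration lesion with an exactly 6-voxel moment axis
#'
#' A 30-voxel blob built so that its second-order central moments are known
#' in closed form: slabs along x with voxel counts (1, 8, 6, 6, 8, 1) give a
#' discrete variance of exactly 103/60 voxel^2; adding the per-voxel cubic
#' self-extent of 1/12 yields 1.8 voxel^2 = (6/2)^2 / 5, the second moment of
#' a solid ellipsoid with a 6-voxel major axis. Transverse slab patterns are
#' sign-symmetric, so cross-covariances vanish and the transverse variances
#' (0.75 and about 0.88 voxel^2) stay well below the axial one. The
#' moment-matched ellipsoid of this lesion therefore has a major axis of
#' exactly 6 voxels: on a 0.9 mm isotropic grid its diameter is exactly
#' 6 x 0.9 = 5.4 mm.
#'
#' @param voxel_dims Isotropic mm per voxel (length 1 or 3).
#' @param grid_shape Grid to embed the lesion in.
#' @param origin 1-based index of the blob's first slab.
#' @return A binary [cmb_volume()] containing the single lesion.
#' @export
#' @examples
#' v <- calibration_lesion()
#' label_components(v)$diameter_mm   # exactly 5.4
calibration_lesion <- function(voxel_dims = c(0.9, 0.9, 0.9),
                               grid_shape = c(12, 12, 12),
                               origin = c(4, 6, 6)) {
  if (length(voxel_dims) == 1L) voxel_dims <- rep(voxel_dims, 3L)
  vx <- calibration_lesion_voxels(origin)
  dm <- as.integer(grid_shape)
  if (any(vx < 1) || any(sweep(vx, 2L, dm) > 0)) {
    abort_validation("calibration lesion does not fit the grid at this origin.")
  }
  m <- array(0L, dm)
  m[lin_index(vx, dm)] <- 1L
  cmb_volume(m, voxel_dims, dtype = "binary")
}

calibration_lesion_voxels <- function(origin = c(1, 1, 1)) {
  ring8 <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  ring6 <- rbind(c(0, 1), c(0, -1), c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  slabs <- list(rbind(c(0, 0)), ring8, ring6, ring6, ring8, rbind(c(0, 0)))
  vx <- do.call(rbind, lapply(seq_along(slabs), function(x) {
    cbind(x - 1, slabs[[x]])
  }))
  sweep(vx, 2L, origin, `+`)
}
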