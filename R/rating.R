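#' Assign a lesion centroid to a MARS structure
#'
#' The real-valued centroid is snapped to the nearest voxel index (halves
#' rounded away from zero) and the atlas label at that voxel is returned.
#' Label 0, or a centroid rounding outside the grid, yields `"unclassified"`.
#'
#' @param centroid_voxel Length-3 real voxel coordinates (1-based).
#' @param atlas A [mars_atlas()] on the same grid as the lesion mask.
#' @return A structure name, or `"unclassified"`.
#' @export
assign_structure <- function(centroid_voxel, atlas) {
  if (!inherits(atlas, "mars_atlas")) abort_validation("`atlas` must be a mars_atlas.")
  idx <- round_half_away(as.numeric(centroid_voxel))
  dm <- dim(atlas$labels$data)
  if (length(idx) != 3L) abort_validation("`centroid_voxel` must have length 3.")
  if (any(idx < 1) || any(idx > dm)) return("unclassified")
  code <- atlas$labels$data[idx[1], idx[2], idx[3]]
  if (code == 0) return("unclassified")
  atlas$lut$name[match(code, atlas$lut$code)]
}

# majority vote over all lesion voxels; ties resolved by the centroid rule,
# then lower structure code
assign_structure_majority <- function(voxels, centroid_voxel, atlas) {
  dm <- dim(atlas$labels$data)
  codes <- atlas$labels$data[lin_index(rbind_matrix(voxels), dm)]
  tab <- sort(table(codes), decreasing = TRUE)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) > 1L) {
    cen <- assign_structure(centroid_voxel, atlas)
    cen_code <- atlas$lut$code[match(cen, atlas$lut$name)]
    if (!is.na(cen_code) && cen_code %in% top) return(cen)
    top <- min(top)
  }
  if (top == 0) return("unclassified")
  atlas$lut$name[match(top, atlas$lut$code)]
}

#' Rate one subject: structure- and region-wise CMB counts
#'
#' Runs the full characterisation chain on a binary CMB mask: connected
#' components, per-lesion centroid and moment-matched diameter, structure
#' assignment against the subject-space atlas, then aggregation into the
#' structure-wise and region-wise counts of a MARS form. Lesions whose
#' centroid falls on background are reported as unclassified rather than
#' silently dropped or reassigned.
#'
#' @param mask Binary [cmb_volume()], same grid as the atlas.
#' @param atlas A [mars_atlas()] in subject space.
#' @param subject_id Identifier recorded in the rating.
#' @param connectivity Component connectivity, see [label_components()].
#' @param method `"centroid"` (count the centroid's voxel label, default) or
#'   `"majority"` (majority vote over all lesion voxels, for lesions
#'   straddling a structure boundary).
#' @return A `mars_rating` object: `subject_id`, `per_lesion` tibble
#'   (component id, structure, region, diameter, centroid), `structure_counts`,
#'   `region_counts`, `unclassified_count` and `total`. [tidy()] returns the
#'   structure counts, [glance()] a one-row region summary.
#' @export
rate_subject <- function(mask, atlas, subject_id = "subject",
                         connectivity = 26,
                         method = c("centroid", "majority")) {
  method <- match.arg(method)
  assert_volume(mask, "binary", "mask")
  if (!inherits(atlas, "mars_atlas")) abort_validation("`atlas` must be a mars_atlas.")
  assert_same_geometry(mask, atlas$labels, "mask and atlas")

  lesions <- label_components(mask, connectivity = connectivity)
  per_lesion <- lesion_assignments(lesions, atlas, method)
  build_rating(subject_id, per_lesion, atlas$lut)
}

lesion_assignments <- function(lesions, atlas, method = "centroid") {
  if (nrow(lesions) == 0L) {
    return(tibble(component_id = integer(), structure = character(),
                  region = character(), diameter_mm = double(),
                  centroid_x_mm = double(), centroid_y_mm = double(),
                  centroid_z_mm = double()))
  }
  structure_of <- function(vx, ci, cj, ck) {
    cen <- c(ci, cj, ck)
    if (method == "majority") assign_structure_majority(vx, cen, atlas)
    else assign_structure(cen, atlas)
  }
  lesions |>
    as_tibble() |>
    mutate(structure = purrr::pmap_chr(
      list(.data$voxels, .data$centroid_i, .data$centroid_j, .data$centroid_k),
      structure_of)) |>
    mutate(region = region_of(.data$structure, atlas$lut)) |>
    select("component_id", "structure", "region", "diameter_mm",
           "centroid_x_mm", "centroid_y_mm", "centroid_z_mm")
}

region_of <- function(structure, lut = mars_lut()) {
  out <- lut$region[match(structure, lut$name)]
  out[structure == "unclassified"] <- "unclassified"
  out
}

build_rating <- function(subject_id, per_lesion, lut) {
  structure_counts <- lut |>
    select("name", "region") |>
    rename(structure = "name") |>
    left_join(
      per_lesion |> count(.data$structure, name = "count"),
      by = "structure") |>
    mutate(count = dplyr::coalesce(.data$count, 0L))
  region_counts <- structure_counts |>
    group_by(region = factor(.data$region, mars_region_names())) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(region = as.character(.data$region))
  unclassified <- sum(per_lesion$structure == "unclassified")
  structure(list(
    subject_id = subject_id,
    per_lesion = per_lesion,
    structure_counts = structure_counts,
    region_counts = region_counts,
    unclassified_count = unclassified,
    total = nrow(per_lesion)
  ), class = "mars_rating")
}

#' @export
print.mars_rating <- function(x, ...) {
  cat(sprintf("<mars_rating> subject '%s': %d CMB(s)\n", x$subject_id, x$total))
  for (r in seq_len(nrow(x$region_counts))) {
    cat(sprintf("  %-15s %d\n", x$region_counts$region[r], x$region_counts$count[r]))
  }
  if (x$unclassified_count > 0) {
    cat(sprintf("  %-15s %d\n", "unclassified", x$unclassified_count))
  }
  invisible(x)
}

#' @rdname rate_subject
#' @param x A `mars_rating`.
#' @param ... Unused.
#' @export
tidy.mars_rating <- function(x, ...) {
  x$structure_counts |> mutate(subject_id = x$subject_id, .before = 1)
}

#' @rdname rate_subject
#' @export
glance.mars_rating <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$region_counts, names_from = "region",
                             values_from = "count")
  bind_cols(tibble(subject_id = x$subject_id), wide,
            tibble(unclassified = x$unclassified_count, total = x$total))
}

#' Rate a cohort of subjects
#'
#' @param masks Named list of binary [cmb_volume()]s (names are subject ids).
#' @param atlas A [mars_atlas()] shared by all masks.
#' @param ... Passed to [rate_subject()].
#' @return A long tibble of structure counts, one row per subject x structure.
#' @export
rate_cohort <- function(masks, atlas, ...) {
  if (is.null(names(masks))) names(masks) <- paste0("subject", seq_along(masks))
  purrr::imap(masks, function(m, id) tidy(rate_subject(m, atlas, id, ...))) |>
    bind_rows()
}

#' Write a MARS rating
#'
#' JSON mirrors the MARS form (structure, region, count) plus the per-lesion
#' table; the CSV holds the structure rows.
#'
#' @param rating A `mars_rating`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return The rating, invisibly.
#' @export
write_rating <- function(rating, json_path = NULL, csv_path = NULL) {
  if (!inherits(rating, "mars_rating")) abort_validation("not a mars_rating.")
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      subject_id = rating$subject_id,
      total = rating$total,
      unclassified = rating$unclassified_count,
      region_counts = rating$region_counts,
      structure_counts = rating$structure_counts,
      per_lesion = rating$per_lesion
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) readr::write_csv(tidy(rating), csv_path)
  invisible(rating)
}

#' Voxelwise CMB prevalence across subjects
#'
#' Counts, at each voxel, the number of subjects whose mask has foreground
#' there. All masks must live on a common grid (e.g. the template space).
#'
#' @param masks List of binary [cmb_volume()]s in a common space.
#' @return A label [cmb_volume()] of per-voxel subject counts.
#' @export
prevalence_map <- function(masks) {
  if (length(masks) == 0L) abort_validation("no masks supplied.")
  purrr::walk(masks, assert_volume, dtype = "binary")
  ref <- masks[[1]]
  purrr::walk(masks, assert_same_geometry, b = ref, what = "prevalence masks")
  total <- Reduce(`+`, lapply(masks, function(m) m$data))
  storage.mode(total) <- "integer"
  cmb_volume(total, ref$voxel_dims, ref$affine, dtype = "label")
}
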