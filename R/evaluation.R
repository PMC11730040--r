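#' Match predicted lesions to reference lesions
#'
#' Greedy one-to-one matching by descending voxel overlap (at least one shared
#' voxel required); ties broken by smaller centroid distance, then lower
#' component ids. Unmatched predicted lesions are false positives, unmatched
#' reference lesions false negatives. A centroid-distance criterion (pairs
#' within `max_centroid_mm`, nearest first) is available for masks whose
#' lesions may not overlap, e.g. after large spatial jitter.
#'
#' @param pred,ref `cmb_lesions` tables (see [label_components()]) from masks
#'   on the same grid.
#' @param criterion `"overlap"` (default) or `"centroid"`.
#' @param max_centroid_mm Pairing radius for the centroid criterion.
#' @return A tibble with one row per match or unmatched lesion: `pred_id`,
#'   `ref_id` (NA when absent), `overlap_voxels`, `status` in
#'   `"true_positive"`, `"false_positive"`, `"false_negative"`.
#' @export
match_lesions <- function(pred, ref, criterion = c("overlap", "centroid"),
                          max_centroid_mm = 5) {
  criterion <- match.arg(criterion)
  check_lesion_table(pred, "pred"); check_lesion_table(ref, "ref")
  if (!identical(attr(pred, "grid_dim"), attr(ref, "grid_dim"))) {
    abort_geometry("pred and ref lesion tables come from different grids.")
  }
  dm <- attr(pred, "grid_dim") %||% c(1L, 1L, 1L)

  pairs <- candidate_pairs(pred, ref, dm, criterion, max_centroid_mm)
  taken_p <- logical(nrow(pred)); taken_r <- logical(nrow(ref))
  rows <- list()
  if (nrow(pairs)) {
    ord <- order(-pairs$score, pairs$centroid_dist, pairs$pred_id, pairs$ref_id)
    for (r in ord) {
      p <- pairs$pred_id[r]; q <- pairs$ref_id[r]
      if (taken_p[p] || taken_r[q]) next
      taken_p[p] <- TRUE; taken_r[q] <- TRUE
      rows[[length(rows) + 1L]] <- tibble(
        pred_id = p, ref_id = q, overlap_voxels = pairs$overlap[r],
        status = "true_positive")
    }
  }
  for (p in pred$component_id[!taken_p]) {
    rows[[length(rows) + 1L]] <- tibble(pred_id = p, ref_id = NA_integer_,
                                        overlap_voxels = 0L, status = "false_positive")
  }
  for (q in ref$component_id[!taken_r]) {
    rows[[length(rows) + 1L]] <- tibble(pred_id = NA_integer_, ref_id = q,
                                        overlap_voxels = 0L, status = "false_negative")
  }
  if (!length(rows)) {
    return(tibble(pred_id = integer(), ref_id = integer(),
                  overlap_voxels = integer(), status = character()))
  }
  bind_rows(rows) |> arrange(.data$status, .data$pred_id, .data$ref_id)
}

check_lesion_table <- function(x, arg) {
  if (!inherits(x, "cmb_lesions")) {
    abort_validation(sprintf("`%s` must be a cmb_lesions table from label_components().", arg))
  }
}

candidate_pairs <- function(pred, ref, dm, criterion, max_centroid_mm) {
  empty <- tibble(pred_id = integer(), ref_id = integer(), overlap = integer(),
                  centroid_dist = double(), score = double())
  if (nrow(pred) == 0L || nrow(ref) == 0L) return(empty)
  pred_lin <- lapply(pred$voxels, lin_index, dm = dm)
  ref_lin <- lapply(ref$voxels, lin_index, dm = dm)
  pc <- as.matrix(pred[, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")])
  rc <- as.matrix(ref[, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")])
  out <- list()
  for (p in seq_len(nrow(pred))) for (q in seq_len(nrow(ref))) {
    ov <- length(intersect(pred_lin[[p]], ref_lin[[q]]))
    cd <- sqrt(sum((pc[p, ] - rc[q, ])^2))
    keep <- if (criterion == "overlap") ov >= 1L else cd <= max_centroid_mm
    if (keep) {
      out[[length(out) + 1L]] <- tibble(
        pred_id = pred$component_id[p], ref_id = ref$component_id[q],
        overlap = ov, centroid_dist = cd,
        score = if (criterion == "overlap") ov else -cd)
    }
  }
  if (!length(out)) empty else bind_rows(out)
}

#' Absolute size errors over matched lesions
#'
#' @param matches Match table from [match_lesions()].
#' @param pred_sizes,ref_sizes Named numeric vectors (names = component ids)
#'   or lesion tables, giving diameters in mm.
#' @return A list with `abs_errors` (tibble: pred_id, ref_id, pred_mm, ref_mm,
#'   abs_error_mm) and `mae` (mean absolute error in mm; `NA` when there are
#'   no matched pairs).
#' @export
size_error <- function(matches, pred_sizes, ref_sizes) {
  pred_sizes <- as_size_lookup(pred_sizes)
  ref_sizes <- as_size_lookup(ref_sizes)
  tp <- matches[matches$status == "true_positive", , drop = FALSE]
  pk <- as.character(tp$pred_id); rk <- as.character(tp$ref_id)
  if (any(!pk %in% names(pred_sizes)) || any(!rk %in% names(ref_sizes))) {
    abort_validation("missing size for a matched component id.")
  }
  errs <- tibble(
    pred_id = tp$pred_id, ref_id = tp$ref_id,
    pred_mm = unname(pred_sizes[pk]), ref_mm = unname(ref_sizes[rk])) |>
    mutate(abs_error_mm = abs(.data$pred_mm - .data$ref_mm))
  list(abs_errors = errs,
       mae = if (nrow(errs)) mean(errs$abs_error_mm) else NA_real_)
}

as_size_lookup <- function(x) {
  if (inherits(x, "cmb_lesions") || (is.data.frame(x) && "diameter_mm" %in% names(x))) {
    return(setNames(x$diameter_mm, x$component_id))
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  abort_validation("sizes must be a named numeric vector or a lesion table.")
}

#' F1 measure
#'
#' Harmonic mean of sensitivity and precision; defined as 0 when both are 0.
#'
#' @param sensitivity,precision Values in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @export
#' @examples
#' f1_score(0.64, 1.00)
f1_score <- function(sensitivity, precision) {
  ifelse(sensitivity + precision > 0,
         2 * sensitivity * precision / (sensitivity + precision), 0)
}

valid_eval_labels <- function() c(mars_region_names(), "unclassified")

check_assignments <- function(assignments) {
  need <- c("status", "pred_region", "ref_region")
  if (!all(need %in% names(assignments))) {
    abort_validation(paste0("assignments need columns: ", paste(need, collapse = ", ")))
  }
  labs <- c(assignments$pred_region, assignments$ref_region)
  bad <- setdiff(labs[!is.na(labs)], valid_eval_labels())
  if (length(bad)) {
    abort_validation(paste0("region labels outside the MARS set: ",
                            paste(unique(bad), collapse = ", ")))
  }
  invisible(assignments)
}

#' Region-wise sensitivity, precision and F1
#'
#' Lesion-level region metrics. For region R: a matched lesion is a TP when
#' prediction and reference both place it in R; a reference lesion in R that
#' is unmatched, or matched but placed elsewhere by the prediction, is an FN;
#' a predicted lesion in R that is unmatched (no manual region exists for it)
#' or matched to a reference outside R is an FP. Overall accuracy is the
#' fraction of matched lesions whose region labels agree.
#'
#' A count-level mode is available for references that provide only MARS
#' subscores (no manual masks): there `TP_R = min(pred_count_R, ref_count_R)`.
#'
#' @param assignments Tibble with columns `status` (`true_positive` /
#'   `false_positive` / `false_negative`), `pred_region`, `ref_region`
#'   (NA where the side is absent).
#' @param mode `"lesion"` (default) or `"count"`.
#' @return A list: `per_region` tibble (region, tp, fn, fp, sensitivity,
#'   precision, f1) and `overall_accuracy` (lesion mode only, NA otherwise).
#' @export
region_metrics <- function(assignments, mode = c("lesion", "count")) {
  mode <- match.arg(mode)
  check_assignments(assignments)
  regions <- mars_region_names()
  tp_rows <- assignments$status == "true_positive"
  per <- purrr::map(regions, function(R) {
    if (mode == "lesion") {
      tp <- sum(tp_rows & assignments$pred_region == R & assignments$ref_region == R,
                na.rm = TRUE)
      fn <- sum((tp_rows & assignments$ref_region %in% R &
                   assignments$pred_region != R) |
                  (assignments$status == "false_negative" &
                     assignments$ref_region %in% R), na.rm = TRUE)
      fp <- sum((tp_rows & assignments$pred_region %in% R &
                   assignments$ref_region != R) |
                  (assignments$status == "false_positive" &
                     assignments$pred_region %in% R), na.rm = TRUE)
    } else {
      np <- sum(assignments$pred_region %in% R, na.rm = TRUE)
      nr <- sum(assignments$ref_region %in% R, na.rm = TRUE)
      tp <- min(np, nr); fn <- nr - tp; fp <- np - tp
    }
    s <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    tibble(region = R, tp = tp, fn = fn, fp = fp,
           sensitivity = s, precision = p,
           f1 = f1_score(dplyr::coalesce(s, 0), dplyr::coalesce(p, 0)))
  }) |> bind_rows()
  acc <- if (mode == "lesion" && any(tp_rows)) {
    mean(assignments$pred_region[tp_rows] == assignments$ref_region[tp_rows])
  } else NA_real_
  list(per_region = per, overall_accuracy = acc)
}

#' Confusion matrices between manual and automated assignments
#'
#' Cell (i, j) counts matched lesions manually labelled i and automatically
#' labelled j; computed over true positives only (false detections have no
#' manual label). Row sums equal the manual per-class counts.
#'
#' @param assignments Tibble with `status`, and `pred_<level>` / `ref_<level>`
#'   columns for the chosen level.
#' @param level `"region"` or `"structure"`.
#' @param lut Structure table, used to order structure classes.
#' @return A square integer matrix (manual rows, automated columns) over the
#'   class labels plus `"unclassified"`.
#' @export
confusion_matrices <- function(assignments, level = c("region", "structure"),
                               lut = mars_lut()) {
  level <- match.arg(level)
  pc <- paste0("pred_", level); rc <- paste0("ref_", level)
  if (!all(c(pc, rc, "status") %in% names(assignments))) {
    abort_validation(sprintf("assignments need columns status, %s, %s.", pc, rc))
  }
  classes <- if (level == "region") valid_eval_labels() else c(lut$name, "unclassified")
  tp <- assignments[assignments$status == "true_positive", , drop = FALSE]
  bad <- setdiff(c(tp[[pc]], tp[[rc]]), classes)
  if (length(bad)) {
    abort_validation(paste0("labels outside the ", level, " set: ",
                            paste(unique(bad), collapse = ", ")))
  }
  table(manual = factor(tp[[rc]], classes),
        automated = factor(tp[[pc]], classes)) |>
    unclass()
}

#' False-negative histogram by structure
#'
#' Counts, per manual structure, the reference lesions the prediction missed.
#'
#' @param assignments Tibble with `status` and `ref_structure`.
#' @param lut Structure table (fixes the structure ordering; zero counts kept).
#' @return A tibble `structure`, `n_false_negative`.
#' @export
fn_histogram <- function(assignments, lut = mars_lut()) {
  if (!all(c("status", "ref_structure") %in% names(assignments))) {
    abort_validation("assignments need columns status and ref_structure.")
  }
  fns <- assignments |>
    filter(.data$status == "false_negative") |>
    count(.data$ref_structure, name = "n_false_negative")
  tibble(structure = c(lut$name, "unclassified")) |>
    left_join(fns, by = c(structure = "ref_structure")) |>
    mutate(n_false_negative = dplyr::coalesce(.data$n_false_negative, 0L))
}

#' Evaluate an automated rating against a manual reference
#'
#' End-to-end comparison of a predicted CMB mask with a manually segmented
#' reference on the same grid: lesion extraction on both sides, greedy
#' matching, per-lesion structure/region assignment through the atlas, size
#' absolute errors over matched pairs, region-wise sensitivity / precision /
#' F1, overall accuracy, structure- and region-level confusion matrices and
#' the false-negative histogram.
#'
#' @param pred_mask,ref_mask Binary [cmb_volume()]s on the atlas grid.
#' @param atlas A subject-space [mars_atlas()].
#' @param connectivity Component connectivity.
#' @param criterion,max_centroid_mm Matching options, see [match_lesions()].
#' @return A `region_evaluation` object: `matches`, `assignments`,
#'   `per_region`, `overall_accuracy`, `size_abs_errors`, `size_mae`,
#'   `confusion_region`, `confusion_structure`, `fn_by_structure`.
#'   [tidy()] returns the per-region metrics, [glance()] a one-row summary.
#' @export
evaluate_subject <- function(pred_mask, ref_mask, atlas, connectivity = 26,
                             criterion = "overlap", max_centroid_mm = 5) {
  assert_volume(pred_mask, "binary", "pred_mask")
  assert_volume(ref_mask, "binary", "ref_mask")
  assert_same_geometry(pred_mask, ref_mask, "pred and ref masks")
  assert_same_geometry(pred_mask, atlas$labels, "masks and atlas")

  pred <- label_components(pred_mask, connectivity)
  ref <- label_components(ref_mask, connectivity)
  matches <- match_lesions(pred, ref, criterion, max_centroid_mm)

  pa <- lesion_assignments(pred, atlas)
  ra <- lesion_assignments(ref, atlas)
  assignments <- matches |>
    left_join(pa |> rename_with_prefix("pred"), by = "pred_id") |>
    left_join(ra |> rename_with_prefix("ref"), by = "ref_id")

  met <- region_metrics(assignments)
  sz <- size_error(matches, pred, ref)
  structure(list(
    matches = matches,
    assignments = assignments,
    per_region = met$per_region,
    overall_accuracy = met$overall_accuracy,
    size_abs_errors = sz$abs_errors,
    size_mae = sz$mae,
    confusion_region = confusion_matrices(assignments, "region", atlas$lut),
    confusion_structure = confusion_matrices(assignments, "structure", atlas$lut),
    fn_by_structure = fn_histogram(assignments, atlas$lut)
  ), class = "region_evaluation")
}

rename_with_prefix <- function(tb, prefix) {
  tb |>
    select("component_id", "structure", "region", "diameter_mm") |>
    rlang::set_names(paste0(prefix, "_", c("id", "structure", "region", "diameter_mm")))
}

#' @export
print.region_evaluation <- function(x, ...) {
  cat("<region_evaluation>\n")
  pr <- x$per_region |>
    mutate(across(c("sensitivity", "precision", "f1"), ~ round(.x, 2)))
  print(as.data.frame(pr), row.names = FALSE)
  cat(sprintf("overall accuracy: %s   size MAE: %s mm\n",
              ifelse(is.na(x$overall_accuracy), "NA", round(x$overall_accuracy, 2)),
              ifelse(is.na(x$size_mae), "NA", round(x$size_mae, 1))))
  invisible(x)
}

#' @rdname evaluate_subject
#' @param x A `region_evaluation`.
#' @param ... Unused.
#' @export
tidy.region_evaluation <- function(x, ...) x$per_region

#' @rdname evaluate_subject
#' @export
glance.region_evaluation <- function(x, ...) {
  tibble(
    n_true_positive = sum(x$matches$status == "true_positive"),
    n_false_positive = sum(x$matches$status == "false_positive"),
    n_false_negative = sum(x$matches$status == "false_negative"),
    overall_accuracy = x$overall_accuracy,
    size_mae = x$size_mae
  )
}

#' Write an evaluation report
#'
#' JSON with metrics, confusion matrices and the per-lesion audit trail; an
#' optional CSV with the per-region metrics table.
#'
#' @param ev A `region_evaluation`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return The evaluation, invisibly.
#' @export
write_evaluation <- function(ev, json_path = NULL, csv_path = NULL) {
  if (!inherits(ev, "region_evaluation")) abort_validation("not a region_evaluation.")
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      per_region = ev$per_region,
      overall_accuracy = ev$overall_accuracy,
      size_mae = ev$size_mae,
      size_abs_errors = ev$size_abs_errors,
      confusion_region = as.data.frame.matrix(ev$confusion_region),
      confusion_structure = as.data.frame.matrix(ev$confusion_structure),
      fn_by_structure = ev$fn_by_structure,
      lesions = ev$assignments
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) readr::write_csv(ev$per_region, csv_path)
  invisible(ev)
}
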