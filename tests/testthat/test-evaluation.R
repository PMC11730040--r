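# lesion matching, size errors, region metrics, confusion matrices

test_that("identical maps self-match as all true positives", {
  mask <- mk_mask(rbind(c(2, 2, 2), c(3, 2, 2), c(7, 7, 7)))
  les <- label_components(mask)
  m <- match_lesions(les, les)
  expect_true(all(m$status == "true_positive"))
  expect_identical(nrow(m), 2L)
  expect_identical(m$pred_id, m$ref_id)
})

test_that("unmatched lesions become false positives / negatives", {
  ref <- label_components(mk_mask(rbind(c(2, 2, 2), c(5, 5, 5), c(8, 8, 8))))
  none <- label_components(mk_mask(NULL))
  m <- match_lesions(none, ref)
  expect_identical(sum(m$status == "false_negative"), 3L)
  expect_identical(sum(m$status != "false_negative"), 0L)

  m2 <- match_lesions(ref, none)
  expect_identical(sum(m2$status == "false_positive"), 3L)
})

test_that("greedy matching prefers the larger overlap", {
  # one predicted rod overlapping two reference lesions by 2 and 5 voxels
  pred <- label_components(mk_mask(cbind(2:11, 5, 5), c(15, 15, 15)))
  ref <- label_components(mk_mask(rbind(cbind(2:3, 5, 5), cbind(7:11, 5, 5)),
                                  c(15, 15, 15)))
  m <- match_lesions(pred, ref)
  tp <- m[m$status == "true_positive", ]
  expect_identical(nrow(tp), 1L)
  expect_identical(tp$ref_id, 2L)          # the 5-voxel overlap wins
  expect_identical(tp$overlap_voxels, 5L)
  expect_identical(m$ref_id[m$status == "false_negative"], 1L)

  expect_error(match_lesions(pred, label_components(mk_mask(NULL, c(5, 5, 5)))),
               class = "cmb_error_geometry")
})

test_that("greedy matching agrees with exhaustive optimum on random instances", {
  set.seed(31)
  dm <- c(32, 32, 32)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    centres <- cbind(sample(seq(5, 28, 4), n), sample(seq(5, 28, 4), n),
                     sample(seq(5, 28, 4), n))
    spec <- phantom_spec(grid_shape = dm, lesions = tibble::tibble(
      cx = centres[, 1], cy = centres[, 2], cz = centres[, 3],
      diameter_mm = sample(c(2.7, 3.5, 4.5), n, TRUE), structure = NA),
      structures = default_phantom_structures()[0, ], seed = rep)
    truth <- make_lesion_mask(spec)$mask
    jit <- perturb_mask(truth, list(kind = "jitter", sigma_mm = 0.8), seed = rep)

    pred <- label_components(jit)
    ref <- label_components(truth)
    m <- match_lesions(pred, ref)
    tp <- m[m$status == "true_positive", c("pred_id", "ref_id")]

    ov <- matrix(0L, nrow(pred), nrow(ref))
    for (p in seq_len(nrow(pred))) for (q in seq_len(nrow(ref))) {
      ov[p, q] <- nrow(dplyr::intersect(
        as.data.frame(pred$voxels[[p]]), as.data.frame(ref$voxels[[q]])))
    }
    if (nrow(pred) && nrow(ref)) {
      opt <- brute_force_match(ov)
      got <- as.matrix(tp[order(tp$pred_id), ])
      expect_equal(unname(got), unname(opt$pairs))
    } else {
      expect_identical(nrow(tp), 0L)
    }
  }
})

test_that("size errors are per-pair absolute differences", {
  matches <- tibble::tibble(pred_id = c(1L, 2L), ref_id = c(1L, 2L),
                            overlap_voxels = c(3L, 3L),
                            status = "true_positive")
  se <- size_error(matches, c(`1` = 5.4, `2` = 3.6), c(`1` = 4.5, `2` = 3.6))
  expect_equal(se$abs_errors$abs_error_mm, c(0.9, 0))
  expect_equal(se$mae, 0.45)

  # identical sizes give zero error
  se0 <- size_error(matches, c(`1` = 2, `2` = 3), c(`1` = 2, `2` = 3))
  expect_equal(se0$mae, 0)

  # no matches: empty list, undefined MAE
  empty <- matches[0, ]
  seE <- size_error(empty, c(`1` = 2), c(`1` = 2))
  expect_identical(nrow(seE$abs_errors), 0L)
  expect_true(is.na(seE$mae))

  expect_error(size_error(matches, c(`1` = 5.4), c(`1` = 4.5, `2` = 3.6)),
               class = "cmb_error_validation")
})

test_that("region metrics follow the lesion-level TP/FN/FP definitions", {
  # perfect agreement
  a <- mk_assignments(rep("true_positive", 4),
                      c("deep", "deep", "lobar", "infratentorial"),
                      c("deep", "deep", "lobar", "infratentorial"))
  m <- region_metrics(a)
  expect_true(all(m$per_region$sensitivity == 1, na.rm = TRUE))
  expect_true(all(m$per_region$precision == 1, na.rm = TRUE))
  expect_equal(m$overall_accuracy, 1)

  # 10 matched lesions, 9 with the same region
  b <- mk_assignments(rep("true_positive", 10),
                      c(rep("lobar", 9), "deep"), rep("lobar", 10))
  mb <- region_metrics(b)
  expect_equal(mb$overall_accuracy, 0.9)
  lob <- mb$per_region[mb$per_region$region == "lobar", ]
  expect_equal(lob$sensitivity, 0.9)
  expect_equal(lob$precision, 1)
  deep <- mb$per_region[mb$per_region$region == "deep", ]
  expect_equal(deep$precision, 0)   # the one deep call is wrong

  # detection misses count as reference-side FNs; spurious detections as FPs
  c3 <- mk_assignments(
    c("true_positive", "false_negative", "false_positive"),
    c("deep", NA, "lobar"), c("deep", "deep", NA))
  mc <- region_metrics(c3)
  dp <- mc$per_region[mc$per_region$region == "deep", ]
  expect_equal(dp$tp, 1); expect_equal(dp$fn, 1)
  expect_equal(dp$sensitivity, 0.5); expect_equal(dp$precision, 1)
  lb <- mc$per_region[mc$per_region$region == "lobar", ]
  expect_equal(lb$fp, 1)

  # count-level mode: TP_R = min of the two counts
  md <- region_metrics(b, mode = "count")
  lobd <- md$per_region[md$per_region$region == "lobar", ]
  expect_equal(lobd$tp, 9); expect_equal(lobd$fn, 1); expect_equal(lobd$fp, 0)

  expect_error(region_metrics(mk_assignments("true_positive", "cortex", "deep")),
               class = "cmb_error_validation")
})

test_that("F1 is the harmonic mean with a zero guard", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(round(f1_score(0.64, 1.00), 2), 0.78)
  expect_equal(round(f1_score(0.79, 0.85), 2), 0.82)
  expect_equal(round(f1_score(0.96, 0.91), 2), 0.93)
})

test_that("confusion matrices count matched lesions with manual rows", {
  a <- tibble::tibble(
    status = rep("true_positive", 3),
    pred_region = c("deep", "deep", "lobar"),
    ref_region = c("deep", "deep", "deep"),
    pred_structure = c("thalamus", "basal_ganglia", "frontal"),
    ref_structure = c("thalamus", "thalamus", "thalamus"))
  cm <- confusion_matrices(a, "region")
  expect_identical(cm["deep", "deep"], 2L)
  expect_identical(cm["deep", "lobar"], 1L)
  expect_identical(sum(cm), 3L)
  expect_identical(rowSums(cm)[["deep"]], 3)   # manual marginal

  cs <- confusion_matrices(a, "structure")
  expect_identical(cs["thalamus", "basal_ganglia"], 1L)
  expect_identical(cs["thalamus", "thalamus"], 1L)
  expect_identical(sum(cs), 3L)

  # perfect agreement is diagonal
  d <- tibble::tibble(status = "true_positive", pred_region = "lobar",
                      ref_region = "lobar")
  cd <- confusion_matrices(d, "region")
  expect_identical(sum(cd) - sum(diag(cd)), 0L)
})

test_that("false-negative histogram tallies missed lesions by manual structure", {
  a <- tibble::tibble(
    status = c("false_negative", "false_negative", "false_negative",
               "true_positive"),
    ref_structure = c("frontal", "frontal", "parietal", "thalamus"))
  h <- fn_histogram(a)
  expect_identical(h$n_false_negative[h$structure == "frontal"], 2L)
  expect_identical(h$n_false_negative[h$structure == "parietal"], 1L)
  expect_identical(sum(h$n_false_negative), 3L)
  h0 <- fn_histogram(a[a$status == "true_positive", ])
  expect_identical(sum(h0$n_false_negative), 0L)
})

test_that("end-to-end evaluation is marginally consistent with the ratings", {
  spec <- phantom_spec(seed = 5)
  ph <- make_atlas_phantom(spec)
  lm <- make_lesion_mask(spec)
  deg <- perturb_mask(lm$mask, list(kind = "drop", p = 0.3), seed = 5)

  ev <- evaluate_subject(deg, lm$mask, ph$atlas)
  rat_ref <- rate_subject(lm$mask, ph$atlas)
  rat_pred <- rate_subject(deg, ph$atlas)

  # TP + FN per region (reference side) equals the manual region count
  for (R in c("infratentorial", "deep", "lobar")) {
    pr <- ev$per_region[ev$per_region$region == R, ]
    expect_identical(pr$tp + pr$fn,
                     rat_ref$region_counts$count[rat_ref$region_counts$region == R])
    expect_identical(pr$tp + pr$fp,
                     rat_pred$region_counts$count[rat_pred$region_counts$region == R])
  }

  # metrics recompute from the region confusion matrix for matched lesions
  cm <- ev$confusion_region
  for (R in c("infratentorial", "deep", "lobar")) {
    tp <- cm[R, R]
    n_tp_ref <- sum(cm[R, ])
    pr <- ev$per_region[ev$per_region$region == R, ]
    expect_identical(unname(tp), pr$tp)
    # sensitivity restricted to matched lesions >= the overall sensitivity
    if (n_tp_ref > 0) expect_gte(tp / n_tp_ref, pr$sensitivity)
  }
  expect_identical(sum(ev$fn_by_structure$n_false_negative),
                   sum(ev$matches$status == "false_negative"))
  # dropped lesions keep their sizes on the surviving side: zero size error
  expect_equal(ev$size_mae, 0)
  expect_equal(ev$overall_accuracy, 1)

  gl <- glance(ev)
  expect_identical(gl$n_true_positive + gl$n_false_negative, 13L)
  td <- tidy(ev)
  expect_identical(nrow(td), 3L)
})
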