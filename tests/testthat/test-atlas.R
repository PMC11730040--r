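# atlas binarisation, dilation, assembly priorities, affine transfer

test_that("probabilistic maps binarise with an inclusive threshold", {
  dm <- c(10, 10, 10)
  uni <- cmb_volume(array(50, dm), dtype = "probability", scale = "percent")
  expect_true(all(binarise_structure(uni, 50)$data == 1))

  # ramp 0..100 along i: foreground fraction approx 40% at threshold 60
  ramp <- cmb_volume(array(rep(seq(0, 100, length.out = 50), 50 * 50),
                           c(50, 50, 50)), dtype = "probability")
  frac <- mean(binarise_structure(ramp, 60)$data)
  expect_equal(frac, mean(seq(0, 100, length.out = 50) >= 60))
  expect_equal(frac, 0.4, tolerance = 0.03)

  zero <- cmb_volume(array(0, dm), dtype = "probability", scale = "percent")
  expect_true(all(binarise_structure(zero, 50)$data == 0))

  # unit-scale maps are thresholded on their own scale
  unit <- cmb_volume(array(0.7, dm), dtype = "probability", scale = "unit")
  expect_true(all(binarise_structure(unit, 60)$data == 1))
  expect_true(all(binarise_structure(unit, 80)$data == 0))

  expect_error(binarise_structure(uni, 0), class = "cmb_error_validation")
  expect_error(binarise_structure(uni, 101), class = "cmb_error_validation")
})

test_that("dilation grows masks by the structuring element", {
  single <- mk_mask(rbind(c(5, 5, 5)))
  d3 <- dilate_mask(single, 3, "box")
  expect_identical(sum(d3$data), 27L)
  expect_true(all(d3$data[4:6, 4:6, 4:6] == 1))

  # ball and cross elements of width 3 are the 6-neighbour cross
  expect_identical(sum(dilate_mask(single, 3, "cross")$data), 7L)
  expect_identical(sum(dilate_mask(single, 3, "ball")$data), 7L)

  empty <- mk_mask(NULL)
  expect_identical(sum(dilate_mask(empty, 3)$data), 0L)

  # extensivity and monotonicity in element size
  set.seed(5)
  blob <- mk_mask(unique(cbind(sample(3:8, 15, TRUE), sample(3:8, 15, TRUE),
                               sample(3:8, 15, TRUE))))
  d1 <- dilate_mask(blob, 3)
  d2 <- dilate_mask(blob, 5)
  expect_true(all(d1$data >= blob$data))
  expect_true(all(d2$data >= d1$data))

  expect_error(dilate_mask(single, 0), class = "cmb_error_validation")
  expect_error(dilate_mask(single, 4), class = "cmb_error_validation")
})

test_that("assembly enforces the white-matter exclusion and priority order", {
  dm <- c(20, 20, 20)
  # deep white matter covers a slab that also contains the corpus callosum
  dwm <- mk_mask(as.matrix(expand.grid(3:18, 3:18, 8:12)), dm)
  cc <- mk_mask(as.matrix(expand.grid(8:12, 8:12, 8:12)), dm)
  thal <- mk_mask(as.matrix(expand.grid(14:17, 3:6, 8:12)), dm)
  # a dilated frontal lobe that reaches into the thalamus block
  frontal <- mk_mask(as.matrix(expand.grid(14:17, 3:6, 13:16)), dm)

  atlas <- assemble_atlas(list(deep_white_matter = dwm, corpus_callosum = cc,
                               thalamus = thal, frontal = frontal))
  lut <- atlas$lut
  code <- function(nm) lut$code[lut$name == nm]
  lab <- atlas$labels$data

  # voxel inside both CC and DWM input masks -> corpus callosum
  expect_identical(lab[10, 10, 10], code("corpus_callosum"))
  # exclusion invariant: no DWM voxel inside capsules/callosum
  expect_identical(sum(lab == code("deep_white_matter") & cc$data == 1), 0L)
  # frontal dilates downward onto the thalamus: deep beats dilated lobar
  expect_identical(lab[15, 4, 12], code("thalamus"))
  # but the dilated lobar ring exists outside deep tissue
  expect_identical(lab[15, 4, 17], code("frontal"))

  # every voxel carries exactly one label; union matches inputs after rules
  expect_true(all(lab %in% c(0L, lut$code)))

  # disjoint masks assemble without relabelling
  a <- mk_mask(as.matrix(expand.grid(2:4, 2:4, 2:4)), dm)
  b <- mk_mask(as.matrix(expand.grid(10:12, 10:12, 10:12)), dm)
  at2 <- assemble_atlas(list(brainstem = a, thalamus = b), dilate = FALSE)
  expect_identical(sum(at2$labels$data == code("brainstem")), 27L)
  expect_identical(sum(at2$labels$data == code("thalamus")), 27L)
  expect_identical(sum(at2$labels$data != 0), 54L)

  # geometry mismatch names the offender
  small <- mk_mask(NULL, c(5, 5, 5))
  expect_error(assemble_atlas(list(brainstem = a, thalamus = small)),
               "thalamus", class = "cmb_error_geometry")
})

test_that("same-priority overlaps go to the nearest undilated structure", {
  dm <- c(24, 12, 12)
  # two lobes 4 voxels apart; their dilated masks meet in the gap
  frontal <- mk_mask(as.matrix(expand.grid(4:8, 4:8, 4:8)), dm)
  parietal <- mk_mask(as.matrix(expand.grid(12:16, 4:8, 4:8)), dm)
  atlas <- assemble_atlas(list(frontal = frontal, parietal = parietal),
                          dilate_size = 5)
  lut <- atlas$lut
  lab <- atlas$labels$data
  # contested voxels at i = 9..11: 9 nearer frontal (ends i=8), 11 nearer parietal
  expect_identical(lab[9, 6, 6], lut$code[lut$name == "frontal"])
  expect_identical(lab[11, 6, 6], lut$code[lut$name == "parietal"])
  # exact midpoint i = 10: tie resolved to the lower structure code (frontal)
  expect_identical(lab[10, 6, 6], lut$code[lut$name == "frontal"])
})

test_that("identity transform is a label-level no-op", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32),
                       structures = default_phantom_structures() |>
                         dplyr::filter(name %in% c("brainstem", "thalamus", "frontal")) |>
                         dplyr::mutate(cx = cx / 2, cy = cy / 2, cz = cz / 2,
                                       rx = pmin(rx, 4), ry = pmin(ry, 4),
                                       rz = pmin(rz, 4)),
                       lesions = tibble::tibble(cx = numeric(), cy = numeric(),
                                                cz = numeric(),
                                                diameter_mm = numeric(),
                                                structure = character()))
  atlas <- make_atlas_phantom(spec)$atlas
  target <- cmb_volume(array(0, spec$grid_shape), spec$voxel_dims,
                       atlas$labels$affine)
  out <- transform_atlas(atlas, diag(4), target)
  expect_identical(out$labels$data, atlas$labels$data)
  expect_identical(out$space, "subject")
})

test_that("integer translations shift labels exactly like an array roll", {
  dm <- c(16, 16, 16); vd <- c(1, 1, 1)
  thal <- mk_ball_mask(c(6, 7, 8), 3, dm, vd)
  atlas <- assemble_atlas(list(thalamus = thal), dilate = FALSE)
  target <- cmb_volume(array(0, dm), vd)
  shift <- c(3, 2, 1)   # voxels = mm on this grid
  aff <- diag(4); aff[1:3, 4] <- shift
  out <- transform_atlas(atlas, aff, target)

  rolled <- array(0L, dm)
  rolled[(1 + shift[1]):dm[1], (1 + shift[2]):dm[2], (1 + shift[3]):dm[3]] <-
    atlas$labels$data[1:(dm[1] - shift[1]), 1:(dm[2] - shift[2]),
                      1:(dm[3] - shift[3])]
  expect_identical(out$labels$data, rolled)
  expect_identical(sum(out$labels$data != 0), sum(atlas$labels$data != 0))
})

test_that("resampling across voxel scales conserves structure volume in mm^3", {
  dm <- c(40, 40, 40)
  sphere <- mk_ball_mask(c(20, 20, 20), 9, dm, c(1, 1, 1))
  atlas <- assemble_atlas(list(cerebellum = sphere), dilate = FALSE)

  # same physical space sampled at 2 mm: mm^3 volume is conserved
  coarse <- cmb_volume(array(0, c(22, 22, 22)), c(2, 2, 2))
  out <- transform_atlas(atlas, diag(4), coarse)
  v_before <- sum(atlas$labels$data != 0) * 1
  v_coarse <- sum(out$labels$data != 0) * 8
  expect_lt(abs(v_coarse - v_before) / v_before, 0.1)

  # a uniform x2 scaling multiplies physical volume by det = 8
  big <- cmb_volume(array(0, c(44, 44, 44)), c(2, 2, 2))
  out2 <- transform_atlas(atlas, diag(c(2, 2, 2, 1)), big)
  v_scaled <- sum(out2$labels$data != 0) * 8
  expect_lt(abs(v_scaled - 8 * v_before) / (8 * v_before), 0.1)

  expect_error(transform_atlas(atlas, matrix(0, 4, 4), coarse),
               class = "cmb_error_geometry")
})

test_that("affine files read in world and FSL conventions", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "aff.mat")
  m <- diag(4); m[1:3, 4] <- c(2, -1, 3)
  writeLines(apply(m, 1, paste, collapse = " "), f)
  expect_equal(read_affine(f), m)

  # FSL identity between identical RAS grids is the world identity
  vol <- mk_mask(NULL, c(10, 10, 10), c(2, 2, 2))
  writeLines(apply(diag(4), 1, paste, collapse = " "), f)
  w <- read_affine(f, convention = "fsl", source = vol, target = vol)
  expect_equal(w, diag(4))

  writeLines("1 2 3", f)
  expect_error(read_affine(f), class = "cmb_error_format")
})

test_that("the LUT round-trips through CSV and validates", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "lut.csv")
  write_lut(mars_lut(), f)
  back <- read_lut(f)
  expect_equal(as.data.frame(back), as.data.frame(mars_lut()))

  # Table-style region membership is fixed
  lut <- mars_lut()
  expect_setequal(lut$name[lut$region == "infratentorial"],
                  c("brainstem", "cerebellum"))
  expect_setequal(lut$name[lut$region == "deep"],
                  c("basal_ganglia", "thalamus", "internal_capsule",
                    "external_capsule", "corpus_callosum", "deep_white_matter"))
  expect_setequal(lut$name[lut$region == "lobar"],
                  c("frontal", "parietal", "temporal", "occipital", "insula"))

  bad <- mars_lut(); bad$region[1] <- "cortex"
  expect_error(write_lut(bad, f), class = "cmb_error_validation")

  # the shipped copy matches the built-in table
  shipped <- system.file("extdata", "mars_lut.csv", package = "cmbmars")
  expect_equal(as.data.frame(read_lut(shipped)), as.data.frame(mars_lut()))
})
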