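test_that("total_volume sums masked voxels times voxel volume, in mL", {
  zero <- tissue_map(array(0, c(4, 4, 4)), voxel_volume_mm3 = 2)
  expect_identical(total_volume(zero), 0)

  # 10 voxels of value 1.0 on a 2x2x2 mm grid: 10 * 8 mm^3 = 0.080 mL
  vals <- array(0, c(5, 5, 5))
  vals[1:10] <- 1
  m <- tissue_map(vals, voxel_volume_mm3 = 8)
  mask <- array(FALSE, c(5, 5, 5)); mask[1:10] <- TRUE
  expect_equal(total_volume(m, mask), 0.080)

  # voxel volume from an affine with 2 mm isotropic spacing
  aff <- diag(c(2, 2, 2, 1))
  expect_equal(tissue_map(vals, affine = aff)$voxel_volume_mm3, 8)
})

test_that("total_volume matches an independent triple-loop oracle", {
  set.seed(42)
  for (rep in 1:5) {
    vals <- array(runif(8^3), c(8, 8, 8))
    mask <- array(runif(8^3) > 0.5, c(8, 8, 8))
    vv <- runif(1, 0.5, 8)
    m <- tissue_map(vals, voxel_volume_mm3 = vv)
    expect_equal(total_volume(m, mask), triple_loop_volume(vals, mask, vv),
                 tolerance = 1e-12)
  }
})

test_that("total_volume rejects bad inputs loudly", {
  m <- tissue_map(array(1, c(4, 4, 4)))
  err <- expect_error(total_volume(m, array(TRUE, c(3, 4, 4))),
                      "grid mismatch")
  expect_match(conditionMessage(err), "4x4x4")
  expect_match(conditionMessage(err), "3x4x4")
  expect_error(tissue_map(array(c(NA, rep(1, 26)), c(3, 3, 3))),
               "non-finite")
  expect_error(tissue_map(array(1, c(4, 4))), "3D")
})

test_that("compute_tiv adds the whole-image GM + WM + CSF volumes", {
  z <- tissue_map(array(0, c(5, 5, 5)))
  expect_equal(compute_tiv(z, z, z), 0)

  # 0.4 + 0.3 + 0.3 over 1000 voxels of 1 mm^3 = 1.0 mL
  g <- tissue_map(array(0.4, c(10, 10, 10)))
  w <- tissue_map(array(0.3, c(10, 10, 10)))
  c_ <- tissue_map(array(0.3, c(10, 10, 10)))
  expect_equal(compute_tiv(g, w, c_), 1.0)

  set.seed(1)
  maps <- lapply(1:3, function(i)
    tissue_map(array(runif(6^3), c(6, 6, 6)), voxel_volume_mm3 = 3))
  full <- array(TRUE, c(6, 6, 6))
  oracle <- sum(vapply(maps, function(m)
    triple_loop_volume(m$values, full, 3), numeric(1)))
  expect_equal(compute_tiv(maps[[1]], maps[[2]], maps[[3]]), oracle,
               tolerance = 1e-12)

  expect_error(compute_tiv(g, w, tissue_map(array(0.3, c(9, 10, 10)))),
               "grid mismatch")
})

test_that("ROI extraction is exact, additive over a partition, and scales", {
  # two labels partitioning the grid: ROI volumes sum to the image total
  lab <- array(1L, c(6, 6, 6)); lab[4:6, , ] <- 2L
  labels <- data.frame(label_id = 1:2, region_name = c("left", "right"),
                       family = "halves")
  atlas <- atlas_definition(lab, labels)
  set.seed(3)
  vals <- array(runif(6^3), c(6, 6, 6))
  subj <- data.frame(id = "S1", med = 0, age = 30, sex = "F", tiv_ml = 1400)
  tab <- extract_roi_table(list(S1 = tissue_map(vals)), atlas, "halves", subj)
  expect_equal(sum(tab$volumes), total_volume(tissue_map(vals)),
               tolerance = 1e-9)

  # one ROI of 50 voxels, value 0.5, 1 mm^3 voxels -> 0.025 mL
  lab2 <- array(0L, c(5, 5, 5)); lab2[1:50] <- 1L
  vals2 <- array(0, c(5, 5, 5)); vals2[1:50] <- 0.5
  atlas2 <- atlas_definition(lab2, data.frame(
    label_id = 1L, region_name = "roi", family = "one"))
  tab2 <- extract_roi_table(list(S1 = tissue_map(vals2)), atlas2, "one", subj)
  expect_equal(unname(tab2$volumes[1, 1]), 0.025)

  # scaling equivariance: values * c -> volumes * c
  tab3 <- extract_roi_table(list(S1 = tissue_map(vals * 2.5)), atlas,
                            "halves", subj)
  expect_equal(tab3$volumes, tab$volumes * 2.5, tolerance = 1e-12)

  # a family label missing from the image warns and records zero
  labels3 <- rbind(labels, data.frame(label_id = 9L, region_name = "ghost",
                                      family = "halves"))
  atlas3 <- atlas_definition(lab, labels3)
  expect_warning(
    tab4 <- extract_roi_table(list(S1 = tissue_map(vals)), atlas3,
                              "halves", subj),
    "absent")
  expect_equal(unname(tab4$volumes[1, "ghost"]), 0)

  expect_error(extract_roi_table(list(), atlas, "halves", subj),
               "missing grey-matter map")
  expect_error(extract_roi_table(list(S1 = tissue_map(vals)), atlas,
                                 "nope", subj), "family")
})

test_that("label tables parse strictly and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  labs <- data.frame(label_id = c(1L, 2L), region_name = c("a", "b"),
                     family = "fam")
  write_label_table(labs, path)
  expect_equal(read_label_table(path), labs)

  writeLines("label_id\tregion_name", path)
  expect_error(read_label_table(path), "family")

  writeLines(c("label_id\tregion_name\tfamily\tcolour",
               "1\ta\tf\tred"), path)
  expect_warning(read_label_table(path), "unknown")

  writeLines(c("label_id\tregion_name\tfamily", "1\ta\tf", "1\tb\tf"), path)
  expect_error(read_label_table(path), "duplicate")
})

test_that("subject and volume tables round-trip and validate", {
  subj <- data.frame(id = c("A", "B"), med = c(0, 1), age = c(30, 40),
                     sex = c("F", "M"), tiv_ml = c(1400, 1600))
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_subjects(subj, sp)
  back <- read_subjects(sp)
  expect_equal(back[c("id", "med", "age", "sex", "tiv_ml")],
               subj, ignore_attr = TRUE)

  vols <- matrix(c(1.5, 2.5, 3.5, 4.5), 2,
                 dimnames = list(NULL, c("r1", "r2")))
  tab <- roi_volume_table(subj, vols)
  vp <- withr::local_tempfile(fileext = ".tsv")
  write_volume_table(tab, vp)
  tab2 <- read_volume_table(vp, subjects = subj)
  expect_equal(tab2$volumes, tab$volumes, tolerance = 1e-12)

  expect_error(roi_volume_table(rbind(subj, subj), rbind(vols, vols)),
               "duplicated subject ids")
  expect_error(roi_volume_table(subj, -vols), "non-negative")
})

test_that("an S1-style wide supplementary table is ingested as shipped", {
  vol_path <- system.file("extdata", "synthetic_s1_style_volumes.tsv",
                          package = "ahglm")
  sub_path <- system.file("extdata", "synthetic_subjects.tsv",
                          package = "ahglm")
  subj <- read_subjects(sub_path)
  tab <- read_volume_table(vol_path, subjects = subj)
  expect_s3_class(tab, "roi_volume_table")
  expect_equal(nrow(tab$subjects), 46L)
  expect_equal(length(tab$regions), 16L)
  raw <- read_volume_table(vol_path)
  expect_equal(ncol(raw) - 1L, 16L)  # region per column after the id
})
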