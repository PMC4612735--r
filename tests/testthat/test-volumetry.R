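mk_mask <- function(idx, dim = c(6, 6, 6), spacing = c(1, 1, 1)) {
  g <- array(FALSE, dim)
  g[idx] <- TRUE
  segmentation_mask(g, spacing)
}

test_that("Dice identities: self, disjoint, 6-of-8 overlap, empty limits", {
  m <- mk_mask(1:10)
  expect_equal(dice(m, m), 1)
  expect_equal(dice(mk_mask(1:8), mk_mask(9:16)), 0)
  # |M| = 8, |S| = 8, overlap 6 -> 12/16
  expect_equal(dice(mk_mask(1:8), mk_mask(3:10)), 0.75)
  empty <- mk_mask(integer(0))
  expect_equal(dice(empty, empty), 1)
  expect_equal(dice(empty, m), 0)
  expect_error(dice(m, mk_mask(1:2, dim = c(5, 5, 5))), "geometry")
})

test_that("dice is symmetric and monotone under union", {
  set.seed(21)
  for (i in 1:20) {
    a <- mk_mask(sample(216, 40))
    b <- mk_mask(sample(216, 40))
    expect_equal(dice(a, b), dice(b, a))
  }
  m <- mk_mask(1:20)
  s <- mk_mask(10:15)
  u <- segmentation_mask(m$grid | s$grid, m$spacing)
  expect_gte(dice(m, u), dice(m, s))
})

test_that("mask volume is voxel count times physical voxel size", {
  m <- mk_mask(1:125, dim = c(10, 10, 20), spacing = c(1, 1, 2))
  expect_equal(mask_volume(m), 125 * 2)
  expect_equal(mask_volume(mk_mask(integer(0))), 0)
  # additivity over disjoint masks
  a <- mk_mask(1:30); b <- mk_mask(31:50)
  u <- segmentation_mask(a$grid | b$grid, a$spacing)
  expect_equal(mask_volume(u), mask_volume(a) + mask_volume(b))
})

test_that("the count-times-size rule is consistent with a clinically reported volume/count pair", {
  # 55246 voxels at the implied voxel volume must give 30592.2 mm^3
  vox_vol <- 30592.2 / 55246
  s <- vox_vol^(1 / 3)
  g <- array(FALSE, c(60, 60, 16))
  g[seq_len(55246)] <- TRUE
  m <- segmentation_mask(g, spacing = rep(s, 3))
  expect_identical(m$voxel_count, 55246L)
  expect_equal(mask_volume(m), 30592.2, tolerance = 1e-9)
})

test_that("evaluation records and summary follow the report layout", {
  a <- mk_mask(1:100, dim = c(10, 10, 10))
  b <- mk_mask(26:125, dim = c(10, 10, 10))
  rec <- evaluation_record("case-1", a, b)
  expect_named(rec, c("case", "volume_manual_mm3", "volume_auto_mm3",
                      "voxels_manual", "voxels_auto", "dsc_percent"))
  expect_equal(rec$dsc_percent, 100 * dice(a, b))

  recs <- rbind(rec, evaluation_record("case-2", a, a))
  recs$dsc_percent <- c(71.78, 83.53)
  s <- summarize_evaluations(recs)
  expect_equal(s["min", "dsc_percent"], 71.78)
  expect_equal(s["max", "dsc_percent"], 83.53)
  expect_equal(s["mean", "dsc_percent"], mean(c(71.78, 83.53)))
  expect_equal(s["sd", "dsc_percent"], sd(c(71.78, 83.53)))
  expect_true(attr(s, "sd_defined"))

  # degenerate single record: sd reported as 0 and flagged
  s1 <- summarize_evaluations(rec)
  expect_equal(s1["sd", "dsc_percent"], 0)
  expect_false(attr(s1, "sd_defined"))
  expect_equal(s1["min", "dsc_percent"], s1["max", "dsc_percent"])
  expect_error(summarize_evaluations(list()), "empty")
  expect_equal(summarize_evaluations(
    data.frame(case = 1:3, volume_manual_mm3 = c(1, 2, 3),
               volume_auto_mm3 = 0, voxels_manual = 0, voxels_auto = 0,
               dsc_percent = 0))["mean", "volume_manual_mm3"], 2)
})

test_that("evaluation reports round-trip through CSV and JSON", {
  a <- mk_mask(1:100, dim = c(10, 10, 10))
  b <- mk_mask(26:125, dim = c(10, 10, 10))
  rec <- evaluation_record("case-1", a, b)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_evaluation_report(rec, csv = csv, json = js)
  back <- read.csv(csv)
  expect_equal(back$dsc_percent, rec$dsc_percent)
  doc <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(doc$records$volume_manual_mm3, rec$volume_manual_mm3)
})
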