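test_that("blank images count zero objects", {
  img <- micrograph(matrix(100, 64, 64), 1.3)
  expect_equal(count_objects(img, threshold_spec("absolute", 200))$count, 0L)
  expect_equal(nrow(count_objects(img, threshold_spec("absolute", 200))$centers), 0L)
})

test_that("well-separated synthetic nuclei are counted exactly with accurate centroids", {
  for (s in 1:5) {
    f <- generate_nuclei_field(50, seed = s, channels = "nuclei")
    res <- count_objects(f$nuclei, threshold_spec())
    expect_equal(res$count, 50L)
    # every truth center has a centroid within 2 px
    d <- sqrt(outer(f$truth$centers[, 1], res$centers[, 1], "-")^2 +
                outer(f$truth$centers[, 2], res$centers[, 2], "-")^2)
    expect_lt(max(apply(d, 1, min)), 2)
  }
})

test_that("overlapping pairs stay within 5 percent after declumping", {
  errs <- vapply(1:10, function(s) {
    f <- generate_nuclei_field(80, overlap_fraction = 0.1, seed = s + 300,
                               channels = "nuclei")
    count_objects(f$nuclei, threshold_spec())$count / 80 - 1
  }, numeric(1))
  expect_true(all(abs(errs) <= 0.05 + 1e-9))
})

test_that("counting matches a flood-fill oracle on binarized images", {
  for (s in 1:3) {
    f <- generate_nuclei_field(40, seed = s * 17, channels = "nuclei")
    # area window wide enough that declumping never triggers: the oracle
    # covers plain component counting on non-touching objects
    sp <- threshold_spec(max_object_area = 200)
    thr <- select_threshold(f$nuclei, sp)
    oracle <- flood_fill_count(f$nuclei$pixels > thr, sp$min_object_area,
                               sp$max_object_area)
    expect_equal(count_objects(f$nuclei, sp)$count, oracle)
  }
})

test_that("raising the threshold never increases the count on nuclei fields", {
  f <- generate_nuclei_field(60, seed = 9, channels = "nuclei")
  thrs <- seq(1050, 1250, by = 25)
  counts <- vapply(thrs, function(t)
    count_objects(f$nuclei, threshold_spec("absolute", t))$count, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("relative-mode counts are invariant to global intensity scaling", {
  f <- generate_nuclei_field(40, seed = 13, channels = "nuclei")
  sp <- threshold_spec()
  base <- count_objects(f$nuclei, sp)$count
  for (c in c(0.5, 3, 10)) {
    scaled <- micrograph(f$nuclei$pixels * c, f$nuclei$pixel_size, "nuclei")
    expect_equal(count_objects(scaled, sp)$count, base)
  }
})

test_that("well summary sums fields and computes ratios", {
  flds <- replicate(3, field_counts(10, 2, 0.001), simplify = FALSE)
  ws <- summarize_well(flds)
  expect_equal(ws$total, 30L)
  expect_equal(ws$dead, 6L)
  expect_equal(ws$live, 24L)
  expect_equal(ws$viability, 0.8)
  expect_equal(ws$live_density, 24 / 0.003)
})

test_that("well summary handles edge cases: all dead, clamping, empty input", {
  expect_equal(summarize_well(list(field_counts(5, 5, 1)))$viability, 0)
  clamped <- summarize_well(list(field_counts(4, 9, 1)))
  expect_equal(clamped$dead, 4L)
  expect_equal(clamped$live, 0L)
  expect_true(is.na(summarize_well(list(field_counts(0, 0, 1)))$viability))
  expect_error(summarize_well(list()), "at least one")
})

test_that("live + dead equals total for any summarized well", {
  set.seed(21)
  for (i in 1:20) {
    flds <- lapply(1:3, function(j)
      field_counts(rpois(1, 40), rpois(1, 15), 0.004))
    ws <- summarize_well(flds)
    expect_equal(ws$live + ws$dead, ws$total)
    if (ws$total > 0) expect_true(ws$viability >= 0 && ws$viability <= 1)
  }
})

test_that("dataset viability analysis recovers truth and flags missing fields", {
  des <- experiment_design(densities = 10000, n_biological = 1,
                           n_technical = 2, fields_per_well = 2)
  td <- withr::local_tempdir()
  out <- file.path(td, "ds")
  gen <- generate_experiment(des, out, assays = "viability", seed = 31)
  res <- run_viability_analysis(out)
  expect_equal(nrow(res), 4L)
  m <- merge(res, gen$truth_wells[, c("well_id", "true_viability")], "well_id")
  expect_lt(max(abs(m$viability - m$true_viability)), 0.03)
  # thresholds uniform within condition
  qc <- read.csv(file.path(out, "viability_fields.csv"))
  qc$cond <- sub("_d.*", "", qc$well_id)
  for (cc in unique(qc$cond))
    expect_length(unique(qc$nuclei_threshold[qc$cond == cc]), 1L)
  # remove one field image: row flagged, not dropped
  victim <- res$well_id[1]
  unlink(file.path(out, "wells", victim, "field2_nuclei.tif"))
  res2 <- run_viability_analysis(out)
  expect_equal(nrow(res2), 4L)
  expect_match(res2$flag[res2$well_id == victim], "missing field 2")
})

test_that("recovered group means preserve the injected co-culture effect", {
  tab <- simulate_viability_experiment(density = 10000,
                                       viability = c(coculture = 0.91, control = 0.69),
                                       n_biological = 1, n_technical = 3,
                                       fields_per_well = 1, seed = 41)
  co <- mean(tab$viability[tab$condition == "coculture"])
  ct <- mean(tab$viability[tab$condition == "control"])
  expect_gt(co, ct)
  expect_lt(abs(co - 0.91), 0.03)
  expect_lt(abs(ct - 0.69), 0.03)
})
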