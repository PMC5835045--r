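test_that("empty nuclei field is pure background with empty truth", {
  f <- generate_nuclei_field(0, seed = 1)
  expect_equal(nrow(f$truth$centers), 0L)
  expect_equal(count_objects(f$nuclei, threshold_spec())$count, 0L)
})

test_that("dead flags follow round(n * dead_fraction) and centers stay in bounds", {
  f <- generate_nuclei_field(50, dead_fraction = 0.2, seed = 2)
  expect_equal(nrow(f$truth$centers), 50L)
  expect_equal(sum(f$truth$dead_flags), 10L)
  expect_true(all(f$truth$centers[, 1] >= 1 & f$truth$centers[, 1] <= 512))
  expect_true(all(f$truth$centers[, 2] >= 1 & f$truth$centers[, 2] <= 512))
  expect_equal(length(f$truth$dead_flags), nrow(f$truth$centers))
  expect_gt(f$truth$field_area, 0)
})

test_that("spot contrast at truth centers exceeds background by >= 5 noise sd", {
  f <- generate_nuclei_field(50, contrast = 10, noise_sd = 1, seed = 3)
  px <- f$nuclei$pixels
  at_centers <- px[cbind(round(f$truth$centers[, 2]), round(f$truth$centers[, 1]))]
  expect_gte(mean(at_centers) - median(px), 5 * 1)
})

test_that("placement rejects infeasible spacing requests", {
  expect_error(generate_nuclei_field(200, image_shape = c(64, 64), min_spacing = 20,
                                     seed = 1),
               "could not place")
})

test_that("generators are bit-identical for identical seeds", {
  a <- generate_nuclei_field(30, seed = 7)
  b <- generate_nuclei_field(30, seed = 7)
  expect_identical(a$nuclei$pixels, b$nuclei$pixels)
  expect_identical(a$truth, b$truth)
  n1 <- generate_neurite_field(5, 150, seed = 7)
  n2 <- generate_neurite_field(5, 150, seed = 7)
  expect_identical(n1$neurite$pixels, n2$neurite$pixels)
  t1 <- generate_calcium_traces(3, 0.1, duration = 20, seed = 7)
  t2 <- generate_calcium_traces(3, 0.1, duration = 20, seed = 7)
  expect_identical(t1$dff, t2$dff)
})

test_that("empty neurite field has zero true length", {
  f <- generate_neurite_field(0, seed = 1)
  expect_equal(f$truth$true_total_length, 0)
  expect_length(f$truth$polylines, 0)
})

test_that("true neurite length equals the vertex-sum of its polylines", {
  f <- generate_neurite_field(8, 200, seed = 11)
  vertex_sum <- sum(vapply(f$truth$polylines, function(v) {
    d <- diff(v)
    sum(sqrt(rowSums(d^2)))
  }, numeric(1))) * 1.3
  expect_equal(f$truth$true_total_length, vertex_sum)
})

test_that("calcium trace generator honors geometry and edge cases", {
  tr <- generate_calcium_traces(2, firing_rate = 0, duration = 120,
                                frame_rate = 32, seed = 5)
  expect_equal(nrow(tr$dff), 3840L)
  expect_true(all(lengths(tr$spike_times) == 0))
  expect_error(generate_calcium_traces(1, 0.1, duration = 0), "positive")
  expect_error(generate_calcium_traces(1, 0.1, tau_rise = 0.5, tau_decay = 0.2),
               "tau_decay")
})

test_that("total spikes across cells follow the Poisson expectation", {
  tot <- 0
  for (s in 1:5) {
    tr <- generate_calcium_traces(20, 0.1, duration = 120, seed = s)
    tot <- tot + sum(lengths(tr$spike_times))
  }
  lambda <- 5 * 20 * 0.1 * 120  # 1200
  expect_lt(abs(tot - lambda), 3 * sqrt(lambda))
  # spike times sorted and in range
  tr <- generate_calcium_traces(10, 0.2, duration = 60, seed = 3)
  for (st in tr$spike_times) {
    expect_true(all(diff(st) > 0) || length(st) < 2)
    expect_true(all(st >= 0 & st <= 60))
  }
})

test_that("movie truth footprints are disjoint and frames match duration", {
  mv <- generate_calcium_movie(5, 0.1, duration = 10, seed = 2)
  expect_equal(dim(mv$movie$frames)[3], 320L)
  all_px <- unlist(mv$truth$footprints)
  expect_equal(anyDuplicated(all_px), 0L)
})

test_that("cells per field track seeding density within Poisson error", {
  area <- 512^2 * 1.3^2 / 1e8
  for (dens in c(5000, 50000)) {
    lambda <- dens * area
    set.seed(dens)
    n <- rpois(20, lambda)
    expect_lt(abs(mean(n) - lambda), 3 * sqrt(lambda / 20))
  }
})

test_that("experiment generator emits the full well grid with exact truth", {
  des <- experiment_design(densities = c(1000, 50000), n_biological = 2,
                           n_technical = 5, fields_per_well = 1)
  td <- withr::local_tempdir()
  out <- file.path(td, "ds")
  gen <- generate_experiment(des, out, assays = "viability", seed = 5,
                             image_shape = c(256L, 256L))
  expect_equal(nrow(gen$design), 2 * 5 * 2 * 2)  # cond x tech x bio x density
  expect_equal(length(list.dirs(file.path(out, "wells"), recursive = FALSE)), 40L)
  # control truth viability equals the curve value exactly
  curve <- default_viability_curve(c(1000, 50000))
  ctrl <- gen$truth_wells[gen$truth_wells$condition == "control", ]
  expect_true(all(ctrl$true_viability ==
                    curve$control[as.character(ctrl$density)]))
  # refuses to overwrite without force
  expect_error(generate_experiment(des, out, assays = "viability", seed = 5),
               "overwrite")
})
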