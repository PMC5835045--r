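test_that("summary image trivial cases: constant movie, single flashing pixel", {
  arr <- array(100, dim = c(8, 8, 20))
  expect_true(all(summary_image(calcium_movie(arr, 32))$pixels == 0))
  arr[3, 5, seq(1, 20, 2)] <- 500
  si <- summary_image(calcium_movie(arr, 32))
  expect_equal(which.max(si$pixels), (5 - 1) * 8 + 3)
  expect_error(summary_image(calcium_movie(array(1, c(4, 4, 1)), 32)),
               "at least two")
})

test_that("summary intensity at truth footprints reflects the transient amplitude", {
  mv <- generate_calcium_movie(6, 0.2, duration = 30, seed = 4)
  si <- summary_image(mv$movie)
  fg <- mean(si$pixels[unlist(mv$truth$footprints)])
  bg <- median(si$pixels)
  # amplitude 0.2 on baseline 1000 counts => ~200-count transients
  expect_gt(fg - bg, 100)
})

test_that("segmentation recovers active cells and ignores silent ones", {
  mv <- generate_calcium_movie(20, 0.1, duration = 120, seed = 1)
  rois <- segment_cells(summary_image(mv$movie))
  expect_equal(length(rois), 20L)
  jac <- vapply(rois, function(r) {
    max(vapply(mv$truth$footprints, function(fp)
      length(intersect(r$footprint, fp)) / length(union(r$footprint, fp)),
      numeric(1)))
  }, numeric(1))
  expect_true(all(jac > 0.5))
  # footprints disjoint
  expect_equal(anyDuplicated(unlist(lapply(rois, `[[`, "footprint"))), 0L)
  # silent cells are invisible to the range summary
  mv0 <- generate_calcium_movie(8, 0, duration = 20, seed = 9)
  expect_length(segment_cells(summary_image(mv0$movie)), 0L)
  # blank summary gives empty ROI list
  blank <- micrograph(matrix(1, 32, 32), 1.3, "calcium")
  expect_length(segment_cells(blank, threshold_spec("absolute", 10)), 0L)
})

test_that("trace extraction normalizes to dff against a low-percentile baseline", {
  arr <- array(100, dim = c(6, 6, 50))
  mv <- calcium_movie(arr, 32)
  tr <- extract_trace(mv, 1:4)
  expect_equal(tr$samples, rep(100, 50))
  expect_equal(tr$dff, rep(0, 50))
  # single-pixel ROI returns that pixel's series
  arr[2, 2, ] <- seq_len(50)
  tr2 <- extract_trace(calcium_movie(arr, 32), (2 - 1) * 6 + 2)
  expect_equal(tr2$samples, as.numeric(seq_len(50)))
  expect_error(extract_trace(mv, integer(0)), "empty")
  expect_error(extract_trace(mv, 10000L), "bounds")
})

test_that("dff peak of a synthetic transient is close to the generated amplitude", {
  mv <- generate_calcium_movie(4, 0.05, duration = 40, amplitude = 0.2, seed = 6)
  peaks <- vapply(seq_along(mv$truth$footprints), function(i) {
    if (length(mv$truth$spike_times[[i]]) == 0) return(NA_real_)
    max(extract_trace(mv$movie, mv$truth$footprints[[i]])$dff)
  }, numeric(1))
  peaks <- peaks[!is.na(peaks)]
  expect_true(all(abs(peaks - 0.2) / 0.2 < 0.35))
})

test_that("flat and pure-zero traces yield no events", {
  expect_length(detect_spikes_wavelet(rep(0, 3840), 32)$event_frames, 0L)
  expect_length(detect_spikes_wavelet(rep(5, 3840), 32)$event_frames, 0L)
  expect_error(detect_spikes_wavelet(numeric(0), 32), "empty")
})

test_that("a single clean transient yields exactly one well-localized event", {
  fr <- 32
  tt <- (0:3839) / fr
  for (true_t in c(30, 60.5, 95)) {
    set.seed(round(true_t))
    dff <- 0.2 * neurocult:::transient_kernel(tt - true_t, 0.18, 0.55) +
      rnorm(3840, 0, 0.02)
    st <- detect_spikes_wavelet(dff, fr)
    expect_length(st$event_frames, 1L)
    expect_lt(abs(st$event_times - true_t), 2 * 0.18 * fr / fr)  # within 0.36 s
  }
})

test_that("event times are strictly increasing and follow the frame convention", {
  tr <- generate_calcium_traces(1, 0.15, duration = 120, seed = 8)
  st <- detect_spikes_wavelet(tr$dff[, 1], 32)
  expect_true(all(diff(st$event_frames) > 0))
  expect_equal(st$event_times, (st$event_frames - 1) / 32)
  expect_true(all(diff(st$event_frames) >= round(0.25 * 32)))
})

test_that("detections are invariant to positive rescaling of the trace", {
  tr <- generate_calcium_traces(1, 0.1, duration = 120, seed = 10)
  base <- detect_spikes_wavelet(tr$dff[, 1], 32)$event_frames
  for (c in c(0.2, 5, 100)) {
    expect_equal(detect_spikes_wavelet(tr$dff[, 1] * c, 32)$event_frames, base)
  }
})

test_that("circularly shifting a trace shifts detections by the same amount", {
  tr <- generate_calcium_traces(1, 0.1, duration = 120, seed = 12)
  x <- tr$dff[, 1]
  base <- detect_spikes_wavelet(x, 32)$event_frames
  shift <- 500L
  shifted <- c(x[(length(x) - shift + 1):length(x)], x[1:(length(x) - shift)])
  moved <- detect_spikes_wavelet(shifted, 32)$event_frames
  n <- length(x)
  # compare away from the wrap-around boundary
  exp_moved <- sort(((base + shift - 1L) %% n) + 1L)
  inner <- exp_moved[exp_moved > 100 & exp_moved < n - 100]
  expect_true(all(inner %in% moved))
})

test_that("raising the noise-floor multipliers never adds events", {
  for (s in c(14, 15)) {
    tr <- generate_calcium_traces(1, 0.15, duration = 120, seed = s)
    ks <- c(1, 1.3, 1.8, 2.5)
    counts <- vapply(ks, function(f)
      length(detect_spikes_wavelet(tr$dff[, 1], 32, k_ridge = 3.5 * f,
                                   k_peak = 5.5 * f,
                                   fine_threshold = 2.8 * f)$event_frames),
      integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("detected rate is monotone in the true Poisson rate", {
  rates <- c(0.02, 0.05, 0.1, 0.2)
  det <- vapply(rates, function(r) {
    n <- 0
    for (s in 1:4) {
      tr <- generate_calcium_traces(2, r, duration = 120, seed = s * 100 + round(r * 1000))
      for (i in 1:2)
        n <- n + length(detect_spikes_wavelet(tr$dff[, i], 32)$event_frames)
    }
    n
  }, numeric(1))
  expect_true(all(diff(det) > 0))
})

test_that("activity summary pools events and divides by duration and cells", {
  mk <- function(k) structure(list(event_frames = seq_len(k),
                                   event_times = seq_len(k) / 32,
                                   frame_rate = 32), class = "spike_train")
  s <- summarize_activity(list(mk(3), mk(5)), n_cells_total = 2, duration = 120)
  expect_equal(s$total_spike_frequency, 8 / 120)
  expect_equal(s$mean_frequency_per_cell, 8 / 120 / 2)
  expect_equal(s$n_events, 8L)
  # conservation: total equals summed event counts over duration
  expect_equal(s$total_spike_frequency * 120, 8)
  z <- summarize_activity(list(), 0, 120)
  expect_equal(z$total_spike_frequency, 0)
  expect_equal(z$mean_frequency_per_cell, 0)
  expect_error(summarize_activity(list(mk(2)), 0, 120), "zero")
  expect_error(summarize_activity(list(), 0, 0), "positive")
})

test_that("end-to-end movie analysis recovers the per-cell firing rate", {
  mv <- generate_calcium_movie(12, 0.1, duration = 120, seed = 2)
  res <- analyze_movie(mv$movie)
  expect_lt(abs(res$summary$mean_frequency_per_cell - 0.1) / 0.1, 0.15)
})
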