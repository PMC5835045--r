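# Calcium-imaging activity quantification.
#
# A recording is reduced to a temporal-activity summary image, segmented into
# cell ROIs with the same threshold/area machinery as the counting assay,
# per-ROI fluorescence traces are normalized to ΔF/F, and transient events
# ("spikes") are detected with a Mexican-hat continuous wavelet transform:
# an event needs ridge support across contiguous scales plus a strong peak
# coefficient, which keeps pure-noise traces event-free while resolving
# transients at amplitude-to-noise ratios down to ~5.

#' Calcium movie container
#'
#' @param frames H x W x T intensity array.
#' @param frame_rate acquisition rate (Hz).
#' @return object of class `calcium_movie` with fields `frames`,
#'   `frame_rate` and `duration` (= T / frame_rate, seconds).
#' @export
calcium_movie <- function(frames, frame_rate) {
  d <- dim(frames)
  if (length(d) != 3L) stop("'frames' must be an H x W x T array")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  structure(list(frames = frames, frame_rate = frame_rate,
                 duration = d[3L] / frame_rate),
            class = "calcium_movie")
}

#' @export
print.calcium_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<calcium_movie> %dx%d px, %d frames @ %g Hz (%.1f s)\n",
              d[1L], d[2L], d[3L], x$frame_rate, x$duration))
  invisible(x)
}

#' Temporal summary image of a calcium movie
#'
#' Collapses the time axis to a per-pixel activity measure: `"range"` is the
#' robust temporal range (95th minus 5th percentile), `"std"` the temporal
#' standard deviation. Active cells light up; silent structures (and the
#' static background) vanish, so segmentation of the summary yields the
#' active, countable cells.
#'
#' @param movie a [calcium_movie()] with at least two frames.
#' @param method `"range"` or `"std"`.
#' @param pixel_size um per pixel for the returned micrograph.
#' @return a [micrograph()] with channel `"calcium"`.
#' @export
summary_image <- function(movie, method = c("range", "std"), pixel_size = 1.3) {
  stopifnot(inherits(movie, "calcium_movie"))
  method <- match.arg(method)
  d <- dim(movie$frames)
  if (d[3L] < 2L) stop("summary image needs at least two frames")
  m <- matrix(movie$frames, d[1L] * d[2L], d[3L])
  v <- if (method == "range") {
    apply(m, 1L, function(r) {
      q <- stats::quantile(r, c(0.05, 0.95), names = FALSE)
      q[2L] - q[1L]
    })
  } else {
    rm1 <- rowMeans(m)
    sqrt(rowMeans(m * m) - rm1^2)
  }
  micrograph(matrix(pmax(v, 0), d[1L], d[2L]), pixel_size, "calcium")
}

#' Segment cells from a summary image
#'
#' Same threshold, labeling, area-filter and declumping contract as
#' [count_objects()], but returns the pixel footprints of the surviving
#' objects, not just their count.
#'
#' @param summary a [micrograph()] (typically from [summary_image()]).
#' @param spec a [threshold_spec()].
#' @return list of ROIs; each is a list with `label` and `footprint`
#'   (integer pixel indices into the image matrix). Footprints are disjoint.
#' @export
segment_cells <- function(summary, spec = threshold_spec(k_mad = 8)) {
  stopifnot(inherits(summary, "micrograph"))
  thr <- select_threshold(summary, spec)
  binary <- (summary$pixels > thr) * 1
  lab <- EBImage::bwlabel(binary)
  n_lab <- max(lab)
  if (n_lab == 0L) return(list())
  areas <- tabulate(lab, nbins = n_lab)
  keep <- which(areas >= spec$min_object_area & areas <= spec$max_object_area)
  rois <- lapply(seq_along(keep), function(i) {
    list(label = i, footprint = which(array(lab, dim(lab)) == keep[i]))
  })
  # oversized components: declump by watershed, keep segments in area window
  big <- which(areas > spec$max_object_area)
  for (b in big) {
    mask <- matrix(0, nrow(binary), ncol(binary))
    idx <- which(array(lab, dim(lab)) == b)
    mask[idx] <- 1
    ws <- EBImage::watershed(EBImage::distmap(mask), tolerance = 0.5, ext = 1)
    wa <- tabulate(ws, nbins = max(1L, max(ws)))
    for (s in which(wa >= spec$min_object_area)) {
      rois[[length(rois) + 1L]] <-
        list(label = length(rois) + 1L, footprint = which(array(ws, dim(ws)) == s))
    }
  }
  for (i in seq_along(rois)) rois[[i]]$label <- i
  rois
}

#' Extract a ΔF/F fluorescence trace for one ROI
#'
#' The raw trace is the per-frame mean intensity over the footprint; the
#' baseline F0 is a low percentile of the raw trace (default 10th), and
#' dff = (F - F0) / F0.
#'
#' @param movie a [calcium_movie()].
#' @param roi an ROI from [segment_cells()] (list with `footprint`), or an
#'   integer vector of pixel indices.
#' @param baseline_percentile percentile (0-1) defining F0.
#' @return list of class `fluorescence_trace` with `samples`, `dff`, `f0`
#'   and `frame_rate`.
#' @export
extract_trace <- function(movie, roi, baseline_percentile = 0.1) {
  stopifnot(inherits(movie, "calcium_movie"))
  fp <- if (is.list(roi)) roi$footprint else roi
  if (length(fp) == 0L) stop("empty ROI footprint")
  d <- dim(movie$frames)
  if (max(fp) > d[1L] * d[2L] || min(fp) < 1L) stop("footprint outside movie bounds")
  m <- matrix(movie$frames, d[1L] * d[2L], d[3L])
  samples <- colMeans(m[fp, , drop = FALSE])
  f0 <- stats::quantile(samples, baseline_percentile, names = FALSE)
  dff <- if (f0 > 0) (samples - f0) / f0 else samples * 0
  structure(list(samples = samples, dff = dff, f0 = f0,
                 frame_rate = movie$frame_rate),
            class = "fluorescence_trace")
}

# Ricker (Mexican hat, second derivative of a Gaussian) wavelet sampled at
# integer offsets -support..support for scale a (in samples)
ricker_wavelet <- function(support, a) {
  x <- seq(-support, support) / a
  (2 / (sqrt(3 * a) * pi^0.25)) * (1 - x^2) * exp(-x^2 / 2)
}

# continuous wavelet transform by circular FFT convolution; rows = scales.
# Circularity makes detection equivariant under circular time shifts.
cwt_ricker <- function(x, scales) {
  n <- length(x)
  fx <- stats::fft(x)
  out <- matrix(0, length(scales), n)
  for (i in seq_along(scales)) {
    a <- scales[i]
    half <- ceiling(5 * a)
    w <- ricker_wavelet(half, a)
    kern <- numeric(n)
    idx <- ((seq_along(w) - half - 1L) %% n) + 1L
    for (j in seq_along(w)) kern[idx[j]] <- kern[idx[j]] + w[j]
    out[i, ] <- Re(stats::fft(fx * Conj(stats::fft(kern)), inverse = TRUE)) / n
  }
  out
}

running_any <- function(v, d) {
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - d, 1L); hi <- pmin(seq_len(n) + d, n)
  (cs[hi + 1L] - cs[lo]) > 0
}

#' Wavelet-based calcium transient detection
#'
#' Computes a continuous wavelet transform of the ΔF/F trace with a
#' Mexican-hat mother wavelet over a geometric grid of scales. The noise
#' floor of each scale is the median absolute deviation of its coefficients
#' (scaled by 1/0.6745 to estimate a Gaussian sd). A candidate event needs
#' (i) ridge support: coefficients above `k_ridge` times the noise floor at
#' `min_scales` or more contiguous scales (allowing a scale-proportional
#' time jitter), and (ii) a peak coefficient of at least `k_peak` noise
#' floors within half a second. Event frames are coefficient maxima of the
#' finest scales, where the response tracks the transient onset most
#' closely; candidates closer than the refractory interval are merged
#' keeping the larger coefficient. Both thresholds scale with the noise
#' floor, so detections are invariant to rescaling of the trace.
#'
#' @param trace a `fluorescence_trace` from [extract_trace()], or a numeric
#'   ΔF/F vector.
#' @param frame_rate sampling rate (Hz); taken from the trace if present.
#' @param scale_range wavelet scale range in seconds; should span the
#'   transient's rise-to-peak width (default 0.1-1.2 s).
#' @param n_scales number of geometrically spaced scales.
#' @param k_ridge per-scale threshold (noise-floor multiples) for ridge
#'   support.
#' @param k_peak peak-coefficient requirement (noise-floor multiples).
#' @param min_scales minimum number of contiguous scales in the ridge.
#' @param refractory minimum event separation (s).
#' @param fine_threshold threshold (noise-floor multiples) on the fine-scale
#'   localization statistic.
#' @param n_fine number of finest scales averaged for localization.
#' @return list of class `spike_train` with `event_frames` (1-based, sorted),
#'   `event_times` (= (frame - 1) / frame_rate, seconds) and `frame_rate`.
#' @export
detect_spikes_wavelet <- function(trace, frame_rate = NULL,
                                  scale_range = c(0.1, 1.2), n_scales = 8L,
                                  k_ridge = 3.5, k_peak = 5.5,
                                  min_scales = 3L, refractory = 0.25,
                                  fine_threshold = 2.8, n_fine = 3L) {
  dff <- if (inherits(trace, "fluorescence_trace")) trace$dff else as.numeric(trace)
  if (is.null(frame_rate)) {
    if (!inherits(trace, "fluorescence_trace"))
      stop("frame_rate required when passing a bare numeric trace")
    frame_rate <- trace$frame_rate
  }
  if (length(dff) == 0L) stop("empty trace")
  empty <- structure(list(event_frames = integer(0), event_times = numeric(0),
                          frame_rate = frame_rate), class = "spike_train")
  n <- length(dff)
  scales <- exp(seq(log(scale_range[1L] * frame_rate),
                    log(scale_range[2L] * frame_rate), length.out = n_scales))
  if (n < 4 * max(scales)) {
    # trace too short for the requested scales
    return(empty)
  }
  C <- cwt_ricker(dff, scales)
  noise <- apply(C, 1L, stats::mad)
  # degenerate (constant) traces: coefficients are pure FFT round-off, with
  # a noise floor at machine precision relative to the trace magnitude
  tol <- 1e-9 * max(abs(dff)) + .Machine$double.xmin
  if (all(noise <= tol) || max(abs(C)) <= tol) return(empty)
  noise[noise <= tol] <- Inf
  Z <- C / noise
  exc <- Z > k_ridge
  for (i in seq_along(scales))
    exc[i, ] <- running_any(exc[i, ], ceiling(scales[i] / 2))
  run <- matrix(0, n_scales, n)
  run[1L, ] <- exc[1L, ]
  for (i in seq_len(n_scales)[-1L]) run[i, ] <- ifelse(exc[i, ], run[i - 1L, ] + 1, 0)
  ridge_len <- apply(run, 2L, max)
  strength <- apply(Z, 2L, max)
  w <- round(0.5 * frame_rate)
  cand <- ridge_len >= min_scales &
    vapply(seq_len(n), function(t) max(strength[max(1L, t - w):min(n, t + w)]),
           numeric(1L)) >= k_peak
  fine <- colMeans(Z[seq_len(min(n_fine, n_scales)), , drop = FALSE])
  is_max <- fine >= c(-Inf, fine[-n]) & fine > c(fine[-1L], -Inf)
  ev <- which(cand & is_max & fine > fine_threshold)
  if (!length(ev)) return(empty)
  rf <- round(refractory * frame_rate)
  keep <- integer(0)
  for (e in ev[order(-fine[ev])])
    if (!length(keep) || !any(abs(keep - e) < rf)) keep <- c(keep, e)
  keep <- sort(keep)
  structure(list(event_frames = keep, event_times = (keep - 1) / frame_rate,
                 frame_rate = frame_rate), class = "spike_train")
}

#' Pool spike trains into a well-level activity summary
#'
#' Events from all positions of a well are summed (not averaged) and divided
#' by the recording duration to give the total spike frequency; dividing by
#' the total number of detected cells gives the mean frequency per cell.
#'
#' @param trains list of `spike_train`s (one per ROI, pooled across
#'   positions).
#' @param n_cells_total number of cells detected in all positions.
#' @param duration recording duration per position (s).
#' @return list of class `activity_summary` with `n_events`,
#'   `total_spike_frequency` (Hz), `n_cells` and `mean_frequency_per_cell`
#'   (Hz).
#' @export
summarize_activity <- function(trains, n_cells_total, duration) {
  if (duration <= 0) stop("duration must be positive")
  n_events <- sum(vapply(trains, function(tr) length(tr$event_frames), integer(1L)))
  if (n_cells_total == 0L && n_events > 0L)
    stop("events detected but n_cells_total is zero")
  total <- n_events / duration
  structure(list(n_events = n_events, total_spike_frequency = total,
                 n_cells = n_cells_total,
                 mean_frequency_per_cell = if (n_cells_total > 0L) total / n_cells_total else 0),
            class = "activity_summary")
}

#' Full activity analysis of one calcium movie
#'
#' Summary image, segmentation, trace extraction and spike detection in one
#' call.
#'
#' @param movie a [calcium_movie()].
#' @param spec segmentation [threshold_spec()].
#' @param ... passed to [detect_spikes_wavelet()].
#' @return list with `rois`, `traces`, `trains` and `summary`
#'   (an [summarize_activity()] result for this single position).
#' @export
analyze_movie <- function(movie, spec = threshold_spec(k_mad = 8), ...) {
  si <- summary_image(movie)
  rois <- segment_cells(si, spec)
  traces <- lapply(rois, function(r) extract_trace(movie, r))
  trains <- lapply(traces, detect_spikes_wavelet, ...)
  list(rois = rois, traces = traces, trains = trains,
       summary = summarize_activity(trains, length(rois), movie$duration))
}

#' Run the activity analysis over a generated dataset
#'
#' Analyzes every position movie of every well and pools positions per well
#' as in [summarize_activity()]. Wells without movies are skipped.
#'
#' @param dataset_dir dataset root from [generate_experiment()] (with the
#'   `"activity"` assay).
#' @param spec segmentation [threshold_spec()].
#' @param out_dir directory for the result CSV.
#' @param ... passed to [detect_spikes_wavelet()].
#' @return data frame with one row per well: `n_events`, `n_cells`,
#'   `total_spike_frequency`, `mean_frequency_per_cell`, plus fold change of
#'   the per-cell frequency within biological replicate; written to
#'   `activity_wells.csv`.
#' @export
run_activity_analysis <- function(dataset_dir, spec = threshold_spec(k_mad = 8),
                                  out_dir = dataset_dir, ...) {
  design <- utils::read.csv(file.path(dataset_dir, "design.csv"))
  rows <- list()
  for (w in seq_len(nrow(design))) {
    row <- design[w, ]
    wdir <- file.path(dataset_dir, "wells", row$well_id)
    movies <- sort(list.files(wdir, pattern = "^position\\d+_calcium\\.tif$",
                              full.names = TRUE))
    if (!length(movies)) next
    trains <- list(); n_cells <- 0L
    for (mv in movies) {
      res <- analyze_movie(read_movie(mv, row$frame_rate), spec, ...)
      trains <- c(trains, res$trains)
      n_cells <- n_cells + length(res$rois)
    }
    s <- summarize_activity(trains, n_cells, row$movie_duration)
    rows[[length(rows) + 1L]] <- data.frame(
      well_id = row$well_id, condition = row$condition, density = row$density,
      biological = row$biological, technical = row$technical,
      n_events = s$n_events, n_cells = s$n_cells,
      total_spike_frequency = s$total_spike_frequency,
      mean_frequency_per_cell = s$mean_frequency_per_cell)
  }
  if (!length(rows)) return(invisible(NULL))
  wells <- do.call(rbind, rows)
  wells <- fold_change(wells, "mean_frequency_per_cell")
  utils::write.csv(wells, file.path(out_dir, "activity_wells.csv"), row.names = FALSE)
  wells
}
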