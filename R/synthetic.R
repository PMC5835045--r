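# Synthetic microscopy with known ground truth.
#
# The generators emulate the data structure of a multi-well co-culture
# experiment: nuclei/dead/live stained fields at seeding densities from
# 1,000 to 50,000 cells/cm^2, neurite-stain images with analytically known
# polyline length, and GCaMP-like calcium recordings (2 min at 32 Hz) with
# Poisson spike trains convolved with a difference-of-exponentials transient.
# Every generator records its ground truth so each analysis stage can be
# scored against what was actually drawn.

# dart-throwing placement with a minimum center-to-center spacing.
# Returns an n x 2 matrix of (x, y) coordinates; errors if the requested
# number of points cannot be placed.
place_centers <- function(n, shape, min_spacing, margin) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  H <- shape[1L]; W <- shape[2L]
  if (W - 2 * margin < 1 || H - 2 * margin < 1)
    stop("field too small for the requested margin")
  xs <- numeric(n); ys <- numeric(n); placed <- 0L
  tries <- 0L; max_tries <- 2000L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf("could not place %d centers at min spacing %.1f px", n, min_spacing))
    x <- stats::runif(1L, 1 + margin, W - margin)
    y <- stats::runif(1L, 1 + margin, H - margin)
    if (placed == 0L ||
        min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >= min_spacing^2) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
    }
  }
  cbind(x = xs, y = ys)
}

# add isotropic Gaussian spots of peak height `amplitude` to a matrix
render_spots <- function(mat, centers, sigma, amplitude) {
  if (nrow(centers) == 0L) return(mat)
  H <- nrow(mat); W <- ncol(mat)
  r <- ceiling(4 * sigma)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1L]; cy <- centers[i, 2L]
    x0 <- max(1L, floor(cx) - r); x1 <- min(W, ceiling(cx) + r)
    y0 <- max(1L, floor(cy) - r); y1 <- min(H, ceiling(cy) + r)
    gx <- exp(-((x0:x1) - cx)^2 / (2 * sigma^2))
    gy <- exp(-((y0:y1) - cy)^2 / (2 * sigma^2))
    mat[y0:y1, x0:x1] <- mat[y0:y1, x0:x1] + amplitude * outer(gy, gx)
  }
  mat
}

#' Generate a synthetic live/dead stained nuclei field
#'
#' Draws `n_cells` nuclei as Gaussian spots on a noisy background. A fixed
#' fraction of cells is flagged dead: dead cells additionally appear in the
#' dead channel, live cells in the live channel (the live channel mirrors the
#' esterase stain and is generated for visual parity only; the counting
#' pipeline never uses it). Centers respect a minimum spacing, except for an
#' optional fraction placed as close overlapping pairs to exercise
#' declumping.
#'
#' @param n_cells number of nuclei to place.
#' @param dead_fraction fraction of cells flagged dead, in \[0, 1\];
#'   `round(n_cells * dead_fraction)` cells are dead.
#' @param image_shape `c(height, width)` in pixels.
#' @param pixel_size um per pixel.
#' @param spot_sigma Gaussian spot standard deviation in pixels.
#' @param contrast peak spot height expressed as a multiple of `noise_sd`.
#' @param noise_sd Gaussian background noise standard deviation (intensity
#'   counts).
#' @param baseline background intensity level (counts).
#' @param min_spacing minimum center-to-center distance in pixels.
#' @param overlap_fraction fraction of cells placed as members of close pairs
#'   (center distance 1.2-2 `spot_sigma`), producing touching objects.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param channels which channels to render (ground truth is unaffected);
#'   rendering fewer channels is purely a compute saving.
#' @return A list with micrographs `nuclei`, `dead`, `live` (NULL when not
#'   rendered) and `truth`, a `ground_truth_field` containing `centers`
#'   (n x 2 matrix of (x, y)), logical `dead_flags` and `field_area` (cm^2).
#' @export
generate_nuclei_field <- function(n_cells, dead_fraction = 0.2,
                                  image_shape = c(512L, 512L),
                                  pixel_size = 1.3, spot_sigma = 3,
                                  contrast = 10, noise_sd = 10,
                                  baseline = 1000, min_spacing = 12,
                                  overlap_fraction = 0, seed = NULL,
                                  channels = c("nuclei", "dead", "live")) {
  if (dead_fraction < 0 || dead_fraction > 1) stop("dead_fraction must be in [0, 1]")
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  H <- image_shape[1L]; W <- image_shape[2L]
  margin <- ceiling(3 * spot_sigma)

  n_pair <- round(n_cells * overlap_fraction / 2)
  n_base <- n_cells - n_pair
  centers <- place_centers(n_base, image_shape, min_spacing, margin)
  if (n_pair > 0L) {
    # partners placed next to existing centers, inside bounds
    idx <- sample.int(n_base, n_pair)
    ang <- stats::runif(n_pair, 0, 2 * pi)
    d <- stats::runif(n_pair, 2 * spot_sigma, 3.3 * spot_sigma)
    px <- pmin(pmax(centers[idx, 1L] + d * cos(ang), 1 + margin), W - margin)
    py <- pmin(pmax(centers[idx, 2L] + d * sin(ang), 1 + margin), H - margin)
    centers <- rbind(centers, cbind(x = px, y = py))
  }

  n_dead <- round(n_cells * dead_fraction)
  dead_flags <- rep(FALSE, n_cells)
  if (n_cells > 0L && n_dead > 0L) dead_flags[sample.int(n_cells, n_dead)] <- TRUE

  amp <- contrast * noise_sd
  mk <- function(chan, sel) {
    if (!chan %in% channels) return(NULL)
    m <- baseline + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
    m <- render_spots(m, centers[sel, , drop = FALSE], spot_sigma, amp)
    micrograph(pmax(m, 0), pixel_size, chan)
  }
  truth <- structure(list(centers = centers, dead_flags = dead_flags,
                          field_area = H * W * pixel_size^2 / 1e8),
                     class = "ground_truth_field")
  list(nuclei = mk("nuclei", rep(TRUE, n_cells)),
       dead = mk("dead", dead_flags),
       live = mk("live", !dead_flags),
       truth = truth)
}

# sample points along a polyline and splat a Gaussian cross-profile onto a
# clean canvas; max-blending keeps the line core at ~`amplitude` regardless
# of sampling density, giving anti-aliased ~2 px wide curves whose
# brightness does not dip where the line passes between pixel centers
rasterize_polyline <- function(mat, verts, amplitude, step = 0.35, sigma = 0.6) {
  H <- nrow(mat); W <- ncol(mat)
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(nrow(verts) - 1L)) {
    p0 <- verts[i, ]; p1 <- verts[i + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    if (len == 0) next
    ts <- seq(0, 1, by = step / len)
    xs <- c(xs, p0[1L] + ts * (p1[1L] - p0[1L]))
    ys <- c(ys, p0[2L] + ts * (p1[2L] - p0[2L]))
  }
  if (!length(xs)) return(mat)
  idx <- numeric(0); val <- numeric(0)
  for (dx in -1:1) for (dy in -1:1) {
    xi <- round(xs) + dx; yi <- round(ys) + dy
    ok <- xi >= 1 & xi <= W & yi >= 1 & yi <= H
    if (!any(ok)) next
    d2 <- (xi[ok] - xs[ok])^2 + (yi[ok] - ys[ok])^2
    idx <- c(idx, (xi[ok] - 1) * H + yi[ok])
    val <- c(val, amplitude * exp(-d2 / (2 * sigma^2)))
  }
  # ascending write order makes duplicate indices resolve to their maximum
  o <- order(val)
  idx <- idx[o]; val <- val[o]
  mat[idx] <- pmax(mat[idx], val)
  mat
}

#' Generate a synthetic neurite-stain field with known total length
#'
#' Each cell gets a soma (rendered in the nuclei channel) and 2-4 neurites
#' grown as persistent random walks. The true total length is the exact sum
#' of Euclidean segment lengths of all polylines, recorded from the vertex
#' geometry before rasterization, times the pixel size.
#'
#' @param n_cells number of cells.
#' @param mean_length_per_cell target total neurite length per cell (um).
#' @param image_shape,pixel_size,seed as in [generate_nuclei_field()].
#' @param noise_sd background noise (counts); neurite line intensity is
#'   20x `noise_sd` per raster sample, soma spots as in the nuclei generator.
#' @param baseline background level (counts).
#' @param step_px random-walk step length in pixels.
#' @param turn_sd direction change per step (radians).
#' @return list with micrographs `neurite`, `nuclei` and `truth`
#'   (`ground_truth_neurites`: `polylines`, a list of vertex matrices, and
#'   `true_total_length` in um).
#' @export
generate_neurite_field <- function(n_cells, mean_length_per_cell = 200,
                                   image_shape = c(512L, 512L),
                                   pixel_size = 1.3, noise_sd = 10,
                                   baseline = 1000, step_px = 4,
                                   turn_sd = 0.25, seed = NULL) {
  if (mean_length_per_cell < 0) stop("mean_length_per_cell must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  H <- image_shape[1L]; W <- image_shape[2L]
  margin <- 10
  somata <- place_centers(n_cells, image_shape, 25, margin)
  polylines <- list()
  total_px <- 0
  if (n_cells > 0L && mean_length_per_cell > 0) {
    target_px <- mean_length_per_cell / pixel_size
    for (i in seq_len(n_cells)) {
      nb <- sample(2:4, 1L)
      share <- as.numeric(stats::rmultinom(1L, 100L, rep(1, nb))) / 100
      for (b in seq_len(nb)) {
        want <- target_px * share[b]
        if (want < step_px) next
        theta <- stats::runif(1L, 0, 2 * pi)
        v <- somata[i, , drop = FALSE]
        got <- 0
        while (got < want) {
          theta <- theta + stats::rnorm(1L, 0, turn_sd)
          nxt <- v[nrow(v), ] + step_px * c(cos(theta), sin(theta))
          if (nxt[1L] < margin || nxt[1L] > W - margin ||
              nxt[2L] < margin || nxt[2L] > H - margin) break
          v <- rbind(v, nxt)
          got <- got + step_px
        }
        if (nrow(v) > 1L) {
          polylines[[length(polylines) + 1L]] <- unname(v)
          d <- diff(v)
          total_px <- total_px + sum(sqrt(rowSums(d^2)))
        }
      }
    }
  }
  canvas <- matrix(0, H, W)
  for (p in polylines) canvas <- rasterize_polyline(canvas, p, 20 * noise_sd)
  neur <- baseline + canvas + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
  nuc <- baseline + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
  nuc <- render_spots(nuc, somata, 3, 10 * noise_sd)
  truth <- structure(list(polylines = polylines,
                          true_total_length = total_px * pixel_size),
                     class = "ground_truth_neurites")
  list(neurite = micrograph(pmax(neur, 0), pixel_size, "neurite"),
       nuclei = micrograph(pmax(nuc, 0), pixel_size, "nuclei"),
       truth = truth)
}

# difference-of-exponentials calcium transient, normalized to unit peak
transient_kernel <- function(t, tau_rise, tau_decay) {
  tpk <- log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
  pk <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  out <- numeric(length(t))
  m <- t >= 0
  out[m] <- (exp(-t[m] / tau_decay) - exp(-t[m] / tau_rise)) / pk
  out
}

#' Generate synthetic ΔF/F fluorescence traces with known spike times
#'
#' Per-cell homogeneous Poisson spike trains are convolved with a
#' difference-of-exponentials transient (defaults emulate a slow genetically
#' encoded indicator: rise 0.18 s, decay 0.55 s, 0.2 ΔF/F amplitude) and
#' Gaussian noise is added. This is the trace-level core of
#' [generate_calcium_movie()], useful when the spatial dimension is not
#' needed.
#'
#' @param n_cells number of cells/traces.
#' @param firing_rate homogeneous Poisson rate per cell (Hz).
#' @param duration recording length (s); must be positive.
#' @param frame_rate sampling rate (Hz).
#' @param tau_rise,tau_decay transient rise/decay time constants (s),
#'   `tau_decay > tau_rise > 0`.
#' @param amplitude single-transient peak (ΔF/F units).
#' @param noise_sd additive Gaussian noise on the trace (ΔF/F units).
#' @param seed integer seed.
#' @return list with `dff` (frames x cells matrix) and `spike_times`
#'   (list of sorted spike times per cell, seconds).
#' @export
generate_calcium_traces <- function(n_cells, firing_rate, duration = 120,
                                    frame_rate = 32, tau_rise = 0.18,
                                    tau_decay = 0.55, amplitude = 0.2,
                                    noise_sd = 0.04, seed = NULL) {
  if (duration <= 0) stop("duration must be positive")
  if (!(tau_decay > tau_rise && tau_rise > 0)) stop("need tau_decay > tau_rise > 0")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_frames <- round(duration * frame_rate)
  tt <- (seq_len(n_frames) - 1) / frame_rate
  dff <- matrix(stats::rnorm(n_frames * n_cells, 0, noise_sd), n_frames, n_cells)
  spike_times <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    nsp <- stats::rpois(1L, firing_rate * duration)
    st <- sort(stats::runif(nsp, 0, duration))
    spike_times[[i]] <- st
    for (s in st) dff[, i] <- dff[, i] + amplitude * transient_kernel(tt - s, tau_rise, tau_decay)
  }
  list(dff = dff, spike_times = spike_times, frame_rate = frame_rate,
       duration = duration)
}

#' Generate a synthetic calcium-imaging movie with known activity
#'
#' Cells are rendered as disk footprints whose intensity follows
#' `baseline * (1 + ΔF/F(t))`; the background sits at a slightly lower
#' constant level. Gaussian noise of `noise_sd` (ΔF/F units, relative to the
#' resting cell fluorescence) is added per pixel, so footprint-averaged
#' traces carry correspondingly less noise - as in real recordings, where
#' ROI averaging suppresses camera noise.
#'
#' @inheritParams generate_calcium_traces
#' @param image_shape `c(height, width)` pixels.
#' @param cell_radius footprint disk radius (px).
#' @param cell_baseline,bg_level resting intensity inside/outside cells
#'   (counts).
#' @param pixel_size um per pixel.
#' @return list with `movie` (a [calcium_movie()]) and `truth`
#'   (`ground_truth_activity`: `footprints`, a list of pixel-index vectors
#'   into the frame matrix, `centers`, and `spike_times` per cell).
#' @export
generate_calcium_movie <- function(n_cells = 12, firing_rate = 0.1,
                                   duration = 120, frame_rate = 32,
                                   tau_rise = 0.18, tau_decay = 0.55,
                                   amplitude = 0.2, noise_sd = 0.04,
                                   image_shape = c(64L, 64L), cell_radius = 3,
                                   cell_baseline = 1000, bg_level = 900,
                                   pixel_size = 1.3, seed = NULL) {
  if (duration <= 0) stop("duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  H <- image_shape[1L]; W <- image_shape[2L]
  centers <- place_centers(n_cells, image_shape, 3.2 * cell_radius,
                           cell_radius + 2)
  xg <- matrix(seq_len(W), H, W, byrow = TRUE)
  yg <- matrix(seq_len(H), H, W)
  footprints <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    footprints[[i]] <- which((xg - centers[i, 1L])^2 + (yg - centers[i, 2L])^2
                             <= cell_radius^2)
  }
  # noiseless dff: the trace-level noise target is realized through pixel
  # noise averaged over the footprint, not injected twice
  tr <- generate_calcium_traces(n_cells, firing_rate, duration, frame_rate,
                                tau_rise, tau_decay, amplitude, noise_sd = 0,
                                seed = NULL)
  n_frames <- nrow(tr$dff)
  # per-pixel noise as a fraction of resting cell fluorescence; the
  # footprint-averaged trace noise is correspondingly ~noise_sd/sqrt(area)
  px_noise <- noise_sd * cell_baseline
  base_img <- matrix(bg_level, H, W)
  for (i in seq_len(n_cells)) base_img[footprints[[i]]] <- cell_baseline
  frames <- array(0, dim = c(H, W, n_frames))
  for (t in seq_len(n_frames)) {
    f <- base_img
    for (i in seq_len(n_cells))
      f[footprints[[i]]] <- cell_baseline * (1 + tr$dff[t, i])
    frames[, , t] <- round(pmax(f + matrix(stats::rnorm(H * W, 0, px_noise), H, W), 0))
  }
  truth <- structure(list(footprints = footprints, centers = centers,
                          spike_times = tr$spike_times),
                     class = "ground_truth_activity")
  list(movie = calcium_movie(frames, frame_rate), truth = truth)
}

#' Experiment design of a multi-well co-culture comparison
#'
#' Bookkeeping for the condition x density x replicate structure: which
#' seeding densities are compared, how many biological replicates (independent
#' cell preparations) each consisting of how many technical replicates
#' (wells), how many stained fields are imaged per well for viability and
#' neurites, and how calcium recordings are acquired. Defaults follow the
#' published design this package emulates: six densities from 1,000 to 50,000
#' cells/cm^2, co-culture vs control, 2 biological x 5 technical replicates,
#' 3 randomized positions per well, and 2-minute recordings at 32 Hz.
#'
#' @param densities seeding densities (cells/cm^2).
#' @param conditions condition labels; first is treated as the treatment,
#'   `control_label` must be among them.
#' @param n_biological,n_technical replicate counts.
#' @param fields_per_well stained fields imaged per well.
#' @param positions_per_well calcium recording positions per well.
#' @param movie_duration recording duration (s).
#' @param frame_rate acquisition rate (Hz).
#' @param control_label name of the control condition.
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(densities = c(1000, 2500, 5000, 10000, 20000, 50000),
                              conditions = c("coculture", "control"),
                              n_biological = 2L, n_technical = 5L,
                              fields_per_well = 3L, positions_per_well = 3L,
                              movie_duration = 120, frame_rate = 32,
                              control_label = "control") {
  if (any(densities <= 0)) stop("densities must be positive")
  if (n_biological < 1L || n_technical < 1L) stop("replicate counts must be >= 1")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (!control_label %in% conditions) stop("control_label must be one of 'conditions'")
  structure(list(densities = densities, conditions = conditions,
                 n_biological = as.integer(n_biological),
                 n_technical = as.integer(n_technical),
                 fields_per_well = as.integer(fields_per_well),
                 positions_per_well = as.integer(positions_per_well),
                 movie_duration = movie_duration, frame_rate = frame_rate,
                 control_label = control_label),
            class = "experiment_design")
}

#' Default condition curves of the synthetic experiment
#'
#' Viability (fraction) and per-cell firing rate (Hz) by seeding density for
#' the co-culture and control conditions. The shapes transcribe the published
#' trends the generator emulates: co-culture viability rises to a plateau of
#' ~0.91 at 10,000 cells/cm^2 and stays near 0.70 even for isolated cells at
#' 1,000 cells/cm^2, while control viability climbs only mildly (0.69 at
#' 10,000 cells/cm^2); activity increases with density and co-culture roughly
#' doubles the per-cell rate at the low end.
#'
#' @param densities seeding densities at which the curve is tabulated.
#' @return named list of named numeric vectors, one per condition.
#' @export
default_viability_curve <- function(densities = c(1000, 2500, 5000, 10000, 20000, 50000)) {
  co <- stats::approx(c(1000, 2500, 5000, 10000, 20000, 50000),
                      c(0.70, 0.78, 0.85, 0.91, 0.91, 0.92),
                      xout = densities, rule = 2)$y
  ct <- stats::approx(c(1000, 2500, 5000, 10000, 20000, 50000),
                      c(0.50, 0.57, 0.62, 0.69, 0.72, 0.75),
                      xout = densities, rule = 2)$y
  list(coculture = stats::setNames(co, densities),
       control = stats::setNames(ct, densities))
}

#' @rdname default_viability_curve
#' @export
default_activity_curve <- function(densities = c(1000, 2500, 5000, 10000, 20000, 50000)) {
  co <- stats::approx(c(1000, 2500, 5000, 10000, 20000, 50000),
                      c(0.06, 0.08, 0.10, 0.12, 0.14, 0.15),
                      xout = densities, rule = 2)$y
  ct <- stats::approx(c(1000, 2500, 5000, 10000, 20000, 50000),
                      c(0.02, 0.03, 0.05, 0.08, 0.10, 0.12),
                      xout = densities, rule = 2)$y
  list(coculture = stats::setNames(co, densities),
       control = stats::setNames(ct, densities))
}

well_id <- function(condition, density, b, t) {
  sprintf("%s_d%05d_b%d_t%d", condition, density, b, t)
}

#' Generate a full synthetic experiment on disk
#'
#' Emits one folder per well containing the per-field channel TIFFs (and,
#' when the activity assay is requested, one movie stack per position), plus
#' a design table, per-field and per-well ground-truth tables, and a JSON
#' manifest recording the seed and all generator parameters. The number of
#' cells per field is drawn as Poisson(density x field area); the per-well
#' dead fraction is `1 - viability_curve[[condition]][density]`.
#'
#' @param design an [experiment_design()].
#' @param out_dir output directory; must not exist unless `overwrite = TRUE`.
#' @param viability_curve,activity_curve named per-condition curves as
#'   produced by [default_viability_curve()] / [default_activity_curve()];
#'   must cover every density in the design.
#' @param assays subset of `c("viability", "neurite", "activity")`.
#' @param seed integer master seed; all per-well seeds derive from it.
#' @param overwrite replace an existing dataset.
#' @param image_shape,pixel_size field geometry.
#' @param mean_neurite_length_per_cell control-condition neurite length per
#'   cell (um); co-culture wells get 1.15x, a slight positive offset
#'   mirroring the reported trend.
#' @param movie_shape,movie_cells geometry of activity recordings.
#' @param ... passed to [generate_nuclei_field()] (e.g. `contrast`,
#'   `noise_sd`, `spot_sigma`).
#' @return invisibly, a list with the design and truth data frames and the
#'   manifest path.
#' @export
generate_experiment <- function(design = experiment_design(),
                                out_dir,
                                viability_curve = default_viability_curve(design$densities),
                                activity_curve = default_activity_curve(design$densities),
                                assays = c("viability", "neurite"),
                                seed = 1L, overwrite = FALSE,
                                image_shape = c(512L, 512L), pixel_size = 1.3,
                                mean_neurite_length_per_cell = 200,
                                movie_shape = c(64L, 64L), movie_cells = 10L,
                                ...) {
  stopifnot(inherits(design, "experiment_design"))
  assays <- match.arg(assays, c("viability", "neurite", "activity"),
                      several.ok = TRUE)
  for (cond in design$conditions) {
    if (!all(as.character(design$densities) %in% names(viability_curve[[cond]])))
      stop("viability_curve must cover every density for condition ", cond)
  }
  if (dir.exists(out_dir)) {
    if (!overwrite) stop("'", out_dir, "' exists; use overwrite = TRUE")
    unlink(out_dir, recursive = TRUE)
  }
  dir.create(out_dir, recursive = TRUE)
  dir.create(file.path(out_dir, "wells"))

  area <- prod(image_shape) * pixel_size^2 / 1e8
  grid <- expand.grid(technical = seq_len(design$n_technical),
                      biological = seq_len(design$n_biological),
                      density = design$densities,
                      condition = design$conditions,
                      stringsAsFactors = FALSE)
  grid$well_id <- with(grid, well_id(condition, density, biological, technical))

  design_rows <- list(); field_rows <- list(); well_rows <- list()
  set.seed(seed)
  well_seeds <- sample.int(.Machine$integer.max, nrow(grid))
  for (w in seq_len(nrow(grid))) {
    g <- grid[w, ]
    wdir <- file.path(out_dir, "wells", g$well_id)
    dir.create(wdir)
    true_viab <- viability_curve[[g$condition]][[as.character(g$density)]]
    set.seed(well_seeds[w])
    fseeds <- sample.int(.Machine$integer.max, design$fields_per_well + design$positions_per_well + 1L)
    n_tot <- 0L; n_dead <- 0L; neur_len <- 0
    for (f in seq_len(design$fields_per_well)) {
      set.seed(fseeds[f])
      n <- stats::rpois(1L, g$density * area)
      fld <- generate_nuclei_field(n, dead_fraction = 1 - true_viab,
                                   image_shape = image_shape,
                                   pixel_size = pixel_size, seed = NULL, ...)
      if ("viability" %in% assays) {
        write_micrograph(fld$nuclei, file.path(wdir, sprintf("field%d_nuclei.tif", f)))
        write_micrograph(fld$dead, file.path(wdir, sprintf("field%d_dead.tif", f)))
        write_micrograph(fld$live, file.path(wdir, sprintf("field%d_live.tif", f)))
      }
      tl <- NA_real_
      if ("neurite" %in% assays) {
        ml <- mean_neurite_length_per_cell *
          if (g$condition == design$control_label) 1 else 1.15
        nf <- generate_neurite_field(max(n, 1L), mean_length_per_cell = ml,
                                     image_shape = image_shape,
                                     pixel_size = pixel_size, seed = NULL)
        write_micrograph(nf$neurite, file.path(wdir, sprintf("field%d_neurite.tif", f)))
        tl <- nf$truth$true_total_length
        neur_len <- neur_len + tl
      }
      n_tot <- n_tot + n
      n_dead <- n_dead + sum(fld$truth$dead_flags)
      field_rows[[length(field_rows) + 1L]] <- data.frame(
        well_id = g$well_id, field = f, n_cells = n,
        n_dead = sum(fld$truth$dead_flags), area_cm2 = area,
        true_neurite_length_um = tl)
    }
    true_rate <- NA_real_
    if ("activity" %in% assays) {
      true_rate <- activity_curve[[g$condition]][[as.character(g$density)]]
      for (p in seq_len(design$positions_per_well)) {
        set.seed(fseeds[design$fields_per_well + p])
        mv <- generate_calcium_movie(n_cells = movie_cells,
                                     firing_rate = true_rate,
                                     duration = design$movie_duration,
                                     frame_rate = design$frame_rate,
                                     image_shape = movie_shape,
                                     pixel_size = pixel_size, seed = NULL)
        write_movie(mv$movie, file.path(wdir, sprintf("position%d_calcium.tif", p)))
      }
    }
    design_rows[[w]] <- data.frame(
      well_id = g$well_id, condition = g$condition, density = g$density,
      biological = g$biological, technical = g$technical,
      n_fields = design$fields_per_well, pixel_size = pixel_size,
      frame_rate = design$frame_rate, movie_duration = design$movie_duration)
    well_rows[[w]] <- data.frame(
      well_id = g$well_id, condition = g$condition, density = g$density,
      biological = g$biological, technical = g$technical,
      true_viability = true_viab, n_cells = n_tot, n_dead = n_dead,
      true_neurite_length_um = if ("neurite" %in% assays) neur_len else NA_real_,
      true_firing_rate = true_rate)
  }
  design_df <- do.call(rbind, design_rows)
  truth_wells <- do.call(rbind, well_rows)
  truth_fields <- do.call(rbind, field_rows)
  utils::write.csv(design_df, file.path(out_dir, "design.csv"), row.names = FALSE)
  utils::write.csv(truth_wells, file.path(out_dir, "truth_wells.csv"), row.names = FALSE)
  utils::write.csv(truth_fields, file.path(out_dir, "truth_fields.csv"), row.names = FALSE)
  manifest <- list(seed = seed, assays = assays,
                   image_shape = image_shape, pixel_size = pixel_size,
                   densities = design$densities,
                   conditions = design$conditions,
                   n_biological = design$n_biological,
                   n_technical = design$n_technical,
                   fields_per_well = design$fields_per_well,
                   generated = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(design = design_df, truth_wells = truth_wells,
                 truth_fields = truth_fields,
                 manifest = file.path(out_dir, "manifest.json")))
}
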