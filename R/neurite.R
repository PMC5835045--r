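# Neurite length measurement: threshold -> skeletonize -> sum step lengths.
#
# The neurite channel is binarized with a threshold shared across all images
# of a condition (resolved once on a reference image), morphologically
# thinned to 1-px-wide centerlines, and the total length is the sum over
# skeleton pixel adjacencies of the step length: 1 px for 4-neighbors and
# sqrt(2) px for diagonal neighbors, times the pixel size. Cell numbers come
# from the nuclei channel via the same counting machinery as the viability
# assay. Comparisons are reported as fold changes computed within each
# biological replicate.

shift_mat <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  ys <- seq_len(H) - dy; xs <- seq_len(W) - dx
  oky <- ys >= 1L & ys <= H; okx <- xs >= 1L & xs <= W
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

#' Morphological thinning of a binary image (Zhang-Suen)
#'
#' Iteratively peels boundary pixels in two subiterations until stable,
#' reducing connected structures to 1-pixel-wide 8-connected centerlines
#' while preserving connectivity.
#'
#' @param binary 0/1 matrix.
#' @return 0/1 integer matrix of the same shape containing the skeleton.
#' @export
skeletonize <- function(binary) {
  M <- matrix(as.integer(binary != 0), nrow(binary), ncol(binary))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbors clockwise from north: P2..P9
      P2 <- shift_mat(M, -1L, 0L); P3 <- shift_mat(M, -1L, 1L)
      P4 <- shift_mat(M, 0L, 1L);  P5 <- shift_mat(M, 1L, 1L)
      P6 <- shift_mat(M, 1L, 0L);  P7 <- shift_mat(M, 1L, -1L)
      P8 <- shift_mat(M, 0L, -1L); P9 <- shift_mat(M, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) +
           (P4 == 0L & P5 == 1L) + (P5 == 0L & P6 == 1L) +
           (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
           (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
      if (sub == 1L) {
        cond <- M == 1L & B >= 2L & B <= 6L & A == 1L &
          (P2 * P4 * P6 == 0L) & (P4 * P6 * P8 == 0L)
      } else {
        cond <- M == 1L & B >= 2L & B <= 6L & A == 1L &
          (P2 * P4 * P8 == 0L) & (P2 * P6 * P8 == 0L)
      }
      if (any(cond)) {
        M[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  prune_staircase(M)
}

# remove residual staircase/corner pixels: a non-endpoint pixel whose
# occupied neighbors already form a single mutually 8-connected cluster is
# redundant - the path continues without it - and would inflate the
# step-length metric. Iterates until stable.
prune_staircase <- function(M) {
  H <- nrow(M); W <- ncol(M)
  off <- cbind(dy = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
               dx = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))
  repeat {
    changed <- FALSE
    for (p in which(M == 1L)) {
      y <- (p - 1L) %% H + 1L; x <- (p - 1L) %/% H + 1L
      if (x < 2L || x > W - 1L || y < 2L || y > H - 1L) next
      nb <- which(M[cbind(y + off[, 1L], x + off[, 2L])] == 1L)
      k <- length(nb)
      if (k < 2L) next
      # neighbors mutually 8-connected without p?
      pos <- off[nb, , drop = FALSE]
      seen <- logical(k); seen[1L] <- TRUE; frontier <- 1L
      while (length(frontier)) {
        nxt <- integer(0)
        for (i in frontier) for (j in which(!seen)) {
          if (max(abs(pos[i, ] - pos[j, ])) <= 1L) { seen[j] <- TRUE; nxt <- c(nxt, j) }
        }
        frontier <- nxt
      }
      if (all(seen)) { M[p] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  M
}

#' Length of a 1-px skeleton under the diagonal-step metric
#'
#' Sums 1 for each orthogonally adjacent skeleton pixel pair and sqrt(2) for
#' each diagonally adjacent pair. A diagonal adjacency is not counted when
#' the two pixels are already connected through a shared orthogonal neighbor
#' (an L-corner), which would otherwise double-count the path.
#'
#' @param skel 0/1 matrix (typically from [skeletonize()]).
#' @param pixel_size um per pixel.
#' @return total length in um.
#' @export
skeleton_length <- function(skel, pixel_size = 1) {
  M <- matrix(as.integer(skel != 0), nrow(skel), ncol(skel))
  H <- nrow(M); W <- ncol(M)
  if (H < 2L || W < 2L) return(0)
  e <- M[, -W] & M[, -1L]                     # east pairs
  s <- M[-H, ] & M[-1L, ]                     # south pairs
  se <- M[-H, -W] & M[-1L, -1L]               # south-east diagonals
  ne <- M[-1L, -W] & M[-H, -1L]               # north-east diagonals
  # bridging orthogonal neighbors of each diagonal pair
  se_bridge <- (M[-H, -1L] | M[-1L, -W]) == 1L
  ne_bridge <- (M[-H, -W] | M[-1L, -1L]) == 1L
  n_orth <- sum(e) + sum(s)
  n_diag <- sum(se & !se_bridge) + sum(ne & !ne_bridge)
  (n_orth + sqrt(2) * n_diag) * pixel_size
}

#' Measure total neurite length and cell count in one image pair
#'
#' @param neurite_img,nuclei_img [micrograph()]s of identical shape and
#'   pixel size.
#' @param neurite_spec,nuclei_spec [threshold_spec()]s; pass absolute-mode
#'   specs produced by [propagate_threshold()] to share thresholds across a
#'   condition.
#' @param min_skeleton_component minimum component area (px) retained in the
#'   binarized neurite mask before thinning (suppresses noise speckles).
#' @param soma_exclusion_radius if positive, pixels within this radius (px)
#'   of a detected nucleus centroid are removed from the skeleton before
#'   length summation, so somata do not contribute; off (0) by default.
#' @return list of class `neurite_measurement` with `total_length` (um),
#'   `n_cells` and `threshold_used`.
#' @export
measure_neurites <- function(neurite_img, nuclei_img,
                             neurite_spec = threshold_spec(),
                             nuclei_spec = threshold_spec(),
                             min_skeleton_component = 10L,
                             soma_exclusion_radius = 0) {
  stopifnot(inherits(neurite_img, "micrograph"), inherits(nuclei_img, "micrograph"))
  if (!identical(dim(neurite_img$pixels), dim(nuclei_img$pixels)))
    stop("neurite and nuclei images must have the same shape")
  if (neurite_img$pixel_size != nuclei_img$pixel_size)
    stop("neurite and nuclei images must have the same pixel size")
  thr <- select_threshold(neurite_img, neurite_spec)
  binary <- (neurite_img$pixels > thr) * 1L
  lab <- EBImage::bwlabel(binary)
  if (max(lab) > 0L) {
    areas <- tabulate(lab, nbins = max(lab))
    drop <- which(areas < min_skeleton_component)
    if (length(drop)) binary[array(lab, dim(lab)) %in% drop] <- 0L
  }
  skel <- skeletonize(binary)
  nuc <- count_objects(nuclei_img, nuclei_spec)
  if (soma_exclusion_radius > 0 && nrow(nuc$centers) > 0L) {
    H <- nrow(skel); W <- ncol(skel)
    idx <- which(skel == 1L)
    ys <- (idx - 1L) %% H + 1L; xs <- (idx - 1L) %/% H + 1L
    for (i in seq_len(nrow(nuc$centers))) {
      hit <- (xs - nuc$centers[i, 1L])^2 + (ys - nuc$centers[i, 2L])^2 <=
        soma_exclusion_radius^2
      skel[idx[hit]] <- 0L
    }
  }
  structure(list(total_length = skeleton_length(skel, neurite_img$pixel_size),
                 n_cells = nuc$count, threshold_used = thr),
            class = "neurite_measurement")
}

#' Propagate a reference threshold across all images of a condition
#'
#' The absolute threshold is resolved on one reference image and reused
#' verbatim for every image of the condition, mirroring the manual practice
#' of setting the threshold once per condition.
#'
#' @param images_in_condition non-empty list of [micrograph()]s.
#' @param reference_index index of the reference image.
#' @param spec a [threshold_spec()] resolved on the reference.
#' @return numeric vector of per-image absolute thresholds (all equal).
#' @export
propagate_threshold <- function(images_in_condition, reference_index = 1L,
                                spec = threshold_spec()) {
  if (length(images_in_condition) == 0L) stop("empty image list")
  if (reference_index < 1L || reference_index > length(images_in_condition))
    stop("reference_index out of range")
  thr <- select_threshold(images_in_condition[[reference_index]], spec)
  rep(thr, length(images_in_condition))
}

#' Fold change relative to control, within biological replicate
#'
#' For each (biological replicate, density) group, every sample's value is
#' divided by the mean of the control samples of that same group, so the mean
#' control fold change is exactly 1 per group by construction. Groups whose
#' control mean is zero (or that lack control samples) are excluded with a
#' warning and flagged.
#'
#' @param data data frame with columns `condition`, `biological`, `density`
#'   and the value column.
#' @param value_col name of the measurement column.
#' @param control_label condition label of the control samples.
#' @return `data` with columns `fold_change` and `fold_flag` appended;
#'   excluded rows carry `NA` fold change.
#' @export
fold_change <- function(data, value_col = "value", control_label = "control") {
  stopifnot(all(c("condition", "biological", "density", value_col) %in% names(data)))
  data$fold_change <- NA_real_
  data$fold_flag <- ""
  for (b in unique(data$biological)) for (d in unique(data$density)) {
    g <- data$biological == b & data$density == d
    if (!any(g)) next
    ctrl <- g & data$condition == control_label
    m <- mean(data[[value_col]][ctrl])
    if (!any(ctrl) || !is.finite(m) || m == 0) {
      warning(sprintf("group (biological=%s, density=%s): control mean is zero or missing; excluded",
                      b, d))
      data$fold_flag[g] <- "zero-control-mean"
      next
    }
    data$fold_change[g] <- data[[value_col]][g] / m
  }
  data
}

#' Run the neurite analysis over a generated dataset
#'
#' Measures total neurite length and cell count for every field, sums them
#' per well, and computes fold changes within biological replicate for both
#' total length and length per cell. The neurite and nuclei thresholds are
#' resolved once per condition on a reference image.
#'
#' @param dataset_dir dataset root from [generate_experiment()].
#' @param neurite_spec,nuclei_spec [threshold_spec()]s.
#' @param out_dir directory for result CSVs.
#' @return data frame with one row per well including `total_length`,
#'   `n_cells`, `length_per_cell` and the two fold-change columns; written
#'   to `neurite_wells.csv`.
#' @export
run_neurite_analysis <- function(dataset_dir,
                                 neurite_spec = threshold_spec(value = 1, k_mad = 8),
                                 nuclei_spec = threshold_spec(),
                                 out_dir = dataset_dir) {
  design <- utils::read.csv(file.path(dataset_dir, "design.csv"))
  conds <- unique(design$condition)
  thr <- lapply(stats::setNames(conds, conds), function(cc) {
    row <- design[design$condition == cc, ][1L, ]
    img <- read_micrograph(file.path(dataset_dir, "wells", row$well_id, "field1_neurite.tif"),
                           row$pixel_size, "neurite")
    threshold_spec("absolute", value = select_threshold(img, neurite_spec),
                   min_object_area = neurite_spec$min_object_area,
                   max_object_area = neurite_spec$max_object_area)
  })
  nthr <- lapply(stats::setNames(conds, conds), function(cc) {
    row <- design[design$condition == cc, ][1L, ]
    img <- read_micrograph(file.path(dataset_dir, "wells", row$well_id, "field1_nuclei.tif"),
                           row$pixel_size, "nuclei")
    threshold_spec("absolute", value = select_threshold(img, nuclei_spec),
                   min_object_area = nuclei_spec$min_object_area,
                   max_object_area = nuclei_spec$max_object_area)
  })
  rows <- list()
  for (w in seq_len(nrow(design))) {
    row <- design[w, ]
    wdir <- file.path(dataset_dir, "wells", row$well_id)
    tl <- 0; nc <- 0L; flag <- ""
    for (f in seq_len(row$n_fields)) {
      fe <- file.path(wdir, sprintf("field%d_neurite.tif", f))
      fn <- file.path(wdir, sprintf("field%d_nuclei.tif", f))
      if (!file.exists(fe) || !file.exists(fn)) {
        flag <- paste0(flag, sprintf("missing field %d;", f)); next
      }
      m <- measure_neurites(read_micrograph(fe, row$pixel_size, "neurite"),
                            read_micrograph(fn, row$pixel_size, "nuclei"),
                            thr[[row$condition]], nthr[[row$condition]])
      tl <- tl + m$total_length; nc <- nc + m$n_cells
    }
    rows[[w]] <- data.frame(
      well_id = row$well_id, condition = row$condition, density = row$density,
      biological = row$biological, technical = row$technical,
      total_length = tl, n_cells = nc,
      length_per_cell = if (nc > 0L) tl / nc else NA_real_, flag = flag)
  }
  wells <- do.call(rbind, rows)
  wells <- fold_change(wells, "total_length")
  names(wells)[names(wells) == "fold_change"] <- "fold_change_length"
  names(wells)[names(wells) == "fold_flag"] <- "fold_flag_length"
  wells <- fold_change(wells, "length_per_cell")
  utils::write.csv(wells, file.path(out_dir, "neurite_wells.csv"), row.names = FALSE)
  wells
}
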