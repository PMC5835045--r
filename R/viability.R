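# Live/dead viability quantification.
#
# Cells are counted per channel by semi-automatic thresholding: a single
# user-chosen relative multiplier is converted to an absolute threshold per
# image (or condition) from robust background statistics, the binarized image
# is labeled by 8-connectivity, components outside an area window are
# discarded, and oversized components are declumped by watershed on the
# distance transform. The dead count comes from the dead channel, the total
# from the nuclei channel; live = total - dead (the live stain is never
# counted). Viability and live-cell density are aggregated per well.

label_objects <- function(binary, spec) {
  lab <- EBImage::bwlabel(binary)
  n_lab <- max(lab)
  if (n_lab == 0L) return(list(count = 0L, centers = matrix(numeric(0), 0L, 2L)))
  areas <- tabulate(lab, nbins = n_lab)
  keep <- which(areas >= spec$min_object_area & areas <= spec$max_object_area)
  big <- which(areas > spec$max_object_area)
  centers <- list()
  idx_all <- which(lab > 0L)
  lab_vals <- lab[idx_all]
  H <- nrow(binary)
  ys <- (idx_all - 1L) %% H + 1L
  xs <- (idx_all - 1L) %/% H + 1L
  if (length(keep)) {
    sel <- lab_vals %in% keep
    cx <- rowsum(xs[sel], lab_vals[sel]) / areas[keep]
    cy <- rowsum(ys[sel], lab_vals[sel]) / areas[keep]
    centers[[1L]] <- cbind(x = as.numeric(cx), y = as.numeric(cy))
  }
  n_extra <- 0L
  for (b in big) {
    # declump an oversized component: watershed on its distance transform
    sel <- lab_vals == b
    x0 <- min(xs[sel]); x1 <- max(xs[sel])
    y0 <- min(ys[sel]); y1 <- max(ys[sel])
    sub <- matrix(0, y1 - y0 + 3L, x1 - x0 + 3L)
    sub[cbind(ys[sel] - y0 + 2L, xs[sel] - x0 + 2L)] <- 1
    ws <- EBImage::watershed(EBImage::distmap(sub), tolerance = 0.5, ext = 1)
    wa <- tabulate(ws, nbins = max(1L, max(ws)))
    ok <- which(wa >= spec$min_object_area)
    n_extra <- n_extra + length(ok)
    if (length(ok)) {
      widx <- which(ws > 0L & array(ws, dim(ws)) %in% ok)
      wl <- ws[widx]
      hh <- nrow(sub)
      wy <- (widx - 1L) %% hh + 1L
      wx <- (widx - 1L) %/% hh + 1L
      m <- wl %in% ok
      cx <- rowsum(wx[m], wl[m]) / wa[ok]
      cy <- rowsum(wy[m], wl[m]) / wa[ok]
      centers[[length(centers) + 1L]] <-
        cbind(x = as.numeric(cx) + x0 - 2L, y = as.numeric(cy) + y0 - 2L)
    }
  }
  centers <- if (length(centers)) do.call(rbind, centers) else matrix(numeric(0), 0L, 2L)
  list(count = length(keep) + n_extra, centers = centers)
}

#' Count stained objects in a micrograph
#'
#' Binarizes the image at the threshold resolved by [select_threshold()],
#' labels connected components (8-connectivity), discards components outside
#' the spec's area window, and splits touching objects whose area exceeds
#' `max_object_area` by watershed declumping on the distance transform.
#'
#' @param image a [micrograph()].
#' @param spec a [threshold_spec()]; pass an absolute-mode spec to reuse a
#'   threshold resolved on a reference image of the same condition.
#' @return list with `count`, `centers` (n x 2 matrix of (x, y) centroids)
#'   and `threshold` (the absolute threshold used).
#' @export
count_objects <- function(image, spec) {
  stopifnot(inherits(image, "micrograph"))
  thr <- select_threshold(image, spec)
  binary <- (image$pixels > thr) * 1
  res <- label_objects(binary, spec)
  list(count = res$count, centers = res$centers, threshold = thr)
}

#' Per-field counts feeding a well summary
#'
#' @param n_total cell count from the nuclei channel.
#' @param n_dead cell count from the dead channel.
#' @param field_area imaged area in cm^2.
#' @return object of class `field_counts`.
#' @export
field_counts <- function(n_total, n_dead, field_area) {
  if (n_total < 0 || n_dead < 0) stop("counts must be nonnegative")
  if (field_area <= 0) stop("field_area must be positive")
  structure(list(n_total = as.integer(n_total), n_dead = as.integer(n_dead),
                 field_area = field_area), class = "field_counts")
}

#' Aggregate field counts into a well-level viability summary
#'
#' Counts are summed over the well's fields before any ratio is formed.
#' Because dead and total counts come from different channels, the summed
#' dead count can pathologically exceed the summed total; it is clamped at
#' the well level so that `live = total - dead` is never negative.
#' Viability is `live / total` (NA when no cells were counted) and live-cell
#' density is live cells per summed imaged area.
#'
#' @param fields list of [field_counts()] (at least one).
#' @return list of class `well_summary` with `total`, `dead`, `live`,
#'   `viability`, `live_density` (cells/cm^2) and `area` (cm^2).
#' @export
summarize_well <- function(fields) {
  if (length(fields) == 0L) stop("need at least one field")
  stopifnot(all(vapply(fields, inherits, logical(1L), "field_counts")))
  total <- sum(vapply(fields, `[[`, integer(1L), "n_total"))
  dead <- min(sum(vapply(fields, `[[`, integer(1L), "n_dead")), total)
  live <- total - dead
  area <- sum(vapply(fields, `[[`, numeric(1L), "field_area"))
  structure(list(total = total, dead = dead, live = live,
                 viability = if (total > 0L) live / total else NA_real_,
                 live_density = live / area, area = area),
            class = "well_summary")
}

# resolve per-condition absolute thresholds on a reference image, mirroring
# the manual practice of setting the threshold once per condition
condition_thresholds <- function(ref_images, spec) {
  lapply(ref_images, function(img) {
    thr <- select_threshold(img, spec)
    threshold_spec("absolute", value = thr,
                   min_object_area = spec$min_object_area,
                   max_object_area = spec$max_object_area)
  })
}

#' Run the viability analysis over a generated dataset
#'
#' Reads the design table of a dataset emitted by [generate_experiment()],
#' counts nuclei and dead cells in every field, and writes per-well and
#' per-field CSV summaries. The nuclei and dead thresholds are resolved once
#' per condition on a reference image (the first field of the condition's
#' first well) and then applied verbatim to every image of that condition.
#'
#' @param dataset_dir dataset root (contains `design.csv` and `wells/`).
#' @param nuclei_spec,dead_spec [threshold_spec()]s for the two channels.
#' @param out_dir directory for the result CSVs (default: the dataset root).
#' @return data frame with one row per well: replicate identifiers, counts,
#'   `viability` and `live_density`; wells with missing images are flagged in
#'   the `flag` column rather than dropped. Written to
#'   `viability_wells.csv`; per-field QC (counts and thresholds used) to
#'   `viability_fields.csv`.
#' @export
run_viability_analysis <- function(dataset_dir,
                                   nuclei_spec = threshold_spec(),
                                   dead_spec = threshold_spec(),
                                   out_dir = dataset_dir) {
  design <- utils::read.csv(file.path(dataset_dir, "design.csv"))
  conds <- unique(design$condition)
  ref <- lapply(stats::setNames(conds, conds), function(cc) {
    row <- design[design$condition == cc, ][1L, ]
    read_micrograph(file.path(dataset_dir, "wells", row$well_id, "field1_nuclei.tif"),
                    row$pixel_size, "nuclei")
  })
  nuc_thr <- condition_thresholds(ref, nuclei_spec)
  ref_dead <- lapply(stats::setNames(conds, conds), function(cc) {
    row <- design[design$condition == cc, ][1L, ]
    read_micrograph(file.path(dataset_dir, "wells", row$well_id, "field1_dead.tif"),
                    row$pixel_size, "dead")
  })
  dead_thr <- condition_thresholds(ref_dead, dead_spec)

  well_rows <- list(); qc_rows <- list()
  for (w in seq_len(nrow(design))) {
    row <- design[w, ]
    wdir <- file.path(dataset_dir, "wells", row$well_id)
    flds <- list(); flag <- ""
    for (f in seq_len(row$n_fields)) {
      fn <- file.path(wdir, sprintf("field%d_nuclei.tif", f))
      fd <- file.path(wdir, sprintf("field%d_dead.tif", f))
      if (!file.exists(fn) || !file.exists(fd)) {
        flag <- paste0(flag, sprintf("missing field %d;", f))
        next
      }
      nuc <- read_micrograph(fn, row$pixel_size, "nuclei")
      ded <- read_micrograph(fd, row$pixel_size, "dead")
      cn <- count_objects(nuc, nuc_thr[[row$condition]])
      cd <- count_objects(ded, dead_thr[[row$condition]])
      flds[[length(flds) + 1L]] <-
        field_counts(cn$count, cd$count, field_area_cm2(nuc))
      qc_rows[[length(qc_rows) + 1L]] <- data.frame(
        well_id = row$well_id, field = f, n_total = cn$count,
        n_dead = cd$count, nuclei_threshold = cn$threshold,
        dead_threshold = cd$threshold)
    }
    ws <- if (length(flds)) summarize_well(flds) else
      list(total = NA, dead = NA, live = NA, viability = NA, live_density = NA)
    well_rows[[w]] <- data.frame(
      well_id = row$well_id, condition = row$condition, density = row$density,
      biological = row$biological, technical = row$technical,
      total = ws$total, dead = ws$dead, live = ws$live,
      viability = ws$viability, live_density = ws$live_density, flag = flag)
  }
  wells <- do.call(rbind, well_rows)
  utils::write.csv(wells, file.path(out_dir, "viability_wells.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, qc_rows),
                   file.path(out_dir, "viability_fields.csv"), row.names = FALSE)
  wells
}

#' Simulate one viability comparison entirely in memory
#'
#' Runs the full measurement chain (field generation, per-condition threshold
#' propagation, per-channel counting, well aggregation) for a single seeding
#' density without touching disk, and returns the per-well measured table.
#' This is the workhorse for power studies of the end-to-end pipeline.
#'
#' @param density seeding density (cells/cm^2).
#' @param viability named vector of true viabilities per condition.
#' @param n_biological,n_technical,fields_per_well replicate structure.
#' @param image_shape,pixel_size field geometry.
#' @param nuclei_spec,dead_spec threshold specs (relative mode; resolved once
#'   per condition).
#' @param seed integer seed.
#' @param ... passed to [generate_nuclei_field()].
#' @return data frame with one row per well: `condition`, `biological`,
#'   `technical`, `viability`, `live_density`, true values alongside.
#' @export
simulate_viability_experiment <- function(density = 10000,
                                          viability = c(coculture = 0.89, control = 0.69),
                                          n_biological = 2L, n_technical = 5L,
                                          fields_per_well = 3L,
                                          image_shape = c(512L, 512L),
                                          pixel_size = 1.3,
                                          nuclei_spec = threshold_spec(),
                                          dead_spec = threshold_spec(),
                                          seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  area <- prod(image_shape) * pixel_size^2 / 1e8
  conds <- names(viability)
  rows <- list()
  thr_nuc <- list(); thr_dead <- list()
  for (cc in conds) {
    for (b in seq_len(n_biological)) for (t in seq_len(n_technical)) {
      flds <- list()
      for (f in seq_len(fields_per_well)) {
        n <- stats::rpois(1L, density * area)
        fld <- generate_nuclei_field(n, dead_fraction = 1 - viability[[cc]],
                                     image_shape = image_shape,
                                     pixel_size = pixel_size,
                                     channels = c("nuclei", "dead"), ...)
        if (is.null(thr_nuc[[cc]])) {
          thr_nuc[[cc]] <- condition_thresholds(list(x = fld$nuclei), nuclei_spec)$x
          thr_dead[[cc]] <- condition_thresholds(list(x = fld$dead), dead_spec)$x
        }
        cn <- count_objects(fld$nuclei, thr_nuc[[cc]])
        cd <- count_objects(fld$dead, thr_dead[[cc]])
        flds[[f]] <- field_counts(cn$count, cd$count, area)
      }
      ws <- summarize_well(flds)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cc, biological = b, technical = t,
        viability = ws$viability, live_density = ws$live_density,
        total = ws$total, dead = ws$dead,
        true_viability = viability[[cc]], density = density)
    }
  }
  do.call(rbind, rows)
}
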