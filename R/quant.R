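# Dry-mass quantification: phase-to-density conversion, threshold
# segmentation at 0.21 rad, marker-seeded separation of touching cells, and
# per-cell measurements (area, dry mass, mean density, centroid).

#' Phase-to-mass calibration
#'
#' The conversion constant kappa (pg per rad*pixel) is fixed by the printed
#' threshold pair: a pixel at the 0.21 rad segmentation threshold carries
#' 0.05 pg, hence kappa = 0.05/0.21 by default.
#'
#' @param kappa pg per (rad*pixel).
#' @param pixel_size pixel pitch, micrometres.
#' @return object of class `calibration`.
#' @export
calibration <- function(kappa = 0.05 / 0.21, pixel_size = 0.64) {
  if (kappa <= 0) stop("kappa must be positive")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(kappa = kappa, pixel_size = pixel_size),
            class = "calibration")
}

#' Segmentation configuration
#'
#' @param tau phase threshold, radians (cells are pixels with phase >= tau).
#' @param min_area minimum component area in pixels (debris filter).
#' @param connectivity 4 or 8.
#' @param fill_holes fill enclosed background holes (nuclei of condensed
#'   cells can dip below tau; area means footprint, not super-threshold
#'   pixels only).
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(tau = 0.21, min_area = 50L,
                                connectivity = 8L, fill_holes = TRUE) {
  if (tau <= 0) stop("tau must be positive")
  if (min_area < 1) stop("min_area must be >= 1")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(tau = tau, min_area = as.integer(min_area),
                 connectivity = as.integer(connectivity),
                 fill_holes = isTRUE(fill_holes)),
            class = "segmentation_config")
}

label_mask <- function(labels, count) {
  structure(list(labels = labels, count = as.integer(count)),
            class = "label_mask")
}

# Renumber labels by decreasing area; ties broken by the component's
# top-left-most (smallest row-major, i.e. row-then-column) pixel.
renumber_by_area <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(label_mask(labels * 0L, 0L))
  areas <- tabulate(labels, nbins = max(ids))[ids]
  nr <- nrow(labels)
  rowmajor <- (row(labels) - 1) * ncol(labels) + (col(labels) - 1)
  first_px <- vapply(ids, function(i) min(rowmajor[labels == i]), numeric(1))
  ord <- order(-areas, first_px)
  new <- integer(max(ids))
  new[ids[ord]] <- seq_along(ids)
  out <- labels
  out[labels > 0] <- new[labels[labels > 0]]
  label_mask(out, length(ids))
}

#' Convert phase to dry-mass density
#'
#' Elementwise linear map `m(x,y) = kappa * phi(x,y)` in pg/pixel. Negative
#' phase yields negative density; nothing is clipped, so background noise
#' statistics stay unbiased (the segmentation threshold excludes it from
#' cells).
#'
#' @param phase a [phase_image()] or matrix, radians.
#' @param calib a [calibration()].
#' @return numeric matrix, pg/pixel.
#' @export
phase_to_mass_density <- function(phase, calib = calibration()) {
  calib$kappa * phase_values(phase)
}

#' Segment cells from a flattened phase image
#'
#' Thresholds at `tau`, optionally fills enclosed holes, labels connected
#' components, removes components smaller than `min_area`, and renumbers
#' labels by decreasing area (ties to the top-left-most component).
#'
#' @param phase a [phase_image()] (background median zero) or matrix.
#' @param cfg a [segmentation_config()].
#' @return object of class `label_mask` with fields `labels` (integer
#'   matrix, 0 = background) and `count`.
#' @export
segment_cells <- function(phase, cfg = segmentation_config()) {
  v <- phase_values(phase)
  bw <- v >= cfg$tau
  if (cfg$fill_holes && any(bw)) {
    reach <- .cpp_border_background(bw)
    bw <- bw | (!bw & !reach)
  }
  if (!any(bw))
    return(label_mask(matrix(0L, nrow(v), ncol(v)), 0L))
  lab <- .cpp_label_components(bw, cfg$connectivity)
  n <- attr(lab, "count")
  if (n > 0) {
    areas <- tabulate(lab, nbins = n)
    drop <- which(areas < cfg$min_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  renumber_by_area(lab)
}

#' Separate touching cells with a marker-seeded watershed
#'
#' Components containing two or more markers are split along watershed lines
#' of the inverted density map (flooding descends from the markers through
#' decreasing density); components with at most one marker are unchanged.
#' Total foreground pixel count is preserved. This reproduces, numerically,
#' the manual separation of cells in contact.
#'
#' @param mask a `label_mask` from [segment_cells()].
#' @param density density (or phase) matrix used as the watershed relief.
#' @param markers matrix or data.frame of marker positions (row, col),
#'   1-based pixels; each marker must fall on a labelled component.
#' @return a new `label_mask` (labels renumbered by decreasing area).
#' @export
split_touching <- function(mask, density, markers) {
  if (is.null(markers) || NROW(markers) == 0) return(mask)
  mk <- as.matrix(markers)[, 1:2, drop = FALSE]
  labs <- mask$labels
  comp <- integer(nrow(mk))
  for (i in seq_len(nrow(mk))) {
    comp[i] <- labs[mk[i, 1], mk[i, 2]]
    if (comp[i] == 0)
      stop(sprintf("marker (%d, %d) lies on background", mk[i, 1], mk[i, 2]))
  }
  out <- labs
  next_id <- max(labs)
  for (cid in unique(comp)) {
    sel <- which(comp == cid)
    if (length(sel) < 2) next
    region <- labs == cid
    seeds <- matrix(0L, nrow(labs), ncol(labs))
    for (j in seq_along(sel)) seeds[mk[sel[j], 1], mk[sel[j], 2]] <- j
    ws <- .cpp_marker_watershed(density, region, seeds)
    out[region] <- 0L
    for (j in seq_along(sel)) {
      next_id <- next_id + 1L
      out[ws == j & region] <- next_id
    }
  }
  renumber_by_area(out)
}

#' Measure per-cell area, dry mass and density
#'
#' One record per label: `area_px` (footprint pixels), `area_um2`,
#' `dry_mass` (sum of density over the footprint, pg), `mean_density`
#' (pg/pixel) and the mass-weighted centroid.
#'
#' @param mask a `label_mask`.
#' @param density density map, pg/pixel (same shape).
#' @param calib a [calibration()] (for the pixel size).
#' @param frame frame index recorded in the output.
#' @return data.frame ordered by `cell_id` with columns `cell_id`, `frame`,
#'   `area_px`, `area_um2`, `dry_mass`, `mean_density`, `centroid_row`,
#'   `centroid_col` (1-based pixel coordinates).
#' @export
measure_cells <- function(mask, density, calib = calibration(), frame = 1L) {
  if (!identical(dim(mask$labels), dim(density)))
    stop("mask and density shapes differ")
  empty <- data.frame(cell_id = integer(), frame = integer(),
                      area_px = integer(), area_um2 = numeric(),
                      dry_mass = numeric(), mean_density = numeric(),
                      centroid_row = numeric(), centroid_col = numeric())
  if (mask$count == 0) return(empty)
  labs <- mask$labels
  idx <- labs > 0
  l <- labs[idx]; d <- density[idx]
  r <- row(labs)[idx]; c <- col(labs)[idx]
  area <- tabulate(l, nbins = mask$count)
  m <- vapply(split(d, l), sum, numeric(1))
  wr <- vapply(split(d * r, l), sum, numeric(1)) / m
  wc <- vapply(split(d * c, l), sum, numeric(1)) / m
  data.frame(cell_id = seq_len(mask$count), frame = as.integer(frame),
             area_px = area, area_um2 = area * calib$pixel_size^2,
             dry_mass = as.numeric(m), mean_density = as.numeric(m) / area,
             centroid_row = as.numeric(wr), centroid_col = as.numeric(wc))
}
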