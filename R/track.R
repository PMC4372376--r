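# Time-lapse trajectory building and classification: link per-frame cell
# measurements into tracks, compute relative-area series, classify each cell
# as size-increase / size-decrease / unchanged, and summarise the cohort.

#' Link per-frame cell measurements into trajectories
#'
#' Greedy mutual-nearest-centroid matching frame to frame: a track head and
#' a current-frame component are linked iff each is the other's nearest
#' neighbour and their distance is within `max_disp`; ties break towards the
#' smaller cell id. Components appearing mid-sequence start no new track and
#' are flagged as orphans. Tracks covering less than 80% of the sequence are
#' flagged incomplete (and excluded from cohort statistics downstream).
#'
#' @param per_frame_measures list of [measure_cells()] data.frames, one per
#'   frame, in frame order (at least 2 frames).
#' @param max_disp maximum per-frame centroid displacement, pixels.
#' @return list of tracks; each track is a list with `cell_id`, `frames`,
#'   `area_series`, `mass_series`, `rel_area_series` (A_t/A_0),
#'   `rel_mass_change` (|m_end - m_0|/m_0), and `complete`. The number of
#'   orphaned mid-sequence components is attached as attribute `"orphans"`.
#' @export
link_tracks <- function(per_frame_measures, max_disp = 20) {
  n_frames <- length(per_frame_measures)
  if (n_frames < 2) stop("need at least 2 frames to link tracks")
  first <- per_frame_measures[[1]]
  tracks <- lapply(seq_len(nrow(first)), function(i) {
    list(cell_id = i, frames = first$frame[i],
         area_series = first$area_px[i], mass_series = first$dry_mass[i],
         head = c(first$centroid_row[i], first$centroid_col[i]),
         active = TRUE)
  })
  orphans <- 0L
  for (f in 2:n_frames) {
    cur <- per_frame_measures[[f]]
    active <- which(vapply(tracks, function(t) t$active, logical(1)))
    if (nrow(cur) == 0 || length(active) == 0) {
      for (i in active) tracks[[i]]$active <- FALSE
      orphans <- orphans + nrow(cur)
      next
    }
    heads <- t(vapply(tracks[active], function(t) t$head, numeric(2)))
    D <- sqrt(outer(heads[, 1], cur$centroid_row, "-")^2 +
                outer(heads[, 2], cur$centroid_col, "-")^2)
    # mutual nearest neighbours within max_disp
    best_for_track <- apply(D, 1, which.min)
    best_for_comp <- apply(D, 2, which.min)
    matched_comp <- rep(NA_integer_, length(active))
    for (k in seq_along(active)) {
      j <- best_for_track[k]
      if (best_for_comp[j] == k && D[k, j] <= max_disp)
        matched_comp[k] <- j
    }
    for (k in seq_along(active)) {
      i <- active[k]
      j <- matched_comp[k]
      if (is.na(j)) {
        tracks[[i]]$active <- FALSE
      } else {
        tracks[[i]]$frames <- c(tracks[[i]]$frames, cur$frame[j])
        tracks[[i]]$area_series <- c(tracks[[i]]$area_series, cur$area_px[j])
        tracks[[i]]$mass_series <- c(tracks[[i]]$mass_series, cur$dry_mass[j])
        tracks[[i]]$head <- c(cur$centroid_row[j], cur$centroid_col[j])
      }
    }
    orphans <- orphans + sum(!seq_len(nrow(cur)) %in% matched_comp)
  }
  tracks <- lapply(tracks, function(t) {
    t$active <- NULL
    t$rel_area_series <- t$area_series / t$area_series[1]
    m0 <- t$mass_series[1]
    t$rel_mass_change <- abs(t$mass_series[length(t$mass_series)] - m0) /
      m0
    t$complete <- length(t$frames) >= 0.8 * n_frames
    class(t) <- "cell_track"
    t
  })
  attr(tracks, "orphans") <- orphans
  tracks
}

#' Classify one size trajectory
#'
#' The decision statistic is the median relative area over the final quarter
#' of frames: `increase` if it reaches `up` (default 1.20), `decrease` if it
#' falls to `down` (default 0.80), otherwise `no_change`. The final-quarter
#' median absorbs segmentation jitter while capturing the end state of the
#' 2 h trajectory.
#'
#' @param track a track from [link_tracks()] (or any list with
#'   `rel_area_series`).
#' @param up,down relative-area thresholds.
#' @return one of `"no_change"`, `"increase"`, `"decrease"`.
#' @export
classify_trajectory <- function(track, up = 1.2, down = 0.8) {
  ra <- track$rel_area_series
  if (length(ra) < 4) stop("trajectory too short to classify (< 4 frames)")
  if (up <= down) stop("'up' threshold must exceed 'down'")
  n <- length(ra)
  s <- median(ra[(n - ceiling(n / 4) + 1):n])
  if (s >= up) "increase" else if (s <= down) "decrease" else "no_change"
}

#' Summarise a classified cohort
#'
#' Percentages per class, the fraction of mass-stable cells (relative
#' end-to-start mass change below `mass_tol`), and the ratio of mean initial
#' mass in the decrease class to the mean initial mass of all other cells.
#' Only complete tracks enter the statistics.
#'
#' @param tracks list of tracks from [link_tracks()].
#' @param classes character vector of per-track classes, aligned with
#'   `tracks` (e.g. from [classify_trajectory()]).
#' @param mass_tol relative mass-change tolerance defining "stable".
#' @return list with `fractions` (named percentages summing to 100),
#'   `mass_stable_fraction` (%), `mass_ratio_decrease_vs_rest`, `mass_tol`,
#'   `n_complete`.
#' @export
cohort_summary <- function(tracks, classes, mass_tol = 0.07) {
  if (length(tracks) == 0) stop("empty cohort")
  if (length(tracks) != length(classes))
    stop("tracks and classes are not aligned")
  keep <- vapply(tracks, function(t) isTRUE(t$complete), logical(1))
  if (!any(keep)) stop("no complete tracks to summarise")
  tracks <- tracks[keep]
  classes <- factor(classes[keep], levels = CELL_FATES)
  fr <- 100 * as.numeric(table(classes)) / length(classes)
  names(fr) <- CELL_FATES
  dm <- vapply(tracks, function(t) {
    m <- t$mass_series
    abs(m[length(m)] - m[1]) / m[1]
  }, numeric(1))
  m0 <- vapply(tracks, function(t) t$mass_series[1], numeric(1))
  dec <- classes == "decrease"
  ratio <- if (any(dec) && any(!dec)) mean(m0[dec]) / mean(m0[!dec])
           else NA_real_
  list(fractions = fr,
       mass_stable_fraction = 100 * mean(dm < mass_tol),
       mass_ratio_decrease_vs_rest = ratio,
       mass_tol = mass_tol, n_complete = length(tracks))
}
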