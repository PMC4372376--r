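# Synthetic-data generator: adherent-cell phase phantoms with known dry mass
# and fate, time-lapse morphodynamics, off-axis hologram rendering, and
# class-conditional flow-cytometry event simulation.

# Integral of the unit raised-cosine dome 0.5*(1 + cos(pi*u)) over the unit
# disk: 2*pi*(1/4 - 1/pi^2). Used to size a cell's footprint from its mass.
RC_DOME_INTEGRAL <- 2 * pi * (0.25 - 1 / pi^2)

# Default phase-to-mass conversion, pinned by the printed threshold pair
# 0.21 rad == 0.05 pg/pixel.
DEFAULT_KAPPA <- 0.05 / 0.21

# Default off-axis carrier, in cycles/pixel (columns, rows). 77/256 puts the
# sideband on an exact spectral bin for 256-px fields and keeps the whole
# tapered sideband window inside the Nyquist square.
DEFAULT_CARRIER <- c(77 / 256, 77 / 256)

# Evaluate RNG-dependent code under a given seed without clobbering the
# caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

CELL_FATES <- c("no_change", "increase", "decrease")

#' Specify a synthetic time-lapse phantom cohort
#'
#' Bundles every parameter of the synthetic world: field geometry, cohort
#' size, ground-truth fate mix, dry-mass distribution and the time base.
#' Defaults mirror the modelled experiment: adherent cells monitored for 2 h
#' at 1 frame/min, fate fractions matching the morphology-derived cohort
#' split (44/32/24 no-change/increase/decrease), and size-decreasing cells
#' drawn 1.3-fold heavier than the rest.
#'
#' @param image_shape integer (rows, cols) of one field of view, pixels.
#' @param pixel_size pixel pitch in micrometres.
#' @param cell_count total number of cells in the cohort.
#' @param class_fractions fractions (no_change, increase, decrease), sum 1.
#' @param mass_mean mean initial dry mass, pg.
#' @param mass_cv coefficient of variation of initial dry mass.
#' @param decrease_mass_factor multiplicative mass offset for decrease-fate
#'   cells (the observed 1.3-fold heavier apoptotic group, used here as a
#'   generator parameter so the pipeline can be tested for recovering it).
#' @param n_frames frames per time-lapse (>= 2).
#' @param frame_interval minutes between frames.
#' @param peak_phase target initial peak phase per cell, radians. The default
#'   6.5 rad exceeds 2*pi (so unwrapping does real work) while keeping the
#'   steepest fate-driven phase gradients within the off-axis sideband
#'   bandwidth; see the methods vignette.
#' @param seed master seed for all phantom randomness.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(256L, 256L), pixel_size = 0.64,
                         cell_count = 9L,
                         class_fractions = c(no_change = 0.44,
                                             increase = 0.32,
                                             decrease = 0.24),
                         mass_mean = 450, mass_cv = 0.2,
                         decrease_mass_factor = 1.3,
                         n_frames = 120L, frame_interval = 1,
                         peak_phase = 6.5, seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 64),
            pixel_size > 0, cell_count >= 0, length(class_fractions) == 3)
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  if (mass_mean < 0) stop("mass_mean must be positive")
  if (n_frames < 2) stop("n_frames must be >= 2")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size,
                 cell_count = as.integer(cell_count),
                 class_fractions = setNames(as.numeric(class_fractions),
                                            CELL_FATES),
                 mass_mean = mass_mean, mass_cv = mass_cv,
                 decrease_mass_factor = decrease_mass_factor,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 peak_phase = peak_phase, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Footprint area scale over normalised time for each fate. Increase-fate
# cells swell to 1.6x their spread area, decrease-fate cells shrink to 0.62x
# (comfortably past the +/-20% classification thresholds), unchanged cells
# wobble within +/-2%.
fate_area_schedule <- function(fate, tfrac, wobble_phase = 0) {
  switch(fate,
         no_change = 1 + 0.02 * sin(2 * pi * tfrac + wobble_phase),
         increase = 1 + 0.6 * tfrac,
         decrease = 1 - 0.38 * tfrac,
         stop("unknown fate: ", fate))
}

# Render one anisotropic raised-cosine dome into patch coordinates.
# rr, cc: pixel coordinate matrices; returns unit-peak profile.
rc_dome <- function(rr, cc, center, radius, ecc = 0, theta = 0) {
  dr <- rr - center[1]; dc <- cc - center[2]
  ct <- cos(theta); st <- sin(theta)
  u1 <- (dr * ct + dc * st) / (radius * (1 + ecc))
  u2 <- (-dr * st + dc * ct) / (radius * (1 - ecc))
  u <- sqrt(u1^2 + u2^2)
  out <- 0.5 + 0.5 * cos(pi * pmin(u, 1))
  out[u > 1] <- 0
  out
}

#' Generate one cell phantom with known mass, fate and morphodynamics
#'
#' Builds a per-frame series of compactly supported phase patches for a
#' single cell. The footprint is a smooth anisotropic raised-cosine dome;
#' swelling cells grow their footprint and sprout peripheral membrane blebs
#' (one every few frames, amplitude well below the cell peak), shrinking
#' cells condense (footprint down, peak density up) and partition part of
#' their mass into dense apoptotic-body satellites in the final 30% of
#' frames, and unchanged cells keep their footprint within +/-5%. Every
#' frame is renormalised so that integrated phase times the default
#' calibration equals the cell's target mass exactly (mass conservation by
#' construction).
#'
#' @param spec a [phantom_spec()].
#' @param center (row, col) cell centre in the field, 1-based pixels.
#' @param fate one of `"no_change"`, `"increase"`, `"decrease"`.
#' @param seed integer seed for this cell's randomness.
#' @param mass target dry mass in pg; drawn from the spec's mass
#'   distribution when `NULL`. `mass = 0` yields an all-zero phase series.
#' @param radius initial footprint radius in px; derived from mass and
#'   `spec$peak_phase` when `NULL`.
#' @param drift optional `n_frames x 2` matrix of per-frame centre offsets.
#' @return object of class `cell_phantom` with fields `phase_map_series`
#'   (list of patches; attributes `row0`/`col0` give the 1-based position of
#'   each patch's top-left pixel), `true_mass_series` (pg),
#'   `true_area_series` (pixels with phase >= 0.21 rad), `fate`,
#'   `bleb_events`, and the generating parameters.
#' @export
make_cell_phantom <- function(spec, center, fate = CELL_FATES, seed = 1L,
                              mass = NULL, radius = NULL, drift = NULL) {
  fate <- match.arg(fate)
  shp <- spec$image_shape
  if (center[1] < 1 || center[1] > shp[1] || center[2] < 1 ||
      center[2] > shp[2])
    stop(sprintf("cell center (%.1f, %.1f) outside image %dx%d",
                 center[1], center[2], shp[1], shp[2]))
  n <- spec$n_frames
  if (is.null(drift)) drift <- matrix(0, n, 2)
  with_seed(seed, {
    if (is.null(mass)) {
      sdlog <- sqrt(log(1 + spec$mass_cv^2))
      m <- rlnorm(1, log(spec$mass_mean) - sdlog^2 / 2, sdlog)
      # truncate extreme draws: heavy cells must keep to their placement
      # slots, and very light cells would shrink into phase gradients
      # beyond the off-axis sideband bandwidth (see vignette)
      m <- min(max(m, 0.6 * spec$mass_mean), 1.8 * spec$mass_mean)
      if (fate == "decrease") m <- m * spec$decrease_mass_factor
      mass <- m
    }
    ecc <- runif(1, 0, 0.15)
    theta <- runif(1, 0, pi)
    wobble_phase <- runif(1, 0, 2 * pi)
    phase_target <- mass / DEFAULT_KAPPA      # rad * px to distribute
    if (is.null(radius)) {
      radius <- if (mass > 0)
        sqrt(phase_target / (RC_DOME_INTEGRAL * spec$peak_phase *
                             (1 - ecc^2))) else 3
    }
    tfrac <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
    s <- sqrt(vapply(tfrac, fate_area_schedule, numeric(1), fate = fate,
                     wobble_phase = wobble_phase))
    # membrane blebs: born one at a time on the boundary, fixed identity
    blebs <- NULL
    if (fate == "increase" && mass > 0) {
      n_bleb <- sample(4:6, 1)
      birth <- round(seq(0.15, 0.9, length.out = n_bleb) * n)
      ang <- runif(n_bleb, 0, 2 * pi)
      r_b <- runif(n_bleb, max(4, 0.18 * radius), max(5, min(7, 0.35 * radius)))
      blebs <- data.frame(birth = birth, angle = ang, radius = r_b,
                          mass_frac = 0.02)
    }
    sats <- NULL
    if (fate == "decrease" && mass > 0) {
      n_sat <- sample(3:6, 1)
      ang <- runif(n_sat, 0, 2 * pi)
      dist <- runif(n_sat, 0.15, 0.37) * radius
      # bodies are kept broad and light enough that their gradients stay
      # within the demodulation bandwidth when stacked on the condensed dome
      sats <- data.frame(angle = ang, dist = dist, radius = 0.35 * radius,
                         mass_frac = 0.015)
    }
    # fixed patch window covering the whole series
    ext <- radius * (1 + ecc) * max(s)
    if (!is.null(blebs)) ext <- ext + max(blebs$radius) + 2
    W <- ceiling(ext) + 3L
    rows <- (round(center[1]) - W):(round(center[1]) + W)
    cols <- (round(center[2]) - W):(round(center[2]) + W)
    rr <- matrix(rows, length(rows), length(cols))
    cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)

    series <- vector("list", n)
    true_mass <- numeric(n)
    true_area <- numeric(n)
    bleb_events <- list()
    for (t in seq_len(n)) {
      ctr <- center + drift[t, ]
      if (mass <= 0) {
        patch <- matrix(0, length(rows), length(cols))
      } else {
        bleb_share <- if (is.null(blebs)) 0 else
          sum(blebs$mass_frac[blebs$birth <= t])
        sat_share <- 0
        if (!is.null(sats)) {
          frag <- max(0, (tfrac[t] - 0.7) / 0.3)   # ramps 0 -> 1 after 70%
          sat_share <- sum(sats$mass_frac) * frag
        }
        body <- rc_dome(rr, cc, ctr, radius * s[t], ecc, theta)
        body_sum <- sum(body)
        patch <- body * (phase_target * (1 - bleb_share - sat_share) /
                           body_sum)
        if (!is.null(blebs)) {
          born <- which(blebs$birth <= t)
          for (b in born) {
            # bleb rides the membrane: centred at 92% of the current boundary
            brad <- 0.92 * radius * s[t]
            bc <- ctr + brad * c(cos(blebs$angle[b]) * (1 + ecc),
                                 sin(blebs$angle[b]) * (1 - ecc))
            dome <- rc_dome(rr, cc, bc, blebs$radius[b])
            dsum <- sum(dome)
            if (dsum > 0)
              patch <- patch + dome * (phase_target * blebs$mass_frac[b] / dsum)
            if (blebs$birth[b] == t)
              bleb_events[[length(bleb_events) + 1]] <-
                data.frame(frame = t, row = bc[1], col = bc[2],
                           amplitude = phase_target * blebs$mass_frac[b] / dsum)
          }
        }
        if (!is.null(sats) && sat_share > 0) {
          frag <- max(0, (tfrac[t] - 0.7) / 0.3)
          for (k in seq_len(nrow(sats))) {
            sc <- ctr + sats$dist[k] * s[t] *
              c(cos(sats$angle[k]), sin(sats$angle[k]))
            dome <- rc_dome(rr, cc, sc, sats$radius[k])
            dsum <- sum(dome)
            if (dsum > 0)
              patch <- patch +
                dome * (phase_target * sats$mass_frac[k] * frag / dsum)
          }
        }
        # exact mass conservation: renormalise the composite patch
        patch <- patch * (phase_target / sum(patch))
      }
      series[[t]] <- structure(patch, row0 = rows[1], col0 = cols[1])
      true_mass[t] <- sum(patch) * DEFAULT_KAPPA
      true_area[t] <- sum(patch >= 0.21)
    }
    structure(list(center = center, fate = fate, mass = mass,
                   radius = radius, ecc = ecc, theta = theta,
                   phase_map_series = series,
                   true_mass_series = true_mass,
                   true_area_series = true_area,
                   bleb_events = if (length(bleb_events))
                     do.call(rbind, bleb_events) else
                     data.frame(frame = integer(), row = numeric(),
                                col = numeric(), amplitude = numeric()),
                   drift = drift, seed = seed),
              class = "cell_phantom")
  })
}

# Grid layout of one field: slot centres with margins wide enough for the
# largest admissible cell at full swelling.
field_slots <- function(image_shape, spacing = 84, margin = 42) {
  pos <- function(dim) {
    k <- floor((dim - 2 * margin) / spacing) + 1
    if (k < 1) return(numeric(0))
    margin + spacing * (0:(k - 1)) + (dim - 2 * margin - spacing * (k - 1)) / 2
  }
  rows <- pos(image_shape[1]); cols <- pos(image_shape[2])
  if (!length(rows) || !length(cols))
    return(matrix(numeric(0), 0, 2))
  as.matrix(expand.grid(row = rows, col = cols))
}

#' Simulate a time-lapse cohort of cell phantoms
#'
#' Draws fates by deterministic largest-remainder apportionment of the spec's
#' class fractions, places cells on a jittered grid (no initial overlap) and
#' generates each cell's phase series with [make_cell_phantom()]. Cells that
#' do not fit into one field of view are distributed over as many identical
#' fields as needed, mirroring multi-position acquisition; pass `n_fields`
#' to cap the number of fields, in which case overflow is a packing error.
#'
#' @param spec a [phantom_spec()].
#' @param n_fields maximum number of fields of view, or `NULL` (auto).
#' @return object of class `phantom_cohort`: list with `cells` (list of
#'   `cell_phantom`, each annotated with its `field`), `truth` (long-format
#'   ground-truth table: cell_id, field, frame, fate, area_px, mass_pg,
#'   centroid_row, centroid_col with 0-based pixel coordinates), `counts`
#'   (per-fate totals) and `n_fields`.
#' @export
simulate_timelapse_cohort <- function(spec, n_fields = NULL) {
  counts <- largest_remainder(spec$cell_count, spec$class_fractions)
  names(counts) <- CELL_FATES
  slots <- field_slots(spec$image_shape)
  cap <- nrow(slots)
  if (cap == 0) stop("image too small to place any cell")
  need <- ceiling(spec$cell_count / cap)
  if (is.null(n_fields)) n_fields <- max(need, 1L)
  if (spec$cell_count > cap * n_fields)
    stop(sprintf(paste0("packing failure: %d cells do not fit into %d ",
                        "field(s) of %dx%d px (%d slots/field)"),
                 spec$cell_count, n_fields, spec$image_shape[1],
                 spec$image_shape[2], cap))
  fates <- rep(CELL_FATES, counts)
  cells <- vector("list", spec$cell_count)
  truth <- vector("list", spec$cell_count)
  with_seed(derive_seed(spec$seed, "phantom"), {
    ord <- sample(seq_along(fates))       # interleave fates across fields
    fates <- fates[ord]
    cell_seeds <- sample.int(2^30, max(spec$cell_count, 1))
    for (i in seq_len(spec$cell_count)) {
      field <- ((i - 1) %/% cap) + 1L
      slot <- ((i - 1) %% cap) + 1L
      jitter <- runif(2, -3, 3)
      ctr <- c(slots[slot, 1], slots[slot, 2]) + jitter
      ang <- runif(1, 0, 2 * pi)
      step <- 0.08
      dr <- outer((seq_len(spec$n_frames) - 1),
                  step * c(cos(ang), sin(ang)))
      cell <- make_cell_phantom(spec, ctr, fates[i], seed = cell_seeds[i],
                                drift = dr)
      cell$field <- field
      cell$cell_id <- i
      cells[[i]] <- cell
      ctr_series <- sweep(dr, 2, ctr, "+")
      truth[[i]] <- data.frame(cell_id = i, field = field,
                               frame = seq_len(spec$n_frames),
                               fate = fates[i],
                               area_px = cell$true_area_series,
                               mass_pg = cell$true_mass_series,
                               centroid_row = ctr_series[, 1] - 1,
                               centroid_col = ctr_series[, 2] - 1)
    }
  })
  structure(list(cells = cells,
                 truth = if (spec$cell_count)
                   do.call(rbind, truth) else NULL,
                 counts = counts, n_fields = as.integer(n_fields),
                 spec = spec),
            class = "phantom_cohort")
}

#' Compose the full-field phase map of one cohort frame
#'
#' @param cohort a [simulate_timelapse_cohort()] result.
#' @param field field-of-view index (1-based).
#' @param frame frame index (1-based).
#' @return numeric matrix of the field's phase in radians.
#' @export
cohort_phase_frame <- function(cohort, field, frame) {
  shp <- cohort$spec$image_shape
  img <- matrix(0, shp[1], shp[2])
  for (cell in cohort$cells) {
    if (cell$field != field) next
    patch <- cell$phase_map_series[[frame]]
    r0 <- attr(patch, "row0"); c0 <- attr(patch, "col0")
    rs <- r0:(r0 + nrow(patch) - 1)
    cs <- c0:(c0 + ncol(patch) - 1)
    keep_r <- rs >= 1 & rs <= shp[1]
    keep_c <- cs >= 1 & cs <= shp[2]
    img[rs[keep_r], cs[keep_c]] <- img[rs[keep_r], cs[keep_c]] +
      patch[keep_r, keep_c]
  }
  img
}

#' Render an off-axis hologram from a phase map
#'
#' Ideal two-beam interference: the object wave carries the phase map, the
#' tilted reference adds linear carrier fringes, and the detector records
#' `I = Ao^2 + Ar^2 + 2*Ao*Ar*cos(2*pi*(fx*x + fy*y) - phi)` plus additive
#' Gaussian read noise (clamped at zero, as a detector would).
#'
#' @param phase_map 2D phase in radians.
#' @param carrier `(f_x, f_y)` carrier in cycles/pixel; `f_x` runs along
#'   columns, `f_y` along rows. Magnitude must lie in `[0.1, 0.45]` so the
#'   sideband is separable from DC yet below Nyquist.
#' @param amps `(A_o, A_r)` object and reference amplitudes.
#' @param noise_sd read-noise standard deviation in detector units; default
#'   1% of the fringe amplitude `2*Ao*Ar`.
#' @return object of class `hologram_frame` with fields `intensity`,
#'   `carrier`, `object_amp`, `reference_amp`, `noise_sd`.
#' @export
render_hologram <- function(phase_map, carrier = DEFAULT_CARRIER,
                            amps = c(1, 1), noise_sd = NULL) {
  fmag <- sqrt(sum(carrier^2))
  if (fmag < 0.1)
    stop("carrier magnitude ", signif(fmag, 3),
         " below separability bound 0.1 cycles/pixel")
  if (fmag > 0.45)
    stop("carrier magnitude ", signif(fmag, 3),
         " above Nyquist-safety bound 0.45 cycles/pixel")
  A_o <- amps[1]; A_r <- amps[2]
  if (is.null(noise_sd)) noise_sd <- 0.01 * 2 * A_o * A_r
  nr <- nrow(phase_map); nc <- ncol(phase_map)
  x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)   # column coordinate
  y <- matrix(0:(nr - 1), nr, nc)                 # row coordinate
  I <- A_o^2 + A_r^2 +
    2 * A_o * A_r * cos(2 * pi * (carrier[1] * x + carrier[2] * y) -
                          phase_map)
  if (noise_sd > 0) I <- I + rnorm(length(I), 0, noise_sd)
  I[I < 0] <- 0
  structure(list(intensity = I, carrier = carrier, object_amp = A_o,
                 reference_amp = A_r, noise_sd = noise_sd),
            class = "hologram_frame")
}

FCM_CLASSES <- c("viable", "apoptotic", "oncotic", "necrotic", "debris")

#' Default class-conditional flow-cytometry channel parameters
#'
#' Log10-normal location/scale per class and channel, chosen to reproduce
#' the canonical annexin V/PI quadrant structure: viable double-negative;
#' apoptotic annexin-high/PI-low at low FSC; oncotic annexin-high/PI-low at
#' high FSC (about 6 sigma above the apoptotic FSC mode, so the annexin+/PI-
#' population is clearly bimodal in FSC); necrotic double-positive at
#' intermediate FSC; debris PI-dim at very low FSC.
#'
#' @return named list: per class, a list of `c(meanlog10, sdlog10)` for
#'   channels `fsc`, `ssc`, `fl1`, `fl3`.
#' @export
fcm_class_params <- function() {
  list(
    viable    = list(fsc = c(2.70, 0.07), ssc = c(2.30, 0.10),
                     fl1 = c(1.95, 0.12), fl3 = c(1.80, 0.12)),
    apoptotic = list(fsc = c(2.42, 0.07), ssc = c(2.40, 0.10),
                     fl1 = c(3.10, 0.15), fl3 = c(1.82, 0.12)),
    oncotic   = list(fsc = c(2.95, 0.07), ssc = c(2.45, 0.10),
                     fl1 = c(3.05, 0.15), fl3 = c(1.85, 0.12)),
    necrotic  = list(fsc = c(2.80, 0.08), ssc = c(2.50, 0.10),
                     fl1 = c(3.10, 0.15), fl3 = c(3.00, 0.15)),
    debris    = list(fsc = c(2.00, 0.15), ssc = c(2.00, 0.15),
                     fl1 = c(1.90, 0.20), fl3 = c(2.60, 0.25))
  )
}

#' Simulate class-conditional flow-cytometry events
#'
#' Event counts per class follow deterministic largest-remainder rounding of
#' `class_mix`; channel values are class-conditional log-normal draws.
#'
#' @param n_events number of events.
#' @param class_mix named fractions over
#'   `viable, apoptotic, oncotic, necrotic, debris` (missing classes are 0);
#'   must sum to 1.
#' @param class_params channel parameters as from [fcm_class_params()].
#' @param seed integer seed.
#' @return data.frame with columns `fsc`, `ssc`, `fl1_annexin`, `fl3_pi`,
#'   `true_class`.
#' @export
simulate_fcm_events <- function(n_events, class_mix,
                                class_params = fcm_class_params(),
                                seed = 1L) {
  mix <- setNames(numeric(length(FCM_CLASSES)), FCM_CLASSES)
  mix[names(class_mix)] <- class_mix
  if (abs(sum(mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  for (cl in names(class_params))
    for (ch in names(class_params[[cl]]))
      if (class_params[[cl]][[ch]][2] <= 0)
        stop("non-positive distribution scale for ", cl, "/", ch)
  if (n_events == 0)
    return(data.frame(fsc = numeric(), ssc = numeric(),
                      fl1_annexin = numeric(), fl3_pi = numeric(),
                      true_class = character()))
  counts <- largest_remainder(n_events, mix)
  with_seed(seed, {
    cls <- rep(FCM_CLASSES, counts)
    draw <- function(ch) {
      v <- numeric(length(cls))
      for (cl in FCM_CLASSES) {
        idx <- cls == cl
        if (!any(idx)) next
        p <- class_params[[cl]][[ch]]
        v[idx] <- 10^rnorm(sum(idx), p[1], p[2])
      }
      v
    }
    out <- data.frame(fsc = draw("fsc"), ssc = draw("ssc"),
                      fl1_annexin = draw("fl1"), fl3_pi = draw("fl3"),
                      true_class = cls)
    out[sample(nrow(out)), , drop = FALSE]
  }) -> out
  rownames(out) <- NULL
  out
}
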