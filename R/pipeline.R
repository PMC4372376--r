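# End-to-end orchestration: the simulate -> reconstruct -> quantify ->
# classify -> gate -> compare -> stage workflow, both as an in-memory chain
# (analyze_cohort) and as a file-based pipeline driven by one YAML config
# (run_pipeline).

# Default treated-sample class mix for the FCM simulation. Chosen so the
# annexin+/PI- population splits 9.51% apoptotic / 13.22% oncotic of all
# events, with necrotic and debris tails, echoing the modelled experiment.
DEFAULT_TREATED_MIX <- c(viable = 0.63, apoptotic = 0.0951,
                         oncotic = 0.1322, necrotic = 0.08,
                         debris = 0.0627)

#' Run the full hologram-to-classification chain on a phantom cohort
#'
#' For every field and frame: compose the ground-truth phase, render an
#' off-axis hologram (default 1% fringe-amplitude read noise), reconstruct
#' (demodulate, unwrap, flatten), convert to dry-mass density, segment at
#' the 0.21 rad threshold and measure; then link tracks per field, classify
#' each complete trajectory and summarise the cohort.
#'
#' @param cohort a [simulate_timelapse_cohort()] result.
#' @param carrier hologram carrier (cycles/pixel).
#' @param amps object/reference amplitudes.
#' @param noise_sd hologram read noise; `NULL` for the 1% default, `0` for
#'   noiseless.
#' @param calib a [calibration()].
#' @param segcfg a [segmentation_config()].
#' @param up,down classification thresholds (see [classify_trajectory()]).
#' @param mass_tol stability tolerance (see [cohort_summary()]).
#' @param max_disp tracking search radius, pixels.
#' @param seed seed for the hologram noise stream.
#' @return list with `summary` ([cohort_summary()] output), `tracks`,
#'   `classes`, `measures` (per-field lists of per-frame data.frames).
#' @export
analyze_cohort <- function(cohort, carrier = DEFAULT_CARRIER,
                           amps = c(1, 1), noise_sd = NULL,
                           calib = calibration(cohort$spec$pixel_size),
                           segcfg = segmentation_config(),
                           up = 1.2, down = 0.8, mass_tol = 0.07,
                           max_disp = 20, seed = cohort$spec$seed) {
  calib <- calibration(pixel_size = cohort$spec$pixel_size)
  n_frames <- cohort$spec$n_frames
  filt <- sideband_filter(carrier)
  all_tracks <- list()
  all_measures <- vector("list", cohort$n_fields)
  with_seed(derive_seed(seed, "hologram"), {
    for (field in seq_len(cohort$n_fields)) {
      frames <- vector("list", n_frames)
      for (t in seq_len(n_frames)) {
        phi <- cohort_phase_frame(cohort, field, t)
        holo <- render_hologram(phi, carrier, amps, noise_sd)
        rec <- flatten_background(unwrap_phase(demodulate(holo, filt)))
        dens <- phase_to_mass_density(rec, calib)
        mask <- segment_cells(rec, segcfg)
        frames[[t]] <- measure_cells(mask, dens, calib, frame = t)
      }
      all_measures[[field]] <- frames
      tr <- link_tracks(frames, max_disp = max_disp)
      for (t in tr) {
        t$field <- field
        all_tracks[[length(all_tracks) + 1]] <- t
      }
    }
  })
  classes <- vapply(all_tracks, function(t)
    if (length(t$rel_area_series) >= 4)
      classify_trajectory(t, up = up, down = down) else NA_character_,
    character(1))
  keep <- !is.na(classes)
  summary <- cohort_summary(all_tracks[keep], classes[keep],
                            mass_tol = mass_tol)
  list(summary = summary, tracks = all_tracks, classes = classes,
       measures = all_measures)
}

# ---- file-based pipeline -------------------------------------------------

read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "out_dir", "stages", "phantom", "fcm", "recon",
             "quant", "classify", "compare", "stage_features")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("config must name a seed")
  config$out_dir <- config$out_dir %||% "."
  config$stages <- config$stages %||%
    c("simulate", "reconstruct", "quantify", "classify", "fcm", "compare")
  config
}

write_provenance <- function(obj, cfg, extra = list()) {
  c(obj, list(provenance = c(list(seed = cfg$seed,
                                  package = "necroscope",
                                  config = cfg[setdiff(names(cfg),
                                                       "out_dir")]),
              extra)))
}

#' Run the file-based analysis pipeline
#'
#' Executes the requested stages in dependency order, handing data between
#' stages as plain files (TIFF/CSV/YAML) under `out_dir`:
#' \describe{
#'   \item{simulate}{phantom cohort -> `holo_f<k>.tif` (multi-page float32),
#'     `truth.csv`, `fcm_control.csv`, `fcm_treated.csv`, `simulate.yaml`.}
#'   \item{reconstruct}{holograms -> `phase_f<k>.tif` (float32 radians,
#'     parameters in the TIFF description tag and `reconstruct.yaml`).}
#'   \item{quantify}{phase stacks -> `cells.csv` (one row per cell and
#'     frame; 0-based centroid pixel coordinates).}
#'   \item{classify}{`cells.csv` -> `tracks.csv` + `summary.yaml`.}
#'   \item{fcm}{event CSVs -> `gates.yaml`, `counts.yaml` (plain and
#'     oncosis-adjusted size classes).}
#'   \item{compare}{`summary.yaml` + `counts.yaml` -> `contingency.yaml`.}
#'   \item{stage}{feature CSV -> `stages.csv` + `stage_histogram.yaml`.}
#' }
#' All randomness derives from the single config seed, so a rerun with the
#' same config reproduces every output byte for byte.
#'
#' @param config path to a YAML config, or an equivalent named list. Keys:
#'   `seed` (required), `out_dir`, `stages`, and per-stage parameter blocks
#'   `phantom`, `fcm`, `recon`, `quant`, `classify`, `stage_features`.
#'   Unknown keys are rejected.
#' @return run report: named list of per-stage output files and summary
#'   numbers.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$out_dir, ...)
  report <- list(seed = cfg$seed, out_dir = cfg$out_dir)
  stages <- cfg$stages

  if ("simulate" %in% stages) {
    ph <- cfg$phantom %||% list()
    ph$seed <- ph$seed %||% cfg$seed
    spec <- do.call(phantom_spec, ph)
    cohort <- simulate_timelapse_cohort(spec)
    holo_files <- character(cohort$n_fields)
    with_seed(derive_seed(cfg$seed, "hologram"), {
      for (k in seq_len(cohort$n_fields)) {
        pages <- lapply(seq_len(spec$n_frames), function(t) {
          render_hologram(cohort_phase_frame(cohort, k, t))$intensity
        })
        holo_files[k] <- out(sprintf("holo_f%02d.tif", k))
        write_tiff(pages, holo_files[k], type = "float32",
                   description = jsonlite::toJSON(
                     list(field = k, seed = cfg$seed,
                          carrier = DEFAULT_CARRIER), auto_unbox = TRUE))
      }
    })
    write.csv(cohort$truth, out("truth.csv"), row.names = FALSE)
    fc <- cfg$fcm %||% list()
    n_ev <- fc$n_events %||% 10000L
    control <- simulate_fcm_events(n_ev, c(viable = 1),
                                   seed = derive_seed(cfg$seed, "fcm"))
    treated_mix <- unlist(fc$treated_mix %||% DEFAULT_TREATED_MIX)
    treated <- simulate_fcm_events(n_ev, treated_mix,
                                   seed = derive_seed(cfg$seed, "fcm") + 1L)
    write_fcm_csv(control, out("fcm_control.csv"))
    write_fcm_csv(treated, out("fcm_treated.csv"))
    yaml::write_yaml(write_provenance(
      list(n_fields = cohort$n_fields,
           fate_counts = as.list(cohort$counts)), cfg),
      out("simulate.yaml"))
    report$simulate <- list(holograms = holo_files,
                            truth = out("truth.csv"),
                            fate_counts = cohort$counts)
  }

  if ("reconstruct" %in% stages) {
    holo_files <- sort(list.files(cfg$out_dir, "^holo_f[0-9]+\\.tif$",
                                  full.names = TRUE))
    if (!length(holo_files))
      stop("no holograms found; run the 'simulate' stage first")
    rc <- cfg$recon %||% list()
    phase_files <- character(length(holo_files))
    for (k in seq_along(holo_files)) {
      pages <- read_tiff(holo_files[k])
      carrier <- rc$carrier %||% as.numeric(estimate_carrier(pages[[1]]))
      filt <- if (is.null(rc$radius)) sideband_filter(carrier)
              else sideband_filter(carrier, rc$radius)
      rec_pages <- lapply(pages, function(I)
        flatten_background(unwrap_phase(demodulate(I, filt)))$values)
      phase_files[k] <- out(sprintf("phase_f%02d.tif", k))
      params <- list(carrier = carrier, radius = filt$radius,
                     taper = filt$taper)
      write_tiff(rec_pages, phase_files[k], type = "float32",
                 description = jsonlite::toJSON(params, auto_unbox = TRUE))
      if (k == 1)
        yaml::write_yaml(write_provenance(params, cfg),
                         out("reconstruct.yaml"))
    }
    report$reconstruct <- list(phase = phase_files)
  }

  if ("quantify" %in% stages) {
    phase_files <- sort(list.files(cfg$out_dir, "^phase_f[0-9]+\\.tif$",
                                   full.names = TRUE))
    if (!length(phase_files))
      stop("no phase stacks found; run the 'reconstruct' stage first")
    qc <- cfg$quant %||% list()
    calib <- calibration(kappa = qc$kappa %||% DEFAULT_KAPPA,
                         pixel_size = qc$pixel_size %||% 0.64)
    segcfg <- segmentation_config(tau = qc$tau %||% 0.21,
                                  min_area = qc$min_area %||% 50L)
    rows <- list()
    for (k in seq_along(phase_files)) {
      pages <- read_tiff(phase_files[k])
      for (t in seq_along(pages)) {
        dens <- phase_to_mass_density(pages[[t]], calib)
        mask <- segment_cells(pages[[t]], segcfg)
        mm <- measure_cells(mask, dens, calib, frame = t)
        if (nrow(mm)) {
          mm$field <- k
          rows[[length(rows) + 1]] <- mm
        }
      }
    }
    cells <- do.call(rbind, rows)
    # file convention: 0-based pixel coordinates
    cells$centroid_row <- cells$centroid_row - 1
    cells$centroid_col <- cells$centroid_col - 1
    write.csv(cells, out("cells.csv"), row.names = FALSE)
    report$quantify <- list(cells = out("cells.csv"), n_rows = nrow(cells))
  }

  if ("classify" %in% stages) {
    if (!file.exists(out("cells.csv")))
      stop("cells.csv not found; run the 'quantify' stage first")
    cells <- read.csv(out("cells.csv"))
    cells$centroid_row <- cells$centroid_row + 1
    cells$centroid_col <- cells$centroid_col + 1
    cl <- cfg$classify %||% list()
    up <- cl$up %||% 1.2; down <- cl$down %||% 0.8
    mass_tol <- cl$mass_tol %||% 0.07
    n_frames <- max(cells$frame)
    all_tracks <- list(); track_rows <- list()
    for (k in sort(unique(cells$field))) {
      sub <- cells[cells$field == k, ]
      frames <- lapply(seq_len(n_frames), function(t)
        sub[sub$frame == t, ])
      tr <- link_tracks(frames, max_disp = cl$max_disp %||% 20)
      for (t in tr) {
        t$field <- k
        all_tracks[[length(all_tracks) + 1]] <- t
        track_rows[[length(track_rows) + 1]] <-
          data.frame(field = k, cell_id = t$cell_id, frame = t$frames,
                     area_px = t$area_series, dry_mass = t$mass_series,
                     rel_area = t$rel_area_series)
      }
    }
    classes <- vapply(all_tracks, function(t)
      if (length(t$rel_area_series) >= 4)
        classify_trajectory(t, up = up, down = down) else NA_character_,
      character(1))
    keep <- !is.na(classes)
    summ <- cohort_summary(all_tracks[keep], classes[keep],
                           mass_tol = mass_tol)
    write.csv(do.call(rbind, track_rows), out("tracks.csv"),
              row.names = FALSE)
    yaml::write_yaml(write_provenance(
      list(fractions = as.list(summ$fractions),
           mass_stable_fraction = summ$mass_stable_fraction,
           mass_ratio_decrease_vs_rest = summ$mass_ratio_decrease_vs_rest,
           n_complete = summ$n_complete,
           thresholds = list(up = up, down = down, mass_tol = mass_tol)),
      cfg), out("summary.yaml"))
    report$classify <- summ
  }

  if ("fcm" %in% stages) {
    if (!file.exists(out("fcm_treated.csv")))
      stop("FCM event tables not found; run the 'simulate' stage first")
    control <- read_fcm_csv(out("fcm_control.csv"))
    treated <- read_fcm_csv(out("fcm_treated.csv"))
    fc <- cfg$fcm %||% list()
    gates <- fit_quadrant_gates(control, fc$percentile %||% 99.5)
    q <- quadrant_counts(treated, gates)
    q4 <- treated[treated$fl1_annexin >= gates$annexin_cut &
                    treated$fl3_pi < gates$pi_cut, ]
    b <- with_seed(derive_seed(cfg$seed, "backgate"),
                   backgate_fsc_split(q4))
    plain <- map_to_size_classes(q)
    adj <- map_to_size_classes(q, b, adjusted = TRUE)
    yaml::write_yaml(write_provenance(
      list(annexin_cut = gates$annexin_cut, pi_cut = gates$pi_cut,
           percentile = gates$percentile_used), cfg), out("gates.yaml"))
    yaml::write_yaml(write_provenance(
      list(quadrants = list(q1 = q$q1, q2 = q$q2, q3 = q$q3, q4 = q$q4,
                            total = q$total),
           backgate = list(r1 = b$r1, r2 = b$r2, fsc_split = b$fsc_split,
                           low_confidence = b$low_confidence),
           plain = as.list(plain$counts),
           adjusted = as.list(adj$counts)), cfg), out("counts.yaml"))
    report$fcm <- list(quadrants = q, backgate = b,
                       plain = plain$counts, adjusted = adj$counts)
  }

  if ("compare" %in% stages) {
    if (!file.exists(out("summary.yaml")) || !file.exists(out("counts.yaml")))
      stop("summary.yaml / counts.yaml not found; run the 'classify' and ",
           "'fcm' stages first")
    summ <- yaml::read_yaml(out("summary.yaml"))
    cnt <- yaml::read_yaml(out("counts.yaml"))
    n <- summ$n_complete
    mhm <- round(n * c(summ$fractions$no_change, summ$fractions$increase,
                       summ$fractions$decrease) / 100)
    fcm_plain <- unlist(cnt$plain)
    # scale the FCM row to the same total as the morphology row
    fcm_row <- round(fcm_plain / sum(fcm_plain) * sum(mhm))
    res <- chi2_compare(mhm, fcm_row)
    yaml::write_yaml(write_provenance(
      list(table = list(mhm = as.list(setNames(as.integer(mhm),
                                               c("normal", "increase",
                                                 "decrease"))),
                        fcm = as.list(setNames(as.integer(fcm_row),
                                               c("normal", "increase",
                                                 "decrease")))),
           chi2 = res$chi2, df = res$df, p = res$p), cfg),
      out("contingency.yaml"))
    report$compare <- list(chi2 = res$chi2, df = res$df, p = res$p)
  }

  if ("stage" %in% stages) {
    feat_file <- cfg$stage_features %||% out("features.csv")
    if (!file.exists(feat_file))
      stop("feature table ", feat_file, " not found; provide ",
           "'stage_features' or generate features first")
    features <- read.csv(feat_file)
    st <- stage_cohort(features)
    write.csv(data.frame(features, stage = st$stages), out("stages.csv"),
              row.names = FALSE)
    yaml::write_yaml(write_provenance(
      list(histogram = as.list(st$histogram)), cfg),
      out("stage_histogram.yaml"))
    report$stage <- st$histogram
  }

  report
}

# FCM CSV interchange with the documented header FSC,SSC,FL1,FL3,true_class.
write_fcm_csv <- function(events, path) {
  df <- data.frame(FSC = events$fsc, SSC = events$ssc,
                   FL1 = events$fl1_annexin, FL3 = events$fl3_pi)
  if (!is.null(events$true_class)) df$true_class <- events$true_class
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_fcm_csv <- function(path) {
  df <- read.csv(path)
  out <- data.frame(fsc = df$FSC, ssc = df$SSC, fl1_annexin = df$FL1,
                    fl3_pi = df$FL3)
  if (!is.null(df$true_class)) out$true_class <- df$true_class
  out
}

#' Build oncosis-staging features from a phantom cell's ground truth
#'
#' Translates a generated cell's known morphodynamics into per-frame feature
#' records: swelling (oncotic-track) cells accumulate blebs and progress
#' through annexin, PI, nuclear-swelling and karyolysis positivity at fixed
#' fractions of the time-lapse; shrinking (apoptotic-track) cells become
#' annexin-positive without blebs; unchanged cells stay negative.
#'
#' @param cell a `cell_phantom`.
#' @param rel_mass mass of the cell relative to the cohort mean.
#' @return data.frame of [oncosis_features()] rows, one per frame.
#' @export
features_from_phantom <- function(cell, rel_mass = 1) {
  n <- length(cell$phase_map_series)
  tfrac <- (seq_len(n) - 1) / (n - 1)
  blebs <- if (nrow(cell$bleb_events))
    vapply(seq_len(n), function(t) sum(cell$bleb_events$frame <= t),
           integer(1)) else integer(n)
  if (cell$fate == "increase") {
    oncosis_features(bleb_count = blebs,
                     spindle_shape_lost = tfrac >= 0.45,
                     nucleus_swollen = tfrac >= 0.75,
                     karyolysis_or_membrane_rupture = tfrac >= 0.95,
                     rel_mass = rel_mass,
                     annexin_pos = tfrac >= 0.45,
                     pi_pos = tfrac >= 0.75)
  } else if (cell$fate == "decrease") {
    oncosis_features(bleb_count = 0L, rel_mass = rel_mass,
                     annexin_pos = tfrac >= 0.4, pi_pos = FALSE)
  } else {
    oncosis_features(bleb_count = integer(n), rel_mass = rel_mass)
  }
}
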