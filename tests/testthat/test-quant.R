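# Dry-mass quantification: calibration, threshold segmentation, touching-cell
# separation and per-cell measurement.

test_that("phase maps linearly to mass density at the printed calibration", {
  calib <- calibration()
  expect_equal(phase_to_mass_density(matrix(0.21, 1, 1), calib)[1, 1], 0.05)
  expect_equal(phase_to_mass_density(matrix(0, 3, 3), calib),
               matrix(0, 3, 3))
  phi <- test_bump(64, 3, 12)
  expect_equal(phase_to_mass_density(2 * phi, calib),
               2 * phase_to_mass_density(phi, calib))
  # measured mass scales exactly with kappa
  mask <- segment_cells(phi, segmentation_config(min_area = 1))
  m1 <- measure_cells(mask, phase_to_mass_density(phi, calibration(1)))
  m2 <- measure_cells(mask, phase_to_mass_density(phi, calibration(2.5)))
  expect_equal(m2$dry_mass, 2.5 * m1$dry_mass)
})

test_that("segmentation is an exact threshold partition", {
  phi <- test_bump(128, 4, 15, center = c(40, 40)) +
    test_bump(128, 3, 12, center = c(90, 95))
  mask <- segment_cells(phi)
  expect_equal(mask$count, 2)
  # labels ordered by decreasing area
  a <- tabulate(mask$labels[mask$labels > 0])
  expect_true(a[1] >= a[2])

  expect_equal(segment_cells(matrix(0.1, 50, 50))$count, 0)

  # component area equals the brute-force count of pixels >= tau
  cfg <- segmentation_config(min_area = 1, fill_holes = FALSE)
  bump <- test_bump(64, 0.4, 18)
  m2 <- segment_cells(bump, cfg)
  expect_equal(sum(m2$labels > 0), sum(bump >= 0.21))

  # property: foreground iff phase >= tau, on random images
  set.seed(31)
  for (i in 1:5) {
    img <- matrix(runif(400, 0, 0.5), 20, 20)
    m <- segment_cells(img, cfg)
    expect_identical(m$labels > 0, img >= 0.21)
  }
})

test_that("hole filling recovers footprints with sub-threshold interiors", {
  phi <- test_bump(64, 4, 20)
  phi[28:36, 28:36] <- 0    # carve a hole below tau
  filled <- segment_cells(phi)
  unfilled <- segment_cells(phi, segmentation_config(fill_holes = FALSE,
                                                     min_area = 1))
  expect_equal(sum(filled$labels > 0) - sum(unfilled$labels > 0), 81)
})

test_that("marker-seeded watershed splits touching cells and conserves mass", {
  phi <- test_bump(100, 4, 20, center = c(50, 35)) +
    test_bump(100, 4, 20, center = c(50, 65))
  mask <- segment_cells(phi)
  expect_equal(mask$count, 1)           # merged pair
  dens <- phase_to_mass_density(phi, calibration())
  total_mass <- sum(dens[mask$labels > 0])

  split <- split_touching(mask, dens, rbind(c(50, 35), c(50, 65)))
  expect_equal(split$count, 2)
  mm <- measure_cells(split, dens)
  expect_lt(abs(mm$area_px[1] - mm$area_px[2]) / mm$area_px[1], 0.05)
  # mass additivity: the split conserves summed dry mass exactly
  expect_equal(sum(mm$dry_mass), total_mass)
  expect_equal(sum(split$labels > 0), sum(mask$labels > 0))

  # one marker per component, or none: identity
  expect_identical(split_touching(mask, dens, rbind(c(50, 35)))$labels,
                   mask$labels)
  expect_identical(split_touching(mask, dens, NULL)$labels, mask$labels)
  expect_error(split_touching(mask, dens, rbind(c(2, 2))), "background")
})

test_that("per-cell measurements are complete and consistent", {
  dens <- matrix(0, 10, 10)
  dens[5, 5] <- 0.05
  mask <- segment_cells(matrix(as.numeric(dens > 0) * 0.3, 10, 10),
                        segmentation_config(min_area = 1))
  mm <- measure_cells(mask, dens)
  expect_equal(mm$area_px, 1L)
  expect_equal(mm$dry_mass, 0.05)
  expect_equal(mm$mean_density, 0.05)
  expect_equal(c(mm$centroid_row, mm$centroid_col), c(5, 5))
  expect_equal(mm$area_um2, 0.64^2)

  empty <- segment_cells(matrix(0, 8, 8))
  expect_equal(nrow(measure_cells(empty, matrix(0, 8, 8))), 0)

  expect_error(measure_cells(mask, matrix(0, 4, 4)), "shape")

  # 300 pg phantom: measured mass within 3% (sub-threshold tail loss only)
  spec <- tiny_spec()
  cell <- make_cell_phantom(spec, c(128, 128), "no_change", seed = 2,
                            mass = 300)
  phi <- matrix(0, 256, 256)
  p <- cell$phase_map_series[[1]]
  r0 <- attr(p, "row0"); c0 <- attr(p, "col0")
  phi[r0:(r0 + nrow(p) - 1), c0:(c0 + ncol(p) - 1)] <- p
  mm2 <- measure_cells(segment_cells(phi),
                       phase_to_mass_density(phi, calibration()))
  expect_equal(mm2$dry_mass, 300, tolerance = 0.03)
  # dry_mass = mean_density * area within rounding
  expect_equal(mm2$dry_mass, mm2$mean_density * mm2$area_px)
})

test_that("noiseless phantom cohort mass recovery is within 1% median", {
  spec <- phantom_spec(cell_count = 9, n_frames = 2, seed = 17)
  coh <- simulate_timelapse_cohort(spec)
  phi <- cohort_phase_frame(coh, 1, 1)
  rec <- roundtrip_phase(phi)
  mm <- measure_cells(segment_cells(rec),
                      phase_to_mass_density(rec, calibration()))
  expect_equal(mm2 <- nrow(mm), 9)
  truth <- coh$truth[coh$truth$frame == 1, ]
  # match measured to truth by centroid
  err <- vapply(seq_len(nrow(truth)), function(i) {
    d <- (mm$centroid_row - (truth$centroid_row[i] + 1))^2 +
      (mm$centroid_col - (truth$centroid_col[i] + 1))^2
    j <- which.min(d)
    abs(mm$dry_mass[j] - truth$mass_pg[i]) / truth$mass_pg[i]
  }, numeric(1))
  expect_lt(median(err), 0.01)
})
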