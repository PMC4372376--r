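# Synthetic-data generator: cell phantoms, cohort assembly, hologram
# rendering and FCM event simulation.

test_that("single cells respect mass, calibration and degenerate cases", {
  spec <- tiny_spec()
  ctr <- c(128, 128)

  zero <- make_cell_phantom(spec, ctr, "no_change", seed = 1, mass = 0)
  expect_true(all(vapply(zero$phase_map_series,
                         function(p) all(p == 0), logical(1))))

  # the printed threshold pair as the unit case: 0.05 pg on one pixel
  # must read 0.21 rad
  px <- make_cell_phantom(spec, ctr, "no_change", seed = 1, mass = 0.05,
                          radius = 0.5)
  p1 <- px$phase_map_series[[1]]
  expect_equal(sum(p1 > 0), 1)
  expect_equal(max(p1), 0.21, tolerance = 1e-12)

  # integrated phase times kappa recovers the target mass (summation oracle)
  cell <- make_cell_phantom(spec, ctr, "increase", seed = 3, mass = 300)
  kappa <- 0.05 / 0.21
  for (t in c(1, 4, 8)) {
    m <- sum(cell$phase_map_series[[t]]) * kappa
    expect_lt(abs(m - 300) / 300, 0.001)
  }

  expect_error(make_cell_phantom(spec, c(-5, 10), "increase"),
               "outside image")
})

test_that("phantom morphodynamics are fate-consistent and mass-conserving", {
  spec <- phantom_spec(cell_count = 9, n_frames = 12, seed = 5)
  coh <- simulate_timelapse_cohort(spec)
  for (cell in coh$cells) {
    m <- cell$true_mass_series
    expect_lt(diff(range(m)) / mean(m), 0.02)       # mass conservation
    expect_true(all(unlist(cell$phase_map_series) >= 0))
    a <- cell$true_area_series
    if (cell$fate == "increase") {
      expect_true(all(diff(a) >= 0))
      expect_gt(nrow(cell$bleb_events), 0)
    } else if (cell$fate == "decrease") {
      expect_true(all(diff(a) <= 0))
    } else {
      expect_lt(max(abs(a / a[1] - 1)), 0.05)
    }
  }
})

test_that("cohort fate apportionment follows largest-remainder rounding", {
  spec <- phantom_spec(cell_count = 100, class_fractions =
                         c(no_change = 0.44, increase = 0.32,
                           decrease = 0.24),
                       n_frames = 2, seed = 2)
  coh <- simulate_timelapse_cohort(spec)
  expect_equal(unname(coh$counts), c(44L, 32L, 24L))
  expect_setequal(unique(coh$truth$fate),
                  c("decrease", "increase", "no_change"))

  all_nc <- simulate_timelapse_cohort(
    phantom_spec(cell_count = 5, class_fractions = c(1, 0, 0),
                 n_frames = 2, seed = 2))
  expect_true(all(all_nc$truth$fate == "no_change"))
})

test_that("packing failures are explicit", {
  spec <- phantom_spec(cell_count = 50, n_frames = 2, seed = 1)
  expect_error(simulate_timelapse_cohort(spec, n_fields = 1),
               "packing failure")
  # auto mode spreads the same cohort over several fields
  coh <- simulate_timelapse_cohort(spec)
  expect_gt(coh$n_fields, 1)
  expect_equal(nrow(coh$truth), 50 * 2)
})

test_that("hologram forward model obeys its bounds and spectral content", {
  phi <- test_bump(128, peak = 2, R = 20)
  h <- render_hologram(phi, carrier = c(0.25, 0), amps = c(1, 0.8),
                       noise_sd = 0)
  expect_true(all(h$intensity >= (1 - 0.8)^2 - 1e-9))
  expect_true(all(h$intensity <= (1 + 0.8)^2 + 1e-9))
  # cosine integrates out: mean intensity = Ao^2 + Ar^2 within 1%
  expect_equal(mean(h$intensity), 1 + 0.8^2, tolerance = 0.01)

  # flat phase: pure fringes at the carrier frequency
  flat <- render_hologram(matrix(0, 128, 128), carrier = c(0.25, 0),
                          noise_sd = 0)
  FI <- Mod(fft(flat$intensity - mean(flat$intensity)))
  peak <- which(FI == max(FI), arr.ind = TRUE)[1, ]
  expect_equal(unname(sort(abs(c((peak[1] - 1), (peak[2] - 1)) %% 128))),
               c(0, 32))  # 0.25 cycles/px on 128 px = bin 32

  # object beam off: constant reference intensity
  ref <- render_hologram(phi, carrier = c(0.25, 0), amps = c(0, 1),
                         noise_sd = 0)
  expect_true(all(abs(ref$intensity - 1) < 1e-12))

  expect_error(render_hologram(phi, carrier = c(0.01, 0)), "separability")
  expect_error(render_hologram(phi, carrier = c(0.4, 0.4)), "Nyquist")
})

test_that("identical seeds give bit-identical phantoms and event tables", {
  s <- phantom_spec(cell_count = 6, n_frames = 5, seed = 99)
  a <- simulate_timelapse_cohort(s)
  b <- simulate_timelapse_cohort(s)
  expect_identical(a$truth, b$truth)
  expect_identical(a$cells[[3]]$phase_map_series,
                   b$cells[[3]]$phase_map_series)
  e1 <- simulate_fcm_events(500, c(viable = 0.5, apoptotic = 0.5), seed = 7)
  e2 <- simulate_fcm_events(500, c(viable = 0.5, apoptotic = 0.5), seed = 7)
  expect_identical(e1, e2)
})

test_that("FCM simulation reproduces the intended gating structure", {
  expect_equal(nrow(simulate_fcm_events(0, c(viable = 1))), 0)
  expect_error(simulate_fcm_events(10, c(viable = 0.5)), "sum to 1")

  control <- simulate_fcm_events(10000, c(viable = 1), seed = 11)
  gates <- fit_quadrant_gates(control)
  stained <- simulate_fcm_events(10000, c(viable = 1), seed = 12)
  q <- quadrant_counts(stained, gates)
  expect_gte(q$q3 / q$total, 0.99)   # viable-only: >= 99% double-negative

  # apoptotic + oncotic mix: annexin+/PI- events bimodal in FSC
  mix <- simulate_fcm_events(3000, c(apoptotic = 0.45, oncotic = 0.55),
                             seed = 13)
  q4 <- mix[mix$fl1_annexin >= gates$annexin_cut &
              mix$fl3_pi < gates$pi_cut, ]
  expect_gt(nrow(q4), 2500)
  st <- local({ set.seed(21); silverman_test(log10(q4$fsc)) })
  expect_lt(st$p_value, 0.05)

  bad <- fcm_class_params()
  bad$viable$fsc[2] <- 0
  expect_error(simulate_fcm_events(10, c(viable = 1), class_params = bad),
               "scale")
})
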