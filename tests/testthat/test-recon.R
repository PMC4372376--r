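# Phase reconstruction: carrier estimation, demodulation, unwrapping,
# background flattening, simulated DIC, and the end-to-end oracle.

test_that("carrier estimation hits generator ground truth", {
  flat <- matrix(0, 256, 256)
  h <- render_hologram(flat, carrier = c(0.25, 0), noise_sd = 0)
  est <- estimate_carrier(h)
  expect_lt(max(abs(est - c(0.25, 0))), 0.002)

  set.seed(4)
  h2 <- render_hologram(test_bump(256, 5, 25), carrier = c(0.18, 0.18),
                        noise_sd = 0.02)
  est2 <- estimate_carrier(h2)
  expect_lt(max(abs(est2 - c(0.18, 0.18))), 0.005)

  expect_error(estimate_carrier(matrix(1, 64, 64)), "no carrier detected")
})

test_that("demodulation recovers wrapped phase from the sideband", {
  flat <- render_hologram(matrix(0, 128, 128), carrier = c(0.25, 0),
                          noise_sd = 0)
  w <- demodulate(flat)
  expect_lt(diff(range(w$values)), 1e-6)
  expect_true(all(w$values > -pi & w$values <= pi))

  # sub-pi bump: no wrapping, demodulated phase matches truth directly
  phi <- test_bump(256, peak = 2.5, R = 30)
  h <- render_hologram(phi, noise_sd = 0)
  w2 <- demodulate(h)
  err <- w2$values - phi
  err <- err - mean(err)
  expect_lt(sqrt(mean(err^2)), 1e-3)

  # phase is invariant to object amplitude
  h_lo <- render_hologram(phi, amps = c(1, 1), noise_sd = 0)
  h_hi <- render_hologram(phi, amps = c(2, 1), noise_sd = 0)
  d <- wrap_to_pi(demodulate(h_hi)$values - demodulate(h_lo)$values)
  expect_lt(max(abs(d - mean(d))), 1e-6)

  expect_warning(
    demodulate(render_hologram(phi, carrier = c(0.31, 0.31), noise_sd = 0),
               sideband_filter(c(0.31, 0.31), radius = 0.21)),
    "clipped")
})

test_that("quality-guided unwrapping handles ramps, identity and wraps", {
  # linear ramp reaching 6*pi across the image, closed-form oracle
  n <- 128
  ramp <- matrix(seq(0, 6 * pi, length.out = n), n, n, byrow = TRUE)
  wrapped <- wrap_to_pi(ramp)
  un <- unwrap_phase(wrapped)$values
  err <- un - ramp
  expect_lt(max(abs(err - mean(err))), 1e-3)

  # already-continuous input: identity up to a constant
  small <- test_bump(64, peak = 2, R = 15)
  out <- unwrap_phase(small)$values
  d <- out - small
  expect_lt(max(abs(d - mean(d))), 1e-9)

  # unwrap(wrap(phi)) - phi is a constant multiple of 2*pi
  set.seed(8)
  phi <- test_gaussian(128, peak = 9, sigma = 18) +
    test_gaussian(128, peak = 4, sigma = 25, center = c(40, 90))
  rec <- unwrap_phase(wrap_to_pi(phi))$values
  d2 <- rec - phi
  expect_lt(diff(range(d2)), 1e-6)
  # spatially constant offset: a 2*pi multiple up to the mode-zeroing
  # convention (background mode snapped to zero in 0.01 rad bins)
  expect_lt(abs(wrap_to_pi(mean(d2))), 0.02)

  expect_error(
    unwrap_phase(structure(list(values = matrix(0, 4, 4),
                                amplitude = matrix(0, 4, 4)),
                           class = "wrapped_phase")),
    "no reliable seed")
})

test_that("full chain recovers an 8 rad peak through 1% noise", {
  set.seed(5)
  phi <- test_gaussian(256, peak = 8, sigma = 22)
  rec <- roundtrip_phase(phi, noise_sd = 0.02)
  expect_equal(max(rec$values), 8, tolerance = 0.05 / 8)
})

test_that("background flattening annihilates planes and preserves mass", {
  n <- 128
  tilt <- outer(seq_len(n), seq_len(n), function(r, c) 0.01 * r - 0.004 * c)
  out <- flatten_background(tilt)$values
  expect_lt(max(abs(out)), 1e-9)

  expect_equal(flatten_background(matrix(0, 64, 64))$values,
               matrix(0, 64, 64))

  # phantom + synthetic tilt: recovered mass within 0.5% of ground truth
  phi <- test_bump(256, peak = 6.5, R = 20)
  kappa <- 0.05 / 0.21
  true_mass <- sum(phi[phi >= 0.21]) * kappa
  tilted <- phi + outer(seq_len(256), seq_len(256),
                        function(r, c) 0.01 * r)
  flat <- flatten_background(tilted)
  mm <- measure_cells(segment_cells(flat),
                      phase_to_mass_density(flat, calibration()))
  expect_equal(mm$dry_mass, true_mass, tolerance = 0.005)

  expect_error(flatten_background(phi, exclude_mask = matrix(TRUE, 256, 256)),
               "90%")
})

test_that("simulated DIC is a biased 1D gradient with edge replication", {
  const <- matrix(3, 32, 32)
  expect_equal(simulated_dic(const, "row", bias = 0.5),
               matrix(0.5, 32, 32))

  ramp <- matrix(seq(0, 3.1, length.out = 32), 32, 32)  # slope s per row
  s <- 3.1 / 31
  expect_equal(simulated_dic(ramp, "row", bias = 0.2),
               matrix(s + 0.2, 32, 32), tolerance = 1e-12)

  # antisymmetric response to a symmetric bump: window sums to bias*count
  phi <- test_bump(65, peak = 3, R = 20, center = c(33, 33))
  d <- simulated_dic(phi, "col", bias = 0.1)
  win <- d[33, 13:53]
  expect_equal(sum(win), 0.1 * length(win), tolerance = 1e-9)
  expect_equal(dim(d), dim(phi))
})

test_that("reconstruction is invariant to carrier direction", {
  phi <- test_bump(256, peak = 6.5, R = 26)
  # carriers at 0, 45 and 90 degrees, on exact spectral bins of the
  # 256-px grid so the rendered fringes are periodic
  recs <- lapply(list(c(64, 0) / 256, c(45, 45) / 256, c(0, 64) / 256),
                 function(cr) roundtrip_phase(phi, carrier = cr)$values)
  for (k in 2:3) {
    d <- recs[[1]] - recs[[k]]
    expect_lt(sqrt(mean(d^2)), 1e-2)
  }
})

test_that("noiseless end-to-end error stays below 1e-2 rad RMS", {
  for (peak in c(4, 8, 12)) {
    phi <- test_bump(256, peak = peak, R = 30)
    rec <- roundtrip_phase(phi)
    expect_lt(sqrt(mean((rec$values - phi)^2)), 1e-2)
  }
})
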