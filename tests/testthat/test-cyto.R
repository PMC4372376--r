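# Flow-cytometry gating, back-gating, size-class mapping and the Pearson
# chi-squared comparison.

control_events <- function(seed = 101, n = 10000)
  simulate_fcm_events(n, c(viable = 1), seed = seed)

test_that("quadrant gates derive from the unstained control percentile", {
  ctl <- control_events()
  gates <- fit_quadrant_gates(ctl)
  expect_equal(gates$percentile_used, 99.5)
  pos <- ctl$fl1_annexin >= gates$annexin_cut |
    ctl$fl3_pi >= gates$pi_cut
  expect_lte(mean(pos), 0.01)

  g100 <- fit_quadrant_gates(ctl, percentile = 100)
  q <- quadrant_counts(ctl, g100)
  expect_equal(q$q3, q$total)

  # stained apoptotic-heavy mix gates far more annexin-positive
  mix <- simulate_fcm_events(5000, c(viable = 0.4, apoptotic = 0.6),
                             seed = 7)
  qm <- quadrant_counts(mix, gates)
  expect_gt((qm$q2 + qm$q4) / qm$total, 10 * mean(pos))

  expect_error(fit_quadrant_gates(ctl[1:50, ]), "100")
})

test_that("quadrant partition is exhaustive with inclusive boundaries", {
  gates <- structure(list(annexin_cut = 100, pi_cut = 200,
                          percentile_used = NA),
                     class = "gate_config")
  ev <- data.frame(fl1_annexin = c(50, 100, 150, 99.9),
                   fl3_pi = c(50, 200, 100, 250))
  q <- quadrant_counts(ev, gates)
  expect_equal(q$q1 + q$q2 + q$q3 + q$q4, q$total)
  expect_equal(c(q$q1, q$q2, q$q3, q$q4), c(1, 1, 1, 1))
  # the event exactly at both cuts landed in Q2
  low <- data.frame(fl1_annexin = rep(1, 5), fl3_pi = rep(1, 5))
  expect_equal(quadrant_counts(low, gates)$q3, 5)

  # partition + gate monotonicity on random event sets
  set.seed(13)
  for (i in 1:5) {
    ev2 <- data.frame(fl1_annexin = rlnorm(500, 5, 1),
                      fl3_pi = rlnorm(500, 5, 1))
    cuts <- sort(rlnorm(4, 5, 1))
    prev <- Inf
    for (ac in cuts) {
      g <- structure(list(annexin_cut = ac, pi_cut = 150),
                     class = "gate_config")
      qq <- quadrant_counts(ev2, g)
      expect_equal(qq$q1 + qq$q2 + qq$q3 + qq$q4, 500)
      expect_lte(qq$q2 + qq$q4, prev)   # raising the cut never adds annexin+
      prev <- qq$q2 + qq$q4
    }
  }
})

test_that("treated-mix quadrant fractions match the generator mix", {
  gates <- fit_quadrant_gates(control_events())
  mix <- simulate_fcm_events(10000, c(viable = 0.62, apoptotic = 0.17,
                                      oncotic = 0.13, necrotic = 0.08),
                             seed = 9)
  q <- quadrant_counts(mix, gates)
  expect_lt(abs(q$q4 / q$total - 0.30), 0.02)
  expect_lt(abs(q$q2 / q$total - 0.08), 0.02)
})

test_that("FSC back-gating separates the two annexin+/PI- populations", {
  # two log-normal FSC modes 6 sigma apart (3 sigma each side of the cut)
  params <- fcm_class_params()
  params$apoptotic$fsc <- c(2.50, 0.075)
  params$oncotic$fsc <- c(2.95, 0.075)
  ev <- simulate_fcm_events(4000, c(apoptotic = 0.42, oncotic = 0.58),
                            class_params = params, seed = 15)
  b <- local({ set.seed(1); backgate_fsc_split(ev) })
  expect_equal(b$r1 + b$r2, nrow(ev))
  truth_r1 <- ev$true_class == "apoptotic"
  mis <- sum((ev$fsc < b$fsc_split) != truth_r1)
  expect_lt(mis / nrow(ev), 0.02)
  expect_false(b$low_confidence)

  # degenerate: identical FSC falls back and is flagged
  same <- data.frame(fsc = rep(300, 50))
  expect_warning(bd <- backgate_fsc_split(same), "low-confidence")
  expect_true(bd$low_confidence)
  expect_equal(bd$r1 + bd$r2, 50)

  expect_error(backgate_fsc_split(data.frame(fsc = 1:5)), "20")
})

test_that("back-gate recovers the 9.51:13.22 apoptotic:oncotic split", {
  gates <- fit_quadrant_gates(control_events())
  mix <- simulate_fcm_events(10000, c(viable = 0.63, apoptotic = 0.0951,
                                      oncotic = 0.1322, necrotic = 0.08,
                                      debris = 0.0627), seed = 33)
  q4 <- mix[mix$fl1_annexin >= gates$annexin_cut &
              mix$fl3_pi < gates$pi_cut, ]
  b <- local({ set.seed(2); backgate_fsc_split(q4) })
  expect_lt(abs(b$r1 / nrow(q4) - 9.51 / (9.51 + 13.22)), 0.02)
  expect_lt(abs(b$r2 / nrow(q4) - 13.22 / (9.51 + 13.22)), 0.02)
})

test_that("size-class mapping follows the plain and adjusted conventions", {
  q <- structure(list(q1 = 0, q2 = 8, q3 = 61, q4 = 31, total = 100),
                 class = "quadrant_counts")
  plain <- map_to_size_classes(q)
  expect_equal(unname(plain$counts), c(61, 8, 31))
  expect_equal(plain$debris, 0)

  b <- structure(list(r1 = 10, r2 = 21, fsc_split = 500),
                 class = "backgate_result")
  adj <- map_to_size_classes(q, b, adjusted = TRUE)
  expect_equal(unname(adj$counts), c(61, 29, 10))

  q0 <- structure(list(q1 = 2, q2 = 5, q3 = 93, q4 = 0, total = 100),
                  class = "quadrant_counts")
  b0 <- structure(list(r1 = 0, r2 = 0), class = "backgate_result")
  expect_equal(unname(map_to_size_classes(q0, b0, TRUE)$counts[3]), 0)

  expect_error(map_to_size_classes(q, adjusted = TRUE), "back-gate")
})

test_that("Pearson chi-squared reproduces printed and hand-computed values", {
  res <- chi2_compare(c(44, 32, 24), c(61, 8, 31))
  expect_equal(round(res$chi2, 3), 18.043)
  expect_equal(res$df, 2)
  expect_equal(res$p, 1.2e-4, tolerance = 0.05)

  same <- chi2_compare(c(10, 20, 30), c(10, 20, 30))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  expect_equal(chi2_compare(c(10, 0), c(0, 10))$chi2, 20)
  expect_error(chi2_compare(c(1, 0), c(2, 0)), "column")
  expect_error(chi2_compare(c(1, 2), c(-1, 2)), "nonnegative")
})

test_that("chi-squared equals the brute-force oracle and is symmetric", {
  set.seed(55)
  for (i in 1:100) {
    a <- rpois(3, 40) + 1
    b <- rpois(3, 40) + 1
    res <- chi2_compare(a, b)
    expect_equal(res$chi2, chi2_bruteforce(rbind(a, b)), tolerance = 1e-12)
    # invariance under row swap and joint column permutation
    expect_equal(chi2_compare(b, a)$chi2, res$chi2)
    p <- sample(3)
    expect_equal(chi2_compare(a[p], b[p])$chi2, res$chi2)
  }
})

test_that("the adjusted Table rows verify against the printed statistic", {
  # oncosis-adjusted comparison row: (61, 13, 21) against morphology
  res <- chi2_compare(c(44, 32, 24), c(61, 13, 21))
  expect_equal(round(res$chi2, 2), 10.85)
  expect_equal(res$p, 0.0044, tolerance = 0.01)
})
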