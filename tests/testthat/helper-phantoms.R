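# Shared fixtures, built in code.

# Radial raised-cosine bump on an n x n grid (matches the generator's dome).
test_bump <- function(n = 256, peak = 6.5, R = 30,
                      center = c(n %/% 2 + 1, n %/% 2 + 1)) {
  r <- row(matrix(0, n, n)) - center[1]
  c2 <- col(matrix(0, n, n)) - center[2]
  u <- sqrt(r^2 + c2^2) / R
  out <- peak * (0.5 + 0.5 * cos(pi * pmin(u, 1)))
  out[u > 1] <- 0
  out
}

test_gaussian <- function(n = 256, peak = 8, sigma = 20,
                          center = c(n %/% 2 + 1, n %/% 2 + 1)) {
  r <- row(matrix(0, n, n)) - center[1]
  c2 <- col(matrix(0, n, n)) - center[2]
  peak * exp(-(r^2 + c2^2) / (2 * sigma^2))
}

tiny_spec <- function(...) {
  phantom_spec(cell_count = 4L, n_frames = 8L, seed = 42L, ...)
}

# Noiseless reconstruction of a phase map through the full forward+inverse
# chain with the default carrier.
roundtrip_phase <- function(phi, noise_sd = 0, carrier = c(77/256, 77/256)) {
  holo <- render_hologram(phi, carrier = carrier, noise_sd = noise_sd)
  flatten_background(unwrap_phase(demodulate(holo)))
}

# Brute-force Pearson chi-square oracle: explicit double loop over the
# observed table, independent of the vectorised implementation.
chi2_bruteforce <- function(O) {
  O <- unname(as.matrix(O))
  total <- sum(O)
  stat <- 0
  for (i in seq_len(nrow(O))) {
    for (j in seq_len(ncol(O))) {
      E <- sum(O[i, ]) * sum(O[, j]) / total
      stat <- stat + (O[i, j] - E)^2 / E
    }
  }
  stat
}
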