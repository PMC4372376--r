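# Internal numeric helpers shared across modules.

#' Wrap phase values to the principal interval (-pi, pi]
#'
#' @param x numeric vector or matrix of phase values in radians.
#' @return object of the same shape with every value in (-pi, pi].
#' @examples
#' wrap_to_pi(c(0, pi, -pi, 7))
#' @export
wrap_to_pi <- function(x) {
  y <- x %% (2 * pi)          # [0, 2*pi)
  y[y > pi] <- y[y > pi] - 2 * pi
  y
}

# FFT sample frequencies in cycles/pixel, unshifted (DC first), like the
# standard fftfreq convention.
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / n
}

# Histogram mode with fixed-width bins (default 0.01 rad), used as the global
# phase-offset convention: the most populated background bin is mapped to zero.
bin_mode <- function(x, bw = 0.01) {
  b <- as.integer(round(x / bw))
  b0 <- min(b)
  counts <- tabulate(b - b0 + 1L)
  (which.max(counts) + b0 - 1L) * bw
}

# Deterministic derivation of per-stage seeds from one master seed; results
# stay below 2^31 so they are valid R integer seeds.
derive_seed <- function(master, stage) {
  offsets <- c(phantom = 101L, hologram = 211L, fcm = 307L, noise = 401L,
               pipeline = 503L, backgate = 601L)
  off <- offsets[[stage]]
  as.integer((as.numeric(master) * 48271 + off) %% 2147483647)
}

# Largest-remainder apportionment of n items to fractions; ties broken by
# position (earlier class wins), so counts are fully deterministic.
largest_remainder <- function(n, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  raw <- n * fractions
  counts <- floor(raw)
  rem <- raw - counts
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(-rem, seq_along(rem))
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
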