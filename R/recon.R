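# Numerical reconstruction of quantitative phase from off-axis holograms:
# carrier estimation, Fourier sideband demodulation, quality-guided phase
# unwrapping, first-order background flattening, and a simulated-DIC display.

as_intensity <- function(holo) {
  if (inherits(holo, "hologram_frame")) holo$intensity
  else if (is.matrix(holo)) holo
  else stop("expected a hologram_frame or intensity matrix")
}

#' Construct a sideband filter
#'
#' Circular spectral window centred on the object sideband. The default
#' window is flat out to 70% of the radius with a cosine (Tukey) rolloff
#' beyond; a full `"hann"` taper is also available but attenuates in-band
#' sideband content and measurably biases dry mass (see vignette).
#'
#' @param center `(f_x, f_y)` sideband centre, cycles/pixel.
#' @param radius window radius, cycles/pixel. Must exclude DC.
#' @param taper `"tukey"` (default) or `"hann"`.
#' @param flat_frac flat fraction of the Tukey window radius.
#' @return object of class `sideband_filter`.
#' @export
sideband_filter <- function(center, radius = 0.45 * sqrt(sum(center^2)),
                            taper = c("tukey", "hann"), flat_frac = 0.7) {
  taper <- match.arg(taper)
  if (radius <= 0) stop("filter radius must be positive")
  if (sqrt(sum(center^2)) <= radius)
    stop("sideband filter must exclude DC: |center| must exceed radius")
  structure(list(center = as.numeric(center), radius = radius,
                 taper = taper, flat_frac = flat_frac),
            class = "sideband_filter")
}

#' Estimate the carrier frequency of an off-axis hologram
#'
#' Locates the strongest spectral magnitude outside a DC-exclusion disk of
#' 0.05 cycles/pixel and refines it to sub-bin precision with a local
#' quadratic fit. The estimate is canonicalised to the `f_x > 0` (or
#' `f_x = 0, f_y > 0`) half-plane; [demodulate()] assumes the object
#' sideband sits there, which holds for holograms rendered with a positive
#' carrier as in [render_hologram()].
#'
#' @param holo `hologram_frame` or intensity matrix.
#' @return numeric `(f_x, f_y)` in cycles/pixel.
#' @export
estimate_carrier <- function(holo) {
  I <- as_intensity(holo)
  nr <- nrow(I); nc <- ncol(I)
  FI <- fft(I - mean(I))
  mag <- Mod(FI)
  fr <- fft_freqs(nr); fc <- fft_freqs(nc)
  dist <- sqrt(matrix(fr^2, nr, nc) + matrix(fc^2, nr, nc, byrow = TRUE))
  mag[dist <= 0.05] <- 0
  med <- median(mag[dist > 0.05])
  peak <- which.max(mag)
  if (mag[peak] < 3 * med || mag[peak] == 0)
    stop("no carrier detected: no off-DC spectral peak above 3x median")
  pr <- (peak - 1) %% nr + 1
  pc <- (peak - 1) %/% nr + 1
  refine <- function(vals) {
    # vertex of the parabola through (-1, v1), (0, v2), (1, v3)
    den <- vals[1] - 2 * vals[2] + vals[3]
    if (den == 0) return(0)
    d <- 0.5 * (vals[1] - vals[3]) / den
    max(min(d, 0.5), -0.5)
  }
  wrap1 <- function(i, n) (i - 1) %% n + 1
  dr <- refine(c(mag[wrap1(pr - 1, nr), pc], mag[pr, pc],
                 mag[wrap1(pr + 1, nr), pc]))
  dc <- refine(c(mag[pr, wrap1(pc - 1, nc)], mag[pr, pc],
                 mag[pr, wrap1(pc + 1, nc)]))
  f_y <- fr[pr] + dr / nr
  f_x <- fc[pc] + dc / nc
  if (f_x > 0.5) f_x <- f_x - 1
  if (f_y > 0.5) f_y <- f_y - 1
  if (f_x < 0 || (f_x == 0 && f_y < 0)) { f_x <- -f_x; f_y <- -f_y }
  c(f_x = f_x, f_y = f_y)
}

#' Demodulate an off-axis hologram to wrapped phase
#'
#' Computes the 2D spectrum, windows the object sideband with the tapered
#' filter, translates it exactly to the origin (sub-bin carriers handled by
#' a spatial-domain complex ramp), and inverse-transforms. The wrapped
#' phase is the argument of the resulting complex field and the amplitude
#' its magnitude. Spectra are zero-padded to the next even fast length;
#' values are returned on the original grid.
#'
#' @param holo `hologram_frame` or intensity matrix.
#' @param filt a [sideband_filter()]; default centres on the rendered (or
#'   estimated) carrier with radius 0.45 times its magnitude.
#' @return object of class `wrapped_phase` with fields `values` (radians,
#'   in `(-pi, pi]`) and `amplitude`.
#' @export
demodulate <- function(holo, filt = NULL) {
  I <- as_intensity(holo)
  if (is.null(filt)) {
    carrier <- if (inherits(holo, "hologram_frame")) holo$carrier
               else estimate_carrier(holo)
    filt <- sideband_filter(carrier)
  }
  nr <- nrow(I); nc <- ncol(I)
  pr <- max(nextn(nr, c(2, 3, 5)), nr); if (pr %% 2) pr <- nextn(pr + 1, 2)
  pc <- max(nextn(nc, c(2, 3, 5)), nc); if (pc %% 2) pc <- nextn(pc + 1, 2)
  pad <- matrix(0, pr, pc)
  pad[seq_len(nr), seq_len(nc)] <- I
  FI <- fft(pad)
  fr <- fft_freqs(pr); fc <- fft_freqs(pc)
  D <- sqrt(matrix(fr - filt$center[2], pr, pc)^2 +
              matrix(fc - filt$center[1], pr, pc, byrow = TRUE)^2)
  if (max(abs(filt$center)) + filt$radius > 0.5)
    warning("sideband filter clipped by the spectrum edge; proceeding ",
            "with the clipped mask")
  mask <- matrix(0, pr, pc)
  if (filt$taper == "hann") {
    inside <- D <= filt$radius
    mask[inside] <- 0.5 + 0.5 * cos(pi * D[inside] / filt$radius)
  } else {
    edge <- filt$radius * filt$flat_frac
    mask[D <= edge] <- 1
    roll <- D > edge & D <= filt$radius
    mask[roll] <- 0.5 + 0.5 * cos(pi * (D[roll] - edge) /
                                    (filt$radius - edge))
  }
  field <- fft(FI * mask, inverse = TRUE) / (pr * pc)
  field <- field[seq_len(nr), seq_len(nc)]
  x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  y <- matrix(0:(nr - 1), nr, nc)
  field <- field * exp(-2i * pi * (filt$center[1] * x + filt$center[2] * y))
  # the sideband at +carrier carries exp(-i*phi); negate to recover phi
  structure(list(values = wrap_to_pi(-Arg(field)), amplitude = Mod(field),
                 filter = filt),
            class = "wrapped_phase")
}

#' Construct a phase image
#'
#' @param values 2D continuous phase map, radians.
#' @param pixel_size pixel pitch in micrometres (NA if unknown).
#' @param provenance named list of reconstruction parameters.
#' @return object of class `phase_image`.
#' @export
phase_image <- function(values, pixel_size = NA_real_,
                        provenance = list()) {
  stopifnot(is.matrix(values))
  structure(list(values = values, pixel_size = pixel_size,
                 provenance = provenance),
            class = "phase_image")
}

phase_values <- function(phase) {
  if (inherits(phase, "phase_image")) phase$values
  else if (is.matrix(phase)) phase
  else stop("expected a phase_image or matrix")
}

#' Quality-guided 2D phase unwrapping
#'
#' Pixel quality is the demodulated amplitude divided by the local variance
#' of the wrapped phase gradients (3x3 window); pixels are integrated by a
#' flood fill from the highest-quality seed, visiting the frontier in
#' decreasing quality order with a deterministic row-major tie-break. The
#' result has its background mode (0.01 rad histogram bins) subtracted, so
#' it equals the true phase up to a global `2*pi*k` offset.
#'
#' @param wrapped a `wrapped_phase` from [demodulate()], or a matrix of
#'   wrapped phase values (unit amplitude assumed).
#' @return a [phase_image()].
#' @export
unwrap_phase <- function(wrapped) {
  if (is.matrix(wrapped))
    wrapped <- structure(list(values = wrapped,
                              amplitude = matrix(1, nrow(wrapped),
                                                 ncol(wrapped))),
                         class = "wrapped_phase")
  w <- wrapped$values
  amp <- wrapped$amplitude
  if (all(amp == 0)) stop("no reliable seed: amplitude map is all zero")
  nr <- nrow(w); nc <- ncol(w)
  # wrapped forward gradients, edge-replicated
  gr <- rbind(wrap_to_pi(w[-1, , drop = FALSE] - w[-nr, , drop = FALSE]),
              matrix(0, 1, nc))
  gc <- cbind(wrap_to_pi(w[, -1, drop = FALSE] - w[, -nc, drop = FALSE]),
              matrix(0, nr, 1))
  box3 <- function(m) {        # 3x3 box sum via cumulative sums, same size
    p <- matrix(0, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- m
    cs <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed cumsum matrix
    cs <- t(cs)
    Z <- rbind(0, cbind(0, cs))
    Z[4:(nr + 3), 4:(nc + 3)] - Z[4:(nr + 3), 1:nc] -
      Z[1:nr, 4:(nc + 3)] + Z[1:nr, 1:nc]
  }
  var_local <- function(g) {
    n <- box3(matrix(1, nr, nc))
    s1 <- box3(g); s2 <- box3(g * g)
    pmax(s2 / n - (s1 / n)^2, 0)
  }
  quality <- amp / (1e-8 + var_local(gr) + var_local(gc))
  seed_idx <- which.max(quality)
  out <- .cpp_unwrap_qg(w, quality, seed_idx - 1L)
  out <- out - bin_mode(out)
  phase_image(out, provenance = list(method = "quality_guided"))
}

#' Flatten the phase background with a first-order plane
#'
#' Fits a least-squares plane to background pixels (those at or below a
#' robust percentile of the phase values, or outside `exclude_mask` when
#' given), subtracts it, and re-zeros the background mode. Required for the
#' absolute 0.21 rad segmentation threshold to be meaningful.
#'
#' @param phase a [phase_image()] or matrix.
#' @param exclude_mask optional logical matrix, TRUE over cells/objects to
#'   exclude from the background fit. Must leave at least 10% of pixels.
#' @param bg_percentile percentile (0-1) below which pixels are treated as
#'   background when no mask is given.
#' @return a [phase_image()] with background median (and mode) at zero.
#' @export
flatten_background <- function(phase, exclude_mask = NULL,
                               bg_percentile = 0.5) {
  v <- phase_values(phase)
  nr <- nrow(v); nc <- ncol(v)
  if (!is.null(exclude_mask)) {
    if (mean(exclude_mask) > 0.9)
      stop("exclude_mask covers more than 90% of the image")
    bg <- !exclude_mask
  } else {
    bg <- v <= quantile(v, bg_percentile)
  }
  if (mean(bg) < 0.1) stop("fewer than 10% background pixels available")
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  idx <- which(bg)
  if (length(idx) > 50000) idx <- idx[seq(1, length(idx), length.out = 50000)]
  X <- cbind(1, rr[idx], cc[idx])
  beta <- qr.solve(crossprod(X), crossprod(X, v[idx]))
  flat <- v - (beta[1] + beta[2] * rr + beta[3] * cc)
  flat <- flat - bin_mode(flat[bg])
  out <- if (inherits(phase, "phase_image")) phase else phase_image(flat)
  out$values <- flat
  out$provenance <- c(out$provenance, list(flatten = as.numeric(beta)))
  out
}

#' Simulated differential interference contrast display
#'
#' 1D forward-difference gradient of the quantitative phase image along the
#' chosen axis, plus a constant bias; the trailing line of the gradient is
#' replicated so the output matches the input shape.
#'
#' @param phase a [phase_image()] or matrix.
#' @param axis `"row"` or `"col"`: direction of differentiation.
#' @param bias constant offset (radians) added for display.
#' @return numeric matrix, same shape as the input.
#' @export
simulated_dic <- function(phase, axis = c("row", "col"), bias = 0) {
  axis <- match.arg(axis)
  v <- phase_values(phase)
  nr <- nrow(v); nc <- ncol(v)
  if (axis == "row") {
    d <- v[-1, , drop = FALSE] - v[-nr, , drop = FALSE]
    d <- rbind(d, d[nr - 1, , drop = FALSE])
  } else {
    d <- v[, -1, drop = FALSE] - v[, -nc, drop = FALSE]
    d <- cbind(d, d[, nc - 1, drop = FALSE])
  }
  d + bias
}

#' Reconstruct an unwrapped, flattened phase image from a hologram
#'
#' Convenience chain: [demodulate()] (auto carrier unless given),
#' [unwrap_phase()], [flatten_background()].
#'
#' @param holo `hologram_frame` or intensity matrix.
#' @param carrier `(f_x, f_y)` carrier override, or `NULL` for automatic
#'   estimation (rendered holograms carry their own).
#' @param radius sideband radius override, cycles/pixel.
#' @param pixel_size propagated to the result.
#' @return a [phase_image()].
#' @export
reconstruct_phase <- function(holo, carrier = NULL, radius = NULL,
                              pixel_size = NA_real_) {
  if (is.null(carrier)) {
    carrier <- if (inherits(holo, "hologram_frame")) holo$carrier
               else estimate_carrier(holo)
  }
  filt <- if (is.null(radius)) sideband_filter(carrier)
          else sideband_filter(carrier, radius)
  out <- flatten_background(unwrap_phase(demodulate(holo, filt)))
  out$pixel_size <- pixel_size
  out$provenance <- c(out$provenance,
                      list(carrier = as.numeric(carrier),
                           radius = filt$radius, taper = filt$taper))
  out
}
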