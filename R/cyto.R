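# Flow-cytometry analysis: quadrant gating from an unstained control, FSC
# back-gating of the annexin+/PI- population, mapping of gated counts to
# size classes, and Pearson chi-squared comparison against morphology.

#' Fit annexin V / PI quadrant gates from an unstained control
#'
#' Places the annexin (FL1) and PI (FL3) cuts at the stated percentile of
#' the unstained control's channel distributions, so at most
#' `2 * (100 - percentile)` percent of the control itself gates positive.
#'
#' @param unstained data.frame of control events with columns `fl1_annexin`
#'   and `fl3_pi` (at least 100 events).
#' @param percentile percentile (in percent) for both cuts.
#' @return object of class `gate_config` with `annexin_cut`, `pi_cut`,
#'   `percentile_used`.
#' @export
fit_quadrant_gates <- function(unstained, percentile = 99.5) {
  if (nrow(unstained) < 100)
    stop("need at least 100 unstained events to set gates")
  a_cut <- unname(quantile(unstained$fl1_annexin, percentile / 100))
  p_cut <- unname(quantile(unstained$fl3_pi, percentile / 100))
  if (percentile >= 100) {
    # positivity is boundary-inclusive, so the 100th-percentile cut sits
    # just above the channel maximum: the whole control stays negative
    a_cut <- a_cut * (1 + 1e-12)
    p_cut <- p_cut * (1 + 1e-12)
  }
  structure(list(annexin_cut = a_cut, pi_cut = p_cut,
                 percentile_used = percentile),
            class = "gate_config")
}

#' Partition events into annexin V / PI quadrants
#'
#' Boundary values count as positive (an event exactly at both cuts is Q2).
#' Q1 = annexin-/PI+, Q2 = annexin+/PI+, Q3 = annexin-/PI- (viable),
#' Q4 = annexin+/PI-.
#'
#' @param events data.frame with `fl1_annexin`, `fl3_pi`.
#' @param gates a [fit_quadrant_gates()] result.
#' @return object of class `quadrant_counts` with `q1`..`q4`, `total`.
#' @export
quadrant_counts <- function(events, gates) {
  ann <- events$fl1_annexin >= gates$annexin_cut
  pi_pos <- events$fl3_pi >= gates$pi_cut
  structure(list(q1 = sum(!ann & pi_pos), q2 = sum(ann & pi_pos),
                 q3 = sum(!ann & !pi_pos), q4 = sum(ann & !pi_pos),
                 total = nrow(events)),
            class = "quadrant_counts")
}

# Smallest kernel bandwidth at which the Gaussian KDE of x is unimodal
# (Silverman's critical bandwidth), found by bisection.
critical_bandwidth <- function(x, tol = 1e-3) {
  nmodes <- function(h) {
    d <- density(x, bw = h, n = 512)
    y <- d$y
    sum(diff(sign(diff(y))) == -2)
  }
  lo <- 0.001 * sd(x); hi <- 2 * sd(x)
  if (nmodes(hi) > 1) return(hi)
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (nmodes(mid) <= 1) hi <- mid else lo <- mid
  }
  hi
}

#' Silverman's bootstrap test of unimodality
#'
#' Tests H0 "the distribution of x is unimodal" by comparing the critical
#' kernel bandwidth of the sample with that of smoothed bootstrap resamples
#' drawn from the unimodal KDE at the critical bandwidth. Small p-values
#' reject unimodality (evidence of two or more modes). Used where a
#' dip-style unimodality check is called for.
#'
#' @param x numeric sample.
#' @param B number of bootstrap resamples.
#' @return list with `p_value`, `critical_bw`, `B`.
#' @export
silverman_test <- function(x, B = 100) {
  n <- length(x)
  h0 <- critical_bandwidth(x)
  v <- var(x)
  shrink <- 1 / sqrt(1 + h0^2 / v)
  xbar <- mean(x)
  exceed <- 0
  for (b in seq_len(B)) {
    y <- x[sample.int(n, n, replace = TRUE)]
    y <- xbar + shrink * (y - xbar + h0 * rnorm(n))
    if (critical_bandwidth(y) > h0) exceed <- exceed + 1
  }
  list(p_value = exceed / B, critical_bw = h0, B = B)
}

# Deterministic 2-component 1D Gaussian mixture EM. Returns NULL when the
# fit degenerates.
em_gmm2 <- function(x, max_iter = 200, tol = 1e-8) {
  mu <- as.numeric(quantile(x, c(0.25, 0.75)))
  s <- rep(max(sd(x) / 2, 1e-8), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], s[1])
    d2 <- w[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    if (any(tot == 0) || !all(is.finite(tot))) return(NULL)
    g <- d1 / tot
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
    n1 <- sum(g); n2 <- length(x) - n1
    if (n1 < 1e-6 || n2 < 1e-6) return(NULL)
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    s <- sqrt(pmax(c(sum(g * (x - mu[1])^2) / n1,
                     sum((1 - g) * (x - mu[2])^2) / n2), 1e-12))
    w <- c(n1, n2) / length(x)
  }
  if (abs(mu[1] - mu[2]) < 1e-6 || any(s < 1e-6) || any(w < 1e-4))
    return(NULL)
  if (mu[1] > mu[2]) { mu <- rev(mu); s <- rev(s); w <- rev(w) }
  list(mu = mu, sigma = s, w = w)
}

# Equal-posterior boundary between the two mixture components; the root
# between the means. NULL if none exists.
gmm2_boundary <- function(fit) {
  f <- function(x) fit$w[1] * dnorm(x, fit$mu[1], fit$sigma[1]) -
    fit$w[2] * dnorm(x, fit$mu[2], fit$sigma[2])
  lo <- fit$mu[1]; hi <- fit$mu[2]
  if (f(lo) * f(hi) > 0) return(NULL)
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# Otsu threshold on a numeric vector (256-bin histogram).
otsu_split <- function(x) {
  h <- hist(x, breaks = 256, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_tot <- mu_cum[length(mu_cum)]
  between <- (mu_tot * w1 - mu_cum)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Split the annexin+/PI- population by forward scatter
#'
#' Back-gating: the Q4 (annexin+/PI-) population is split on log-FSC into a
#' lower-FSC sub-population R1 (smaller cells, putative apoptosis) and a
#' higher-FSC sub-population R2 (larger cells, putative oncosis). The
#' default split is the equal-posterior boundary of a deterministic
#' two-component Gaussian mixture on log10(FSC) (means initialised at the
#' 25th/75th percentiles, <= 200 iterations, tolerance 1e-8); if the fit
#' degenerates the histogram-valley (Otsu) threshold is used. When the
#' log-FSC distribution shows no significant bimodality (Silverman test,
#' alpha 0.05) the result is flagged low-confidence with a warning.
#'
#' @param events_q4 data.frame of Q4 events with column `fsc`.
#' @param method `"gmm2"` or `"otsu"`.
#' @return object of class `backgate_result` with `r1`, `r2`, `fsc_split`
#'   (linear FSC units; events with `fsc < fsc_split` are R1), `method_used`
#'   and `low_confidence`.
#' @export
backgate_fsc_split <- function(events_q4, method = c("gmm2", "otsu")) {
  method <- match.arg(method)
  if (nrow(events_q4) < 20)
    stop("need at least 20 annexin+/PI- events to back-gate")
  x <- log10(events_q4$fsc)
  used <- method
  split <- NULL
  if (method == "gmm2") {
    fit <- em_gmm2(x)
    if (!is.null(fit)) split <- gmm2_boundary(fit)
    if (is.null(split)) used <- "otsu"
  }
  if (is.null(split)) {
    if (length(unique(x)) == 1) {
      # fully degenerate: no information to split on
      split <- x[1]
      used <- "degenerate"
    } else split <- otsu_split(x)
  }
  st <- if (sd(x) > 0) silverman_test(x)
        else list(p_value = 1, critical_bw = 0, B = 0L)
  low_conf <- st$p_value >= 0.05
  if (low_conf)
    warning("Q4 log-FSC distribution not significantly bimodal ",
            "(Silverman p = ", signif(st$p_value, 2),
            "); back-gate split flagged low-confidence")
  r1 <- sum(x < split)
  structure(list(r1 = r1, r2 = nrow(events_q4) - r1,
                 fsc_split = 10^split, method_used = used,
                 low_confidence = low_conf,
                 unimodality_p = st$p_value),
            class = "backgate_result")
}

#' Map gated counts to morphological size classes
#'
#' Plain mapping: annexin-/PI- cells are "normal", annexin+/PI+ (late
#' apoptotic/necrotic) are "increase size", annexin+/PI- are "decrease
#' size". Adjusted-for-oncosis mapping: the higher-FSC part of Q4 (R2,
#' putative oncosis) moves from "decrease" to "increase", so increase =
#' Q2 + R2 and decrease = R1. Q1 (debris) is excluded from all classes and
#' reported separately.
#'
#' @param q a [quadrant_counts()].
#' @param b a [backgate_fsc_split()] result (required when `adjusted`).
#' @param adjusted apply the oncosis adjustment.
#' @return list with `counts` (named: normal, increase, decrease) and
#'   `debris` (Q1).
#' @export
map_to_size_classes <- function(q, b = NULL, adjusted = FALSE) {
  if (adjusted && is.null(b))
    stop("adjusted mapping requires a back-gate result")
  counts <- if (adjusted)
    c(normal = q$q3, increase = q$q2 + b$r2, decrease = b$r1)
  else
    c(normal = q$q3, increase = q$q2, decrease = q$q4)
  list(counts = counts, debris = q$q1)
}

#' Pearson chi-squared comparison of two classifications
#'
#' Builds the 2xK contingency table of the two count rows and computes the
#' Pearson statistic `sum((O-E)^2/E)` with expectations from the row/column
#' margins, no continuity correction; `df = K - 1`, p from the upper tail.
#'
#' @param row_a,row_b nonnegative count vectors of equal length (>= 2);
#'   every column total must be positive.
#' @return object of class `contingency_result` with `table`, `chi2`, `df`,
#'   `p`.
#' @export
chi2_compare <- function(row_a, row_b) {
  if (length(row_a) != length(row_b) || length(row_a) < 2)
    stop("rows must have equal length >= 2")
  if (any(row_a < 0) || any(row_b < 0)) stop("counts must be nonnegative")
  O <- rbind(row_a, row_b)
  colt <- colSums(O)
  if (any(colt == 0)) stop("zero column total in contingency table")
  E <- outer(rowSums(O), colt) / sum(O)
  chi2 <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  structure(list(table = O, chi2 = chi2, df = df,
                 p = pchisq(chi2, df, lower.tail = FALSE)),
            class = "contingency_result")
}
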