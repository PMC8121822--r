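#' One-sided FFT power spectrum of an interpolated interval series
#'
#' Removes the mean, computes the periodogram by FFT and normalizes the bin
#' powers so that their sum equals the sample variance of the input
#' (Parseval).
#'
#' @param values evenly sampled interval series (ms).
#' @param fs sampling rate of the series (Hz, 4 for the standard pipeline).
#' @return a `spectral_estimate`: `freqs` (Hz, increasing, positive) and
#'   `power` (ms^2 per bin).
#' @export
power_spectrum <- function(values, fs) {
  n <- length(values)
  if (n < 64) stop("need at least 64 samples for a spectrum", call. = FALSE)
  x <- values - mean(values)
  X <- stats::fft(x)
  half <- floor(n / 2)
  k <- seq_len(half)
  pw <- 2 * Mod(X[k + 1])^2 / n^2
  if (n %% 2 == 0) pw[half] <- pw[half] / 2  # Nyquist bin is not doubled
  pw <- pw * n / (n - 1)                     # population -> sample variance
  structure(list(freqs = k * fs / n, power = pw), class = "spectral_estimate")
}

# canonical analysis bands (Hz)
vlf_band <- c(0.0033, 0.04)
lf_band <- c(0.04, 0.15)
hf_band <- c(0.15, 0.40)
tp_band <- c(0.0033, 0.40)

band_power <- function(spec, band) {
  sum(spec$power[spec$freqs >= band[1] & spec$freqs < band[2]])
}

#' Time-domain variability indices
#'
#' @param nn raw NN intervals (ms).
#' @return list with `AVNN` (mean, ms), `SDNN` (sample SD, ms), `RMSSD`
#'   (root mean square of successive differences, ms), `NN50` (count of
#'   successive differences above 50 ms) and `pNN50` (percent of NN50 over
#'   the number of NN intervals).
#' @export
time_domain_indices <- function(nn) {
  stopifnot(length(nn) >= 2)
  d <- diff(nn)
  nn50 <- sum(abs(d) > 50)
  list(AVNN = mean(nn), SDNN = stats::sd(nn), RMSSD = sqrt(mean(d^2)),
       NN50 = nn50, pNN50 = 100 * nn50 / length(nn))
}

#' Frequency-domain variability indices
#'
#' Band powers are sums over the canonical VLF (0.0033-0.04 Hz), LF
#' (0.04-0.15 Hz), HF (0.15-0.40 Hz) and total (0.0033-0.40 Hz) bands.
#' Normalized powers use the Task-Force convention `nLF = LF / (TP - VLF)`;
#' the spectral entropy is the base-2 Shannon entropy of the bin-power
#' distribution over the total band.
#'
#' @param spec a `spectral_estimate`.
#' @return list with `VLF`, `LF`, `HF`, `TP` (ms^2), `nLF`, `nHF`, `LF_HF`,
#'   `SpEn`. `LF_HF` is `NA` when HF is zero.
#' @export
frequency_domain_indices <- function(spec) {
  stopifnot(inherits(spec, "spectral_estimate"))
  if (max(spec$freqs) < 0.40) stop("spectrum must cover 0.40 Hz", call. = FALSE)
  vlf <- band_power(spec, vlf_band)
  lf <- band_power(spec, lf_band)
  hf <- band_power(spec, hf_band)
  tp <- band_power(spec, tp_band)
  denom <- tp - vlf
  p <- spec$power[spec$freqs >= tp_band[1] & spec$freqs < tp_band[2]]
  spen <- if (sum(p) > 0) {
    q <- p[p > 0] / sum(p)
    -sum(q * log2(q))
  } else 0
  list(VLF = vlf, LF = lf, HF = hf, TP = tp,
       nLF = if (denom > 0) lf / denom else NA_real_,
       nHF = if (denom > 0) hf / denom else NA_real_,
       LF_HF = if (hf > 0) lf / hf else NA_real_,
       SpEn = spen)
}

#' Spectral band centroids
#'
#' Treats the in-band spectrum as the planar region under the power curve:
#' the x coordinate is the power-weighted mean frequency and the y
#' coordinate the area centroid height `sum(P^2)/2 / sum(P)`.
#'
#' @param spec a `spectral_estimate`.
#' @return list `cLFx`, `cLFy`, `cHFx`, `cHFy`, `cTPx`, `cTPy`; `NA` for a
#'   band with zero power.
#' @export
band_centroids <- function(spec) {
  stopifnot(inherits(spec, "spectral_estimate"))
  one <- function(band) {
    sel <- spec$freqs >= band[1] & spec$freqs < band[2]
    p <- spec$power[sel]
    f <- spec$freqs[sel]
    if (!length(p) || sum(p) <= 0) return(c(NA_real_, NA_real_))
    c(sum(f * p) / sum(p), sum(p^2) / 2 / sum(p))
  }
  lf <- one(lf_band); hf <- one(hf_band); tp <- one(tp_band)
  list(cLFx = lf[1], cLFy = lf[2], cHFx = hf[1], cHFy = hf[2],
       cTPx = tp[1], cTPy = tp[2])
}

#' Poincare plot indices
#'
#' From the lagged scatter (nn_i, nn_{i+1}): `SD1` is the dispersion
#' perpendicular to the identity line, `SD2` along it, `S = pi * SD1 * SD2`
#' the ellipse area, and `COM` the mean Euclidean distance of the points to
#' their centroid normalized by the mean NN interval. `SD1` uses the
#' uncentered root-mean-square about the identity line, so the algebraic
#' identity `SD1 = RMSSD / sqrt(2)` holds to machine precision.
#'
#' @param nn raw NN intervals (ms).
#' @return list `S` (ms^2), `SD1`, `SD2` (ms), `SD1_SD2`, `COM`
#'   (dimensionless).
#' @export
poincare_indices <- function(nn) {
  stopifnot(length(nn) >= 3)
  x <- nn[-length(nn)]
  y <- nn[-1]
  sd1 <- sqrt(mean(((y - x) / sqrt(2))^2))
  sd2 <- stats::sd((y + x) / sqrt(2))
  cx <- mean(x); cy <- mean(y)
  com <- mean(sqrt((x - cx)^2 + (y - cy)^2)) / mean(nn)
  list(S = pi * sd1 * sd2, SD1 = sd1, SD2 = sd2,
       SD1_SD2 = if (sd2 > 0) sd1 / sd2 else NA_real_, COM = com)
}

# delay embedding as a matrix of rows
embed_series <- function(x, dim, delay = 1L) {
  n <- length(x) - (dim - 1L) * delay
  if (n < 1) stop("series too short to embed", call. = FALSE)
  sapply(seq_len(dim), function(j) x[(j - 1L) * delay + seq_len(n)])
}

# counts of Chebyshev-matching template pairs used by ApEn/SampEn
template_counts <- function(x, m, r, self = FALSE) {
  em <- embed_series(x, m)
  n <- nrow(em)
  d <- matrix(0, n, n)
  for (j in seq_len(m)) d <- pmax(d, abs(outer(em[, j], em[, j], "-")))
  match <- d <= r
  if (!self) diag(match) <- FALSE
  match
}

approx_entropy <- function(x, m = 2L, r) {
  phi <- function(mm) {
    match <- template_counts(x, mm, r, self = TRUE)
    mean(log(rowMeans(match)))
  }
  phi(m) - phi(m + 1L)
}

sample_entropy <- function(x, m = 2L, r) {
  # the m+1 embedding has one fewer template; restrict the m-matches to the
  # same first N-m rows so A and B count comparable pairs
  match_m <- template_counts(x, m, r, self = FALSE)
  nm1 <- length(x) - m
  b <- sum(match_m[seq_len(nm1), seq_len(nm1)][upper.tri(diag(nm1))])
  a <- sum(template_counts(x, m + 1L, r, self = FALSE)[upper.tri(diag(nm1))])
  if (b == 0 || a == 0) return(NA_real_)
  -log(a / b)
}

#' Entropy-family variability indices
#'
#' Approximate and sample entropy with `m = 2`, `r = 0.2 * SDNN`; multiscale
#' entropy as the sum of sample entropies of the coarse-grained
#' (non-overlapping mean) series over scales 1-5 with `r` fixed from the
#' original series; base-scale entropy (4-point embedding, 4-symbol
#' deviation alphabet with base scale `0.2 * mean |successive difference|`)
#' and sign-series entropy (signs of successive differences, overlapping
#' words of length 3), both as base-2 Shannon entropies of their word
#' histograms.
#'
#' @param nn raw NN intervals (ms).
#' @return list `BSE`, `SSE`, `ApEn`, `SampEn`, `MSE` (dimensionless);
#'   `NA` markers when the series is shorter than the index requires
#'   (60 intervals for ApEn/SampEn, 200 for MSE).
#' @export
entropy_indices <- function(nn) {
  r <- 0.2 * stats::sd(nn)
  n <- length(nn)
  apen <- sampen <- mse <- NA_real_
  if (n >= 60) {
    apen <- approx_entropy(nn, 2L, r)
    sampen <- sample_entropy(nn, 2L, r)
    if (is.na(sampen) && stats::sd(nn) == 0) sampen <- 0
  }
  if (n >= 200) {
    mse <- 0
    for (tau in 1:5) {
      cg <- coarse_grain(nn, tau)
      se <- sample_entropy(cg, 2L, r)
      if (is.na(se) && stats::sd(cg) == 0) se <- 0
      mse <- mse + se
    }
  }
  list(BSE = base_scale_entropy(nn), SSE = sign_series_entropy(nn),
       ApEn = apen, SampEn = sampen, MSE = mse)
}

coarse_grain <- function(x, tau) {
  n <- floor(length(x) / tau)
  colMeans(matrix(x[seq_len(n * tau)], nrow = tau))
}

base_scale_entropy <- function(nn, m = 4L, a = 0.2) {
  if (length(nn) < m + 1) return(NA_real_)
  bs <- a * mean(abs(diff(nn)))
  em <- embed_series(nn, m)
  wm <- rowMeans(em)
  sym <- matrix(3L, nrow(em), m)
  for (j in seq_len(m)) {
    x <- em[, j]
    sym[x > wm + bs, j] <- 0L
    sym[x > wm & x <= wm + bs, j] <- 1L
    sym[x > wm - bs & x <= wm, j] <- 2L
  }
  words <- sym %*% 4L^(seq_len(m) - 1L)
  shannon2(table(words))
}

sign_series_entropy <- function(nn, word_len = 3L) {
  s <- sign(diff(nn))
  if (length(s) < word_len) return(NA_real_)
  em <- embed_series(s + 1, word_len)
  words <- em %*% 3^(seq_len(word_len) - 1)
  shannon2(table(words))
}

shannon2 <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Phase-space indices: correlation dimension and Lyapunov exponent
#'
#' Both use a delay embedding of dimension 10 and delay 1 with a Theiler
#' window of 10 beats. `D2` is the Grassberger-Procaccia correlation
#' dimension: the log-log slope of the correlation sum over radii between
#' the 10th and 50th percentile of pairwise distances. `LYA` is the largest
#' Lyapunov exponent by the nearest-neighbour divergence (Rosenstein)
#' method: the slope of the mean log divergence over the first 10 beats.
#'
#' @param nn raw NN intervals (ms), at least 200.
#' @param dim embedding dimension (default 10).
#' @param theiler Theiler exclusion window in beats (default 10).
#' @return list `D2`, `LYA` (dimensionless); `D2 = 0` and `LYA = NA` for a
#'   degenerate (constant) series.
#' @export
phase_indices <- function(nn, dim = 10L, theiler = 10L) {
  if (length(nn) < 200) return(list(D2 = NA_real_, LYA = NA_real_))
  em <- embed_series(nn, dim)
  n <- nrow(em)
  d <- as.matrix(stats::dist(em))
  lagmat <- abs(outer(seq_len(n), seq_len(n), "-"))
  valid <- lagmat > theiler
  dv <- d[valid & upper.tri(d)]
  if (!length(dv) || max(dv) == 0) return(list(D2 = 0, LYA = NA_real_))
  qs <- stats::quantile(dv[dv > 0], c(0.10, 0.50), names = FALSE)
  d2 <- NA_real_
  if (qs[2] > qs[1]) {
    rr <- exp(seq(log(qs[1]), log(qs[2]), length.out = 8))
    cr <- vapply(rr, function(r) mean(dv < r), numeric(1))
    ok <- cr > 0
    if (sum(ok) >= 3) {
      d2 <- unname(stats::coef(stats::lm(log(cr[ok]) ~ log(rr[ok])))[2])
    }
  }
  # Rosenstein divergence curve
  horizon <- 10L
  dn <- d
  dn[!valid] <- Inf
  diag(dn) <- Inf
  nn_idx <- apply(dn, 1, which.min)
  logdiv <- rep(NA_real_, horizon + 1L)
  for (k in 0:horizon) {
    i <- seq_len(n - k)
    j <- nn_idx[i]
    keep <- j + k <= n
    dk <- d[cbind(i[keep] + k, j[keep] + k)]
    dk <- dk[dk > 0]
    if (length(dk)) logdiv[k + 1L] <- mean(log(dk))
  }
  lya <- NA_real_
  ks <- which(!is.na(logdiv)) - 1L
  if (length(ks) >= 3) {
    lya <- unname(stats::coef(stats::lm(logdiv[ks + 1L] ~ ks))[2])
  }
  list(D2 = d2, LYA = lya)
}

#' Detrended fluctuation analysis scaling exponents
#'
#' DFA-1: integrate the mean-centred series, split into non-overlapping
#' boxes of size n, remove a linear trend per box, and measure the RMS
#' residual F(n). F(n) is divided by the exact finite-size factor
#' `sqrt(1 - 4/n^2)` of linear detrending (which otherwise biases the
#' small-box slope of uncorrelated noise upward by ~0.08). `A1` is the
#' log-log slope over box sizes 4-16 and `A2` over 16-64.
#'
#' @param nn raw NN intervals (ms), at least 200 for both exponents.
#' @return list `A1`, `A2`; `A2` is `NA` when the series cannot fill two
#'   boxes of size 64.
#' @export
dfa_exponents <- function(nn) {
  if (length(nn) < 200) return(list(A1 = NA_real_, A2 = NA_real_))
  short <- 4:16
  long <- unique(round(exp(seq(log(16), log(64), length.out = 10))))
  fluct <- function(n) dfa_fluct(nn, n) / sqrt(1 - 4 / n^2)
  f_short <- vapply(short, fluct, numeric(1))
  a1 <- unname(stats::coef(stats::lm(log(f_short) ~ log(short)))[2])
  a2 <- NA_real_
  if (floor(length(nn) / 64) >= 2) {
    f_long <- vapply(long, fluct, numeric(1))
    a2 <- unname(stats::coef(stats::lm(log(f_long) ~ log(long)))[2])
  }
  list(A1 = a1, A2 = a2)
}

dfa_fluct <- function(x, n) {
  y <- cumsum(x - mean(x))
  nbox <- floor(length(y) / n)
  res2 <- numeric(0)
  tt <- seq_len(n)
  for (b in seq_len(nbox)) {
    seg <- y[(b - 1) * n + tt]
    fit <- stats::lm.fit(cbind(1, tt), seg)
    res2 <- c(res2, fit$residuals^2)
  }
  sqrt(mean(res2))
}

index_names <- c("AVNN", "SDNN", "RMSSD", "NN50", "pNN50",
                 "VLF", "LF", "HF", "TP", "nLF", "nHF", "LF_HF",
                 "cLFx", "cLFy", "cHFx", "cHFy", "cTPx", "cTPy", "SpEn",
                 "S", "SD1", "SD2", "SD1_SD2", "COM",
                 "BSE", "SSE", "ApEn", "SampEn", "MSE",
                 "D2", "LYA", "A1", "A2")

#' Compute the full 33-index set from one interval series
#'
#' Time-domain, Poincare, entropy, phase and DFA indices are computed on
#' the raw NN series; spectral indices on the 4 Hz cubic-spline
#' interpolation (built here if the series has not been interpolated yet).
#' Indices whose preconditions are not met are returned as `NA` without
#' aborting the rest.
#'
#' @param series a corrected `interval_series`.
#' @return an `index_set`: named list of the 33 indices (times in ms,
#'   powers in ms^2), plus attributes `source`.
#' @export
compute_all <- function(series) {
  stopifnot(inherits(series, "interval_series"))
  if (!length(series$interp_values_ms)) {
    series <- interpolate_series(series)
  }
  nn <- series$nn_ms
  safe <- function(expr, fields) {
    tryCatch(expr, error = function(e) {
      stats::setNames(as.list(rep(NA_real_, length(fields))), fields)
    })
  }
  td <- safe(time_domain_indices(nn), c("AVNN", "SDNN", "RMSSD", "NN50", "pNN50"))
  spec <- tryCatch(power_spectrum(series$interp_values_ms, series$interp_fs),
                   error = function(e) NULL)
  fd <- if (!is.null(spec)) {
    safe(frequency_domain_indices(spec),
         c("VLF", "LF", "HF", "TP", "nLF", "nHF", "LF_HF", "SpEn"))
  } else {
    stats::setNames(as.list(rep(NA_real_, 8)),
                    c("VLF", "LF", "HF", "TP", "nLF", "nHF", "LF_HF", "SpEn"))
  }
  cen <- if (!is.null(spec)) {
    safe(band_centroids(spec), c("cLFx", "cLFy", "cHFx", "cHFy", "cTPx", "cTPy"))
  } else {
    stats::setNames(as.list(rep(NA_real_, 6)),
                    c("cLFx", "cLFy", "cHFx", "cHFy", "cTPx", "cTPy"))
  }
  pc <- safe(poincare_indices(nn), c("S", "SD1", "SD2", "SD1_SD2", "COM"))
  en <- safe(entropy_indices(nn), c("BSE", "SSE", "ApEn", "SampEn", "MSE"))
  ph <- safe(phase_indices(nn), c("D2", "LYA"))
  df <- safe(dfa_exponents(nn), c("A1", "A2"))
  out <- c(td, fd[c("VLF", "LF", "HF", "TP", "nLF", "nHF", "LF_HF")],
           cen, fd["SpEn"], pc, en, ph, df)
  out <- out[index_names]
  structure(out, class = "index_set", source = series$source)
}

#' @export
print.index_set <- function(x, ...) {
  cat(sprintf("index_set (%s): 33 variability indices\n", attr(x, "source")))
  print(unlist(x))
  invisible(x)
}

#' Turn index sets into a one-row-per-series data.frame
#'
#' @param sets list of `index_set` objects.
#' @param ids optional identifiers (e.g. segment labels).
#' @return data.frame with `id`, `source` and the 33 canonical columns.
#' @export
index_table <- function(sets, ids = seq_along(sets)) {
  rows <- lapply(seq_along(sets), function(i) {
    data.frame(id = ids[i], source = attr(sets[[i]], "source"),
               t(unlist(sets[[i]])))
  })
  do.call(rbind, rows)
}
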