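make_series <- function(nn_ms, t0 = 0) {
  build_interval_series(t0 + cumsum(c(0, nn_ms / 1000)), "ECG")
}

test_that("spectrum satisfies Parseval and localizes a pure tone", {
  fs <- 4
  n <- 1200
  t <- (0:(n - 1)) / fs
  a <- 40
  tone <- a * sin(2 * pi * 0.25 * t)
  spec <- power_spectrum(tone, fs)
  expect_equal(sum(spec$power), var(tone), tolerance = 1e-9)
  expect_equal(sum(spec$power), a^2 / 2, tolerance = 0.01 * a^2 / 2)
  near <- abs(spec$freqs - 0.25) <= 2 * fs / n
  expect_gte(sum(spec$power[near]) / sum(spec$power), 0.95)
  # white noise: total power equals the sample variance
  set.seed(3)
  x <- rnorm(n, 0, 25)
  spec2 <- power_spectrum(x, fs)
  expect_equal(sum(spec2$power), var(x), tolerance = 1e-9)
  # constant input carries no power
  expect_lt(sum(power_spectrum(rep(5, 128), fs)$power), 1e-18)
  expect_error(power_spectrum(rnorm(32), fs), "64")
})

test_that("time-domain indices match hand values and a naive loop oracle", {
  td <- time_domain_indices(rep(800, 300))
  expect_equal(unlist(td), c(AVNN = 800, SDNN = 0, RMSSD = 0, NN50 = 0, pNN50 = 0))
  alt <- rep(c(800, 860), 150)
  td2 <- time_domain_indices(alt)
  expect_equal(td2$RMSSD, 60)
  expect_equal(td2$NN50, 299)
  expect_equal(td2$pNN50, 100 * 299 / 300)
  # naive loop oracle on random input
  set.seed(11)
  nn <- rnorm(1000, 850, 60)
  td3 <- time_domain_indices(nn)
  n <- length(nn)
  avnn <- sum(nn) / n
  sdnn <- sqrt(sum((nn - avnn)^2) / (n - 1))
  ss <- 0; nn50 <- 0
  for (i in 1:(n - 1)) {
    d <- nn[i + 1] - nn[i]
    ss <- ss + d^2
    if (abs(d) > 50) nn50 <- nn50 + 1
  }
  expect_equal(td3$AVNN, avnn, tolerance = 1e-9)
  expect_equal(td3$SDNN, sdnn, tolerance = 1e-9)
  expect_equal(td3$RMSSD, sqrt(ss / (n - 1)), tolerance = 1e-9)
  expect_equal(td3$NN50, nn50)
  expect_equal(td3$pNN50, 100 * nn50 / n, tolerance = 1e-9)
})

test_that("band powers isolate single tones and entropy hits its extremes", {
  fs <- 4; n <- 1200; t <- (0:(n - 1)) / fs
  hf_tone <- power_spectrum(30 * sin(2 * pi * 0.25 * t), fs)
  fd <- frequency_domain_indices(hf_tone)
  expect_gte(fd$HF / fd$TP, 0.95)
  expect_gte(fd$nHF, 0.95)
  expect_lte(fd$LF_HF, 0.06)
  lf_tone <- power_spectrum(30 * sin(2 * pi * 0.10 * t), fs)
  fd2 <- frequency_domain_indices(lf_tone)
  expect_gte(fd2$LF / fd2$TP, 0.95)
  # entropy extremes: a tone concentrates, white noise spreads
  expect_lt(fd$SpEn, 2)
  set.seed(4)
  fdw <- frequency_domain_indices(power_spectrum(rnorm(n), fs))
  nbins <- sum(hf_tone$freqs >= 0.0033 & hf_tone$freqs < 0.40)
  expect_gt(fdw$SpEn, 0.8 * log2(nbins))
  expect_lte(fdw$SpEn, log2(nbins) + 1e-9)
})

test_that("band centroids sit at the tone, the midpoint, and half-height", {
  fs <- 4; n <- 1200; t <- (0:(n - 1)) / fs
  spec <- power_spectrum(30 * sin(2 * pi * 0.25 * t), fs)
  cen <- band_centroids(spec)
  expect_equal(cen$cHFx, 0.25, tolerance = fs / n + 1e-9)
  # synthetic spectra exercise the closed-form properties
  freqs <- seq(0.002, 0.4, by = 0.002)
  mid <- (0.15 + 0.40) / 2
  sym <- exp(-((freqs - mid) / 0.04)^2)
  sym[freqs < 0.15 | freqs >= 0.40] <- 0
  spec_sym <- structure(list(freqs = freqs, power = sym),
                        class = "spectral_estimate")
  expect_equal(band_centroids(spec_sym)$cHFx, mid, tolerance = 1e-6)
  p0 <- 3.7
  unif <- ifelse(freqs >= 0.15 & freqs < 0.40, p0, 0)
  spec_u <- structure(list(freqs = freqs, power = unif),
                      class = "spectral_estimate")
  expect_equal(band_centroids(spec_u)$cHFy, p0 / 2, tolerance = 1e-9)
})

test_that("Poincare indices: identities and the alternating-series oracle", {
  pc0 <- poincare_indices(rep(800, 100))
  expect_equal(pc0$SD1, 0); expect_equal(pc0$SD2, 0)
  expect_equal(pc0$S, 0); expect_equal(pc0$COM, 0)
  # SD1 = RMSSD/sqrt(2): exact algebraic identity under the uncentered
  # rotation-of-coordinates convention
  set.seed(7)
  for (i in 1:100) {
    nn <- rnorm(sample(50:300, 1), 800, 40)
    sd1 <- poincare_indices(nn)$SD1
    rmssd <- time_domain_indices(nn)$RMSSD
    expect_equal(sd1, rmssd / sqrt(2), tolerance = 1e-12)
    # rotation oracle: RMS of the perpendicular coordinate
    d <- diff(nn)
    expect_equal(sd1, sqrt(mean((d / sqrt(2))^2)), tolerance = 1e-12)
  }
  alt <- rep(c(800, 860), 150)
  pc <- poincare_indices(alt)
  expect_equal(pc$SD1, 60 / sqrt(2), tolerance = 1e-12)
  expect_lt(pc$SD2, 3)
  expect_equal(pc$S, pi * pc$SD1 * pc$SD2)
})

test_that("entropy indices degenerate correctly and rank noise above rhythm", {
  const <- rep(800, 300)
  en <- entropy_indices(const)
  expect_equal(en$SampEn, 0)
  expect_equal(en$ApEn, 0, tolerance = 1e-12)
  expect_equal(en$SSE, 0)
  expect_equal(en$BSE, 0)
  expect_equal(entropy_indices(seq(700, 999, by = 1))$SSE, 0)
  # i.i.d. Gaussian is more irregular than a period-2 alternation on every index
  set.seed(21)
  alt <- rep(c(780, 840), 150)
  wins <- replicate(50, {
    g <- rnorm(300, 810, 30)
    eg <- entropy_indices(g)
    ea <- entropy_indices(alt)
    all(unlist(eg) > unlist(ea))
  })
  expect_true(all(wins))
})

test_that("sample entropy matches a naive template-counting oracle", {
  naive_sampen <- function(x, m, r) {
    n <- length(x)
    count <- function(mm) {
      tot <- 0L
      for (i in 1:(n - m)) {
        for (j in 1:(n - m)) {
          if (j <= i) next
          if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) {
            tot <- tot + 1L
          }
        }
      }
      tot
    }
    -log(count(m + 1) / count(m))
  }
  set.seed(9)
  x <- rnorm(300, 800, 30)
  r <- 0.2 * sd(x)
  got <- entropy_indices(x)$SampEn
  expect_equal(got, naive_sampen(x, 2, r), tolerance = 1e-10)
})

test_that("phase indices: constant collapses, a closed curve has dimension one", {
  ph0 <- phase_indices(rep(800, 300))
  expect_equal(ph0$D2, 0)
  expect_true(is.na(ph0$LYA))
  i <- 1:300
  sine <- 800 + 50 * sin(2 * pi * i / 40)
  ph <- phase_indices(sine)
  expect_equal(ph$D2, 1, tolerance = 0.3)
  # a noise-free rhythm diverges more slowly than white noise
  set.seed(14)
  cmp <- replicate(20, {
    noise <- rnorm(300, 800, sd(sine) * sqrt(299 / 300))
    phase_indices(sine + rnorm(300, 0, 0.01))$LYA < phase_indices(noise)$LYA
  })
  expect_gte(mean(cmp), 0.95)
})

test_that("DFA exponents recover the white-noise and Brownian limits", {
  set.seed(31)
  a1 <- a2 <- b1 <- b2 <- numeric(20)
  for (k in 1:20) {
    w <- rnorm(600)
    d <- dfa_exponents(w)
    a1[k] <- d$A1; a2[k] <- d$A2
    db <- dfa_exponents(cumsum(w))
    b1[k] <- db$A1; b2[k] <- db$A2
  }
  expect_lt(abs(mean(a1) - 0.5), 0.1)
  expect_lt(abs(mean(a2) - 0.5), 0.1)
  expect_lt(abs(mean(b1) - 1.5), 0.15)
  expect_lt(abs(mean(b2) - 1.5), 0.15)
})

test_that("DFA fluctuation is non-decreasing in box size", {
  set.seed(8)
  for (x in list(rnorm(400), cumsum(rnorm(400)), rep(c(800, 860), 200))) {
    f <- vapply(c(4, 8, 16, 32, 64), function(n) pulsevar:::dfa_fluct(x, n),
                numeric(1))
    expect_true(all(diff(f) >= -1e-9))
  }
})

test_that("compute_all is deterministic and respects the invariant block", {
  set.seed(17)
  nn <- 800 + 30 * sin(2 * pi * (1:350) * 0.25 * 0.8) + rnorm(350, 0, 10)
  ser <- make_series(nn)
  a <- compute_all(ser)
  b <- compute_all(ser)
  expect_identical(a, b)
  expect_named(a, c("AVNN", "SDNN", "RMSSD", "NN50", "pNN50",
                    "VLF", "LF", "HF", "TP", "nLF", "nHF", "LF_HF",
                    "cLFx", "cLFy", "cHFx", "cHFy", "cTPx", "cTPy", "SpEn",
                    "S", "SD1", "SD2", "SD1_SD2", "COM",
                    "BSE", "SSE", "ApEn", "SampEn", "MSE",
                    "D2", "LYA", "A1", "A2"))
  for (k in 1:12) {
    nn_k <- 800 + rnorm(320, 0, runif(1, 5, 40))
    ix <- compute_all(make_series(nn_k))
    expect_equal(ix$S, pi * ix$SD1 * ix$SD2, tolerance = 1e-12)
    expect_equal(ix$SD1, ix$RMSSD / sqrt(2), tolerance = 1e-12)
    expect_true(ix$pNN50 >= 0 && ix$pNN50 <= 100)
    expect_true(ix$cLFx >= 0.04 && ix$cLFx < 0.15)
    expect_true(ix$cHFx >= 0.15 && ix$cHFx < 0.40)
    expect_true(ix$cTPx >= 0.0033 && ix$cTPx < 0.40)
    expect_gte(ix$TP + 1e-9, ix$VLF + ix$LF + ix$HF)
  }
})

test_that("indices are scale-equivariant in the expected way", {
  set.seed(23)
  nn <- 800 + rnorm(300, 0, 25)
  c0 <- 1.7
  base_td <- time_domain_indices(nn)
  scl_td <- time_domain_indices(c0 * nn)
  expect_equal(scl_td$AVNN, c0 * base_td$AVNN)
  expect_equal(scl_td$SDNN, c0 * base_td$SDNN)
  expect_equal(scl_td$RMSSD, c0 * base_td$RMSSD)
  base_pc <- poincare_indices(nn)
  scl_pc <- poincare_indices(c0 * nn)
  expect_equal(scl_pc$SD1, c0 * base_pc$SD1)
  expect_equal(scl_pc$SD2, c0 * base_pc$SD2)
  expect_equal(scl_pc$S, c0^2 * base_pc$S)
  base_dfa <- dfa_exponents(nn)
  scl_dfa <- dfa_exponents(c0 * nn)
  expect_equal(scl_dfa$A1, base_dfa$A1, tolerance = 1e-9)
  expect_equal(scl_dfa$A2, base_dfa$A2, tolerance = 1e-9)
  # the 50 ms threshold is absolute: scaling can only increase NN50
  expect_gte(scl_td$NN50, base_td$NN50)
})

test_that("missing-value markers propagate without aborting", {
  short <- make_series(800 + rnorm(30, 0, 10))
  ix <- compute_all(short)
  expect_true(is.na(ix$MSE))
  expect_true(is.na(ix$D2))
  expect_true(is.na(ix$A2) || is.finite(ix$A2))
  expect_true(is.finite(ix$AVNN))
  expect_true(is.finite(ix$SD1))
})
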