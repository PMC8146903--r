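test_that("replicate averaging gives the point-wise mean and SD", {
  g <- seq(400, 3100, by = 5)
  a <- raman_spectrum(g, sin(g / 300) + 2)
  same <- average_spectra(list(a, a, a))
  expect_equal(same$mean, a$intensity)
  expect_true(all(same$sd == 0))
  b <- raman_spectrum(g, a$intensity + 2)
  two <- average_spectra(list(a, b))
  expect_equal(two$mean, a$intensity + 1)
  expect_equal(two$sd, rep(sqrt(2), length(g)))
})

test_that("mean of noisy replicates converges to the generator truth (CLT)", {
  truth <- gen_raman_spectrum(noise_sigma = 0)
  reps <- lapply(1:10, function(s) gen_raman_spectrum(noise_sigma = 2, seed = s))
  avg <- average_spectra(reps)
  # per-point: |mean - truth| < 3 sd / sqrt(10) for nearly all points
  ok <- abs(avg$mean - truth$intensity) < 3 * 2 / sqrt(10)
  expect_gt(mean(ok), 0.99)
})

test_that("polynomial baseline removal is exact on band-free spectra and idempotent", {
  cubic <- gen_raman_spectrum(bands = data.frame(center = numeric(0),
                                                 area = numeric(0),
                                                 width = numeric(0)),
                              baseline_coeffs = c(5, -2, 3, 1))
  corr <- baseline_correct(cubic, "polynomial", degree = 3)
  expect_lt(max(abs(corr$intensity)), 1e-6 * max(abs(cubic$intensity)))
  # baseline-free spectrum passes through nearly unchanged
  clean <- gen_raman_spectrum()
  corr2 <- baseline_correct(clean, "polynomial", degree = 3)
  expect_equal(band_integral(corr2, band_2937()),
               band_integral(clean, band_2937()), tolerance = 0.02)
  expect_error(baseline_correct(clean, "polynomial", degree = -1), ">= 0")
})

test_that("band integral survives a linear baseline after correction", {
  sp <- gen_raman_spectrum(bands = data.frame(center = 1453, area = 100,
                                              width = 10),
                           baseline_coeffs = c(50, 30))
  for (method in c("polynomial", "rubberband")) {
    corr <- baseline_correct(sp, method, degree = 1)
    expect_equal(band_integral(corr, band_1453()), 100, tolerance = 0.02)
  }
})

test_that("band integral agrees with a fine-grid quadrature oracle", {
  band <- band_definition(1500, c(1440, 1560))
  coarse <- gen_raman_spectrum(bands = data.frame(center = 1500, area = 80,
                                                  width = 12),
                               grid = seq(400, 3100, by = 1))
  fine <- gen_raman_spectrum(bands = data.frame(center = 1500, area = 80,
                                                width = 12),
                             grid = seq(400, 3100, by = 0.05))
  keep <- fine$wavenumber >= 1440 & fine$wavenumber <= 1560
  oracle <- pracma::trapz(fine$wavenumber[keep], fine$intensity[keep])
  expect_equal(band_integral(coarse, band), oracle, tolerance = 1e-3)
  expect_equal(band_integral(raman_spectrum(coarse$wavenumber,
                                            rep(0, nrow(coarse))), band), 0)
  expect_error(band_integral(coarse, band_definition(300, c(200, 390))),
               "outside")
})

test_that("band ratio is scale invariant and monotone in the marker band", {
  sp <- gen_raman_spectrum(bands = data.frame(center = c(2937, 1453),
                                              area = c(150, 100),
                                              width = c(15, 10)))
  r <- band_ratio(sp, correct_baseline = FALSE)
  scaled <- raman_spectrum(sp$wavenumber, sp$intensity * 3.7)
  expect_equal(band_ratio(scaled, correct_baseline = FALSE), r,
               tolerance = 1e-12)
  areas <- c(100, 150, 220, 300)
  ratios <- vapply(areas, function(a2937) {
    s <- gen_raman_spectrum(bands = data.frame(center = c(2937, 1453),
                                               area = c(a2937, 100),
                                               width = c(15, 10)))
    band_ratio(s, correct_baseline = FALSE)
  }, 0)
  expect_true(all(diff(ratios) > 0))
  # equal-area bands give a ratio of 1 (same window-truncation on both)
  eq <- gen_raman_spectrum(bands = data.frame(center = c(2937, 1453),
                                              area = c(100, 100),
                                              width = c(8, 8)))
  expect_equal(band_ratio(eq, correct_baseline = FALSE), 1, tolerance = 0.01)
})

test_that("ANOVA F on a fixed 2x5 table matches the hand-computed formula", {
  g1 <- c(2.10, 2.30, 2.25, 2.18, 2.22)
  g2 <- c(1.80, 1.95, 1.88, 1.91, 1.85)
  res <- group_compare(DSM = g1, DRM = g2)
  k <- 2; n <- 10
  gm <- mean(c(g1, g2))
  ssb <- 5 * (mean(g1) - gm)^2 + 5 * (mean(g2) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  f_hand <- (ssb / (k - 1)) / (ssw / (n - k))
  p_hand <- pf(f_hand, k - 1, n - k, lower.tail = FALSE)
  expect_equal(res$anova_p, p_hand, tolerance = 1e-10)
  expect_true(res$significant)
})

test_that("group comparison edge behaviour: identical groups, huge effects", {
  same <- group_compare(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_gt(same$anova_p, 0.99)
  expect_false(same$significant)
  sep <- group_compare(a = rnorm(5, 10, 0.1), b = rnorm(5, 20, 0.1))
  expect_lt(sep$tukey$p_adj[1], 0.05)
  expect_error(group_compare(a = c(1, 2), b = c(1, 2, 3)), ">= 3")
})

test_that("a >= 2-pooled-SD group separation is detected in >= 95% of seeds", {
  detect <- vapply(1:100, function(s) {
    dsm <- vapply(1:10, function(r) {
      sp <- gen_raman_spectrum(bands = data.frame(center = c(2937, 1453),
                                                  area = c(200, 100),
                                                  width = c(15, 10)),
                               noise_sigma = 0.15, seed = s * 1000 + r)
      band_ratio(sp, correct_baseline = FALSE)
    }, 0)
    drm <- vapply(11:20, function(r) {
      sp <- gen_raman_spectrum(bands = data.frame(center = c(2937, 1453),
                                                  area = c(160, 100),
                                                  width = c(15, 10)),
                               noise_sigma = 0.15, seed = s * 1000 + r)
      band_ratio(sp, correct_baseline = FALSE)
    }, 0)
    diff_sd <- sqrt((var(dsm) + var(drm)) / 2)
    effect_ok <- (mean(dsm) - mean(drm)) > 0   # ordering always holds
    res <- group_compare(DSM = dsm, DRM = drm)
    effect_ok && res$significant
  }, TRUE)
  expect_gte(mean(detect), 0.95)
})
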