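# Peak integration, recalibration, QC filtering, isotopic scoring and
# normalization.

make_gaussian_spectrum <- function(area = 500, mu = 1500, sigma = 0.05,
                                   baseline = 0, range = c(1480, 1520),
                                   step = 0.02) {
  mz <- seq(range[1], range[2], by = step)
  list(mz = mz, intensity = baseline + area * dnorm(mz, mu, sigma))
}

test_that("a flat spectrum integrates to zero area and zero S/N", {
  sp <- list(mz = seq(1000, 1100, 0.02), intensity = rep(7, 5001))
  pk <- integrate_peak(sp, c(1049, 1051))
  expect_equal(pk$area, 0, tolerance = 1e-9)
  expect_equal(pk$sn, 0)
})

test_that("a synthetic Gaussian integrates to its analytic area", {
  sp <- make_gaussian_spectrum(area = 500)
  pk <- integrate_peak(sp, c(1500 - 0.3, 1500 + 0.3))
  expect_equal(pk$area, 500, tolerance = 0.01 * 500)
})

test_that("area is linear in intensity and S/N scale-invariant", {
  set.seed(4)
  mz <- seq(1480, 1520, 0.02)
  y <- 300 * dnorm(mz, 1500, 0.05) + abs(rnorm(length(mz), 10, 2))
  pk1 <- integrate_peak(list(mz = mz, intensity = y), c(1499.7, 1500.3))
  pk2 <- integrate_peak(list(mz = mz, intensity = 2 * y), c(1499.7, 1500.3))
  expect_equal(pk2$area / pk1$area, 2, tolerance = 0.01)
  expect_equal(pk2$sn, pk1$sn, tolerance = 1e-9)
  expect_error(integrate_peak(list(mz = mz, intensity = y), c(100, 101)),
               "outside")
})

test_that("recalibration removes injected constant drifts up to +/-40 ppm", {
  p <- make_profile("ntc_like")
  for (drift in c(-40, -15, 15, 40)) {
    sp <- simulate_spectrum(p, quiet_design(drift_ppm = drift,
                                            baseline_level = 1),
                            1, 1, "a", seed = 101 + drift)
    pt <- process_spectrum(sp)
    cal <- attr(pt, "calibration")
    expect_gte(nrow(cal$calibrants), 3)
    expect_lt(mean(abs(cal$calibrants$ppm_after)), 5)
    expect_lt(max(abs(cal$calibrants$ppm_after)), 5)
    expect_lt(mean(abs(cal$calibrants$ppm_after)),
              mean(abs(cal$calibrants$ppm_before)))
  }
})

test_that("recalibration on drift-free data is near-identity", {
  obs <- theoretical_mz(default_calibrants())
  cal <- recalibrate(obs)
  expect_equal(cal$coef[["intercept"]], 0, tolerance = 1e-9)
  expect_equal(cal$mz_corrected, obs, tolerance = 1e-9)
  # apply-then-invert is identity
  back <- apply_calibration(cal, apply_calibration(cal, obs), invert = TRUE)
  expect_equal(back, obs, tolerance = 1e-9)
})

test_that("recalibration requires at least three matched calibrants", {
  obs <- theoretical_mz(c("H5N2", "H6N2"))
  expect_error(recalibrate(obs, c("H5N2", "H6N2")), "at least 3")
  expect_error(recalibrate(c(1500.1), default_calibrants()), "at least 3")
})

test_that("linear drift model recovers a mass-dependent drift", {
  obs <- theoretical_mz(default_calibrants())
  drift <- 5 + 0.004 * obs  # ppm, linear in m/z
  shifted <- obs * (1 + drift * 1e-6)
  cal <- recalibrate(shifted, model = "linear")
  expect_lt(max(abs(cal$calibrants$ppm_after)), 0.5)
})

test_that("QC keeps and rejects exactly per the threshold rules", {
  peaks <- tibble::tibble(
    isotopic_score = c(0.96, 0.96, 0.96, 0.94, 0.95, 0.96, 0.90),
    sn             = c(3,    1.5,  3,    3,    2.01, 2,    1),
    ppm            = c(5,    5,    25,   5,    20,   5,    25)
  )
  out <- qc_filter(peaks)
  expect_equal(out$kept, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$reasons[2], "sn")
  expect_equal(out$reasons[3], "ppm")
  expect_equal(out$reasons[4], "isotopic_score")
  expect_equal(out$reasons[6], "sn")        # S/N comparison is strict
  expect_equal(out$reasons[7], "isotopic_score;sn;ppm")
})

test_that("tightening any QC threshold never grows the kept set", {
  set.seed(9)
  peaks <- tibble::tibble(isotopic_score = runif(200, 0.8, 1),
                          sn = runif(200, 0, 10), ppm = runif(200, -30, 30))
  base_kept <- qc_filter(peaks)$kept
  tighter <- list(qc_thresholds(min_isotopic_score = 0.98),
                  qc_thresholds(min_sn = 4),
                  qc_thresholds(max_abs_ppm = 10))
  for (th in tighter) {
    kept <- qc_filter(peaks, th)$kept
    expect_true(all(kept <= base_kept))
  }
})

test_that("isotopic fit score is 1 for identical and 0 for disjoint envelopes", {
  theo <- isotope_pattern("H3N4", 4)$abundance
  expect_equal(isotopic_fit_score(theo, "H3N4"), 1, tolerance = 1e-9)
  expect_equal(isotopic_fit_score(c(0, 0, 0, 1), c(1, 0, 0, 0)), 0)
  expect_error(isotopic_fit_score(c(0, 0, 0, 0), theo), "all-zero")
  expect_error(isotopic_fit_score(1, theo), "at least 2")
})

test_that("noise-free simulated peaks score above 0.99", {
  # H3N4 plus enough calibrant species for the internal recalibration
  p <- make_profile(c(H3N4 = 0.4, H5N2 = 0.2, H6N2 = 0.2, H7N2 = 0.2))
  sp <- simulate_spectrum(p, quiet_design(), 1, 1, "a", 1)
  pt <- process_spectrum(sp)
  h3n4 <- pt[!is.na(pt$composition) & pt$composition == "H3N4", ]
  expect_equal(nrow(h3n4), 1)
  expect_gt(h3n4$isotopic_score, 0.99)
})

test_that("TIC normalization yields percentages with the right properties", {
  expect_equal(normalize_tic(c(2, 3, 5)), c(20, 30, 50))
  expect_equal(normalize_tic(7), 100)
  set.seed(2)
  for (i in 1:20) {
    a <- runif(sample(2:30, 1), 0, 100)
    pct <- normalize_tic(a)
    expect_equal(sum(pct), 100, tolerance = 1e-9)
    expect_equal(normalize_tic(a * runif(1, 0.1, 10)), pct, tolerance = 1e-9)
  }
  expect_error(normalize_tic(numeric(0)), "no kept peaks")
  expect_error(normalize_tic(c(0, 0)), "total area is zero")
})
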