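# EIC extraction, peak detection/integration, RT matching.

test_that("EIC of a lone on-target centroid is the centroid's trace", {
  target <- mz_deprotonated("32:6")
  trace <- c(1, 5, 100, 5, 1, 1)
  run <- single_trace_run(target, trace)
  eic <- extract_eic(run, target, 5)
  expect_equal(eic$intensity, trace)
})

test_that("centroids 10 ppm off target stay outside a 5 ppm window", {
  target <- mz_deprotonated("32:6")
  run <- single_trace_run(target * (1 + 10e-6), c(1, 5, 100, 5, 1))
  eic <- extract_eic(run, target, 5)
  expect_equal(eic$intensity, rep(0, 5))
})

test_that("co-eluting in-window centroids sum per spectrum", {
  target <- 500
  rt <- seq(0.1, 0.5, by = 0.1)
  spectra <- lapply(rt, function(t) list(
    rt_min = t,
    mz = c(499.999, 500.001, 510),   # first two inside a 5 ppm window
    intensity = c(10 * t, 3, 999)))
  run <- spectrum_run(spectra, run_id = "two")
  eic <- extract_eic(run, target, 5)
  # brute-force oracle: per-spectrum sum over the window
  w <- ppm_window(target, 5)
  oracle <- vapply(run$spectra, function(sp)
    sum(sp$intensity[sp$mz >= w[1] & sp$mz <= w[2]]), numeric(1))
  expect_equal(eic$intensity, oracle)
  expect_equal(oracle, 10 * rt + 3)
})

test_that("a target outside the scan range warns and flags empty", {
  run <- single_trace_run(400, c(1, 2, 1))
  expect_warning(eic <- extract_eic(run, 900, 5), "outside scan range")
  expect_true(attr(eic, "empty"))
  expect_equal(eic$intensity, rep(0, 3))
  expect_error(extract_eic(run, 400, 0), "tolerance_ppm")
})

test_that("EIC intensity is monotone in tolerance and sums to the TIC", {
  set.seed(401)
  for (rep in 1:5) {
    run <- suppressWarnings(
      simulate_run(challenge_amounts(), noise_cv = 0.05, run_id = "m"))
    target <- mz_deprotonated("34:6")
    tols <- c(1, 2, 5, 20)
    eics <- lapply(tols, function(tp) extract_eic(run, target, tp)$intensity)
    for (i in seq_len(length(tols) - 1))
      expect_true(all(eics[[i]] <= eics[[i + 1]] + 1e-9))

    # partition the m/z axis into contiguous windows; their EICs sum to TIC
    edges <- seq(250, 800, length.out = 21)
    centers <- (edges[-1] + edges[-21]) / 2
    tol_ppm <- (edges[-1] - edges[-21]) / (edges[-1] + edges[-21]) * 1e6
    total <- Reduce(`+`, lapply(seq_along(centers), function(i)
      extract_eic(run, centers[i], tol_ppm[i])$intensity))
    expect_equal(total, extract_tic(run)$intensity, tolerance = 1e-9)
  }
})

test_that("a noiseless Gaussian yields one peak at its center", {
  ch <- gauss_chrom(list(list(A = 80, mu = 2.13, sigma = 0.05)))
  pk <- detect_peaks(ch)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$apex_rt - 2.13), 0.0100001)  # within one sampling step
  expect_lte(pk$left_rt, pk$apex_rt)
  expect_gte(pk$right_rt, pk$apex_rt)
  expect_lte(pk$area, pk$height * (pk$right_rt - pk$left_rt))
})

test_that("flat traces yield no peaks; short traces error", {
  expect_equal(nrow(detect_peaks(chromatogram(1:10 / 10, rep(0, 10)))), 0L)
  expect_equal(nrow(detect_peaks(chromatogram(1:10 / 10, rep(7, 10)))), 0L)
  expect_error(detect_peaks(chromatogram(c(0.1, 0.2), c(0, 1))), "5 points")
})

test_that("two Gaussians 6 sigma apart resolve with areas within 2%", {
  s <- 0.05
  ch <- gauss_chrom(list(list(A = 100, mu = 1.8, sigma = s),
                         list(A = 60, mu = 1.8 + 6 * s, sigma = s)))
  pk <- detect_peaks(ch)
  expect_equal(nrow(pk), 2L)
  expect_lt(abs(pk$area[1] - 100) / 100, 0.02)
  expect_lt(abs(pk$area[2] - 60) / 60, 0.02)
})

test_that("peak integration matches closed forms", {
  rt <- seq(0, 4, by = 0.01)
  # rectangle against a zero baseline: area = h * w
  yr <- ifelse(rt >= 1 & rt <= 2, 7, 0)
  chr <- chromatogram(rt, yr)
  expect_equal(integrate_peak(chr, list(left_rt = 1, right_rt = 2),
                              baseline = 0), 7 * 1)
  # sampled Gaussian with boundaries at +/- 4 sigma: within 1% of A
  A <- 123; mu <- 2; s <- 0.05
  chg <- gauss_chrom(list(list(A = A, mu = mu, sigma = s)))
  got <- integrate_peak(chg, list(left_rt = mu - 4 * s, right_rt = mu + 4 * s))
  expect_lt(abs(got - A) / A, 0.01)
  # all-zero trace integrates to zero
  expect_equal(integrate_peak(chromatogram(rt, rep(0, length(rt))),
                              list(left_rt = 1, right_rt = 2)), 0)
  expect_error(integrate_peak(chg, list(left_rt = 2, right_rt = 1)),
               "inverted")
})

test_that("RT matching picks the nearest peak, larger area on ties", {
  peaks <- data.frame(apex_rt = c(3.20, 3.60), left_rt = c(3.1, 3.5),
                      right_rt = c(3.3, 3.7), height = c(10, 20),
                      area = c(1, 2), snr = c(5, 5))
  hit <- match_peak_to_rt(peaks, expected_rt = 3.23, rt_tolerance = 0.15)
  expect_equal(hit$apex_rt, 3.20)
  expect_null(match_peak_to_rt(peaks[0, ], 3.23, 0.15))
  expect_null(match_peak_to_rt(peaks, 5.0, 0.15))
  # equidistant candidates: the larger area wins
  tie <- data.frame(apex_rt = c(3.1, 3.3), left_rt = c(3.0, 3.2),
                    right_rt = c(3.2, 3.4), height = c(1, 1),
                    area = c(5, 50), snr = c(5, 5))
  expect_equal(match_peak_to_rt(tie, 3.2, 0.15)$area, 50)
  expect_error(match_peak_to_rt(peaks, 3.2, 0), "rt_tolerance")
})

test_that("integrated area is linear in spiked amount over a 50x range", {
  amounts <- 2e-12 * c(1, 2, 5, 10, 20, 50)
  areas <- vapply(seq_along(amounts), function(i) {
    run <- simulate_run(c("34:6" = amounts[i]), noise_cv = 0,
                        background_per_scan = 0, run_id = "lin", seed = 500 + i)
    q <- quantify_run(run)
    q$raw_area[q$species_label == "34:6"]
  }, numeric(1))
  true_areas <- amounts * 1e14        # generator sensitivity, counts*min/mol
  fit <- stats::lm(areas ~ true_areas)
  # the fit is near-perfect by design; lm warns about that
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.999)
  expect_lt(abs(stats::coef(fit)[2] - 1), 0.02)
})
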