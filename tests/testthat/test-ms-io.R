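# Run container invariants and mzML / TSV round trips.

test_that("spectrum_run sorts spectra by RT and enforces invariants", {
  sp <- list(
    list(rt_min = 2.0, mz = c(300, 400), intensity = c(5, 6)),
    list(rt_min = 1.0, mz = c(310, 410), intensity = c(1, 2)),
    list(rt_min = 3.0, mz = c(320, 420), intensity = c(3, 4)))
  run <- spectrum_run(sp)
  expect_equal(run_rt(run), c(1, 2, 3))  # shuffled input comes back sorted
  expect_equal(run$spectra[[1]]$mz, c(310, 410))

  expect_error(spectrum_run(list()), class = "vlcpufa_empty_run")
  expect_error(spectrum_run(list(list(rt_min = 1, mz = c(300, 301),
                                      intensity = 5))), "equal length")
  expect_error(spectrum_run(list(list(rt_min = 1, mz = 300, intensity = -1))),
               "negative")
  expect_error(spectrum_run(list(list(rt_min = 1, mz = 100, intensity = 1))),
               "scan range")
  expect_error(spectrum_run(list(list(rt_min = 1, mz = 300, intensity = 1),
                                 list(rt_min = 1, mz = 310, intensity = 1))),
               "duplicate")
})

test_that("mzML write/read round-trips a small and a full-size run", {
  sp <- list(
    list(rt_min = 0.5, mz = c(300.1234567, 450.7654321),
         intensity = c(1000, 2000)),
    list(rt_min = 0.6, mz = 315.2330277, intensity = 1500),
    list(rt_min = 0.7, mz = c(260, 467.3894545, 790),
         intensity = c(1, 123456.789, 3)))
  run <- spectrum_run(sp, run_id = "tiny")
  f <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(run, f)
  back <- read_mzml(f, run_id = "tiny")
  expect_equal(run_rt(back), run_rt(run), tolerance = 1e-9)
  for (i in seq_along(sp)) {
    expect_equal(back$spectra[[i]]$mz, run$spectra[[i]]$mz, tolerance = 1e-6)
    expect_equal(back$spectra[[i]]$intensity, run$spectra[[i]]$intensity,
                 tolerance = 1e-6)
  }
  expect_equal(back$polarity, "negative")
  expect_equal(back$scan_range, c(250, 800))

  big <- suppressWarnings(
    simulate_run(challenge_amounts(), noise_cv = 0.03, seed = 5,
                 run_id = "big"))
  f2 <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(big, f2)
  back2 <- read_mzml(f2, run_id = "big")
  expect_equal(length(back2$spectra), length(big$spectra))
  m1 <- unlist(lapply(big$spectra, `[[`, "mz"))
  m2 <- unlist(lapply(back2$spectra, `[[`, "mz"))
  expect_equal(m2, m1, tolerance = 1e-6)
})

test_that("mzML reader rejects missing, malformed and MS1-free files", {
  expect_error(read_mzml("no/such/file.mzML"), class = "vlcpufa_missing_file")

  bad <- withr::local_tempfile(fileext = ".mzML")
  writeLines("this is not mzML", bad)
  expect_error(read_mzml(bad), class = "vlcpufa_bad_format")

  # a file holding only MS2 spectra has nothing to quantify
  ms2 <- withr::local_tempfile(fileext = ".mzML")
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 2L, polarity = 0L,
    peaksCount = 2L, totIonCurrent = 30, retentionTime = 6,
    basePeakMZ = 400.5, basePeakIntensity = 20, collisionEnergy = 35,
    ionisationEnergy = 0, lowMZ = 300, highMZ = 402, precursorScanNum = 0L,
    precursorMZ = 467.39, precursorCharge = 1L, precursorIntensity = 100,
    mergedScan = 0L, mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0,
    filterString = NA_character_, spectrumId = "scan=1", centroided = TRUE,
    ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = 467.39,
    isolationWindowLowerOffset = 1, isolationWindowUpperOffset = 1,
    scanWindowLowerLimit = 250, scanWindowUpperLimit = 800,
    stringsAsFactors = FALSE)
  mzR::writeMSData(list(cbind(mz = c(300, 400.5), intensity = c(10, 20))),
                   file = ms2, header = hdr)
  expect_error(read_mzml(ms2), class = "vlcpufa_no_ms1")
})

test_that("TSV run dialect round-trips and groups interleaved RTs", {
  run <- single_trace_run(467.3894545, c(0, 10, 100, 10, 0) + 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_run(run, f)
  back <- read_tsv_run(f, run_id = "trace")
  expect_equal(run_rt(back), run_rt(run))
  for (i in seq_along(run$spectra)) {
    expect_equal(back$spectra[[i]]$mz, run$spectra[[i]]$mz, tolerance = 1e-9)
    expect_equal(back$spectra[[i]]$intensity, run$spectra[[i]]$intensity,
                 tolerance = 1e-9)
  }

  # rows interleaved across spectra regroup by identical rt
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rt_min\tmz\tintensity",
               "1.0\t300\t5", "2.0\t310\t7", "1.0\t400\t6", "2.0\t410\t8"),
             f2)
  run2 <- read_tsv_run(f2)
  expect_equal(run_rt(run2), c(1, 2))
  expect_equal(run2$spectra[[1]]$mz, c(300, 400))
  expect_equal(run2$spectra[[2]]$intensity, c(7, 8))

  hdr_only <- withr::local_tempfile(fileext = ".tsv")
  writeLines("rt_min\tmz\tintensity", hdr_only)
  expect_error(read_tsv_run(hdr_only), class = "vlcpufa_empty_run")

  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rt_min\tmz\tintensity", "1.0\tabc\t5"), ragged)
  expect_error(read_tsv_run(ragged), class = "vlcpufa_bad_format")
})
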