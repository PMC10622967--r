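# Shared fixtures, all built in code.

# Chromatogram carrying one or more analytic Gaussians (area, center, sigma).
gauss_chrom <- function(peaks, rt = seq(0, 4, by = 0.01)) {
  y <- rep(0, length(rt))
  for (p in peaks) y <- y + p$A * stats::dnorm(rt, p$mu, p$sigma)
  chromatogram(rt, y)
}

# Minimal hand-built run: one centroid per spectrum at a fixed m/z.
single_trace_run <- function(mz, intensities, rt = NULL,
                             scan_range = c(250, 800)) {
  if (is.null(rt)) rt <- seq_along(intensities) * 0.01
  spectra <- Map(function(t, i) {
    if (i > 0) list(rt_min = t, mz = mz, intensity = i)
    else list(rt_min = t, mz = numeric(0), intensity = numeric(0))
  }, rt, intensities)
  spectrum_run(unname(spectra), scan_range = scan_range, run_id = "trace")
}

# Remove every centroid within tol_ppm of the internal standard m/z.
strip_internal_standard <- function(run, tol_ppm = 20) {
  w <- ppm_window(mz_deprotonated("21:5"), tol_ppm)
  spectra <- lapply(run$spectra, function(sp) {
    keep <- sp$mz < w[1] | sp$mz > w[2]
    list(rt_min = sp$rt_min, mz = sp$mz[keep], intensity = sp$intensity[keep])
  })
  out <- spectrum_run(spectra, polarity = run$polarity,
                      scan_range = run$scan_range, run_id = run$run_id)
  attr(out, "truth") <- attr(run, "truth")
  out
}

# Marker-plus-DHA amount set typical of a POS challenge (no isomer pairs,
# so every species is chromatographically unambiguous).
challenge_amounts <- function(scale = 1) {
  c("20:4" = 1e-9, "22:6" = 4.8e-10, "32:6" = 3.84e-11, "34:4" = 4.8e-11,
    "34:5" = 5.76e-11, "34:6" = 6.432e-11, "36:6" = 3.1552e-11) * scale
}
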