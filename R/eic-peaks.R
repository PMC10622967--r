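## Extracted ion chromatograms at ppm tolerance, chromatographic peak
## detection, trapezoidal integration over a local linear baseline, and
## retention-time matching against the panel's expected RTs.

#' Construct a chromatogram
#'
#' @param rt Ascending retention times, minutes.
#' @param intensity Non-negative intensities, same length as `rt`.
#' @param target_mz Target m/z (NA for a total ion chromatogram).
#' @param tolerance_ppm Extraction tolerance in ppm (NA for TIC).
#' @param run_id Source run identifier.
#' @return Object of class `Chromatogram`.
#' @export
chromatogram <- function(rt, intensity, target_mz = NA_real_,
                         tolerance_ppm = NA_real_, run_id = "run") {
  if (length(rt) != length(intensity))
    stop("rt and intensity must have equal length")
  if (length(rt) > 1L && any(diff(rt) <= 0))
    stop("rt must be strictly ascending")
  if (any(intensity < 0)) stop("negative intensity in chromatogram")
  structure(list(target_mz = target_mz, tolerance_ppm = tolerance_ppm,
                 rt = as.numeric(rt), intensity = as.numeric(intensity),
                 run_id = run_id),
            class = "Chromatogram")
}

#' @export
print.Chromatogram <- function(x, ...) {
  lab <- if (is.na(x$target_mz)) "TIC"
         else sprintf("m/z %.4f +/- %g ppm", x$target_mz, x$tolerance_ppm)
  cat(sprintf("<Chromatogram> %s, %d points, RT %.2f-%.2f min, max %.3g\n",
              lab, length(x$rt), min(x$rt), max(x$rt), max(x$intensity)))
  invisible(x)
}

#' Extract an ion chromatogram at ppm tolerance
#'
#' For each spectrum, sums the intensities of all centroids whose m/z falls
#' within the symmetric ppm window around `target_mz`; spectra with no
#' matching centroid contribute zero. A target outside the run's scan range
#' yields an all-zero chromatogram flagged empty, with a warning.
#'
#' @param run A `SpectrumRun` (or a pre-flattened run, internal use).
#' @param target_mz Target m/z in Th.
#' @param tolerance_ppm Extraction tolerance in ppm, > 0.
#' @return A `Chromatogram`; attribute `"empty"` is `TRUE` when the target
#'   was outside the scan range.
#' @export
extract_eic <- function(run, target_mz, tolerance_ppm = 5) {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0")
  flat <- if (inherits(run, "SpectrumRun")) .flatten_run(run) else run
  out_of_range <- inherits(run, "SpectrumRun") &&
    (target_mz < run$scan_range[1] || target_mz > run$scan_range[2])
  w <- ppm_window(target_mz, tolerance_ppm)
  inten <- numeric(flat$n_scans)
  sel <- flat$mz >= w[1] & flat$mz <= w[2]
  if (any(sel)) {
    s <- rowsum(flat$intensity[sel], flat$scan[sel])
    inten[as.integer(rownames(s))] <- s[, 1]
  }
  run_id <- if (inherits(run, "SpectrumRun")) run$run_id else "run"
  ch <- chromatogram(flat$rt, inten, target_mz, tolerance_ppm, run_id)
  if (out_of_range) {
    warning("target m/z ", target_mz, " outside scan range; empty chromatogram")
    ch$intensity[] <- 0
    attr(ch, "empty") <- TRUE
  }
  ch
}

#' Total ion chromatogram
#'
#' @param run A `SpectrumRun`.
#' @return A `Chromatogram` with per-spectrum summed intensity.
#' @export
extract_tic <- function(run) {
  stopifnot(inherits(run, "SpectrumRun"))
  inten <- vapply(run$spectra, function(sp) sum(sp$intensity), numeric(1))
  chromatogram(run_rt(run), inten, run_id = run$run_id)
}

#' Detect chromatographic peaks
#'
#' Peaks are local maxima of the (optionally moving-average smoothed) trace
#' exceeding `baseline + min_snr * noise`, where the baseline is the median
#' of the trace and noise its scaled median absolute deviation (robust to
#' the peaks themselves). Boundaries extend from each apex to the nearest
#' local minimum or baseline crossing on either side.
#'
#' @param chrom A `Chromatogram` with at least 5 points.
#' @param min_snr Minimum apex signal-to-noise over baseline (default 3).
#' @param smoothing_window Moving-average window in points (default 3; 1
#'   disables smoothing).
#' @return data.frame of peaks sorted by `apex_rt` with columns `apex_rt`,
#'   `left_rt`, `right_rt`, `height`, `area`, `snr`; zero rows for a flat
#'   trace.
#' @export
detect_peaks <- function(chrom, min_snr = 3, smoothing_window = 3) {
  stopifnot(inherits(chrom, "Chromatogram"))
  y <- chrom$intensity
  n <- length(y)
  if (n < 5L) stop("chromatogram too short for peak detection (< 5 points)")
  empty <- data.frame(apex_rt = numeric(0), left_rt = numeric(0),
                      right_rt = numeric(0), height = numeric(0),
                      area = numeric(0), snr = numeric(0))
  if (max(y) == min(y)) return(empty)   # flat trace
  ys <- if (smoothing_window > 1L) .movavg(y, smoothing_window) else y
  baseline <- stats::median(ys)
  noise <- stats::mad(ys)               # scaled MAD (constant 1.4826)
  threshold <- baseline + min_snr * noise
  apex <- which(ys > c(-Inf, ys[-n]) & ys >= c(ys[-1], -Inf) & ys > threshold)
  if (length(apex) == 0L) return(empty)
  ## Boundary walk: descend from the apex until the trace crosses the
  ## baseline or reaches a significant valley (a local minimum below half
  ## the apex rise); small noise-induced upticks on the flank are walked
  ## through so one noisy peak is not fragmented.
  walk <- function(a, dir) {
    i <- a
    rise <- ys[a] - baseline
    repeat {
      j <- i + dir
      if (j < 1L || j > n) break
      if (ys[j] <= baseline) { i <- j; break }
      if (ys[j] > ys[i] && ys[i] - baseline < 0.5 * rise) break
      i <- j
    }
    i
  }
  bounds <- t(vapply(apex, function(a)
    c(left = walk(a, -1L), right = walk(a, 1L)), c(left = 0L, right = 0L)))
  ## merge intervals overlapping by more than a shared endpoint (flank bumps
  ## detected as separate apexes collapse into their parent peak)
  o <- order(bounds[, "left"], bounds[, "right"])
  bounds <- bounds[o, , drop = FALSE]
  merged <- list(bounds[1, ])
  if (nrow(bounds) > 1L) for (i in 2:nrow(bounds)) {
    cur <- merged[[length(merged)]]
    if (bounds[i, "left"] < cur["right"]) {
      cur["right"] <- max(cur["right"], bounds[i, "right"])
      cur["left"] <- min(cur["left"], bounds[i, "left"])
      merged[[length(merged)]] <- cur
    } else merged[[length(merged) + 1L]] <- bounds[i, ]
  }
  out <- do.call(rbind, lapply(merged, function(b) {
    seg <- b["left"]:b["right"]
    apex_raw <- seg[which.max(y[seg])]
    pk <- data.frame(apex_rt = chrom$rt[apex_raw],
                     left_rt = chrom$rt[b["left"]],
                     right_rt = chrom$rt[b["right"]],
                     height = y[apex_raw], area = NA_real_,
                     snr = if (noise > 0) (y[apex_raw] - baseline) / noise
                           else Inf)
    ## constant robust baseline: a valley between partly resolved peaks must
    ## not drag the integration baseline up (perpendicular-drop convention)
    pk$area <- integrate_peak(chrom, pk, baseline = baseline)
    pk
  }))
  rownames(out) <- NULL
  out[order(out$apex_rt), , drop = FALSE]
}

.movavg <- function(y, w) {
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L       # centered window must be odd
  k <- rep(1 / w, w)
  n <- length(y)
  pad <- (w - 1L) %/% 2L
  yp <- c(rep(y[1], pad), y, rep(y[n], pad))
  as.numeric(stats::filter(yp, k, sides = 2))[(pad + 1L):(pad + n)]
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal integral of the intensity minus a linear baseline over
#' `[left_rt, right_rt]`, floored at zero. By default the baseline is the
#' line between the two observed boundary points; [detect_peaks()] instead
#' passes its robust constant baseline estimate, so a valley between partly
#' resolved peaks does not raise the integration baseline.
#'
#' @param chrom A `Chromatogram`.
#' @param peak One peak (a row from [detect_peaks()], or any list with
#'   `left_rt` and `right_rt`).
#' @param baseline `NULL` (line between the boundary intensities), a scalar
#'   constant level, or a length-2 vector of baseline values at the two
#'   boundaries.
#' @return Area in counts * min.
#' @export
integrate_peak <- function(chrom, peak, baseline = NULL) {
  stopifnot(inherits(chrom, "Chromatogram"))
  l <- peak$left_rt; r <- peak$right_rt
  if (l > r) stop("inverted peak boundaries")
  sel <- which(chrom$rt >= l & chrom$rt <= r)
  if (length(sel) < 2L) return(0)
  x <- chrom$rt[sel]; y <- chrom$intensity[sel]
  nb <- length(y)
  bv <- if (is.null(baseline)) c(y[1], y[nb])
        else if (length(baseline) == 1L) rep(baseline, 2L)
        else baseline[1:2]
  bl <- bv[1] + (bv[2] - bv[1]) * (x - x[1]) / (x[nb] - x[1])
  d <- y - bl
  area <- sum(diff(x) * (d[-1] + d[-nb]) / 2)
  max(area, 0)
}

#' Match detected peaks to an expected retention time
#'
#' Among peaks whose apex lies within `rt_tolerance` of `expected_rt`,
#' returns the closest; ties are broken in favor of the larger area. Isomers
#' sharing one m/z are resolved by calling this once per expected RT on the
#' shared chromatogram's peaks.
#'
#' @param peaks data.frame from [detect_peaks()].
#' @param expected_rt Expected apex retention time, minutes.
#' @param rt_tolerance Maximum |apex - expected| in minutes (default 0.15).
#' @return One-row data.frame, or `NULL` when no peak qualifies.
#' @export
match_peak_to_rt <- function(peaks, expected_rt, rt_tolerance = 0.15) {
  if (rt_tolerance <= 0) stop("rt_tolerance must be > 0")
  if (is.null(peaks) || nrow(peaks) == 0L) return(NULL)
  dd <- abs(peaks$apex_rt - expected_rt)
  cand <- which(dd <= rt_tolerance)
  if (length(cand) == 0L) return(NULL)
  cand <- cand[order(dd[cand], -peaks$area[cand])]
  peaks[cand[1L], , drop = FALSE]
}

#' Plot a chromatogram with detected peak boundaries
#'
#' Base-graphics QC plot: the trace, plus shaded integration regions for any
#' supplied peaks.
#'
#' @param chrom A `Chromatogram`.
#' @param peaks Optional data.frame from [detect_peaks()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_eic <- function(chrom, peaks = NULL, ...) {
  lab <- if (is.na(chrom$target_mz)) "TIC"
         else sprintf("m/z %.4f (%g ppm)", chrom$target_mz, chrom$tolerance_ppm)
  graphics::plot(chrom$rt, chrom$intensity, type = "l",
                 xlab = "retention time (min)", ylab = "intensity",
                 main = lab, ...)
  if (!is.null(peaks) && nrow(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      sel <- chrom$rt >= peaks$left_rt[i] & chrom$rt <= peaks$right_rt[i]
      graphics::polygon(c(chrom$rt[sel], rev(chrom$rt[sel])),
                        c(chrom$intensity[sel], numeric(sum(sel))),
                        col = grDevices::adjustcolor("steelblue", 0.3),
                        border = NA)
      graphics::abline(v = peaks$apex_rt[i], lty = 3)
    }
  }
  invisible(NULL)
}
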