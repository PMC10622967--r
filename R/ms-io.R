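## SpectrumRun container and I/O: mzML via mzR, plus a plain-text TSV run
## dialect used for small fixtures. Retention time is minutes everywhere in
## this package; mzML stores seconds and is converted on read/write.

.io_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "vlcpufa_io_error")))
}

#' Construct an LC-MS run
#'
#' An ordered collection of centroided mass spectra. Spectra are sorted by
#' retention time on construction; each spectrum's centroids are sorted by
#' m/z.
#'
#' @param spectra List of spectra, each a list with numeric fields `rt_min`
#'   (scalar, minutes), `mz` (ascending, Th) and `intensity` (same length,
#'   non-negative counts).
#' @param polarity `"negative"` (default) or `"positive"`.
#' @param scan_range Numeric `c(low, high)` acquisition m/z range; all
#'   centroids must fall inside it.
#' @param run_id Identifier used as the sample id downstream.
#' @param metadata Free-form named list (gradient, instrument, ...), carried
#'   but unused.
#' @return Object of class `SpectrumRun`.
#' @export
spectrum_run <- function(spectra, polarity = "negative",
                         scan_range = c(250, 800), run_id = "run",
                         metadata = list()) {
  if (!is.list(spectra) || length(spectra) == 0L)
    .io_error("a SpectrumRun needs at least one spectrum", "vlcpufa_empty_run")
  polarity <- match.arg(polarity, c("negative", "positive"))
  spectra <- lapply(spectra, function(sp) {
    if (!all(c("rt_min", "mz", "intensity") %in% names(sp)))
      stop("each spectrum needs rt_min, mz and intensity")
    if (length(sp$mz) != length(sp$intensity))
      stop("mz and intensity must have equal length")
    o <- order(sp$mz)
    list(rt_min = as.numeric(sp$rt_min), mz = as.numeric(sp$mz)[o],
         intensity = as.numeric(sp$intensity)[o])
  })
  rts <- vapply(spectra, `[[`, numeric(1), "rt_min")
  if (anyDuplicated(rts))
    stop("duplicate spectrum retention times in run")
  spectra <- spectra[order(rts)]
  run <- structure(
    list(spectra = spectra, polarity = polarity,
         scan_range = as.numeric(scan_range), run_id = run_id,
         metadata = metadata),
    class = "SpectrumRun")
  validate_run(run)
  run
}

#' Validate SpectrumRun invariants
#'
#' Checks strictly increasing retention times, ascending m/z within each
#' spectrum, equal-length arrays, non-negative intensities and containment in
#' the declared scan range.
#'
#' @param run A `SpectrumRun`.
#' @return The run, invisibly; errors on violation.
#' @export
validate_run <- function(run) {
  stopifnot(inherits(run, "SpectrumRun"))
  rts <- run_rt(run)
  if (any(diff(rts) <= 0)) stop("retention times not strictly increasing")
  for (sp in run$spectra) {
    if (length(sp$mz) != length(sp$intensity))
      stop("mz/intensity length mismatch")
    if (length(sp$mz) > 1L && any(diff(sp$mz) <= 0))
      stop("m/z values not strictly ascending within a spectrum")
    if (any(sp$intensity < 0)) stop("negative intensity")
    if (length(sp$mz) &&
        (min(sp$mz) < run$scan_range[1] || max(sp$mz) > run$scan_range[2]))
      stop("centroid m/z outside declared scan range")
  }
  invisible(run)
}

#' Retention times of a run's spectra
#' @param run A `SpectrumRun`.
#' @return Numeric vector of retention times in minutes.
#' @export
run_rt <- function(run) vapply(run$spectra, `[[`, numeric(1), "rt_min")

#' @export
print.SpectrumRun <- function(x, ...) {
  rts <- run_rt(x)
  cat(sprintf("<SpectrumRun> '%s': %d spectra, RT %.2f-%.2f min, %s mode, m/z %g-%g\n",
              x$run_id, length(x$spectra), min(rts), max(rts), x$polarity,
              x$scan_range[1], x$scan_range[2]))
  invisible(x)
}

## Flatten all centroids into parallel vectors (scan index, mz, intensity);
## used by EIC extraction so one run is traversed once per window.
.flatten_run <- function(run) {
  n <- vapply(run$spectra, function(sp) length(sp$mz), integer(1))
  list(scan = rep.int(seq_along(run$spectra), n),
       mz = unlist(lapply(run$spectra, `[[`, "mz"), use.names = FALSE),
       intensity = unlist(lapply(run$spectra, `[[`, "intensity"),
                          use.names = FALSE),
       rt = run_rt(run), n_scans = length(run$spectra))
}

#' Read a centroided LC-MS run from mzML
#'
#' Reads MS1 spectra, converts retention time to minutes and sorts by RT.
#' Profile-mode spectra are rejected unless `centroid_profile = TRUE`, in
#' which case a naive local-maximum centroider is applied (approximate; meant
#' for viewing, not quantification).
#'
#' @param path Path to an mzML file (gzip-compressed accepted).
#' @param run_id Run identifier; defaults to the file name without extension.
#' @param centroid_profile Logical; centroid profile spectra instead of
#'   erroring.
#' @return A `SpectrumRun`.
#' @export
read_mzml <- function(path, run_id = NULL, centroid_profile = FALSE) {
  if (!file.exists(path))
    .io_error(paste0("file not found: ", path), "vlcpufa_missing_file")
  fh <- tryCatch(mzR::openMSfile(path),
                 error = function(e)
                   .io_error(paste0("not a readable mzML file: ", path),
                             "vlcpufa_bad_format"))
  on.exit(mzR::close(fh), add = TRUE)
  hdr <- mzR::header(fh)
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) == 0L)
    .io_error("no MS1 spectra in file", "vlcpufa_no_ms1")
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  spectra <- lapply(ms1, function(i) {
    m <- pk[[i]]
    centroided <- hdr$centroided[i]
    mzv <- m[, 1]; iv <- m[, 2]
    if (isFALSE(centroided)) {
      if (!centroid_profile)
        .io_error("profile-mode spectra present; set centroid_profile = TRUE",
                  "vlcpufa_profile_data")
      keep <- .local_maxima(iv)
      mzv <- mzv[keep]; iv <- iv[keep]
    }
    list(rt_min = hdr$retentionTime[i] / 60, mz = mzv, intensity = iv)
  })
  pol <- unique(hdr$polarity[ms1])
  polarity <- if (all(pol == 1L)) "positive" else "negative"
  lo <- suppressWarnings(min(hdr$scanWindowLowerLimit[ms1], na.rm = TRUE))
  hi <- suppressWarnings(max(hdr$scanWindowUpperLimit[ms1], na.rm = TRUE))
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0) {
    allmz <- unlist(lapply(spectra, `[[`, "mz"), use.names = FALSE)
    lo <- if (length(allmz)) floor(min(allmz)) else 0
    hi <- if (length(allmz)) ceiling(max(allmz)) else 1
  }
  if (is.null(run_id)) run_id <- sub("\\.mzML(\\.gz)?$", "", basename(path),
                                     ignore.case = TRUE)
  spectrum_run(spectra, polarity = polarity, scan_range = c(lo, hi),
               run_id = run_id)
}

.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(seq_len(n))
  which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf) & y > 0)
}

#' Write a run to mzML
#'
#' Produces a standards-conformant centroided mzML file readable by
#' [read_mzml()] and by common external viewers.
#'
#' @param run A `SpectrumRun`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  validate_run(run)
  n <- length(run$spectra)
  pks <- lapply(run$spectra, function(sp)
    cbind(mz = sp$mz, intensity = sp$intensity))
  pol <- if (run$polarity == "positive") 1L else 0L
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = pol,
    peaksCount = vapply(pks, nrow, integer(1)),
    totIonCurrent = vapply(run$spectra, function(sp) sum(sp$intensity),
                           numeric(1)),
    retentionTime = run_rt(run) * 60,
    basePeakMZ = vapply(run$spectra, function(sp)
      if (length(sp$mz)) sp$mz[which.max(sp$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(run$spectra, function(sp)
      if (length(sp$intensity)) max(sp$intensity) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$spectra, function(sp)
      if (length(sp$mz)) min(sp$mz) else 0, numeric(1)),
    highMZ = vapply(run$spectra, function(sp)
      if (length(sp$mz)) max(sp$mz) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = run$scan_range[1],
    scanWindowUpperLimit = run$scan_range[2],
    stringsAsFactors = FALSE)
  mzR::writeMSData(pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read / write a run in the long TSV dialect
#'
#' Plain-text fixture format: tab-separated columns `rt_min`, `mz`,
#' `intensity`, one row per centroid; rows with identical `rt_min` form one
#' spectrum. Values are written with 10 significant digits, so a write/read
#' cycle is an identity well past 6 significant digits.
#'
#' @param path File path.
#' @param run_id Run identifier; defaults to the file name without extension.
#' @param polarity,scan_range,metadata As for [spectrum_run()].
#' @return `read_tsv_run()` returns a `SpectrumRun`; `write_tsv_run()`
#'   returns `path` invisibly.
#' @export
read_tsv_run <- function(path, run_id = NULL, polarity = "negative",
                         scan_range = NULL) {
  if (!file.exists(path))
    .io_error(paste0("file not found: ", path), "vlcpufa_missing_file")
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rt_min", "mz", "intensity")
  if (!all(need %in% names(d)))
    .io_error("TSV run needs columns rt_min, mz, intensity",
              "vlcpufa_bad_format")
  if (nrow(d) == 0L)
    .io_error("TSV run file has no rows", "vlcpufa_empty_run")
  if (!all(vapply(d[need], is.numeric, logical(1))))
    .io_error("non-numeric cells in TSV run", "vlcpufa_bad_format")
  if (is.null(scan_range)) scan_range <- c(floor(min(d$mz)), ceiling(max(d$mz)))
  groups <- split(d, d$rt_min)   # groups rows by identical rt, any interleaving
  spectra <- lapply(groups, function(g)
    list(rt_min = g$rt_min[1], mz = g$mz, intensity = g$intensity))
  if (is.null(run_id)) run_id <- sub("\\.tsv$", "", basename(path))
  spectrum_run(unname(spectra), polarity = polarity, scan_range = scan_range,
               run_id = run_id)
}

#' @rdname read_tsv_run
#' @param run A `SpectrumRun`.
#' @export
write_tsv_run <- function(run, path) {
  validate_run(run)
  rows <- lapply(run$spectra, function(sp)
    data.frame(rt_min = rep(sp$rt_min, length(sp$mz)), mz = sp$mz,
               intensity = sp$intensity))
  d <- do.call(rbind, rows)
  fmt <- function(x) formatC(x, format = "g", digits = 10)
  out <- data.frame(rt_min = fmt(d$rt_min), mz = fmt(d$mz),
                    intensity = fmt(d$intensity), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
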