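## End-to-end quantification: run -> EIC -> peaks -> areas -> IS-normalized
## responses -> molar amounts, then experiment-level assay report.

#' Quantify one run against a target panel
#'
#' For every unique target m/z in the panel one EIC is extracted at
#' `tolerance_ppm` and its peaks detected once; each panel entry (isomers
#' share the EIC) is then matched to its expected retention time. Matched
#' peak areas are normalized to the internal standard and converted to moles
#' when `is_amount_mol` is supplied.
#'
#' @param run A `SpectrumRun`.
#' @param panel Target panel (see [default_panel()]).
#' @param tolerance_ppm EIC extraction tolerance in ppm (default 5).
#' @param rt_tolerance_min RT matching tolerance in minutes (default 0.15).
#' @param min_snr,smoothing_window Passed to [detect_peaks()].
#' @param is_amount_mol Moles of internal standard spiked per sample; when
#'   `NULL` (default, 1 ug of the 21:5 IS) it is computed with
#'   [is_amount_from_mass()].
#' @return data.frame with one row per panel species: `sample_id`,
#'   `species_label`, `role`, `target_mz`, `expected_rt_min`, `apex_rt`,
#'   `raw_area`, `normalized_response`, `est_amount_mol`, `not_detected`,
#'   `no_is`.
#' @export
quantify_run <- function(run, panel = default_panel(), tolerance_ppm = 5,
                         rt_tolerance_min = 0.15, min_snr = 3,
                         smoothing_window = 3, is_amount_mol = NULL) {
  stopifnot(inherits(run, "SpectrumRun"))
  if (is.null(is_amount_mol)) is_amount_mol <- is_amount_from_mass(1e-6)
  flat <- .flatten_run(run)
  flat$n_scans <- length(run$spectra)
  targets <- unique(round(panel$mz, 6))
  peaks_by_mz <- lapply(targets, function(tmz) {
    if (tmz < run$scan_range[1] || tmz > run$scan_range[2]) return(NULL)
    ch <- extract_eic(flat, tmz, tolerance_ppm)
    ch$run_id <- run$run_id
    if (length(ch$rt) < 5L || max(ch$intensity) == min(ch$intensity))
      return(NULL)
    detect_peaks(ch, min_snr = min_snr, smoothing_window = smoothing_window)
  })
  names(peaks_by_mz) <- as.character(targets)

  rows <- lapply(seq_len(nrow(panel)), function(i) {
    pk <- NULL
    if (!is.na(panel$expected_rt_min[i])) {
      pks <- peaks_by_mz[[as.character(round(panel$mz[i], 6))]]
      pk <- match_peak_to_rt(pks, panel$expected_rt_min[i], rt_tolerance_min)
    }
    data.frame(
      sample_id = run$run_id,
      species_label = panel$species_label[i],
      role = panel$role[i],
      target_mz = panel$mz[i],
      expected_rt_min = panel$expected_rt_min[i],
      apex_rt = if (is.null(pk)) NA_real_ else pk$apex_rt,
      raw_area = if (is.null(pk)) NA_real_ else pk$area,
      response_factor = panel$response_factor[i],
      stringsAsFactors = FALSE)
  })
  q <- do.call(rbind, rows)
  q$not_detected <- is.na(q$raw_area)

  is_row <- which(q$role == "internal_standard")
  is_area <- if (length(is_row) == 1L && !q$not_detected[is_row])
    q$raw_area[is_row] else NA_real_
  no_is <- is.na(is_area) || is_area <= 0
  q$no_is <- no_is
  area0 <- ifelse(q$not_detected, 0, q$raw_area)
  if (no_is) {
    q$normalized_response <- NA_real_
    q$est_amount_mol <- NA_real_
  } else {
    q$normalized_response <- area0 / is_area
    q$normalized_response[is_row] <- 1
    q$est_amount_mol <- amount_mol(q$normalized_response, is_amount_mol,
                                   q$response_factor)
    q$est_amount_mol[is_row] <- is_amount_mol
  }
  q$response_factor <- NULL
  rownames(q) <- NULL
  q
}

#' Quantify a set of runs with an experiment design
#'
#' Applies [quantify_run()] to every run and joins the design table. Runs
#' without a usable internal standard are flagged (`no_is`) and kept.
#'
#' @param runs Named list of `SpectrumRun` objects, or character vector of
#'   file paths (mzML or TSV runs, dispatched on extension); names/run ids
#'   must match `design$sample_id`.
#' @param design Experiment design data.frame (see [read_design()]).
#' @inheritParams quantify_run
#' @return Long data.frame (one row per sample x species), the quant table.
#' @export
quantify_experiment <- function(runs, design, panel = default_panel(), ...) {
  if (length(runs) == 0L) stop("no runs supplied")
  if (is.character(runs)) {
    paths <- runs
    runs <- lapply(paths, function(p)
      if (grepl("\\.mzML(\\.gz)?$", p, ignore.case = TRUE)) read_mzml(p)
      else read_tsv_run(p))
    names(runs) <- vapply(runs, `[[`, character(1), "run_id")
  }
  ids <- vapply(runs, `[[`, character(1), "run_id")
  missing_runs <- setdiff(design$sample_id, ids)
  if (length(missing_runs))
    stop("design samples without runs: ", paste(missing_runs, collapse = ", "))
  q <- do.call(rbind, lapply(runs, quantify_run, panel = panel, ...))
  rownames(q) <- NULL
  merge(q, design, by = "sample_id", sort = FALSE)
}

#' Assay report: condition summaries, impairment and reproducibility
#'
#' Aggregates a quant table into the assay's read-outs: per-condition
#' mean / SD / CV of each marker's molar amount, percent change of each
#' marker versus a reference condition, and the across-marker impairment
#' summary (mean +/- SD of the per-marker percent decreases).
#'
#' @param quant Quant table from [quantify_experiment()].
#' @param markers Marker species labels (default [default_markers()]).
#' @param reference_condition Condition name percent changes are computed
#'   against; default the first condition in the design.
#' @param config Optional named list of resolved parameters echoed into the
#'   report (reproducibility contract).
#' @return List of class `assay_report`: `package_version`, `config`,
#'   `condition_summary` (data.frame), `marker_changes` (data.frame with
#'   signed `percent_change` and `percent_decrease` vs reference),
#'   `impairment_summary` (mean/sd of per-marker percent decreases, per
#'   non-reference condition), `cv` (per condition x marker).
#' @export
assay_report <- function(quant, markers = default_markers(),
                         reference_condition = NULL, config = list()) {
  stopifnot(all(c("condition", "species_label", "est_amount_mol") %in%
                names(quant)))
  m <- quant[quant$species_label %in% markers, ]
  if (nrow(m) == 0L) stop("no marker species in quant table")
  conds <- unique(quant$condition)
  if (is.null(reference_condition)) reference_condition <- conds[1]
  if (!reference_condition %in% conds)
    stop("reference condition '", reference_condition, "' not in design")

  amount0 <- ifelse(is.na(m$est_amount_mol), 0, m$est_amount_mol)
  agg <- function(f) stats::aggregate(
    list(value = amount0), by = list(condition = m$condition,
                                     species_label = m$species_label), f)
  s_mean <- agg(mean); s_sd <- agg(function(x) stats::sd(x))
  s_n <- agg(length)
  cs <- data.frame(s_mean[, 1:2], mean_amount_mol = s_mean$value,
                   sd_amount_mol = s_sd$value, n = s_n$value)
  cs$cv_percent <- ifelse(cs$mean_amount_mol > 0 & cs$n >= 2,
                          100 * cs$sd_amount_mol / cs$mean_amount_mol,
                          NA_real_)

  ref <- cs[cs$condition == reference_condition, ]
  chg <- do.call(rbind, lapply(setdiff(conds, reference_condition),
    function(cond) {
      cc <- cs[cs$condition == cond, ]
      i <- match(cc$species_label, ref$species_label)
      ok <- !is.na(i) & ref$mean_amount_mol[i] > 0
      data.frame(condition = cond, species_label = cc$species_label,
                 percent_change = ifelse(ok,
                   percent_change(ref$mean_amount_mol[i], cc$mean_amount_mol),
                   NA_real_))
    }))
  if (!is.null(chg) && nrow(chg)) {
    chg$percent_decrease <- -chg$percent_change
    imp <- lapply(split(chg, chg$condition), function(g) {
      v <- g$percent_decrease[!is.na(g$percent_decrease)]
      if (length(v) >= 2L) as.list(summarize_marker_changes(v))
      else list(mean = if (length(v)) v else NA_real_, sd = NA_real_)
    })
  } else {
    chg <- data.frame(condition = character(0), species_label = character(0),
                      percent_change = numeric(0),
                      percent_decrease = numeric(0))
    imp <- list()
  }

  structure(list(
    package_version = as.character(utils::packageVersion("vlcpufa")),
    reference_condition = reference_condition,
    config = config,
    condition_summary = cs,
    marker_changes = chg,
    impairment_summary = imp,
    cv = cs[, c("condition", "species_label", "cv_percent", "n")]),
    class = "assay_report")
}

#' @export
print.assay_report <- function(x, ...) {
  cat("<assay_report> vlcpufa", x$package_version, "\n")
  cat("reference condition:", x$reference_condition, "\n")
  cat("\nPer-condition marker amounts (mol):\n")
  print(x$condition_summary, digits = 4)
  if (nrow(x$marker_changes)) {
    cat("\nPercent change vs reference:\n")
    print(x$marker_changes, digits = 4)
    for (cond in names(x$impairment_summary)) {
      s <- x$impairment_summary[[cond]]
      cat(sprintf("\n%s: mean decrease %.2f%% +/- %.2f%% (across markers)\n",
                  cond, s$mean, s$sd))
    }
  }
  invisible(x)
}

#' Write a quant table / assay report to disk
#'
#' The quant table is written as long TSV and, with `wide = TRUE`, also as a
#' wide per-sample summary (one column per species, molar amounts). The
#' report is written as JSON with the resolved configuration embedded.
#'
#' @param quant Quant table data.frame.
#' @param path Output file path.
#' @param wide Also write a `<path>_wide.tsv` per-sample matrix.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, path, wide = FALSE) {
  utils::write.table(quant, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (wide) {
    w <- stats::reshape(
      quant[, c("sample_id", "species_label", "est_amount_mol")],
      idvar = "sample_id", timevar = "species_label", direction = "wide")
    names(w) <- sub("^est_amount_mol\\.", "", names(w))
    utils::write.table(w, sub("(\\.tsv)?$", "_wide.tsv", path), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_quant_table
#' @param report An `assay_report`.
#' @export
write_assay_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}
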