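## Synthetic LC-MS runs and experiments with known ground truth. The
## generator emulates the assay's acquisition: negative-mode centroided full
## scans over m/z 250-800, Gaussian chromatographic peaks at the panel's
## expected retention times, centroids at theoretical [M-H]- m/z with a small
## ppm offset, multiplicative scan noise, and flat chemical background
## placed outside every target window. All randomness flows from one seed.

#' Default per-POS marker amounts (mol per POS particle)
#'
#' The 32:6, 34:6 and 36:6 values are the assay's published per-POS amounts;
#' 34:4 and 34:5 (not published) are plausible same-order stand-ins, and
#' 22:6 (DHA, abundant in POS membranes) is included so challenge runs carry
#' an LC-PUFA signal as well.
#'
#' @return Named numeric vector, mol/POS.
#' @export
default_per_pos_amounts <- function() {
  c("22:6" = 1.5e-14,
    "32:6" = 1.20e-15,
    "34:4" = 1.5e-15,
    "34:5" = 1.8e-15,
    "34:6" = 2.01e-15,
    "36:6" = 9.86e-16)
}

#' Default endogenous LC-PUFA content of cultured RPE cells (mol per cell)
#'
#' Cultured RPE carries the common LC-PUFAs but no species of 30 or more
#' carbons; that absence is what makes VLC-PUFAs usable as POS-uptake
#' tracers.
#'
#' @return Named numeric vector, mol/cell.
#' @export
default_cell_amounts <- function() {
  c("20:4" = 1.0e-14, "20:5" = 2.0e-15, "22:4" = 1.5e-15,
    "22:5 (1)" = 1.0e-15, "22:5 (2)" = 1.2e-15, "22:6" = 8.0e-15)
}

#' Scenario configuration for synthetic experiments
#'
#' @param scenario One of `"untreated_rpe"`, `"pos_only"`, `"pos_challenge"`,
#'   `"knockdown"`, `"replicate_cv"`, `"calibration_series"`.
#' @param pos_per_cell POS dose(s) per cell; for `"pos_challenge"` a vector
#'   of doses (default 0/10/20/40), otherwise a scalar.
#' @param incubation_h Incubation time in hours (metadata).
#' @param n_cells Cells per sample (default 1e5, a confluent 48-well).
#' @param uptake_fraction Fraction of offered POS internalized during the
#'   incubation (default 0.016, consistent with the published per-POS and
#'   per-cell amounts at 20 POS/cell for 5 h).
#' @param knockdown_effect Fractional reduction of uptake in the knockdown
#'   arm (default 0.82).
#' @param noise_cv Multiplicative scan-noise CV; in the `"replicate_cv"`
#'   scenario it is additionally applied to per-replicate amounts.
#' @param per_pos_amounts Named mol/POS vector (default
#'   [default_per_pos_amounts()]).
#' @param base_cell_amounts Named mol/cell vector of endogenous LC-PUFAs
#'   (default [default_cell_amounts()]).
#' @param calibration_levels Concentrations (nmol/L) for
#'   `"calibration_series"`.
#' @param calibration_species Species calibrated (default `"32:6"`).
#' @param sample_volume_L Volume converting nmol/L to moles (default 1 mL).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("untreated_rpe", "pos_only",
                                         "pos_challenge", "knockdown",
                                         "replicate_cv", "calibration_series"),
                            pos_per_cell = NULL, incubation_h = 2,
                            n_cells = 1e5, uptake_fraction = 0.016,
                            knockdown_effect = 0.82, noise_cv = 0.05,
                            per_pos_amounts = default_per_pos_amounts(),
                            base_cell_amounts = default_cell_amounts(),
                            calibration_levels = c(5, 10, 50, 100, 250, 500,
                                                   1000),
                            calibration_species = "32:6",
                            sample_volume_L = 1e-3) {
  scenario <- match.arg(scenario)
  if (is.null(pos_per_cell))
    pos_per_cell <- if (scenario == "pos_challenge") c(0, 10, 20, 40) else 20
  if (any(pos_per_cell < 0)) stop("pos_per_cell must be non-negative")
  stopifnot(uptake_fraction >= 0, uptake_fraction <= 1,
            knockdown_effect >= 0, knockdown_effect <= 1,
            noise_cv >= 0, noise_cv <= 1, n_cells > 0)
  structure(list(scenario = scenario, pos_per_cell = pos_per_cell,
                 incubation_h = incubation_h, n_cells = n_cells,
                 uptake_fraction = uptake_fraction,
                 knockdown_effect = knockdown_effect, noise_cv = noise_cv,
                 per_pos_amounts = per_pos_amounts,
                 base_cell_amounts = base_cell_amounts,
                 calibration_levels = calibration_levels,
                 calibration_species = calibration_species,
                 sample_volume_L = sample_volume_L),
            class = "scenario_config")
}

#' Simulate one LC-MS run from known per-species amounts
#'
#' Each species with a positive amount contributes a Gaussian elution profile
#' centered at its expected panel RT whose *area* in counts x min equals
#' `amount_mol * sensitivity`; in every scan a centroid is placed at the
#' species' theoretical [M-H]- m/z shifted by a per-species ppm offset drawn
#' within `ppm_jitter`. The internal standard is always present at
#' `is_amount_mol`. Flat chemical background centroids are placed at random
#' m/z at least 2x the extraction tolerance away from every target.
#'
#' @param amounts Named numeric vector (species label -> mol). Zero-amount
#'   species contribute nothing.
#' @param panel Target panel giving expected RTs (default [default_panel()]).
#' @param rt_range Acquisition window in minutes (default 0-8, covering the
#'   whole RT library).
#' @param rt_step Scan period in minutes (default 0.01).
#' @param sigma_min Chromatographic peak sigma in minutes (default 0.04,
#'   baseline-resolving the closest isomer pair in the library).
#' @param noise_cv Multiplicative per-centroid noise CV (default 0).
#' @param ppm_jitter Max |ppm| mass offset per species (default 2, inside the
#'   5 ppm extraction window).
#' @param background_per_scan Background centroids per scan (default 20).
#' @param background_height Height of background centroids; default 0.1x the
#'   median species peak height.
#' @param sensitivity Instrument response, counts x min per mol (default
#'   1e14).
#' @param is_amount_mol Internal-standard amount (default 1 ug of 21:5).
#' @param scan_range Acquisition m/z range (default 250-800).
#' @param run_id Run identifier.
#' @param seed Optional integer; when given the run is fully reproducible on
#'   its own. When `NULL` the ambient RNG stream is used (so a wrapping
#'   `set.seed()` governs a whole experiment).
#' @return A `SpectrumRun` with attribute `"truth"`: data.frame
#'   `species_label`, `amount_mol`, `true_area`, `apex_rt`, `sigma_min`,
#'   `ppm_offset`.
#' @export
simulate_run <- function(amounts, panel = default_panel(),
                         rt_range = c(0, 8), rt_step = 0.01,
                         sigma_min = 0.04, noise_cv = 0, ppm_jitter = 2,
                         background_per_scan = 20, background_height = NULL,
                         sensitivity = 1e14, is_amount_mol = NULL,
                         scan_range = c(250, 800), run_id = "sim",
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (rt_step <= 0) stop("rt_step must be positive")
  if (is.null(is_amount_mol)) is_amount_mol <- is_amount_from_mass(1e-6)
  amounts <- amounts[amounts > 0]
  is_label <- panel$species_label[panel$role == "internal_standard"][1]
  if (!is.na(is_label) && !is_label %in% names(amounts))
    amounts <- c(amounts, stats::setNames(is_amount_mol, is_label))
  i <- match(names(amounts), panel$species_label)
  if (anyNA(i))
    stop("species not in panel: ",
         paste(names(amounts)[is.na(i)], collapse = ", "))
  truth <- data.frame(
    species_label = names(amounts),
    amount_mol = unname(amounts),
    true_area = unname(amounts) * sensitivity,
    apex_rt = panel$expected_rt_min[i],
    sigma_min = sigma_min,
    ppm_offset = stats::runif(length(amounts), -ppm_jitter, ppm_jitter),
    mz = panel$mz[i],
    stringsAsFactors = FALSE)
  if (anyNA(truth$apex_rt))
    stop("no expected RT in panel for: ",
         paste(truth$species_label[is.na(truth$apex_rt)], collapse = ", "))
  ## unresolvable isomers: same m/z closer than 3 sigma
  for (mzv in unique(truth$mz)) {
    rts <- sort(truth$apex_rt[truth$mz == mzv])
    if (length(rts) > 1L && any(diff(rts) < 3 * sigma_min))
      warning("isomer peaks at m/z ", round(mzv, 4),
              " closer than 3 sigma: unresolvable by design")
  }

  scans <- seq(rt_range[1], rt_range[2], by = rt_step)
  ns <- length(scans)
  scan_idx <- integer(0); mzv <- numeric(0); inten <- numeric(0)
  for (k in seq_len(nrow(truth))) {
    sel <- which(abs(scans - truth$apex_rt[k]) <= 5 * sigma_min)
    if (!length(sel)) next
    h <- truth$true_area[k] *
      stats::dnorm(scans[sel], truth$apex_rt[k], sigma_min)
    scan_idx <- c(scan_idx, sel)
    mzv <- c(mzv, rep(truth$mz[k] * (1 + truth$ppm_offset[k] * 1e-6),
                      length(sel)))
    inten <- c(inten, h)
  }
  if (noise_cv > 0)
    inten <- inten * pmax(0, 1 + stats::rnorm(length(inten), 0, noise_cv))

  ## flat chemical background, excluded from every target window
  if (background_per_scan > 0) {
    if (is.null(background_height)) {
      peak_heights <- truth$true_area / (sigma_min * sqrt(2 * pi))
      background_height <- 0.1 * stats::median(peak_heights)
    }
    nbg <- background_per_scan * ns
    excl <- ppm_window(panel$mz, 10)   # 2x default extraction tolerance
    bg_mz <- numeric(0)
    while (length(bg_mz) < nbg) {
      cand <- stats::runif(nbg - length(bg_mz), scan_range[1], scan_range[2])
      bad <- rep(FALSE, length(cand))
      for (j in seq_len(nrow(excl)))
        bad <- bad | (cand >= excl[j, 1] & cand <= excl[j, 2])
      bg_mz <- c(bg_mz, cand[!bad])
    }
    scan_idx <- c(scan_idx, rep(seq_len(ns), each = background_per_scan))
    mzv <- c(mzv, bg_mz)
    inten <- c(inten, background_height *
                 stats::runif(nbg, 0.5, 1.5))
  }

  keep <- inten > 0
  scan_idx <- scan_idx[keep]; mzv <- mzv[keep]; inten <- inten[keep]
  spectra <- vector("list", ns)
  ord <- order(scan_idx, mzv)
  scan_idx <- scan_idx[ord]; mzv <- mzv[ord]; inten <- inten[ord]
  starts <- c(which(!duplicated(scan_idx)), length(scan_idx) + 1L)
  present <- unique(scan_idx)
  for (q in seq_along(present)) {
    rows <- starts[q]:(starts[q + 1L] - 1L)
    m <- mzv[rows]; v <- inten[rows]
    if (anyDuplicated(m)) {            # coinciding centroids merge
      v <- as.numeric(rowsum(v, m))
      m <- sort(unique(m))
    }
    spectra[[present[q]]] <- list(rt_min = scans[present[q]], mz = m,
                                  intensity = v)
  }
  for (q in which(vapply(spectra, is.null, logical(1))))
    spectra[[q]] <- list(rt_min = scans[q], mz = numeric(0),
                         intensity = numeric(0))
  run <- spectrum_run(spectra, polarity = "negative", scan_range = scan_range,
                      run_id = run_id,
                      metadata = list(generator = "vlcpufa::simulate_run",
                                      sensitivity = sensitivity))
  truth$mz <- NULL
  attr(run, "truth") <- truth
  run
}

#' Simulate a whole phagocytosis experiment
#'
#' Builds per-condition, per-replicate ground-truth amounts from the scenario
#' rules and generates one run per sample:
#' * `untreated_rpe` - endogenous LC-PUFAs only, no species of >= 30 carbons;
#' * `pos_only` - the POS preparation itself (per-POS amounts x particle
#'   count);
#' * `pos_challenge` - cells plus internalized POS at each dose:
#'   `dose x n_cells x per_pos_amount x uptake_fraction`;
#' * `knockdown` - `control` and `triple_kd` arms, the latter with uptake
#'   scaled by `1 - knockdown_effect`;
#' * `replicate_cv` - one condition with per-replicate amount jitter at
#'   `noise_cv`;
#' * `calibration_series` - one run per concentration level of the
#'   calibration species.
#'
#' @param config A [scenario_config()].
#' @param n_replicates Replicates per condition (default 3).
#' @param seed Integer seed governing the whole experiment (default 1).
#' @param panel Target panel.
#' @param ... Passed on to [simulate_run()] (e.g. `noise_cv` is taken from
#'   `config` but `rt_step`, `sensitivity` may be overridden).
#' @return List of class `synthetic_experiment`: `runs` (named list of
#'   `SpectrumRun`), `design` (data.frame), `truth` (data.frame with one row
#'   per sample x species: nominal ground-truth amounts and realized peak
#'   parameters), `config`.
#' @export
simulate_experiment <- function(config, n_replicates = 3, seed = 1,
                                panel = default_panel(), ...) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  arms <- .scenario_arms(config)
  design <- list(); runs <- list(); truth <- list()
  for (a in seq_along(arms)) {
    arm <- arms[[a]]
    for (r in seq_len(n_replicates)) {
      sample_id <- sprintf("%s_rep%d", arm$condition, r)
      amounts <- arm$amounts
      if (config$scenario == "replicate_cv" && config$noise_cv > 0)
        amounts <- amounts * pmax(0, 1 + stats::rnorm(length(amounts), 0,
                                                      config$noise_cv))
      dots <- list(...)
      if (is.null(dots$noise_cv)) dots$noise_cv <- config$noise_cv
      run <- do.call(simulate_run,
                     c(list(amounts, panel = panel, run_id = sample_id),
                       dots))
      tr <- attr(run, "truth")
      tr$sample_id <- sample_id
      tr$condition <- arm$condition
      tr$replicate <- r
      runs[[sample_id]] <- run
      truth[[sample_id]] <- tr
      design[[sample_id]] <- data.frame(
        sample_id = sample_id, condition = arm$condition,
        pos_per_cell = arm$pos_per_cell, incubation_h = config$incubation_h,
        n_cells = config$n_cells, replicate = r, stringsAsFactors = FALSE)
    }
  }
  structure(list(runs = runs, design = do.call(rbind, c(design,
                                                        make.row.names = FALSE)),
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 config = config, seed = seed),
            class = "synthetic_experiment")
}

## Condition arms (name, dose, nominal amounts) for each scenario.
.scenario_arms <- function(config) {
  base <- config$base_cell_amounts * config$n_cells
  challenge <- function(dose, uptake) {
    add <- config$per_pos_amounts * dose * config$n_cells * uptake
    lab <- union(names(base), names(add))
    v <- stats::setNames(numeric(length(lab)), lab)
    v[names(base)] <- base
    v[names(add)] <- v[names(add)] + add
    v
  }
  switch(config$scenario,
    untreated_rpe = list(list(condition = "untreated", pos_per_cell = 0,
                              amounts = base)),
    pos_only = {
      n_pos <- config$pos_per_cell[1] * config$n_cells
      list(list(condition = "pos_only", pos_per_cell = config$pos_per_cell[1],
                amounts = config$per_pos_amounts * n_pos))
    },
    pos_challenge = lapply(config$pos_per_cell, function(d)
      list(condition = sprintf("dose_%g", d), pos_per_cell = d,
           amounts = challenge(d, config$uptake_fraction))),
    knockdown = list(
      list(condition = "control", pos_per_cell = config$pos_per_cell[1],
           amounts = challenge(config$pos_per_cell[1],
                               config$uptake_fraction)),
      list(condition = "triple_kd", pos_per_cell = config$pos_per_cell[1],
           amounts = challenge(config$pos_per_cell[1],
                               config$uptake_fraction *
                                 (1 - config$knockdown_effect)))),
    replicate_cv = list(list(condition = "replicate",
                             pos_per_cell = config$pos_per_cell[1],
                             amounts = challenge(config$pos_per_cell[1],
                                                 config$uptake_fraction))),
    calibration_series = lapply(config$calibration_levels, function(lev)
      list(condition = sprintf("cal_%g", lev), pos_per_cell = 0,
           amounts = stats::setNames(lev * 1e-9 * config$sample_volume_L,
                                     config$calibration_species))),
    stop("unknown scenario: ", config$scenario))
}

#' Write a synthetic experiment to disk
#'
#' Emits one run file per sample (`.tsv` dialect or `.mzML`), the design
#' table as TSV and the ground truth as JSON.
#'
#' @param experiment A `synthetic_experiment`.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"mzml"`.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir, format = c("tsv", "mzml")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(experiment$runs)) {
    run <- experiment$runs[[id]]
    if (format == "tsv")
      write_tsv_run(run, file.path(dir, paste0(id, ".tsv")))
    else
      write_mzml(run, file.path(dir, paste0(id, ".mzML")))
  }
  write_design(experiment$design, file.path(dir, "design.tsv"))
  jsonlite::write_json(
    list(seed = experiment$seed,
         scenario = experiment$config$scenario,
         truth = experiment$truth),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
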