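## Assay arithmetic: internal-standard normalization, calibration, molar
## conversion, composition profiles, per-POS / per-cell amounts, percent
## impairment, and replicate CV.

#' Normalize peak areas to the internal standard
#'
#' Each peak area is divided by the internal-standard area measured in the
#' same run; this cancels run-to-run variation in injection and ionization.
#' The IS itself has response 1 by definition.
#'
#' @param areas Named numeric vector of peak areas (counts * min), IS
#'   excluded.
#' @param is_area Internal-standard peak area in the same run.
#' @return Named numeric vector of dimensionless responses. If `is_area` is
#'   missing, `NA` or non-positive, all responses are `NA` and the result
#'   carries attribute `no_is = TRUE` (with a warning).
#' @export
#' @examples
#' normalize_to_is(c("32:6" = 500), is_area = 1000)
normalize_to_is <- function(areas, is_area) {
  stopifnot(is.numeric(areas))
  if (missing(is_area) || length(is_area) != 1L || is.na(is_area) ||
      is_area <= 0) {
    warning("internal standard missing or non-positive; responses unavailable")
    out <- rep(NA_real_, length(areas))
    names(out) <- names(areas)
    attr(out, "no_is") <- TRUE
    return(out)
  }
  areas / is_area
}

#' Molar amount from an IS-normalized response
#'
#' With the internal standard spiked at a known molar amount, a response of 1
#' corresponds to that amount (divided by the per-species response factor,
#' which defaults to 1 when no species-specific calibration is available).
#'
#' @param response Dimensionless normalized response (>= 0). Vectorized.
#' @param is_amount_mol Moles of internal standard spiked into the sample.
#' @param response_factor Relative response of the species vs the IS
#'   (default 1). Vectorized along `response`.
#' @return Amount in mol.
#' @export
#' @examples
#' amount_mol(0.5, is_amount_from_mass(1e-6))
amount_mol <- function(response, is_amount_mol, response_factor = 1) {
  if (!is.numeric(is_amount_mol) || length(is_amount_mol) != 1L ||
      is.na(is_amount_mol) || is_amount_mol <= 0)
    stop("is_amount_mol must be a single positive number")
  if (any(response_factor <= 0, na.rm = TRUE))
    stop("response_factor must be positive")
  response * is_amount_mol / response_factor
}

#' Fit a linear calibration curve
#'
#' Ordinary least-squares fit of response against concentration, with the
#' Pearson correlation coefficient and a back-calculation based limit of
#' quantification: the lowest calibration level whose back-calculated
#' concentration, `(response - intercept) / slope`, lies within
#' `loq_accuracy` of nominal.
#'
#' @param concentration Concentrations, nmol/L (>= 3 distinct values spanning
#'   more than a 2x range).
#' @param response Measured responses, same length.
#' @param species Optional species label carried in the result.
#' @param loq_accuracy Maximum relative back-calculation error at the LOQ
#'   (default 0.2, i.e. 20%).
#' @return Object of class `CalibrationCurve`: list with `species`, `points`,
#'   `slope`, `intercept`, `r`, `loq` (`NA` when no level qualifies).
#' @export
#' @examples
#' fit_calibration(c(50, 100, 500, 1000), c(50, 100, 500, 1000) * 2e-3)
fit_calibration <- function(concentration, response, species = NA_character_,
                            loq_accuracy = 0.2) {
  if (length(concentration) != length(response))
    stop("concentration and response must have equal length")
  if (length(concentration) < 3L)
    stop("calibration needs at least 3 points")
  if (length(unique(concentration)) < 2L || stats::sd(concentration) == 0)
    stop("degenerate calibration: all concentrations equal")
  if (max(concentration) < 2 * min(concentration))
    stop("calibration must span more than a 2-fold concentration range")
  fit <- stats::lm(response ~ concentration)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r <- stats::cor(concentration, response)
  back <- (response - intercept) / slope
  rel_err <- abs(back - concentration) / concentration
  ok <- which(rel_err <= loq_accuracy)
  loq <- if (length(ok)) min(concentration[ok]) else NA_real_
  structure(list(species = species,
                 points = data.frame(concentration = concentration,
                                     response = response),
                 slope = slope, intercept = intercept, r = r, loq = loq),
            class = "CalibrationCurve")
}

#' @export
print.CalibrationCurve <- function(x, ...) {
  cat(sprintf("<CalibrationCurve>%s %d points: response = %.4g x conc %+.4g, r = %.4f, LOQ = %s nmol/L\n",
              if (is.na(x$species)) "" else paste0(" ", x$species),
              nrow(x$points), x$slope, x$intercept, x$r,
              if (is.na(x$loq)) "NA" else format(x$loq)))
  invisible(x)
}

#' Relative composition profile
#'
#' Fraction of each species in the summed response of all detected species
#' (internal standard excluded by the caller). Not-detected species (`NA`)
#' contribute zero but keep their entry.
#'
#' @param responses Named numeric vector of IS-normalized responses.
#' @return Named numeric vector of fractions summing to 1.
#' @export
#' @examples
#' composition_profile(c(A = 1, B = 3))
composition_profile <- function(responses) {
  stopifnot(is.numeric(responses), length(responses) >= 1L)
  v <- ifelse(is.na(responses), 0, responses)
  if (any(v < 0)) stop("negative responses")
  total <- sum(v)
  if (total == 0) stop("all responses zero or missing; no composition defined")
  v / total
}

#' POS uptake per cell
#'
#' Increase in a marker's molar amount in challenged cells over the
#' unchallenged reference, divided by the number of cells. A negative result
#' (challenged below reference) is returned as-is with attribute
#' `negative_uptake = TRUE`.
#'
#' @param challenged_mol Total moles in the POS-challenged sample.
#' @param unchallenged_mol Total moles in the reference (unchallenged) sample.
#' @param n_cells Number of cells, > 0.
#' @return Moles per cell.
#' @export
#' @examples
#' uptake_per_cell(1e-10, 0, 1e6)  # 1e-16 mol/cell
uptake_per_cell <- function(challenged_mol, unchallenged_mol, n_cells) {
  if (!is.numeric(n_cells) || any(n_cells <= 0))
    stop("n_cells must be positive")
  out <- (challenged_mol - unchallenged_mol) / n_cells
  if (any(out < 0)) attr(out, "negative_uptake") <- TRUE
  out
}

#' Molar amount per POS particle
#'
#' @param total_mol Total moles of a species measured in a POS preparation.
#' @param n_pos Number of POS particles, > 0.
#' @return Moles per POS.
#' @export
#' @examples
#' amount_per_pos(1.2e-9, 1e6)  # 1.2e-15 mol/POS
amount_per_pos <- function(total_mol, n_pos) {
  if (!is.numeric(n_pos) || any(n_pos <= 0)) stop("n_pos must be positive")
  total_mol / n_pos
}

#' Percent change of a treated value against a reference
#'
#' Signed percent: `100 * (treated - reference) / reference`; negative values
#' are decreases. Use [percent_decrease()] when reporting impairment as a
#' positive "decreased by X%" figure.
#'
#' @param reference Reference value, non-zero.
#' @param treated Treated/comparison value.
#' @return Percent change (vectorized).
#' @export
#' @examples
#' percent_change(21.01, 32.12)  # ~ +52.9
percent_change <- function(reference, treated) {
  if (any(reference == 0)) stop("zero reference in percent change")
  100 * (treated - reference) / reference
}

#' @rdname percent_change
#' @export
percent_decrease <- function(reference, treated) {
  -percent_change(reference, treated)
}

#' Mean and SD of per-marker percent changes
#'
#' Summarizes the per-marker impairment percentages of a knockdown (or other
#' treatment) as arithmetic mean and sample (n-1) standard deviation.
#'
#' @param per_marker_percent Numeric vector of >= 2 percentages.
#' @return Named numeric `c(mean, sd)`.
#' @export
#' @examples
#' summarize_marker_changes(c(84.82, 76.63, 94.70, 76.50, 77.40))
summarize_marker_changes <- function(per_marker_percent) {
  if (length(per_marker_percent) < 2L)
    stop("need at least 2 per-marker values")
  c(mean = mean(per_marker_percent), sd = stats::sd(per_marker_percent))
}

#' Replicate coefficient of variation
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation; the assay's
#' reproducibility metric across independent replicates.
#'
#' @param values Numeric vector of >= 2 positive values.
#' @return CV in percent.
#' @export
#' @examples
#' replicate_cv(c(8, 12))  # 28.28
replicate_cv <- function(values) {
  if (length(values) < 2L) stop("need at least 2 replicate values")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("replicate mean must be positive")
  100 * stats::sd(values) / m
}

#' Read an experiment design table
#'
#' Tab-separated, one row per sample: `sample_id`, `condition`,
#' `pos_per_cell`, `incubation_h`, `n_cells`, `replicate`.
#'
#' @param path Path to the design TSV.
#' @return data.frame.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "pos_per_cell", "incubation_h",
            "n_cells", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in design")
  if (any(d$n_cells <= 0)) stop("n_cells must be positive")
  d
}

#' @rdname read_design
#' @param design Design data.frame.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
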