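## Target panel: the species to quantify, their expected retention times and
## roles. The packaged default is the LC/VLC-PUFA retention-time library for
## the bovine-retina reference separation (20:4 through 36:6 plus the 21:5
## internal standard). m/z values are always computed from the label by the
## chemistry module; a separately packaged table of previously published m/z
## values serves as a validation fixture, not as the source of truth.

#' Default LC/VLC-PUFA target panel
#'
#' One row per target species: label, theoretical [M-H]- m/z (computed),
#' expected retention time (bovine-retina reference library, minutes), role
#' (`marker` or `internal_standard`) and response factor (1 by default).
#' Isomer pairs (e.g. "32:5 (1)"/"32:5 (2)") share one m/z but have distinct
#' expected RTs; species without an established RT (here 30:6, not detected
#' in the reference tissue) keep their theoretical m/z and an `NA` RT and are
#' skipped during peak matching.
#'
#' @return data.frame with columns `species_label`, `mz`, `expected_rt_min`,
#'   `role`, `response_factor`.
#' @export
#' @examples
#' head(default_panel())
default_panel <- function() {
  ref <- reference_mz_table()
  data.frame(
    species_label   = ref$species_label,
    mz              = vapply(ref$species_label,
                             function(l) mz_deprotonated(parse_species(l)),
                             numeric(1), USE.NAMES = FALSE),
    expected_rt_min = ref$rt_retina_min,
    role            = ref$role,
    response_factor = 1,
    stringsAsFactors = FALSE)
}

#' Published m/z and retention-time reference table
#'
#' The packaged copy of the published m/z / RT library used as a validation
#' fixture for the mass calculator (see [check_panel_masses()]). One row per
#' panel species; `mz_printed` is `NA` where the source table printed none
#' (the second 24:4 isomer shares the first's m/z).
#'
#' @return data.frame with columns `species_label`, `mz_printed`,
#'   `rt_standard_min`, `rt_retina_min`, `role`.
#' @export
reference_mz_table <- function() {
  path <- system.file("extdata", "reference_panel.tsv", package = "vlcpufa",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "numeric", "numeric",
                                   "numeric", "character"))
}

#' Read a target panel from TSV
#'
#' Expected columns: `species_label`, `expected_rt_min`,
#' `role` (`marker` | `internal_standard` | `other`), optional
#' `response_factor` (default 1). The theoretical m/z is computed from the
#' label.
#'
#' @param path Path to a tab-separated panel file.
#' @return data.frame as for [default_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_label", "expected_rt_min", "role")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("panel file missing column(s): ", paste(miss, collapse = ", "))
  ok <- p$role %in% c("marker", "internal_standard", "other")
  if (!all(ok))
    stop("unknown panel role(s): ", paste(unique(p$role[!ok]), collapse = ", "))
  if (is.null(p$response_factor)) p$response_factor <- 1
  p$mz <- vapply(p$species_label,
                 function(l) mz_deprotonated(parse_species(l)),
                 numeric(1), USE.NAMES = FALSE)
  p[, c("species_label", "mz", "expected_rt_min", "role", "response_factor")]
}

#' Check computed masses against the published reference table
#'
#' Compares the theoretical [M-H]- m/z of every panel species against the
#' packaged published value, after rounding the computed value to the
#' precision each reference value was printed with (the table mixes 3- and
#' 4-decimal entries).
#'
#' @param max_diff Maximum allowed absolute difference after rounding
#'   (default 0.001 Th).
#' @return data.frame with one row per species having a published m/z:
#'   `species_label`, `mz_printed`, `mz_computed`, `mz_rounded`, `diff`,
#'   `ok`. An attribute `"all_ok"` gives the overall verdict.
#' @export
#' @examples
#' all(check_panel_masses()$ok)
check_panel_masses <- function(max_diff = 0.001) {
  ref <- reference_mz_table()
  ref <- ref[!is.na(ref$mz_printed), ]
  computed <- vapply(ref$species_label,
                     function(l) mz_deprotonated(parse_species(l)),
                     numeric(1), USE.NAMES = FALSE)
  digits <- vapply(ref$mz_printed, .decimal_places, integer(1))
  rounded <- round(computed, digits)
  out <- data.frame(
    species_label = ref$species_label,
    mz_printed    = ref$mz_printed,
    mz_computed   = computed,
    mz_rounded    = rounded,
    diff          = rounded - ref$mz_printed,
    ok            = abs(rounded - ref$mz_printed) <= max_diff,
    stringsAsFactors = FALSE)
  attr(out, "all_ok") <- all(out$ok)
  out
}

## Number of decimals a value was printed with (from its shortest decimal
## representation).
.decimal_places <- function(x) {
  s <- format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  if (!grepl("\\.", s)) return(0L)
  nchar(strsplit(s, ".", fixed = TRUE)[[1]][2])
}

#' Default marker species for the phagocytosis read-out
#'
#' VLC-PUFAs absent from cultured RPE but abundant in POS, used as tracers of
#' internalized cargo.
#'
#' @return Character vector of species labels.
#' @export
default_markers <- function() c("32:6", "34:4", "34:5", "34:6", "36:6")
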