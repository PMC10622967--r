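## Fatty-acid chemistry: nomenclature, formulas, monoisotopic masses,
## deprotonated-ion m/z, fragment ladders, ppm windows.

## Monoisotopic masses (Da, CODATA/IUPAC), >= 6 decimals. The [M-H]- ion is
## computed as neutral monoisotopic mass minus the proton mass; removing an
## H atom and adding an electron gives the same value to within the electron
## binding energy (H - e = 1.00782503 - 0.00054858 = 1.00727645 ~ proton).
.fa_const <- list(
  C        = 12.0,
  H        = 1.00782503207,
  O        = 15.99491461956,
  proton   = 1.007276466879,
  electron = 0.000548579909,
  CO2      = 12.0 + 2 * 15.99491461956,
  CH2      = 12.0 + 2 * 1.00782503207
)

## Standard atomic weights (isotopic-mixture averages), for gram <-> mol
## conversion of weighed bulk material.
.fa_avg <- list(C = 12.011, H = 1.008, O = 15.999)

#' Monoisotopic mass constants
#'
#' Returns the elemental monoisotopic masses and derived neutral-loss masses
#' (CO2, CH2) used throughout the chemistry module, in Da.
#'
#' @return Named list with elements `C`, `H`, `O`, `proton`, `electron`,
#'   `CO2`, `CH2`.
#' @export
#' @examples
#' fa_mass_constants()$CH2  # 14.01565
fa_mass_constants <- function() .fa_const

#' Construct a fatty-acid species
#'
#' A free fatty acid is identified by its carbon count and number of double
#' bonds ("C:D" shorthand, e.g. "32:6"). Chromatographic isomers sharing one
#' formula are distinguished by an isomer tag ("(1)", "(2)"); the internal
#' standard carries an IS flag. The omega series (n-3 vs n-6) is not
#' resolvable by mass alone and is carried as annotation only.
#'
#' @param carbons Integer carbon count, >= 12.
#' @param double_bonds Integer double-bond count, >= 0 and <= carbons - 1.
#' @param isomer_tag Optional isomer suffix such as "(1)".
#' @param is_standard Logical; `TRUE` for the internal standard.
#' @param series Optional omega-series annotation (e.g. "n-3"); informational.
#' @return Object of class `fa_species`.
#' @export
#' @examples
#' fa_species(32, 6)
fa_species <- function(carbons, double_bonds, isomer_tag = NA_character_,
                       is_standard = FALSE, series = NA_character_) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  if (is.na(carbons) || carbons < 12)
    stop("carbon count must be an integer >= 12, got '", carbons, "'")
  if (is.na(double_bonds) || double_bonds < 0)
    stop("double-bond count must be a non-negative integer, got '",
         double_bonds, "'")
  ## CnH(2n-2d)O2 needs a positive hydrogen count: 2c - 2d >= 2
  if (double_bonds > carbons - 1L)
    stop("double-bond count ", double_bonds, " too large for ", carbons,
         " carbons (hydrogen count of CnH(2n-2d)O2 would be non-positive)")
  structure(
    list(carbons = carbons, double_bonds = double_bonds,
         isomer_tag = isomer_tag, is_standard = isTRUE(is_standard),
         series = series),
    class = "fa_species")
}

#' Parse a fatty-acid label
#'
#' Accepts "C:D" labels with an optional isomer suffix "(k)" or internal
#' standard marker "(IS)", e.g. `"32:6"`, `"22:5 (2)"`, `"21:5 (IS)"`.
#'
#' @param label Character scalar.
#' @return An `fa_species` object.
#' @export
#' @examples
#' parse_species("22:5 (2)")
parse_species <- function(label) {
  if (inherits(label, "fa_species")) return(label)
  if (!is.character(label) || length(label) != 1L || is.na(label))
    stop("species label must be a single character string")
  m <- regexec("^\\s*([0-9]+):([0-9]+)\\s*(?:\\(([0-9]+|IS)\\))?\\s*$", label)
  g <- regmatches(label, m)[[1]]
  if (length(g) == 0L)
    stop("malformed fatty-acid label '", label,
         "': expected \"C:D\" with optional \"(k)\" or \"(IS)\" suffix")
  carbons <- as.integer(g[2])
  db <- as.integer(g[3])
  tag <- g[4]
  is_std <- identical(tag, "IS")
  isomer <- if (nzchar(tag) && !is_std) paste0("(", tag, ")") else NA_character_
  fa_species(carbons, db, isomer_tag = isomer, is_standard = is_std)
}

#' Format a fatty-acid species as its label
#'
#' Inverse of [parse_species()]: `parse_species(format_species(x))` recovers
#' `x` (carbons, double bonds, isomer tag, IS flag).
#'
#' @param x An `fa_species` object.
#' @return Character label such as `"22:5 (2)"` or `"21:5 (IS)"`.
#' @export
format_species <- function(x) {
  stopifnot(inherits(x, "fa_species"))
  lab <- paste0(x$carbons, ":", x$double_bonds)
  if (!is.na(x$isomer_tag)) lab <- paste(lab, x$isomer_tag)
  if (x$is_standard) lab <- paste(lab, "(IS)")
  lab
}

#' @export
print.fa_species <- function(x, ...) {
  cat("<fa_species>", format_species(x),
      sprintf("(%s, [M-H]- %.4f Th)\n", paste0(fa_formula_string(x)),
              mz_deprotonated(x)))
  invisible(x)
}

.as_species <- function(x) {
  if (inherits(x, "fa_species")) x else parse_species(x)
}

#' Elemental composition of a free fatty acid
#'
#' A fatty acid C:D has formula CnH(2n-2d)O2.
#'
#' @param x An `fa_species` or a label accepted by [parse_species()].
#' @return Named integer vector with elements `C`, `H`, `O`.
#' @export
#' @examples
#' fa_formula("22:6")  # C22 H32 O2
fa_formula <- function(x) {
  s <- .as_species(x)
  c(C = s$carbons, H = 2L * s$carbons - 2L * s$double_bonds, O = 2L)
}

#' @rdname fa_formula
#' @export
fa_formula_string <- function(x) {
  f <- fa_formula(x)
  sprintf("C%dH%dO%d", f["C"], f["H"], f["O"])
}

#' Neutral monoisotopic mass of a fatty acid
#'
#' @inheritParams fa_formula
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(x) {
  f <- fa_formula(x)
  unname(f["C"] * .fa_const$C + f["H"] * .fa_const$H + f["O"] * .fa_const$O)
}

#' Molar mass of a fatty acid
#'
#' The average molar mass (standard atomic weights) is appropriate for
#' converting a weighed bulk amount (an isotopic mixture) to moles, e.g. the
#' spiked internal standard; the monoisotopic variant matches the mass
#' spectrometer's m/z axis.
#'
#' @inheritParams fa_formula
#' @param type `"average"` (default) or `"monoisotopic"`.
#' @return Molar mass in g/mol.
#' @export
#' @examples
#' molar_mass("21:5")  # ~316.5 g/mol
molar_mass <- function(x, type = c("average", "monoisotopic")) {
  type <- match.arg(type)
  f <- fa_formula(x)
  if (type == "monoisotopic") return(monoisotopic_mass(x))
  unname(f["C"] * .fa_avg$C + f["H"] * .fa_avg$H + f["O"] * .fa_avg$O)
}

#' Moles of internal standard from a weighed mass
#'
#' @param mass_g Weighed mass in grams (e.g. `1e-6` for 1 ug).
#' @param species Species label or `fa_species`; default the 21:5 internal
#'   standard.
#' @param type Molar-mass convention passed to [molar_mass()].
#' @return Amount in mol.
#' @export
#' @examples
#' is_amount_from_mass(1e-6)  # 1 ug of 21:5 -> ~3.16e-9 mol
is_amount_from_mass <- function(mass_g, species = "21:5",
                                type = c("average", "monoisotopic")) {
  stopifnot(is.numeric(mass_g), mass_g > 0)
  mass_g / molar_mass(species, match.arg(type))
}

#' Deprotonated-ion m/z of a fatty acid
#'
#' m/z of the [M-H]- ion observed in negative-mode electrospray: neutral
#' monoisotopic mass minus the proton mass. Isomers sharing C:D share this
#' value; they are separated chromatographically, not by mass.
#'
#' @inheritParams fa_formula
#' @return m/z in Th.
#' @export
#' @examples
#' mz_deprotonated("32:6")  # 467.3895
mz_deprotonated <- function(x) {
  monoisotopic_mass(x) - .fa_const$proton
}

#' Predicted fragment m/z in the decarboxylation / CH2-loss ladder
#'
#' Collision-induced dissociation of a fatty-acid [M-H]- ion first loses CO2
#' (44 Da, the decarboxylation product at `n_ch2_losses = 0`); at higher
#' collision energy successive losses of CH2 (14 Da) produce a ladder of
#' fragments spaced by the CH2 mass.
#'
#' @inheritParams fa_formula
#' @param n_ch2_losses Number of CH2 losses after decarboxylation (>= 0).
#' @return Fragment m/z in Th.
#' @export
#' @examples
#' fragment_mz("32:6")      # ~423.40, loss of CO2 from 467.3895
#' fragment_mz("32:6", 2)   # two further CH2 losses
fragment_mz <- function(x, n_ch2_losses = 0L) {
  s <- .as_species(x)
  n_ch2_losses <- as.integer(n_ch2_losses)
  if (is.na(n_ch2_losses) || n_ch2_losses < 0L)
    stop("n_ch2_losses must be a non-negative integer")
  ## carbons retained: one lost as CO2, one per CH2 loss
  if (s$carbons - 1L - n_ch2_losses < 2L)
    stop("fragment would retain fewer than 2 carbons")
  mz <- mz_deprotonated(s) - .fa_const$CO2 - n_ch2_losses * .fa_const$CH2
  if (mz < 50)
    stop("fragment m/z ", round(mz, 4), " below instrument range (50 Th)")
  mz
}

#' Symmetric ppm tolerance window around an m/z value
#'
#' @param mz m/z in Th, > 0. Vectorized.
#' @param tolerance_ppm Tolerance in parts per million, >= 0.
#' @return For scalar input, numeric `c(low, high)`; for vector input a
#'   two-column matrix.
#' @export
#' @examples
#' ppm_window(467.3895, 5)
ppm_window <- function(mz, tolerance_ppm) {
  if (!is.numeric(mz) || any(mz <= 0)) stop("mz must be positive")
  if (!is.numeric(tolerance_ppm) || length(tolerance_ppm) != 1L ||
      is.na(tolerance_ppm) || tolerance_ppm < 0)
    stop("tolerance_ppm must be a single non-negative number")
  lo <- mz * (1 - tolerance_ppm * 1e-6)
  hi <- mz * (1 + tolerance_ppm * 1e-6)
  if (length(mz) == 1L) c(low = lo, high = hi)
  else cbind(low = lo, high = hi)
}
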