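#' Parse a molecular formula string
#'
#' Parses a Hill-style formula such as `"C15H9Br4O4S"` into a named count
#' vector. Counts may be multi-digit; an omitted count means 1. Repeated
#' element symbols are summed. Only elements present in the pinned atomic
#' mass table (C, H, N, O, S, Br) are accepted.
#'
#' @param text A single formula string.
#' @param table Atomic mass table (defines the allowed element symbols).
#' @return A `mol_formula` object: named integer vector of element counts.
#' @examples
#' parse_formula("C15H9Br4O4S")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text, table = atomic_mass_table()) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (paste(tokens, collapse = "") != text)
    stop("cannot parse formula: '", text, "'")
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- sub("^[A-Za-z]+", "", tokens)
  cnts <- ifelse(nzchar(cnts), as.integer(cnts), 1L)
  known <- unique(table$isotopes$element)
  bad <- setdiff(syms, known)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  counts <- tapply(cnts, syms, sum)
  mol_formula(stats::setNames(as.integer(counts), names(counts)))
}

#' Construct a molecular formula from element counts
#'
#' @param counts Named integer vector (element symbol -> count >= 0).
#' @return A `mol_formula` object with zero counts dropped.
#' @export
mol_formula <- function(counts) {
  stopifnot(!is.null(names(counts)), all(nzchar(names(counts))))
  counts <- counts[counts != 0]
  if (!length(counts)) stop("formula must contain at least one atom")
  if (any(counts < 0)) stop("element counts must be non-negative")
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[hill_order(names(counts))]
  structure(counts, class = "mol_formula")
}

## Hill convention ordering: C first, then H, then the rest alphabetically
## (all alphabetical when no carbon).
hill_order <- function(elements) {
  if ("C" %in% elements) {
    rest <- sort(setdiff(elements, c("C", "H")))
    c("C", intersect("H", elements), rest)
  } else sort(elements)
}

#' Format a molecular formula in Hill order
#'
#' @param x A `mol_formula` object.
#' @return A single character string, e.g. `"C15H9Br4O4S"`.
#' @export
format_formula <- function(x) {
  stopifnot(inherits(x, "mol_formula"))
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}

#' Define an ion species (adduct, charge, heavy-isotope substitutions)
#'
#' Builds the charged, adduct-adjusted form of a neutral molecule, optionally
#' with a fixed number of heavy-isotope substitutions. The workhorse case in
#' negative-mode screening of brominated phenols is the deprotonated anion
#' `[M-H]-` with a chosen number of 81Br atoms: e.g. the quantifier ion of
#' TBBPS-MAE is the two-81Br isotopologue of `[C15H10Br4O4S - H]-`.
#'
#' @param neutral Neutral molecule: a `mol_formula` or formula string.
#' @param adduct One of `"M-H"` (deprotonation, default charge -1), `"M+H"`
#'   (protonation, default charge +1) or `"M"` (intact charged species,
#'   `charge` required, e.g. `Br-`).
#' @param charge Signed integer charge; defaults to the adduct's natural
#'   charge. Must be non-zero.
#' @param substitutions Named integer vector of heavy-isotope substitutions,
#'   e.g. `c("81Br" = 2)` replaces two 79Br with 81Br. Counts may not exceed
#'   the element's count in the *ion* formula.
#' @param table Atomic mass table.
#' @return An `ion_species` object (list with `ion` formula, `neutral`,
#'   `adduct`, `charge`, `substitutions`).
#' @examples
#' ion_species("C15H10Br4O4S", "M-H", substitutions = c("81Br" = 2))
#' ion_species("Br", "M", charge = -1)
#' @export
ion_species <- function(neutral, adduct = c("M-H", "M+H", "M"),
                        charge = NULL, substitutions = integer(),
                        table = atomic_mass_table()) {
  if (is.character(neutral)) neutral <- parse_formula(neutral, table)
  stopifnot(inherits(neutral, "mol_formula"))
  adduct <- match.arg(adduct)
  ion <- unclass(neutral)
  if (adduct == "M-H") {
    if (is.null(charge)) charge <- -1L
    if (is.na(ion["H"]) || ion["H"] < 1L)
      stop("cannot deprotonate a molecule without hydrogen")
    ion["H"] <- ion["H"] - 1L
  } else if (adduct == "M+H") {
    if (is.null(charge)) charge <- 1L
    ion["H"] <- if (is.na(ion["H"])) 1L else ion["H"] + 1L
  } else {
    if (is.null(charge)) stop("adduct 'M' requires an explicit charge")
  }
  charge <- as.integer(charge)
  if (charge == 0L) stop("charge must be non-zero")
  ion <- mol_formula(ion[ion != 0])
  if (length(substitutions)) {
    if (is.null(names(substitutions))) stop("substitutions must be named by isotope label")
    for (lab in names(substitutions)) {
      el <- sub("^[0-9]+", "", lab)
      if (!lab %in% table$isotopes$isotope) stop("unknown isotope label: ", lab)
      have <- if (el %in% names(ion)) ion[[el]] else 0L
      if (substitutions[[lab]] < 0 || substitutions[[lab]] > have)
        stop("substitution count for ", lab, " exceeds ", el,
             " count in ion formula (", have, ")")
    }
  }
  structure(list(ion = ion, neutral = neutral, adduct = adduct,
                 charge = charge,
                 substitutions = stats::setNames(as.integer(substitutions),
                                                 names(substitutions))),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  z <- x$charge
  zs <- paste0(if (abs(z) > 1) abs(z), if (z < 0) "-" else "+")
  cat("<ion> [", format_formula(x$ion), "]", zs, sep = "")
  if (length(x$substitutions))
    cat("  subs:", paste(names(x$substitutions), x$substitutions,
                         sep = "x", collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Exact m/z of an ion species
#'
#' Sums the pinned exact isotope masses of the ion formula (principal
#' isotopes, with the stated heavy-isotope substitutions), applies the
#' electron-mass correction (`- charge * m_e`, i.e. anions gain electrons)
#' and divides by the absolute charge. This is the same first-principles
#' calculation that vendor software performs; it reproduces published
#' Orbitrap values such as 604.69196 for the two-81Br `[M-H]-` ion of
#' TBBPS-MAE to better than 1e-4 Da.
#'
#' @param ion An `ion_species`.
#' @param table Atomic mass table.
#' @return m/z in Da per unit charge (double).
#' @examples
#' ion_mz(ion_species("C15H10Br4O4S", "M-H", substitutions = c("81Br" = 2)))
#' ion_mz(ion_species("Br", "M", charge = -1))  # bromide, 78.91889
#' @export
ion_mz <- function(ion, table = atomic_mass_table()) {
  stopifnot(inherits(ion, "ion_species"))
  pm <- principal_masses(table)
  counts <- unclass(ion$ion)
  mass <- sum(pm[names(counts)] * counts)
  if (length(ion$substitutions)) {
    for (lab in names(ion$substitutions)) {
      el <- sub("^[0-9]+", "", lab)
      mass <- mass + ion$substitutions[[lab]] * (isotope_mass(lab, table) - pm[[el]])
    }
  }
  mass <- mass - ion$charge * table$electron_mass
  unname(mass / abs(ion$charge))
}

#' Mass error in parts per million
#'
#' `|observed - calculated| / calculated * 1e6`, the conventional accuracy
#' measure for high-resolution MS identification (the screening gate here
#' is 5 ppm). Always non-negative; the calculated (theoretical) value is
#' the denominator.
#'
#' @param observed Observed m/z (vectorized).
#' @param calculated Theoretical m/z (> 0, vectorized).
#' @return Absolute ppm error(s). Round to 2 decimals for reporting.
#' @examples
#' ppm_error(604.69189, 604.69196)  # 0.116 -> prints as 0.12
#' @export
ppm_error <- function(observed, calculated) {
  if (any(!is.finite(calculated)) || any(calculated <= 0))
    stop("calculated m/z must be positive")
  abs(observed - calculated) / calculated * 1e6
}
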