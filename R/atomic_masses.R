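## Internal cache shared across the package (mass table, isotope envelopes).
.brscreen_cache <- new.env(parent = emptyenv())

#' Pinned isotope mass and abundance table
#'
#' Loads the packaged table of exact isotope masses (Da) and natural
#' abundances used for all mass arithmetic and envelope prediction. The
#' table is pinned to a published compilation (AME2020 masses, IUPAC 2021
#' representative abundances, CODATA 2018 electron mass) so that computed
#' ion masses are reproducible to well below 1e-4 Da. Elements covered:
#' C, H, N, O, S, Br.
#'
#' @param path Optional path to an alternative CSV with columns
#'   `element`, `isotope`, `mass_da`, `abundance`. A row with
#'   `element == "e"` carries the electron mass. Defaults to the packaged
#'   table (cached after first load).
#' @return An object of class `amu_table`: a list with `isotopes`
#'   (data.frame), `electron_mass` (Da) and `version` (character tag).
#' @examples
#' tab <- atomic_mass_table()
#' tab$electron_mass
#' @export
atomic_mass_table <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0("amu_table", envir = .brscreen_cache)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "atomic_masses.csv",
                        package = "brscreen", mustWork = TRUE)
  }
  first <- readLines(path, n = 1L)
  version <- if (startsWith(first, "#")) sub("^#\\s*version:\\s*", "", first) else "unversioned"
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("element", "isotope", "mass_da", "abundance") %in% names(df)))
  if (any(df$mass_da <= 0) && !any(df$element == "e"))
    stop("isotope masses must be positive")
  e_row <- df$element == "e"
  if (!any(e_row)) stop("mass table must include an electron row (element 'e')")
  iso <- df[!e_row, , drop = FALSE]
  if (any(iso$mass_da <= 0)) stop("isotope masses must be positive")
  sums <- tapply(iso$abundance, iso$element, sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("isotope abundances must sum to 1 per element; offending: ",
         paste(names(sums)[abs(sums - 1) > 1e-6], collapse = ", "))
  ## order isotopes by mass within element; first = principal (monoisotopic)
  iso <- iso[order(iso$element, iso$mass_da), , drop = FALSE]
  rownames(iso) <- NULL
  obj <- structure(
    list(isotopes = iso,
         electron_mass = df$mass_da[e_row][1],
         version = version),
    class = "amu_table")
  if (identical(path, system.file("extdata", "atomic_masses.csv",
                                  package = "brscreen", mustWork = TRUE)))
    assign("amu_table", obj, envir = .brscreen_cache)
  obj
}

#' @export
print.amu_table <- function(x, ...) {
  cat("<atomic mass table> ", x$version, "\n", sep = "")
  cat("elements:", paste(unique(x$isotopes$element), collapse = " "), "\n")
  cat("electron mass:", format(x$electron_mass, digits = 12), "Da\n")
  invisible(x)
}

## Monoisotopic (principal = lightest) mass of each element, named vector.
principal_masses <- function(table) {
  iso <- table$isotopes
  firsts <- !duplicated(iso$element)
  stats::setNames(iso$mass_da[firsts], iso$element[firsts])
}

## Exact mass of a specific isotope label such as "81Br".
isotope_mass <- function(label, table) {
  i <- match(label, table$isotopes$isotope)
  if (is.na(i)) stop("unknown isotope label: ", label)
  table$isotopes$mass_da[i]
}

## Mass difference 81Br - 79Br, the spacing of bromine isotopologues.
br_delta <- function(table = atomic_mass_table()) {
  isotope_mass("81Br", table) - isotope_mass("79Br", table)
}
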