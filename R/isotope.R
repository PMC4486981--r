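#' Binomial bromine isotopologue envelope
#'
#' Bromine has two stable isotopes (79Br/81Br) of nearly equal abundance, so
#' an ion with `n_br` bromines shows `n_br + 1` isotopologue peaks spaced by
#' the 81Br-79Br mass difference (~1.99795 Da) with near-binomial
#' intensities. At equal abundance (`p81 = 0.5`) the pattern is exactly the
#' Pascal-triangle row: 1:4:6:4:1 for Br4, 1:5:10:10:5:1 for Br5,
#' 1:6:15:20:15:6:1 for Br6 — the signatures used to recognize brominated
#' compounds in full-scan HRMS.
#'
#' @param n_br Number of bromine atoms (>= 0).
#' @param base_mz m/z of the all-79Br (monoisotopic) peak.
#' @param p81 Probability (abundance) of 81Br; default natural abundance.
#' @param table Atomic mass table (for the isotope spacing).
#' @return An `isotope_envelope`: data.frame with columns `mz` and
#'   `rel_abundance` (max = 1), plus provenance attributes.
#' @examples
#' binomial_br_envelope(4, 600.69605, p81 = 0.5)
#' @export
binomial_br_envelope <- function(n_br, base_mz, p81 = NULL,
                                 table = atomic_mass_table()) {
  if (length(n_br) != 1L || n_br < 0 || n_br != round(n_br))
    stop("n_br must be a single non-negative integer")
  if (is.null(p81)) {
    iso <- table$isotopes
    p81 <- iso$abundance[iso$isotope == "81Br"]
  }
  stopifnot(p81 >= 0, p81 <= 1)
  k <- 0:n_br
  ab <- stats::dbinom(k, n_br, p81)
  new_envelope(base_mz + k * br_delta(table), ab / max(ab),
               provenance = "binomial_Br")
}

new_envelope <- function(mz, rel_abundance, provenance, resolution = NA_real_) {
  o <- order(mz)
  structure(data.frame(mz = mz[o], rel_abundance = rel_abundance[o]),
            provenance = provenance, resolution = resolution,
            class = c("isotope_envelope", "data.frame"))
}

## Exact isotope distribution of n atoms of one element: all multinomial
## compositions of n over the element's isotopes, with log-multinomial
## weights. Returns data.frame(mass, prob).
element_isotope_dist <- function(n, masses, probs, prune = 0) {
  k <- length(masses)
  if (n == 0L) return(data.frame(mass = 0, prob = 1))
  comp <- compositions_of(n, k)
  logw <- lgamma(n + 1) - rowSums(lgamma(comp + 1)) +
    comp %*% matrix(log(probs), ncol = 1)
  prob <- exp(as.vector(logw))
  mass <- as.vector(comp %*% matrix(masses, ncol = 1))
  keep <- prob >= prune * max(prob)
  data.frame(mass = mass[keep], prob = prob[keep])
}

## All compositions of n into k non-negative parts (rows sum to n).
compositions_of <- function(n, k) {
  if (k == 1L) return(matrix(n, 1, 1))
  out <- NULL
  for (i in 0:n) {
    sub <- compositions_of(n - i, k - 1L)
    out <- rbind(out, cbind(i, sub))
  }
  unname(out)
}

## Convolve two (mass, prob) distributions, pruning and aggregating masses
## that coincide to < 1e-9 Da.
convolve_dists <- function(a, b, prune) {
  mass <- outer(a$mass, b$mass, `+`)
  prob <- outer(a$prob, b$prob, `*`)
  d <- data.frame(mass = as.vector(mass), prob = as.vector(prob))
  d <- d[order(d$mass), , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(d$mass) > 1e-9))
  d <- data.frame(mass = tapply(d$mass * d$prob, grp, sum) / tapply(d$prob, grp, sum),
                  prob = as.vector(tapply(d$prob, grp, sum)))
  d[d$prob >= prune * max(d$prob), , drop = FALSE]
}

#' Full fine-structure isotope envelope of an ion
#'
#' Exact multinomial expansion over every element's isotopes (13C, 2H,
#' 15N, 17O/18O, 33S/34S/36S, 79Br/81Br), convolved element by element with
#' pruning, then merged into centroids at the stated resolving power:
#' peaks closer than the Gaussian FWHM (`m/z / resolution`) are combined by
#' abundance-weighted mean, emulating what an Orbitrap reports. At
#' resolving power 60000 the 13C x2 and 34S satellites collapse into the
#' bromine isotopologue centroids, which is why observed envelopes of
#' polybrominated ions look like the pure Br binomial pattern.
#'
#' @param ion An `ion_species` (isotope substitutions are ignored: the
#'   envelope describes the natural distribution of the ion formula).
#' @param table Atomic mass table.
#' @param prune Relative-abundance pruning threshold in (0, 1).
#' @param resolution Resolving power (FWHM-based) used for centroid merging.
#' @return An `isotope_envelope` (max rel_abundance = 1).
#' @examples
#' fine_structure_envelope(ion_species("C15H10Br4O4S", "M-H"))
#' @export
fine_structure_envelope <- function(ion, table = atomic_mass_table(),
                                    prune = 1e-4, resolution = 60000) {
  stopifnot(inherits(ion, "ion_species"))
  if (!(prune > 0 && prune < 1)) stop("prune must be in (0, 1)")
  if (resolution <= 0) stop("resolution must be positive")
  counts <- unclass(ion$ion)
  if (!length(counts)) stop("empty formula")
  iso <- table$isotopes
  dist <- data.frame(mass = 0, prob = 1)
  for (el in names(counts)) {
    rows <- iso[iso$element == el, , drop = FALSE]
    d <- element_isotope_dist(counts[[el]], rows$mass_da, rows$abundance, prune)
    dist <- convolve_dists(dist, d, prune)
  }
  mass <- dist$mass - ion$charge * table$electron_mass
  mz <- mass / abs(ion$charge)
  ## merge centroids closer than the FWHM at that m/z
  o <- order(mz)
  mz <- mz[o]; prob <- dist$prob[o]
  grp <- cumsum(c(TRUE, diff(mz) > mz[-length(mz)] / resolution))
  cmz <- tapply(mz * prob, grp, sum) / tapply(prob, grp, sum)
  cab <- as.vector(tapply(prob, grp, sum))
  keep <- cab >= prune * max(cab)
  new_envelope(as.vector(cmz)[keep], cab[keep] / max(cab),
               provenance = "fine_structure", resolution = resolution)
}

#' Score agreement between an observed peak cluster and a predicted envelope
#'
#' Greedy nearest-m/z pairing of predicted envelope peaks to observed
#' centroids within a ppm tolerance (most abundant predicted peaks first;
#' each observed peak used once). Both sides are normalized to their most
#' intense peak; the score is `1 - mean(|obs - pred| / pred)` over matched
#' peaks, clamped to [0, 1], and 0 when fewer than 2 predicted peaks are
#' matched (a single peak carries no isotope-pattern evidence).
#'
#' @param observed Observed cluster: data.frame/matrix with columns `mz`
#'   and `intensity` (non-empty).
#' @param predicted An `isotope_envelope`.
#' @param mz_tol_ppm Pairing tolerance in ppm (> 0).
#' @return List with `score` in [0, 1] and `matches`, a data.frame of
#'   per-peak pairings and relative-abundance deviations.
#' @export
envelope_match_score <- function(observed, predicted, mz_tol_ppm = 10) {
  observed <- as.data.frame(observed)
  stopifnot(nrow(observed) > 0, all(c("mz", "intensity") %in% names(observed)))
  stopifnot(inherits(predicted, "isotope_envelope"))
  if (mz_tol_ppm <= 0) stop("mz_tol_ppm must be positive")
  obs_rel <- observed$intensity / max(observed$intensity)
  used <- rep(FALSE, nrow(observed))
  ordp <- order(predicted$rel_abundance, decreasing = TRUE)
  match_rows <- lapply(ordp, function(i) {
    tol <- predicted$mz[i] * mz_tol_ppm * 1e-6
    d <- abs(observed$mz - predicted$mz[i])
    d[used] <- Inf
    j <- which.min(d)
    if (!length(j) || d[j] > tol) return(NULL)
    used[j] <<- TRUE
    data.frame(pred_mz = predicted$mz[i], pred_rel = predicted$rel_abundance[i],
               obs_mz = observed$mz[j], obs_rel = obs_rel[j],
               rel_dev = abs(obs_rel[j] - predicted$rel_abundance[i]) /
                 predicted$rel_abundance[i])
  })
  matches <- do.call(rbind, match_rows)
  if (is.null(matches) || nrow(matches) < 2)
    return(list(score = 0, matches = matches))
  list(score = max(0, min(1, 1 - mean(matches$rel_dev))), matches = matches)
}

#' Nearest-integer ratio string of an envelope
#'
#' Renders an envelope the way published tables print it, e.g.
#' `"1:4:6:4:1"`: abundances are scaled so the smallest peak is 1 and
#' rounded to the nearest integer.
#'
#' @param envelope An `isotope_envelope`.
#' @return A single character string.
#' @export
ratio_string <- function(envelope) {
  stopifnot(inherits(envelope, "isotope_envelope"))
  ab <- envelope$rel_abundance
  paste(round(ab / min(ab)), collapse = ":")
}

#' @export
print.isotope_envelope <- function(x, digits = 5, ...) {
  cat("<isotope envelope> ", attr(x, "provenance"),
      ", ", nrow(x), " peaks, pattern ", ratio_string(x), "\n", sep = "")
  print.data.frame(round(as.data.frame(x), digits), ...)
  invisible(x)
}
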