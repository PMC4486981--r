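#' Define a screening target
#'
#' A target compound for accurate-mass suspect screening: neutral formula,
#' adduct, quantifier and qualifier isotopologue m/z, expected retention
#' time and bromine count. The quantifier is the most abundant
#' isotopologue (used for peak area); the qualifier is a second
#' isotopologue whose co-elution and abundance ratio confirm identity.
#'
#' @param name Compound name.
#' @param neutral_formula Neutral formula (string or `mol_formula`).
#' @param quantifier_mz,qualifier_mz Distinct isotopologue m/z values (Da);
#'   both must lie inside the compound's predicted envelope.
#' @param expected_rt Expected retention time (minutes).
#' @param n_br Number of bromine atoms.
#' @param adduct Adduct (default deprotonation, `"M-H"`).
#' @param table Atomic mass table.
#' @return A `target_compound` object.
#' @export
target_compound <- function(name, neutral_formula, quantifier_mz,
                            qualifier_mz, expected_rt, n_br,
                            adduct = "M-H", table = atomic_mass_table()) {
  if (is.character(neutral_formula))
    neutral_formula <- parse_formula(neutral_formula, table)
  if (quantifier_mz == qualifier_mz)
    stop("quantifier and qualifier m/z must differ")
  env <- compound_envelope(neutral_formula, adduct, table)
  for (mz in c(quantifier_mz, qualifier_mz))
    if (min(abs(env$mz - mz)) / mz * 1e6 > 20)
      stop("ion m/z ", mz, " is not within the predicted envelope of ",
           format_formula(neutral_formula))
  structure(list(name = name, neutral_formula = neutral_formula,
                 adduct = adduct, quantifier_mz = quantifier_mz,
                 qualifier_mz = qualifier_mz, expected_rt = expected_rt,
                 n_br = as.integer(n_br)),
            class = "target_compound")
}

## Cached fine-structure envelope per (formula, adduct).
compound_envelope <- function(neutral_formula, adduct = "M-H",
                              table = atomic_mass_table()) {
  key <- paste0("env:", format_formula(neutral_formula), ":", adduct)
  cached <- get0(key, envir = .brscreen_cache)
  if (!is.null(cached)) return(cached)
  env <- fine_structure_envelope(ion_species(neutral_formula, adduct,
                                             table = table), table)
  assign(key, env, envir = .brscreen_cache)
  env
}

#' Built-in targets: the three TBBPS-BDBPE byproducts
#'
#' The mono-modified byproducts of tetrabromobisphenol-S
#' bis(2,3-dibromopropyl ether): TBBPS mono(allyl ether) (MAE, Br4),
#' TBBPS mono(2-bromoallyl ether) (MBAE, Br5) and TBBPS
#' mono(2,3-dibromopropyl ether) (MDBPE, Br6), screened as `[M-H]-` anions
#' with their published quantifier/qualifier isotopologues and retention
#' times (4.20, 4.56, 4.80 min).
#'
#' @return A named list of `target_compound` objects.
#' @export
tbbps_targets <- function() {
  list(
    "TBBPS-MAE" = target_compound(
      "TBBPS-MAE", "C15H10Br4O4S",
      quantifier_mz = 604.69189, qualifier_mz = 602.69415,
      expected_rt = 4.20, n_br = 4),
    "TBBPS-MBAE" = target_compound(
      "TBBPS-MBAE", "C15H9Br5O4S",
      quantifier_mz = 682.60248, qualifier_mz = 684.60022,
      expected_rt = 4.56, n_br = 5),
    "TBBPS-MDBPE" = target_compound(
      "TBBPS-MDBPE", "C15H10Br6O4S",
      quantifier_mz = 764.52643, qualifier_mz = 762.52856,
      expected_rt = 4.80, n_br = 6))
}

## Theoretical m/z of the envelope peak nearest a stated ion m/z.
nearest_envelope_mz <- function(env, mz) env$mz[which.min(abs(env$mz - mz))]

#' Targeted identification of a compound in a run
#'
#' Applies the full HRMS identification rule: the compound is detected iff
#' (1) a quantifier-ion peak with S/N >= 3 is found at
#' `expected_rt +/- rt_tol`, (2) its observed m/z is within `mz_tol_ppm` of
#' the theoretical isotopologue m/z, (3) a qualifier-ion peak co-elutes
#' (apex within `rt_tol / 2` of the quantifier apex), and (4) the observed
#' qualifier/quantifier area ratio is within `ratio_tol` (relative) of the
#' ratio predicted by the fine-structure envelope. Every failed criterion
#' is recorded in `flags`, so rejected identifications are auditable.
#'
#' @param run A `centroid_run`.
#' @param target A `target_compound`.
#' @param mz_tol_ppm Mass tolerance (ppm, default 5).
#' @param rt_tol Retention-time tolerance (minutes, default 0.10).
#' @param ratio_tol Relative ion-ratio tolerance (default 0.20).
#' @param table Atomic mass table.
#' @return A `detection_result`: list with `compound`, `detected`,
#'   `apex_rt`, `quantifier_area`, `qualifier_area`, `ion_ratio`,
#'   `predicted_ratio`, `envelope_score`, `mass_error_ppm`, `flags`.
#' @export
identify_target <- function(run, target, mz_tol_ppm = 5, rt_tol = 0.10,
                            ratio_tol = 0.20, table = atomic_mass_table()) {
  stopifnot(inherits(run, "centroid_run"), inherits(target, "target_compound"))
  if (mz_tol_ppm <= 0 || rt_tol <= 0 || ratio_tol <= 0)
    stop("tolerances must be positive")
  if (!length(run$scans)) stop("run has no scans")
  env <- compound_envelope(target$neutral_formula, target$adduct, table)
  theo_q <- nearest_envelope_mz(env, target$quantifier_mz)
  theo_l <- nearest_envelope_mz(env, target$qualifier_mz)
  pred_ratio <- env$rel_abundance[which.min(abs(env$mz - theo_l))] /
    env$rel_abundance[which.min(abs(env$mz - theo_q))]
  flags <- character()
  res <- list(compound = target$name, detected = FALSE, apex_rt = NA_real_,
              quantifier_area = 0, qualifier_area = 0, ion_ratio = NA_real_,
              predicted_ratio = pred_ratio, envelope_score = NA_real_,
              mass_error_ppm = NA_real_, flags = character())

  eic_q <- extract_eic(run, target$quantifier_mz, mz_tol_ppm)
  pk_q <- integrate_peak(eic_q, target$expected_rt, rt_tol)
  if (is.null(pk_q)) {
    res$flags <- "no quantifier peak"
    return(structure(res, class = "detection_result"))
  }
  res$apex_rt <- pk_q$apex_rt
  res$quantifier_area <- pk_q$area

  ## observed m/z: intensity-weighted mean of centroids near the target in
  ## the apex scan, compared against the theoretical isotopologue m/z
  apx <- which.min(abs(vapply(run$scans, `[[`, numeric(1), "rt") - pk_q$apex_rt))
  s <- run$scans[[apx]]
  near <- abs(s$mz - target$quantifier_mz) <=
    target$quantifier_mz * mz_tol_ppm * 1e-6
  obs_mz <- if (any(near)) sum(s$mz[near] * s$intensity[near]) /
    sum(s$intensity[near]) else NA_real_
  res$mass_error_ppm <- if (is.na(obs_mz)) NA_real_ else ppm_error(obs_mz, theo_q)
  if (is.na(res$mass_error_ppm) || res$mass_error_ppm > mz_tol_ppm)
    flags <- c(flags, "mass error")

  eic_l <- extract_eic(run, target$qualifier_mz, mz_tol_ppm)
  pk_l <- integrate_peak(eic_l, target$expected_rt, rt_tol)
  if (is.null(pk_l) || abs(pk_l$apex_rt - pk_q$apex_rt) > rt_tol / 2) {
    flags <- c(flags, "qualifier co-elution")
  } else {
    res$qualifier_area <- pk_l$area
    res$ion_ratio <- pk_l$area / pk_q$area
    if (abs(res$ion_ratio - pred_ratio) / pred_ratio > ratio_tol)
      flags <- c(flags, "ion ratio")
  }
  ## informative envelope score from the apex scan cluster
  win <- abs(s$mz - theo_q) <= 1.2 * target$n_br * br_delta(table)
  if (sum(win) >= 2)
    res$envelope_score <- envelope_match_score(
      data.frame(mz = s$mz[win], intensity = s$intensity[win]), env,
      mz_tol_ppm = mz_tol_ppm)$score
  res$flags <- flags
  res$detected <- length(flags) == 0
  structure(res, class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat("<detection> ", x$compound, ": ",
      if (x$detected) "DETECTED" else "not detected", sep = "")
  if (!is.na(x$apex_rt))
    cat(sprintf(" (RT %.2f min, area %.4g, ratio %.3f, dppm %.2f)",
                x$apex_rt, x$quantifier_area, x$ion_ratio, x$mass_error_ppm))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "))
  cat("\n")
  invisible(x)
}

#' Untargeted discovery of bromine-containing unknowns
#'
#' Scans each spectrum for clusters of centroids spaced by the
#' 81Br-79Br mass difference (~1.99795 Da) — the diagnostic signature of
#' polybrominated ions — then infers the bromine count by least-squares
#' fit of the normalized cluster intensities against binomial envelopes
#' for candidate counts bracketing the cluster size (tolerating one
#' missing edge peak). Clusters whose intensity pattern deviates from the
#' best binomial fit by more than `fit_tol` (mean absolute deviation of
#' sum-normalized intensities) are rejected, which keeps halogen-free
#' spectra free of false hits. Hits are deduplicated across adjacent scans
#' by monoisotopic m/z and retention-time proximity, keeping the most
#' intense occurrence.
#'
#' @param run A `centroid_run`.
#' @param min_n_br Minimum inferred bromine count to report (>= 1).
#' @param spacing_tol_da Allowed deviation from the Br spacing (Da).
#' @param intensity_floor Minimum apex centroid intensity of a cluster.
#' @param fit_tol Binomial-pattern gate (mean abs deviation, default 0.15).
#' @param decompose_bounds Optional named element bounds; when supplied,
#'   each hit's monoisotopic m/z is decomposed into candidate formulas via
#'   [decompose_formula()].
#' @param tol_ppm ppm tolerance for the optional formula decomposition.
#' @param table Atomic mass table.
#' @return A list of `unknown_br_hit` objects (possibly empty), each with
#'   `apex_rt`, `cluster` (data.frame mz/intensity), `inferred_n_br`,
#'   `mono_mz` (estimated all-79Br m/z) and `candidate_formulas`.
#' @export
discover_br_unknowns <- function(run, min_n_br = 1, spacing_tol_da = 0.01,
                                 intensity_floor = 0, fit_tol = 0.15,
                                 decompose_bounds = NULL, tol_ppm = 5,
                                 table = atomic_mass_table()) {
  stopifnot(inherits(run, "centroid_run"))
  if (min_n_br < 1) stop("min_n_br must be >= 1")
  delta <- br_delta(table)
  iso <- table$isotopes
  p81 <- iso$abundance[iso$isotope == "81Br"]
  hits <- list()
  for (s in run$scans) {
    if (length(s$mz) < 2) next
    o <- order(s$mz)
    mz <- s$mz[o]; int <- s$intensity[o]
    used <- rep(FALSE, length(mz))
    for (start in seq_along(mz)) {
      if (used[start]) next
      chain <- start
      repeat {
        nxt_target <- mz[chain[length(chain)]] + delta
        cand <- which(!used & abs(mz - nxt_target) <= spacing_tol_da)
        if (!length(cand)) break
        nxt <- cand[which.max(int[cand])]
        chain <- c(chain, nxt)
        used[nxt] <- TRUE
      }
      if (length(chain) < 2) next
      used[chain] <- TRUE
      if (max(int[chain]) < intensity_floor) next
      fit <- fit_br_count(int[chain], min_n_br, p81)
      if (is.null(fit) || fit$mad > fit_tol) next
      hits[[length(hits) + 1L]] <- list(
        apex_rt = s$rt,
        cluster = data.frame(mz = mz[chain], intensity = int[chain]),
        inferred_n_br = fit$n_br,
        mono_mz = mz[chain[1]] - fit$offset * delta,
        max_intensity = max(int[chain]))
    }
  }
  hits <- dedupe_hits(hits)
  if (!is.null(decompose_bounds)) {
    hits <- lapply(hits, function(h) {
      h$candidate_formulas <- decompose_formula(
        h$mono_mz, charge = -1L, tol_ppm = tol_ppm,
        bounds = decompose_bounds, table = table)
      h
    })
  }
  lapply(hits, function(h) structure(h, class = "unknown_br_hit"))
}

## Least-squares fit of a cluster's intensities to binomial Br envelopes
## with n_br in [size-1, size+1]; returns best n_br, alignment offset and
## mean absolute deviation of sum-normalized intensities.
fit_br_count <- function(intensities, min_n_br, p81) {
  size <- length(intensities)
  obs <- intensities / sum(intensities)
  best <- NULL
  for (n in max(min_n_br, size - 1L):(size + 1L)) {
    pred_full <- stats::dbinom(0:n, n, p81)
    for (off in 0:(n + 1L - size)) {
      pred <- pred_full[(off + 1L):(off + size)]
      pred <- pred / sum(pred)
      mad <- mean(abs(obs - pred))
      if (is.null(best) || mad < best$mad)
        best <- list(n_br = n, offset = off, mad = mad)
    }
  }
  best
}

dedupe_hits <- function(hits) {
  if (length(hits) <= 1) return(hits)
  mono <- vapply(hits, `[[`, numeric(1), "mono_mz")
  rt <- vapply(hits, `[[`, numeric(1), "apex_rt")
  keep <- rep(TRUE, length(hits))
  o <- order(-vapply(hits, `[[`, numeric(1), "max_intensity"))
  for (i in o) {
    if (!keep[i]) next
    dup <- keep & abs(mono - mono[i]) < 0.02 & abs(rt - rt[i]) <= 0.2
    dup[i] <- FALSE
    keep[dup] <- FALSE
  }
  hits[keep]
}

#' @export
print.unknown_br_hit <- function(x, ...) {
  cat(sprintf("<Br unknown> RT %.2f min, %d peaks, inferred n(Br) = %d, mono m/z %.5f\n",
              x$apex_rt, nrow(x$cluster), x$inferred_n_br, x$mono_mz))
  invisible(x)
}

#' Decompose an accurate mass into candidate elemental formulas
#'
#' Exhaustive search over C/H/N/O/S/Br compositions within per-element
#' bounds for ion formulas whose exact m/z (with electron-mass correction)
#' matches the observed value within a ppm tolerance. Candidates are
#' filtered by ring-plus-double-bond equivalents computed on the
#' (re)protonated neutral, `RDBE = C - (H + Br)/2 + N/2 + 1`, and ranked
#' by absolute ppm error. This is the "delta ppm < 5" formula assignment
#' used to attribute unknown bromine clusters to compositions such as
#' `[C6H2OBr3]-`.
#'
#' @param mz Observed m/z (Da) of the all-principal-isotope peak.
#' @param charge Ion charge (default -1; deprotonated anions).
#' @param tol_ppm Tolerance in ppm (>= 0).
#' @param bounds Named vector of per-element maximum counts over
#'   C, H, N, O, S, Br (missing elements default to 0).
#' @param rdbe_min Minimum RDBE of the neutral (default 0).
#' @param table Atomic mass table.
#' @return data.frame with columns `formula`, element counts, `mz_calc`,
#'   `ppm` and `rdbe`, ordered by `ppm` (possibly zero rows).
#' @export
decompose_formula <- function(mz, charge = -1L, tol_ppm = 5,
                              bounds = c(C = 20, H = 20, N = 2, O = 6,
                                         S = 2, Br = 8),
                              rdbe_min = 0, table = atomic_mass_table()) {
  if (!length(bounds) || all(bounds <= 0)) stop("bounds must allow at least one atom")
  if (any(!is.finite(bounds))) stop("bounds must be finite")
  if (tol_ppm < 0) stop("tol_ppm must be non-negative")
  els <- c("C", "H", "N", "O", "S", "Br")
  if (length(setdiff(names(bounds), els)))
    stop("bounds may only name C, H, N, O, S, Br")
  b <- stats::setNames(rep(0L, length(els)), els)
  b[names(bounds)] <- as.integer(bounds)
  pm <- principal_masses(table)
  grid <- expand.grid(C = 0:b["C"], H = 0:b["H"], N = 0:b["N"],
                      O = 0:b["O"], S = 0:b["S"], Br = 0:b["Br"],
                      KEEP.OUT.ATTRS = FALSE)
  mass <- as.matrix(grid) %*% pm[els]
  mz_calc <- (as.vector(mass) - charge * table$electron_mass) / abs(charge)
  ok <- mz_calc > 0 & abs(mz - mz_calc) / mz_calc * 1e6 <= tol_ppm &
    rowSums(grid) > 0
  grid <- grid[ok, , drop = FALSE]
  mz_calc <- mz_calc[ok]
  if (!nrow(grid)) return(empty_decomposition())
  ## RDBE on the neutral: deprotonated anions get |charge| protons back
  h_neutral <- grid$H + abs(charge) * (charge < 0) - abs(charge) * (charge > 0)
  rdbe <- grid$C - (h_neutral + grid$Br) / 2 + grid$N / 2 + 1
  ok <- rdbe >= rdbe_min
  grid <- grid[ok, , drop = FALSE]; mz_calc <- mz_calc[ok]; rdbe <- rdbe[ok]
  if (!nrow(grid)) return(empty_decomposition())
  ppm <- abs(mz - mz_calc) / mz_calc * 1e6
  formula <- apply(grid, 1, function(r) {
    r <- r[r > 0]
    format_formula(mol_formula(r))
  })
  out <- cbind(data.frame(formula = formula, stringsAsFactors = FALSE),
               grid, data.frame(mz_calc = mz_calc, ppm = ppm, rdbe = rdbe))
  out <- out[order(out$ppm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_decomposition <- function() {
  data.frame(formula = character(), C = integer(), H = integer(),
             N = integer(), O = integer(), S = integer(), Br = integer(),
             mz_calc = numeric(), ppm = numeric(), rdbe = numeric())
}

#' Bioaccumulation flag from partitioning properties
#'
#' A compound is flagged as bioaccumulative when both `log Kow > 5` and
#' `BCF > 5000` (strict inequalities) — the conventional screening rule
#' for persistent, bioaccumulative substances. Property values (e.g. EPI
#' Suite estimates) are consumed as inputs, never computed here.
#'
#' @param log_kow Octanol-water partition coefficient (log10).
#' @param bcf Bioconcentration factor (L/kg).
#' @return Logical (vectorized).
#' @examples
#' bioaccumulation_flag(7.01, 13200)  # TRUE  (TBBPS-MBAE)
#' bioaccumulation_flag(5.21, 1266)   # FALSE (TBBPS)
#' @export
bioaccumulation_flag <- function(log_kow, bcf) {
  stopifnot(all(is.finite(log_kow)), all(is.finite(bcf)))
  log_kow > 5 & bcf > 5000
}
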