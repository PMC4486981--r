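#' Fit an external-standard calibration curve
#'
#' Unweighted ordinary least squares `area = intercept + slope * conc` over
#' a dilution series (at least 5 distinct concentrations; the reference
#' workflow uses 7 points spanning 0.05-100 ng/mL). The curve is accepted
#' when the determination coefficient exceeds 0.99.
#'
#' @param points data.frame with columns `conc` (ng/mL) and `area`
#'   (counts), or a numeric concentration vector when `area` is given.
#' @param area Optional numeric area vector matching `points`.
#' @param compound Optional compound name carried in the result.
#' @return A `calibration_curve`: list with `compound`, `slope`,
#'   `intercept`, `r_squared`, `range`, `n_points`, `accepted`.
#' @examples
#' fit_calibration(data.frame(conc = c(0.05, 0.1, 0.5, 1, 5, 10, 100),
#'                            area = 304964 + 519149 * c(0.05, 0.1, 0.5, 1, 5, 10, 100)))
#' @export
fit_calibration <- function(points, area = NULL, compound = NA_character_) {
  if (!is.null(area)) points <- data.frame(conc = points, area = area)
  stopifnot(all(c("conc", "area") %in% names(points)))
  conc <- points$conc; area <- points$area
  if (length(unique(conc)) < 5)
    stop("calibration requires at least 5 distinct concentrations")
  if (stats::var(conc) == 0) stop("zero variance in concentrations")
  if (stats::var(area) == 0)
    stop("all areas equal: degenerate (zero-slope) calibration")
  fit <- stats::lm(area ~ conc)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((area - mean(area))^2)
  structure(list(compound = compound,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 range = range(conc),
                 n_points = length(conc),
                 accepted = r2 > 0.99),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration> %s: Y = %.6g + %.6g * X, R^2 = %.4f (%s), %d points over %g-%g ng/mL\n",
              if (is.na(x$compound)) "curve" else x$compound,
              x$intercept, x$slope, x$r_squared,
              if (x$accepted) "accepted" else "NOT accepted (R^2 <= 0.99)",
              x$n_points, x$range[1], x$range[2]))
  invisible(x)
}

#' Quantify a detection against a calibration curve
#'
#' Back-calculates the solution concentration
#' `(area - intercept) / slope` (ng/mL) and converts to a tissue
#' concentration `conc * extract_volume_mL / dry_mass_g` (ng/g dry
#' weight). Negative back-calculations are floored at 0 and flagged;
#' areas outside the calibration range are flagged as extrapolated.
#'
#' @param result A `detection_result` with `detected == TRUE`, or a bare
#'   numeric quantifier area.
#' @param curve A `calibration_curve` with positive slope.
#' @param extract_volume_mL Final extract volume (mL, default 1).
#' @param dry_mass_g Dry tissue mass (g).
#' @return A `quant_result`: list with `conc_ng_g`, `conc_solution_ng_mL`,
#'   `extrapolated`, `floored`.
#' @export
quantify <- function(result, curve, extract_volume_mL = 1, dry_mass_g) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be positive")
  if (inherits(result, "detection_result")) {
    if (!isTRUE(result$detected))
      stop("cannot quantify a non-detected result (", result$compound, ")")
    area <- result$quantifier_area
  } else {
    area <- result
  }
  stopifnot(is.numeric(area), length(area) == 1)
  if (dry_mass_g <= 0) stop("dry_mass_g must be positive")
  conc_sol <- (area - curve$intercept) / curve$slope
  floored <- conc_sol < 0
  if (floored) conc_sol <- 0
  extrapolated <- conc_sol < curve$range[1] || conc_sol > curve$range[2]
  structure(list(conc_ng_g = conc_sol * extract_volume_mL / dry_mass_g,
                 conc_solution_ng_mL = conc_sol,
                 extrapolated = extrapolated, floored = floored),
            class = "quant_result")
}

#' Spike recovery
#'
#' `100 * measured / spiked` per replicate, with mean and sample standard
#' deviation (n - 1) over replicates — the through-workflow accuracy
#' measure determined at several spiking amounts.
#'
#' @param measured_ng Measured amounts (ng), one per replicate.
#' @param spiked_ng Spiked amount(s) (ng, > 0; recycled).
#' @return List with `percent` (vector), `mean` and `sd` (percent).
#' @examples
#' recovery(8.5, 10)$percent  # 85
#' @export
recovery <- function(measured_ng, spiked_ng) {
  if (any(spiked_ng <= 0)) stop("spiked amount must be positive")
  pct <- 100 * measured_ng / spiked_ng
  list(percent = pct, mean = mean(pct),
       sd = if (length(pct) > 1) stats::sd(pct) else NA_real_)
}

#' Matrix effect
#'
#' Ratio of the analyte response in a post-extraction matrix spike to the
#' response of a solvent standard at equal concentration. A value of 1
#' means no effect; below 1 indicates ion suppression by the matrix.
#'
#' @param area_matrix_spike Area(s) in matrix (vectorized).
#' @param area_solvent_standard Area(s) in pure solvent (> 0).
#' @return Ratio(s).
#' @export
matrix_effect <- function(area_matrix_spike, area_solvent_standard) {
  if (any(area_solvent_standard <= 0))
    stop("solvent-standard area must be positive")
  area_matrix_spike / area_solvent_standard
}

#' Instrument detection limit from a replicate dilution series
#'
#' The IDL is the smallest injected on-column mass whose five replicate
#' injections all give a detected peak and whose signal relative standard
#' deviation is at most 20%.
#'
#' @param series data.frame with columns `mass_pg` (injected mass),
#'   `area` (signal) and optionally `detected` (logical; defaults to
#'   `area > 0`). At least 2 mass levels with 5 replicates each.
#' @param max_rsd Maximum relative SD (default 0.20).
#' @param n_replicates Required replicates per level (default 5).
#' @return List with `idl_pg` (numeric, `Inf` when no level qualifies),
#'   `above_highest` (logical) and `levels` (per-level summary).
#' @export
estimate_idl <- function(series, max_rsd = 0.20, n_replicates = 5) {
  stopifnot(all(c("mass_pg", "area") %in% names(series)))
  if (length(unique(series$mass_pg)) < 2)
    stop("IDL estimation requires at least 2 mass levels")
  if (is.null(series$detected)) series$detected <- series$area > 0
  lv <- lapply(split(series, series$mass_pg), function(d) {
    if (nrow(d) < n_replicates)
      stop("each mass level needs at least ", n_replicates, " replicates")
    rsd <- if (mean(d$area) > 0) stats::sd(d$area) / mean(d$area) else Inf
    data.frame(mass_pg = d$mass_pg[1], all_detected = all(d$detected),
               rsd = rsd, qualifies = all(d$detected) & rsd <= max_rsd)
  })
  levels <- do.call(rbind, lv)
  levels <- levels[order(levels$mass_pg), ]
  rownames(levels) <- NULL
  ok <- levels$mass_pg[levels$qualifies]
  list(idl_pg = if (length(ok)) min(ok) else Inf,
       above_highest = !length(ok), levels = levels)
}

#' Method detection limit from replicate spiked analyses
#'
#' `MDL = t(0.99, n - 1) * SD` of n replicate measured concentrations of a
#' matrix sample spiked near the detection limit (the HRMS convention; at
#' n = 10 the one-sided 99% Student-t quantile is 2.821).
#'
#' @param replicate_concs Measured concentrations (ng/g dw), n >= 7.
#' @param conf One-sided confidence level (default 0.99).
#' @return MDL in ng/g dw.
#' @examples
#' estimate_mdl(rep(0.5, 10))        # 0
#' @export
estimate_mdl <- function(replicate_concs, conf = 0.99) {
  n <- length(replicate_concs)
  if (n < 7) stop("MDL estimation requires at least 7 replicates")
  stats::qt(conf, df = n - 1) * stats::sd(replicate_concs)
}

#' Summarize quantified detections over a sample cohort
#'
#' A sample counts as a detection when the identification criteria passed
#' and the quantified concentration is at or above the compound's MDL.
#' Detection frequencies are reported in percent of all samples;
#' concentration range, mean and median are computed over detected
#' samples only (non-detects excluded, no MDL substitution).
#'
#' @param results data.frame with one row per sample x compound:
#'   columns `sample_id`, `compound`, `species`, `year`, `detected`
#'   (logical), `conc_ng_g`.
#' @param mdl Named numeric vector of MDLs (ng/g dw) per compound.
#' @return A `cohort_summary`: list with `by_compound` (frequency, range,
#'   mean, median, n), `by_species_year` breakdown and `n_samples`.
#' @export
summarize_cohort <- function(results, mdl) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  need <- c("sample_id", "compound", "species", "year", "detected", "conc_ng_g")
  if (!all(need %in% names(results)))
    stop("results must have columns: ", paste(need, collapse = ", "))
  if (is.null(names(mdl)) || !all(unique(results$compound) %in% names(mdl)))
    stop("mdl must be named and cover every compound")
  results$hit <- results$detected & !is.na(results$conc_ng_g) &
    results$conc_ng_g >= mdl[results$compound]
  by_comp <- lapply(split(results, results$compound), function(d) {
    det <- d$conc_ng_g[d$hit]
    data.frame(compound = d$compound[1],
               n_samples = nrow(d), n_detected = sum(d$hit),
               detection_frequency = 100 * sum(d$hit) / nrow(d),
               min = if (length(det)) min(det) else NA_real_,
               max = if (length(det)) max(det) else NA_real_,
               mean = if (length(det)) mean(det) else NA_real_,
               median = if (length(det)) stats::median(det) else NA_real_)
  })
  by_sy <- stats::aggregate(hit ~ compound + species + year, results, sum)
  names(by_sy)[names(by_sy) == "hit"] <- "n_detected"
  by_sy$n_samples <- stats::aggregate(hit ~ compound + species + year,
                                      results, length)$hit
  structure(list(by_compound = do.call(rbind, by_comp),
                 by_species_year = by_sy,
                 n_samples = length(unique(results$sample_id))),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort summary> ", x$n_samples, " samples\n", sep = "")
  df <- x$by_compound
  df$detection_frequency <- round(df$detection_frequency)
  print.data.frame(df, row.names = FALSE, digits = 3)
  invisible(x)
}
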