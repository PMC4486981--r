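#' Pipeline configuration
#'
#' The tolerance block and bookkeeping shared by all pipeline stages:
#' 5 ppm mass tolerance, 0.10 min retention-time tolerance and 20%
#' relative ion-ratio tolerance by default, plus the MDLs used for cohort
#' summaries and an optional seed. Round-trips through YAML via
#' [write_config()] / [read_config()].
#'
#' @param mz_tol_ppm Mass tolerance (ppm).
#' @param rt_tol_min Retention-time tolerance (minutes).
#' @param ratio_tol Relative ion-ratio tolerance.
#' @param mdl Named MDLs (ng/g dw) per compound.
#' @param seed Optional integer seed recorded in provenance.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mz_tol_ppm = 5, rt_tol_min = 0.10,
                            ratio_tol = 0.20,
                            mdl = c("TBBPS-MAE" = 0.04,
                                    "TBBPS-MBAE" = 0.08,
                                    "TBBPS-MDBPE" = 0.06),
                            seed = NULL) {
  stopifnot(mz_tol_ppm > 0, rt_tol_min > 0, ratio_tol > 0, all(mdl > 0))
  structure(list(mz_tol_ppm = mz_tol_ppm, rt_tol_min = rt_tol_min,
                 ratio_tol = ratio_tol, mdl = mdl, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(list(mz_tol_ppm = config$mz_tol_ppm,
                        rt_tol_min = config$rt_tol_min,
                        ratio_tol = config$ratio_tol,
                        mdl = as.list(config$mdl),
                        seed = config$seed), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(mz_tol_ppm = x$mz_tol_ppm, rt_tol_min = x$rt_tol_min,
                  ratio_tol = x$ratio_tol, mdl = unlist(x$mdl),
                  seed = x$seed)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  write_config(config, f)
  unname(tools::md5sum(f))
}

#' Run the screening-and-quantification pipeline over a batch of runs
#'
#' Orchestrates the full workflow: targeted identification of every target
#' in every run, external-standard quantification of detections, the
#' procedural-blank check (any target detected in a blank above its MDL
#' voids the batch) and a cohort summary over `cohort_sample` runs. The
#' report is deterministic given the same inputs and configuration and
#' carries a provenance block (config hash, mass-table version).
#'
#' @param runs List of `centroid_run` objects (standards, blanks, cohort
#'   samples; sample type is taken from each run's metadata).
#' @param targets List of `target_compound` (default the three TBBPS
#'   byproducts).
#' @param calibration Named list per compound: `calibration_curve` objects
#'   or data.frames of `(conc, area)` points to fit. A detected compound
#'   without a calibration entry is an error naming the compound.
#' @param config A `pipeline_config`.
#' @param table Atomic mass table.
#' @return A `pipeline_report`: list with `detections` (data.frame),
#'   `quantities` (data.frame), `cohort_summary` (or NULL), `batch_valid`,
#'   `blank_failures` and `provenance`.
#' @export
run_pipeline <- function(runs, targets = tbbps_targets(), calibration,
                         config = pipeline_config(),
                         table = atomic_mass_table()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!length(runs)) stop("no runs supplied")
  curves <- lapply(calibration, function(x)
    if (inherits(x, "calibration_curve")) x else fit_calibration(x))

  det_rows <- list(); quant_rows <- list()
  for (run in runs) {
    md <- run$metadata
    for (tc in targets) {
      r <- identify_target(run, tc, mz_tol_ppm = config$mz_tol_ppm,
                           rt_tol = config$rt_tol_min,
                           ratio_tol = config$ratio_tol, table = table)
      det_rows[[length(det_rows) + 1L]] <- data.frame(
        sample_id = md$sample_id, sample_type = md$sample_type,
        species = md$species, year = md$year, compound = tc$name,
        detected = r$detected, apex_rt = r$apex_rt,
        quantifier_area = r$quantifier_area,
        qualifier_area = r$qualifier_area, ion_ratio = r$ion_ratio,
        mass_error_ppm = r$mass_error_ppm,
        flags = paste(r$flags, collapse = "; "))
      if (r$detected) {
        if (is.null(curves[[tc$name]]))
          stop("missing calibration for detected compound: ", tc$name)
        q <- quantify(r, curves[[tc$name]],
                      extract_volume_mL = md$extract_volume_mL %||% 1,
                      dry_mass_g = if (is.na(md$dry_mass_g)) 1 else md$dry_mass_g)
        quant_rows[[length(quant_rows) + 1L]] <- data.frame(
          sample_id = md$sample_id, sample_type = md$sample_type,
          species = md$species, year = md$year, compound = tc$name,
          quantifier_area = r$quantifier_area,
          conc_solution_ng_mL = q$conc_solution_ng_mL,
          conc_ng_g = q$conc_ng_g, extrapolated = q$extrapolated,
          calibration_id = paste0(tc$name, "_curve"))
      }
    }
  }
  detections <- if (length(det_rows)) do.call(rbind, det_rows) else
    data.frame(sample_id = character(), sample_type = character(),
               species = character(), year = integer(),
               compound = character(), detected = logical(),
               apex_rt = numeric(), quantifier_area = numeric(),
               qualifier_area = numeric(), ion_ratio = numeric(),
               mass_error_ppm = numeric(), flags = character())
  quantities <- if (length(quant_rows)) do.call(rbind, quant_rows) else
    data.frame(sample_id = character(), sample_type = character(),
               species = character(), year = integer(),
               compound = character(), quantifier_area = numeric(),
               conc_solution_ng_mL = numeric(), conc_ng_g = numeric(),
               extrapolated = logical(), calibration_id = character())

  ## blank policy: a target quantified in a procedural blank above its MDL
  ## voids the batch
  blank_fail <- character()
  bq <- quantities[quantities$sample_type == "blank", , drop = FALSE]
  if (nrow(bq)) {
    over <- bq$conc_ng_g >= config$mdl[bq$compound]
    blank_fail <- unique(bq$compound[over])
  }

  cohort <- NULL
  cq <- detections[detections$sample_type == "cohort_sample", , drop = FALSE]
  if (nrow(cq)) {
    conc <- rep(NA_real_, nrow(cq))
    key <- paste(cq$sample_id, cq$compound)
    qkey <- paste(quantities$sample_id, quantities$compound)
    hit <- match(key, qkey)
    conc[!is.na(hit)] <- quantities$conc_ng_g[hit[!is.na(hit)]]
    cohort <- summarize_cohort(
      data.frame(sample_id = cq$sample_id, compound = cq$compound,
                 species = cq$species, year = cq$year,
                 detected = cq$detected, conc_ng_g = conc),
      mdl = config$mdl)
  }
  structure(list(detections = detections, quantities = quantities,
                 cohort_summary = cohort,
                 batch_valid = length(blank_fail) == 0,
                 blank_failures = blank_fail,
                 provenance = list(config_hash = config_hash(config),
                                   mass_table_version = table$version,
                                   n_runs = length(runs),
                                   seed = config$seed)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline report> ", x$provenance$n_runs, " runs, ",
      sum(x$detections$detected), " detections, batch ",
      if (x$batch_valid) "valid" else
        paste("VOID (blank contamination:",
              paste(x$blank_failures, collapse = ", "), ")"),
      "\n", sep = "")
  if (!is.null(x$cohort_summary)) print(x$cohort_summary)
  invisible(x)
}

#' Write a report bundle to CSV
#'
#' Writes `detections.csv`, `quantities.csv` and (when present)
#' `cohort_summary.csv` with the reporting precision used in published
#' tables: m/z to 5 decimals, ppm errors to 2 decimals, concentrations to
#' 1 decimal ng/g dw. Output is deterministic, so re-running the same
#' pipeline yields byte-identical files.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  det <- report$detections
  det$apex_rt <- round(det$apex_rt, 2)
  det$ion_ratio <- round(det$ion_ratio, 3)
  det$mass_error_ppm <- round(det$mass_error_ppm, 2)
  utils::write.csv(det, file.path(dir, "detections.csv"), row.names = FALSE)
  q <- report$quantities
  q$conc_solution_ng_mL <- round(q$conc_solution_ng_mL, 4)
  q$conc_ng_g <- round(q$conc_ng_g, 1)
  utils::write.csv(q, file.path(dir, "quantities.csv"), row.names = FALSE)
  if (!is.null(report$cohort_summary)) {
    s <- report$cohort_summary$by_compound
    s$detection_frequency <- round(s$detection_frequency)
    num <- vapply(s, is.numeric, logical(1))
    s[num] <- lapply(s[num], round, digits = 1)
    utils::write.csv(s, file.path(dir, "cohort_summary.csv"),
                     row.names = FALSE)
  }
  writeLines(c(paste0("config_hash: ", report$provenance$config_hash),
               paste0("mass_table_version: ", report$provenance$mass_table_version),
               paste0("n_runs: ", report$provenance$n_runs)),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}
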