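#' Construct a centroided run
#'
#' The in-memory container for a centroided full-scan acquisition: an
#' ordered list of scans, each a retention time (minutes) plus centroid
#' `mz`/`intensity` vectors, together with sample metadata used downstream
#' (sample type, dry mass, extract volume).
#'
#' @param scans List of scans, each a list with elements `rt` (minutes),
#'   `mz` (Da) and `intensity` (counts).
#' @param sample_id Sample identifier.
#' @param sample_type One of `"standard"`, `"blank"`, `"matrix_spike"`,
#'   `"cohort_sample"`.
#' @param dry_mass_g Freeze-dried tissue mass (g), for ng/g dw conversion.
#' @param extract_volume_mL Final extract volume (mL).
#' @param species,year Optional cohort covariates.
#' @return A `centroid_run` object.
#' @export
centroid_run <- function(scans, sample_id = "sample",
                         sample_type = c("standard", "blank", "matrix_spike",
                                         "cohort_sample"),
                         dry_mass_g = NA_real_, extract_volume_mL = NA_real_,
                         species = NA_character_, year = NA_integer_) {
  sample_type <- match.arg(sample_type)
  if (!length(scans)) stop("a run must contain at least one scan")
  rts <- vapply(scans, function(s) s$rt, numeric(1))
  if (any(diff(rts) <= 0)) stop("retention times must be strictly increasing")
  for (s in scans) {
    if (length(s$mz) != length(s$intensity))
      stop("mz and intensity must have equal length in every scan")
    if (length(s$mz) && (any(s$mz <= 0) || any(s$intensity < 0)))
      stop("m/z must be positive and intensities non-negative")
  }
  structure(list(scans = scans,
                 metadata = list(sample_id = sample_id,
                                 sample_type = sample_type,
                                 dry_mass_g = dry_mass_g,
                                 extract_volume_mL = extract_volume_mL,
                                 species = species, year = year)),
            class = "centroid_run")
}

#' @export
print.centroid_run <- function(x, ...) {
  rts <- vapply(x$scans, function(s) s$rt, numeric(1))
  cat("<centroid run> ", x$metadata$sample_id, " (", x$metadata$sample_type,
      "): ", length(x$scans), " scans, RT ", round(min(rts), 3), "-",
      round(max(rts), 3), " min\n", sep = "")
  invisible(x)
}

#' Write a run to the native JSON or long CSV format
#'
#' The native JSON schema stores `metadata` and a `scans` array of
#' `{rt, mz[], intensity[]}` records at full double precision, so a
#' write/read cycle reproduces the run exactly. The CSV form is a long
#' table `(rt, mz, intensity)` without metadata, convenient for fixtures.
#'
#' @param run A `centroid_run`.
#' @param path Output file path.
#' @param format `"native_json"` or `"native_csv"` (guessed from the
#'   extension when omitted).
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path, format = NULL) {
  stopifnot(inherits(run, "centroid_run"))
  format <- format %||% guess_run_format(path)
  if (format == "native_json") {
    payload <- list(metadata = run$metadata,
                    scans = lapply(run$scans, function(s)
                      list(rt = s$rt, mz = as.numeric(s$mz),
                           intensity = as.numeric(s$intensity))))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else if (format == "native_csv") {
    df <- do.call(rbind, lapply(run$scans, function(s)
      if (length(s$mz)) data.frame(rt = s$rt, mz = s$mz, intensity = s$intensity)))
    utils::write.csv(df, path, row.names = FALSE)
  } else stop("unsupported write format: ", format)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_run_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         json = "native_json", csv = "native_csv",
         mzml = "mzml",
         stop("cannot guess run format from extension of ", path))
}

#' Read a centroided run
#'
#' Reads the native JSON/CSV formats, or centroided MS1 spectra from an
#' mzML file via the `mzR` package. Profile-mode mzML spectra are rejected:
#' the pipeline operates on centroids only.
#'
#' @param path Input file.
#' @param format `"native_json"`, `"native_csv"` or `"mzml"`; guessed from
#'   the extension when omitted.
#' @param ... Metadata fields passed to [centroid_run()] for formats that
#'   do not carry metadata (CSV, mzML).
#' @return A `centroid_run`.
#' @export
read_run <- function(path, format = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% guess_run_format(path)
  if (format == "native_json") {
    x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!length(x$scans)) stop("empty run: no scans in ", path)
    scans <- lapply(x$scans, function(s)
      list(rt = s$rt, mz = as.numeric(unlist(s$mz)),
           intensity = as.numeric(unlist(s$intensity))))
    md <- x$metadata
    centroid_run(scans, sample_id = md$sample_id %||% "sample",
                 sample_type = md$sample_type %||% "cohort_sample",
                 dry_mass_g = md$dry_mass_g %||% NA_real_,
                 extract_volume_mL = md$extract_volume_mL %||% NA_real_,
                 species = md$species %||% NA_character_,
                 year = md$year %||% NA_integer_)
  } else if (format == "native_csv") {
    df <- utils::read.csv(path)
    if (!nrow(df)) stop("empty run: no rows in ", path)
    stopifnot(all(c("rt", "mz", "intensity") %in% names(df)))
    scans <- lapply(split(df, df$rt), function(d)
      list(rt = d$rt[1], mz = d$mz, intensity = d$intensity))
    scans <- scans[order(vapply(scans, `[[`, numeric(1), "rt"))]
    centroid_run(scans, ...)
  } else if (format == "mzml") {
    read_run_mzml(path, ...)
  } else stop("unsupported format: ", format)
}

read_run_mzml <- function(path, ...) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  h <- NULL
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  h <- mzR::header(ms)
  if (!nrow(h)) stop("empty run: mzML file has zero spectra")
  ms1 <- which(h$msLevel == 1L)
  if (!length(ms1)) stop("mzML file contains no MS1 spectra")
  if ("centroided" %in% names(h) && any(!is.na(h$centroided[ms1]) &
                                        !h$centroided[ms1]))
    stop("profile-mode spectra are not supported (centroid-only contract); ",
         "offending scan index: ", ms1[which(!h$centroided[ms1])[1]])
  scans <- lapply(ms1, function(i) {
    p <- mzR::peaks(ms, i)
    list(rt = h$retentionTime[i] / 60, mz = p[, 1], intensity = p[, 2])
  })
  centroid_run(scans, ...)
}

#' Extract an ion chromatogram
#'
#' Per scan, sums the intensities of all centroids whose m/z lies within
#' `tol_ppm` of `center_mz` (the published workflow uses a 5 ppm window
#' around each quantifier/qualifier ion). Scans with no matching centroid
#' contribute zero.
#'
#' @param run A `centroid_run`.
#' @param center_mz Window center (Da).
#' @param tol_ppm Half-width in ppm (> 0).
#' @return An `eic` object: list with `times`, `intensities`, `center_mz`,
#'   `tol_ppm`.
#' @export
extract_eic <- function(run, center_mz, tol_ppm = 5) {
  stopifnot(inherits(run, "centroid_run"), center_mz > 0)
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  tol_da <- center_mz * tol_ppm * 1e-6
  ints <- vapply(run$scans, function(s) {
    if (!length(s$mz)) return(0)
    sum(s$intensity[abs(s$mz - center_mz) <= tol_da])
  }, numeric(1))
  structure(list(times = vapply(run$scans, `[[`, numeric(1), "rt"),
                 intensities = ints, center_mz = center_mz,
                 tol_ppm = tol_ppm),
            class = "eic")
}

#' @export
print.eic <- function(x, ...) {
  cat("<EIC> m/z ", format(x$center_mz, digits = 8), " +/- ", x$tol_ppm,
      " ppm, ", length(x$times), " scans, max ",
      format(max(x$intensities), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Integrate a chromatographic peak from an EIC
#'
#' Finds the peak apex within `expected_rt +/- rt_tol` (among local maxima,
#' the one nearest the expected retention time; ties go to the higher
#' intensity), extends integration bounds outward until the trace falls
#' below `max(3 * baseline_noise, 0.5% of apex)`, and integrates by the
#' trapezoid rule. Baseline noise is the scaled median absolute deviation
#' of the trace outside the search window. Returns `NULL` ("absent") when
#' no apex reaches a signal-to-noise ratio of `sn_min`.
#'
#' @param eic An `eic`.
#' @param expected_rt Expected retention time (minutes).
#' @param rt_tol Search half-window (minutes, > 0).
#' @param sn_min Minimum apex signal-to-noise ratio (default 3).
#' @return A `chrom_peak` (list with `apex_rt`, `area`, `height`,
#'   `rt_start`, `rt_end`, `signal_to_noise`) or `NULL` when absent.
#' @export
integrate_peak <- function(eic, expected_rt, rt_tol = 0.10, sn_min = 3) {
  stopifnot(inherits(eic, "eic"))
  if (!length(eic$times)) stop("empty EIC")
  if (rt_tol <= 0) stop("rt_tol must be positive")
  t <- eic$times; y <- eic$intensities
  inwin <- abs(t - expected_rt) <= rt_tol
  if (!any(inwin) || all(y[inwin] <= 0)) return(NULL)
  noise <- stats::mad(y[!inwin], constant = 1.4826)
  ## local maxima inside the window that clear the detection threshold
  n <- length(y)
  left <- c(-Inf, y[-n]); right <- c(y[-1], -Inf)
  is_max <- inwin & y > 0 & y >= left & y >= right
  cand <- which(is_max & (noise == 0 | y / max(noise, .Machine$double.eps) >= sn_min))
  if (!length(cand)) {
    ## fall back to the global max in window for S/N reporting
    cand <- which(inwin)[which.max(y[inwin])]
  }
  d <- abs(t[cand] - expected_rt)
  best <- cand[order(d, -y[cand])][1]
  height <- y[best]
  sn <- height / max(noise, .Machine$double.eps)
  if (height <= 0 || sn < sn_min) return(NULL)
  thr <- max(sn_min * noise, 0.005 * height)
  lo <- best
  while (lo > 1 && y[lo - 1] > thr) lo <- lo - 1
  if (lo > 1) lo <- lo - 1  # include first sub-threshold point (tail)
  hi <- best
  while (hi < n && y[hi + 1] > thr) hi <- hi + 1
  if (hi < n) hi <- hi + 1
  idx <- lo:hi
  area <- sum(diff(t[idx]) * (y[idx][-1] + y[idx][-length(idx)]) / 2)
  structure(list(apex_rt = t[best], area = area, height = height,
                 rt_start = t[lo], rt_end = t[hi], signal_to_noise = sn),
            class = "chrom_peak")
}

#' @export
print.chrom_peak <- function(x, ...) {
  cat(sprintf("<peak> apex %.3f min, area %.4g, height %.4g, S/N %.1f, bounds [%.3f, %.3f]\n",
              x$apex_rt, x$area, x$height, x$signal_to_noise,
              x$rt_start, x$rt_end))
  invisible(x)
}
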