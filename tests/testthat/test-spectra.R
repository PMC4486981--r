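make_toy_run <- function() {
  centroid_run(list(
    list(rt = 1.00, mz = c(100.0004, 200.5, 500.0), intensity = c(10, 20, 30)),
    list(rt = 1.01, mz = c(100.0, 500.0012), intensity = c(5, 40)),
    list(rt = 1.02, mz = numeric(), intensity = numeric())),
    sample_id = "toy", sample_type = "standard")
}

test_that("run container enforces its invariants", {
  expect_error(centroid_run(list()), "at least one scan")
  expect_error(centroid_run(list(list(rt = 2, mz = 1, intensity = 1),
                                 list(rt = 1, mz = 1, intensity = 1))),
               "strictly increasing")
  expect_error(centroid_run(list(list(rt = 1, mz = -5, intensity = 1))),
               "positive")
  expect_error(centroid_run(list(list(rt = 1, mz = c(1, 2), intensity = 1))),
               "equal length")
})

test_that("native JSON round-trips a run exactly", {
  run <- make_toy_run()
  f <- tempfile(fileext = ".json")
  write_run(run, f)
  back <- read_run(f)
  expect_equal(back$scans, run$scans)
  expect_equal(back$metadata$sample_id, "toy")
  expect_equal(back$metadata$sample_type, "standard")
  ## a second write of the re-read run is byte-identical
  f2 <- tempfile(fileext = ".json")
  write_run(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("long CSV runs load and empty files error", {
  run <- make_toy_run()
  f <- tempfile(fileext = ".csv")
  write_run(run, f)
  back <- read_run(f, sample_id = "toy")
  ## CSV drops empty scans but preserves all centroids
  expect_equal(sum(lengths(lapply(back$scans, `[[`, "mz"))), 5)
  empty <- tempfile(fileext = ".csv")
  writeLines("rt,mz,intensity", empty)
  expect_error(read_run(empty), "empty run")
  expect_error(read_run(tempfile(fileext = ".json")), "not found")
})

test_that("mzML files read through mzR and respect the centroid-only contract", {
  skip_if_not_installed("mzR")
  run <- make_toy_run()
  f <- tempfile(fileext = ".mzML")
  write_mini_mzml(f, run$scans)
  back <- read_run(f, sample_id = "toy")
  expect_equal(length(back$scans), 3)
  expect_equal(back$scans[[1]]$mz, run$scans[[1]]$mz, tolerance = 1e-9)
  expect_equal(vapply(back$scans, `[[`, numeric(1), "rt"),
               c(1.00, 1.01, 1.02), tolerance = 1e-9)
  empty <- tempfile(fileext = ".mzML")
  write_mini_mzml(empty, list())
  expect_error(read_run(empty), "zero spectra|empty|cannot|error",
               ignore.case = TRUE)
})

test_that("EIC extraction sums within the ppm window and is monotone in tolerance", {
  run <- make_toy_run()
  ## 5 ppm around 100.0: picks up 100.0004 (4 ppm away) and 100.0 exactly
  eic <- extract_eic(run, 100.0, 5)
  expect_equal(eic$intensities, c(10, 5, 0))
  ## narrow window drops the 4-ppm-away centroid
  eic2 <- extract_eic(run, 100.0, 1)
  expect_equal(eic2$intensities, c(0, 5, 0))
  ## no peaks near center: all-zero trace
  expect_equal(extract_eic(run, 900, 5)$intensities, rep(0, 3))
  ## widening the window never decreases any intensity
  for (center in c(100.0, 200.5, 500.0)) {
    narrow <- extract_eic(run, center, 2)$intensities
    wide <- extract_eic(run, center, 4)$intensities
    expect_true(all(wide >= narrow))
  }
  expect_error(extract_eic(run, 100, 0), "positive")
})

test_that("peak integration recovers the analytic Gaussian area", {
  amp <- 1e6; sigma <- 0.05
  eic <- gaussian_eic(amplitude = amp, rt = 4.8, sigma = sigma)
  pk <- integrate_peak(eic, expected_rt = 4.8, rt_tol = 0.1)
  expect_equal(pk$apex_rt, 4.8)
  expect_equal(pk$area, gaussian_area(amp, sigma), tolerance = 0.01)
  expect_lt(pk$rt_start, pk$apex_rt)
  expect_gt(pk$rt_end, pk$apex_rt)
  ## linear intensity scaling scales the area linearly
  eic10 <- eic; eic10$intensities <- eic10$intensities * 10
  expect_equal(integrate_peak(eic10, 4.8, 0.1)$area, 10 * pk$area,
               tolerance = 1e-9)
})

test_that("flat traces are absent and nearest-of-two apexes wins", {
  flat <- structure(list(times = seq(0, 1, 0.01),
                         intensities = rep(0, 101), center_mz = 500,
                         tol_ppm = 5), class = "eic")
  expect_null(integrate_peak(flat, 0.5, 0.1))
  expect_error(integrate_peak(structure(list(times = numeric(),
                                             intensities = numeric()),
                                        class = "eic"), 0.5, 0.1), "empty")
  ## two peaks inside the window: the apex nearer the expected RT is chosen
  t <- seq(4, 5.6, by = 0.01)
  y <- 5e5 * exp(-(t - 4.75)^2 / (2 * 0.03^2)) +
       9e5 * exp(-(t - 4.95)^2 / (2 * 0.03^2))
  two <- structure(list(times = t, intensities = y, center_mz = 500,
                        tol_ppm = 5), class = "eic")
  pk <- integrate_peak(two, expected_rt = 4.80, rt_tol = 0.3)
  expect_equal(pk$apex_rt, 4.75, tolerance = 0.011)
})

test_that("generator-produced runs load with the documented scan structure", {
  run <- make_run("TBBPS-MDBPE", 10, seed = 11)
  expect_equal(length(run$scans), 600)
  rts <- vapply(run$scans, `[[`, numeric(1), "rt")
  expect_equal(diff(rts)[1], 0.01, tolerance = 1e-9)
  f <- tempfile(fileext = ".json")
  write_run(run, f)
  expect_equal(read_run(f)$scans, run$scans)
})
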