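cal7 <- function() {
  conc <- c(0.05, 0.1, 0.5, 1, 5, 10, 100)
  data.frame(conc = conc, area = 304964 + 519149 * conc)
}

test_that("calibration refits exactly on points generated from the published line", {
  cur <- fit_calibration(cal7(), compound = "TBBPS-MAE")
  expect_equal(cur$slope, 519149, tolerance = 1e-9)
  expect_equal(cur$intercept, 304964, tolerance = 1e-9)
  expect_equal(cur$r_squared, 1, tolerance = 1e-12)
  expect_true(cur$accepted)
  expect_equal(cur$range, c(0.05, 100))
  expect_equal(cur$n_points, 7)
})

test_that("degenerate calibration inputs error", {
  expect_error(fit_calibration(data.frame(conc = c(1, 2, 3, 4),
                                          area = 1:4)), "at least 5")
  expect_error(fit_calibration(data.frame(conc = rep(1, 7), area = 1:7)),
               "at least 5")
  expect_error(fit_calibration(data.frame(conc = c(0.05, 0.1, 0.5, 1, 5),
                                          area = rep(100, 5))), "degenerate")
})

test_that("noisy calibration series stay above R^2 = 0.99 in at least 95/100 seeds", {
  conc <- cal7()$conc
  pass <- vapply(1:100, function(s) {
    set.seed(s)
    area <- (304964 + 519149 * conc) * exp(rnorm(7, 0, 0.05))
    fit_calibration(data.frame(conc = conc, area = area))$r_squared > 0.99
  }, logical(1))
  expect_gte(sum(pass), 95)
})

test_that("quantification back-calculates through the curve and workup factors", {
  cur <- fit_calibration(cal7())
  ## area exactly at the intercept: zero concentration
  q0 <- quantify(304964, cur, extract_volume_mL = 1, dry_mass_g = 0.5)
  expect_equal(q0$conc_ng_g, 0)
  ## 2 ng/mL in solution, 1 mL extract, 0.5 g dry mass: 4.0 ng/g dw
  q <- quantify(304964 + 519149 * 2, cur, extract_volume_mL = 1,
                dry_mass_g = 0.5)
  expect_equal(q$conc_ng_g, 4.0, tolerance = 1e-9)
  expect_false(q$extrapolated)
  ## negative back-calculation floors at zero with a flag
  qneg <- quantify(100, cur, dry_mass_g = 0.5)
  expect_equal(qneg$conc_ng_g, 0)
  expect_true(qneg$floored)
  ## guard rails
  bad <- cur; bad$slope <- -1
  expect_error(quantify(1e6, bad, dry_mass_g = 0.5), "positive")
  nd <- structure(list(compound = "x", detected = FALSE),
                  class = "detection_result")
  expect_error(quantify(nd, cur, dry_mass_g = 0.5), "non-detected")
})

test_that("recovery percentages and aggregates follow the n-1 convention", {
  expect_equal(recovery(8.5, 10)$percent, 85)
  r <- recovery(c(8, 8, 8), 10)
  expect_equal(r$mean, 80)
  expect_equal(r$sd, 0)
  expect_error(recovery(5, 0), "positive")
  ## simulated 85% recovery with 8% CV, n = 7: mean within [77, 93] in
  ## >= 95% of seeds
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    meas <- 10 * 0.85 * exp(rnorm(7, 0, 0.08))
    m <- recovery(meas, 10)$mean
    m >= 77 && m <= 93
  }, logical(1))
  expect_gte(sum(ok), 95)
})

test_that("matrix effect is the spike-to-solvent response ratio", {
  expect_equal(matrix_effect(1000, 1000), 1)
  expect_equal(matrix_effect(0.9 * 5e5, 5e5), 0.90)
  expect_error(matrix_effect(100, 0), "positive")
  set.seed(21)
  ratios <- matrix_effect(0.86 * 1e5 * exp(rnorm(3, 0, 0.05)), 1e5)
  expect_equal(mean(ratios), 0.86, tolerance = 0.1)
})

test_that("IDL is the lowest level with full detection and RSD <= 20%", {
  series <- data.frame(
    mass_pg = rep(c(0.02, 0.06, 0.2), each = 5),
    area = c(0, 3, 0, 5, 2,            # partial detection
             100, 105, 95, 102, 98,    # clean
             500, 510, 490, 505, 495),
    detected = c(FALSE, TRUE, FALSE, TRUE, TRUE, rep(TRUE, 10)))
  est <- estimate_idl(series)
  expect_equal(est$idl_pg, 0.06)
  expect_false(est$above_highest)
  ## noise-free series: lowest detected level wins
  clean <- data.frame(mass_pg = rep(c(0.05, 0.5), each = 5),
                      area = rep(c(10, 100), each = 5))
  expect_equal(estimate_idl(clean)$idl_pg, 0.05)
  ## all-blank series: reported as above the highest tested level
  blank <- data.frame(mass_pg = rep(c(0.05, 0.5), each = 5), area = 0,
                      detected = FALSE)
  est2 <- estimate_idl(blank)
  expect_true(est2$above_highest)
  expect_equal(est2$idl_pg, Inf)
  expect_error(estimate_idl(data.frame(mass_pg = rep(1, 5), area = 1:5)),
               "2 mass levels")
})

test_that("MDL uses the one-sided 99% t-quantile and scales with the SD", {
  ## independent check of the t-quantile via numerical inversion of the
  ## incomplete-beta CDF rather than qt()
  f <- function(t) stats::pbeta(9 / (9 + t^2), 9 / 2, 1 / 2) / 2 - 0.01
  t99 <- uniroot(f, c(2, 4), tol = 1e-10)$root
  expect_equal(t99, 2.821, tolerance = 1e-3)
  expect_equal(stats::qt(0.99, 9), 2.821, tolerance = 1e-3)
  expect_equal(estimate_mdl(rep(0.5, 10)), 0)
  x <- c(0.48, 0.50, 0.52, 0.49, 0.51, 0.50, 0.47, 0.53, 0.50, 0.50)
  expect_equal(estimate_mdl(x), stats::qt(0.99, 9) * sd(x))
  ## replicate set with SD 0.0142 lands on the published smallest MDL
  y <- 0.2 + 0.0142 * scale(rnorm(10, 0, 1))[, 1]
  expect_equal(round(estimate_mdl(y), 2), 0.04)
  ## linear scaling in the SD
  expect_equal(estimate_mdl(3 * x), 3 * estimate_mdl(x), tolerance = 1e-12)
  expect_error(estimate_mdl(rep(0.5, 6)), "at least 7")
})

test_that("cohort summaries count detections above the MDL and exclude non-detects", {
  set.seed(40)
  res <- data.frame(
    sample_id = sprintf("S%02d", 1:38), compound = "TBBPS-MDBPE",
    species = rep_len(c("RapL", "Nev"), 38), year = rep_len(2009:2013, 38),
    detected = c(rep(TRUE, 36), FALSE, FALSE),
    conc_ng_g = c(runif(36, 0.3, 4.1), NA, NA))
  s <- summarize_cohort(res, mdl = c("TBBPS-MDBPE" = 0.06))
  expect_equal(round(s$by_compound$detection_frequency), 95)
  expect_equal(s$by_compound$n_detected, 36)
  expect_lte(s$by_compound$min, s$by_compound$median)
  expect_lte(s$by_compound$median, s$by_compound$max)
  ## zero detections: 0% and empty range
  res0 <- res; res0$detected <- FALSE
  s0 <- summarize_cohort(res0, mdl = c("TBBPS-MDBPE" = 0.06))
  expect_equal(s0$by_compound$detection_frequency, 0)
  expect_true(is.na(s0$by_compound$min))
  ## detections below the MDL do not count
  res2 <- res; res2$conc_ng_g[1:36] <- 0.01
  s2 <- summarize_cohort(res2, mdl = c("TBBPS-MDBPE" = 0.06))
  expect_equal(s2$by_compound$n_detected, 0)
  expect_error(summarize_cohort(res[0, ], c("TBBPS-MDBPE" = 0.06)))
  expect_error(summarize_cohort(res, mdl = 0.06), "named")
})
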