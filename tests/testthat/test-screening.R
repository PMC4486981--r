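# Remove all centroids of a run falling within tol_ppm of a given m/z
# (used to construct qualifier-suppressed fixtures).
suppress_mz <- function(run, mz, tol_ppm = 10) {
  run$scans <- lapply(run$scans, function(s) {
    keep <- abs(s$mz - mz) > mz * tol_ppm * 1e-6
    list(rt = s$rt, mz = s$mz[keep], intensity = s$intensity[keep])
  })
  run
}

test_that("target definitions validate their quantifier/qualifier ions", {
  tg <- tbbps_targets()
  expect_named(tg, c("TBBPS-MAE", "TBBPS-MBAE", "TBBPS-MDBPE"))
  expect_equal(vapply(tg, `[[`, numeric(1), "expected_rt"),
               c("TBBPS-MAE" = 4.20, "TBBPS-MBAE" = 4.56,
                 "TBBPS-MDBPE" = 4.80))
  expect_error(target_compound("x", "C15H10Br4O4S", 604.69189, 604.69189,
                               4.2, 4), "differ")
  expect_error(target_compound("x", "C15H10Br4O4S", 604.69189, 777.7,
                               4.2, 4), "envelope")
})

test_that("a spiked synthetic run is identified with all criteria passing", {
  run <- make_run("TBBPS-MDBPE", 2, seed = 31)
  res <- identify_target(run, tbbps_targets()[["TBBPS-MDBPE"]])
  expect_true(res$detected)
  expect_equal(res$apex_rt, 4.80, tolerance = 0.02 / 4.8)
  expect_length(res$flags, 0)
  expect_lt(res$mass_error_ppm, 5)
  expect_equal(res$ion_ratio, res$predicted_ratio, tolerance = 0.2)
  expect_gt(res$envelope_score, 0.7)
})

test_that("blank runs and suppressed qualifiers are rejected with audit flags", {
  blank <- make_run("TBBPS-MDBPE", 0, seed = 32, sample_type = "blank")
  res <- identify_target(blank, tbbps_targets()[["TBBPS-MDBPE"]])
  expect_false(res$detected)
  expect_equal(res$flags, "no quantifier peak")
  spiked <- make_run("TBBPS-MDBPE", 2, seed = 33)
  noqual <- suppress_mz(spiked, tbbps_targets()[["TBBPS-MDBPE"]]$qualifier_mz)
  res2 <- identify_target(noqual, tbbps_targets()[["TBBPS-MDBPE"]])
  expect_false(res2$detected)
  expect_true("qualifier co-elution" %in% res2$flags)
})

test_that("relaxing tolerances never turns a detection into a non-detection", {
  run <- make_run("TBBPS-MAE", 1, seed = 34)
  tg <- tbbps_targets()[["TBBPS-MAE"]]
  base <- identify_target(run, tg, mz_tol_ppm = 5, rt_tol = 0.05,
                          ratio_tol = 0.15)
  for (fac in c(1.5, 2, 4)) {
    relaxed <- identify_target(run, tg, mz_tol_ppm = 5 * fac,
                               rt_tol = 0.05 * fac, ratio_tol = 0.15 * fac)
    if (base$detected) expect_true(relaxed$detected)
  }
})

test_that("bromine-cluster discovery infers the bromine count from the pattern", {
  delta <- 1.99795208
  ## Br2 phenol-like triplet (1:2:1) and a Br4 quintet (1:4:6:4:1)
  scans <- list(list(
    rt = 2.0,
    mz = c(250.90, 250.90 + delta, 250.90 + 2 * delta,
           564.66068 - 2 * delta + 0:4 * delta),
    intensity = c(5e4, 1e5, 5e4, 1e5 * c(1, 4, 6, 4, 1) / 6)))
  run <- centroid_run(scans, sample_id = "u")
  hits <- discover_br_unknowns(run, min_n_br = 1)
  expect_length(hits, 2)
  nbr <- vapply(hits, `[[`, integer(1), "inferred_n_br")
  mono <- vapply(hits, `[[`, numeric(1), "mono_mz")
  expect_setequal(nbr, c(2L, 4L))
  expect_equal(sort(mono), c(250.90, 564.66068 - 2 * delta),
               tolerance = 1e-6)
})

test_that("the TBBPS-like unknown's two-81Br isotopologue lies in the published EIC window", {
  ## Fig.-4-style containment: computed isotopologue inside 564.65784-564.66348
  mz <- ion_mz(ion_species("C12H5O4Br4S", "M", charge = -1,
                           substitutions = c("81Br" = 2)))
  expect_gt(mz, 564.65784)
  expect_lt(mz, 564.66348)
})

test_that("non-halogenated spectra yield no bromine-cluster hits", {
  set.seed(35)
  scans <- list(list(rt = 1.0, mz = sort(runif(30, 100, 900)),
                     intensity = rexp(30, 1 / 100)))
  run <- centroid_run(scans)
  expect_length(discover_br_unknowns(run, min_n_br = 2), 0)
})

test_that("formula decomposition recovers the published assignments", {
  hits1 <- decompose_formula(326.76612, tol_ppm = 5)
  expect_true("C6H2Br3O" %in% hits1$formula)
  hits2 <- decompose_formula(600.69605, tol_ppm = 5)
  expect_true("C15H9Br4O4S" %in% hits2$formula)
  hits3 <- decompose_formula(293.84069, tol_ppm = 5)
  expect_true("C6H2Br2NO3" %in% hits3$formula)
  ## ranked by ppm error
  expect_true(!is.unsorted(hits2$ppm))
  ## zero tolerance on a non-exact mass: empty result
  expect_equal(nrow(decompose_formula(600.1234, tol_ppm = 0)), 0)
  expect_error(decompose_formula(300, bounds = c(C = 0)), "at least one atom")
})

test_that("decomposition agrees with the naive nested-loop oracle", {
  bounds <- c(C = 20, H = 20, N = 2, O = 6, S = 2, Br = 8)
  set.seed(36)
  masses <- c(runif(4, 100, 750), 326.76612, 600.69605)
  for (mz in masses) {
    fast <- decompose_formula(mz, tol_ppm = 5, bounds = bounds)
    fast_keys <- sort(paste(fast$C, fast$H, fast$N, fast$O, fast$S, fast$Br,
                            sep = ","))
    expect_identical(fast_keys, oracle_decompose(mz, bounds, 5))
  }
})

test_that("cluster discovery recovers injected Br2-Br6 clusters and rejects halogen-free spectra", {
  set.seed(37)
  n_spec <- 200
  recovered <- logical(n_spec)
  for (i in seq_len(n_spec)) {
    n_br <- sample(2:6, 1)
    mono <- runif(1, 250, 700)
    env <- binomial_br_envelope(n_br, mono)
    base_n <- rpois(1, 20)
    mzs <- c(env$mz, runif(base_n, 100, 900))
    ints <- c(env$rel_abundance * 2e4, rexp(base_n, 1 / 50))
    o <- order(mzs)
    run <- centroid_run(list(list(rt = 1, mz = mzs[o], intensity = ints[o])))
    hits <- discover_br_unknowns(run, min_n_br = 2, intensity_floor = 1e3)
    recovered[i] <- any(vapply(hits, function(h)
      abs(h$mono_mz - mono) < 0.02 && h$inferred_n_br == n_br, logical(1)))
  }
  expect_gte(mean(recovered), 0.95)
  false_hits <- 0
  for (i in seq_len(n_spec)) {
    base_n <- rpois(1, 20)
    run <- centroid_run(list(list(rt = 1, mz = sort(runif(base_n, 100, 900)),
                                  intensity = rexp(base_n, 1 / 50))))
    false_hits <- false_hits +
      length(discover_br_unknowns(run, min_n_br = 2, intensity_floor = 1e3))
  }
  expect_equal(false_hits, 0)
})

test_that("bioaccumulation rule uses strict thresholds on both properties", {
  expect_true(bioaccumulation_flag(7.01, 13200))   # TBBPS-MBAE
  expect_true(bioaccumulation_flag(6.61, 10730))   # TBBPS-MAE
  expect_false(bioaccumulation_flag(5.21, 1266))   # TBBPS
  expect_false(bioaccumulation_flag(9.52, 775))    # TBBPS-BDBPE
  expect_false(bioaccumulation_flag(5.0, 5000))    # boundary is strict
  expect_false(bioaccumulation_flag(5.0, 6000))
  expect_false(bioaccumulation_flag(6.0, 5000))
})
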