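# Independent oracles used to freeze expected values.

# Brute-force bromine envelope: enumerate all 2^n isotope assignments of n
# Br atoms and accumulate probability by number of 81Br. Independent of the
# package's binomial/multinomial code paths.
oracle_br_envelope <- function(n, p81) {
  k_counts <- numeric(n + 1)
  for (assign in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(assign))[1:n]
    k <- sum(bits)
    prob <- p81^k * (1 - p81)^(n - k)
    k_counts[k + 1] <- k_counts[k + 1] + prob
  }
  k_counts / max(k_counts)
}

# Naive nested-loop formula decomposition with mass pruning: returns the set
# of ion formulas (as strings of counts) matching mz within tol_ppm.
oracle_decompose <- function(mz, bounds, tol_ppm, rdbe_min = 0) {
  tab <- atomic_mass_table()
  pm <- sapply(c("C", "H", "N", "O", "S", "Br"), function(el) {
    iso <- tab$isotopes[tab$isotopes$element == el, ]
    iso$mass_da[which.min(iso$mass_da)]
  })
  me <- tab$electron_mass
  hi_mass <- mz * (1 + tol_ppm * 1e-6)
  out <- character()
  for (c_ in 0:bounds["C"]) {
    mc <- c_ * pm["C"]
    if (mc > hi_mass) break
    for (h_ in 0:bounds["H"]) {
      mh <- mc + h_ * pm["H"]
      if (mh > hi_mass) break
      for (n_ in 0:bounds["N"]) {
        mn <- mh + n_ * pm["N"]
        if (mn > hi_mass) break
        for (o_ in 0:bounds["O"]) {
          mo <- mn + o_ * pm["O"]
          if (mo > hi_mass) break
          for (s_ in 0:bounds["S"]) {
            ms <- mo + s_ * pm["S"]
            if (ms > hi_mass) break
            for (b_ in 0:bounds["Br"]) {
              m <- ms + b_ * pm["Br"] + me
              if (m > hi_mass) break
              if (c_ + h_ + n_ + o_ + s_ + b_ == 0) next
              if (abs(mz - m) / m * 1e6 <= tol_ppm) {
                rdbe <- c_ - (h_ + 1 + b_) / 2 + n_ / 2 + 1
                if (rdbe >= rdbe_min)
                  out <- c(out, paste(c_, h_, n_, o_, s_, b_, sep = ","))
              }
            }
          }
        }
      }
    }
  }
  sort(out)
}

# Closed-form area of a Gaussian chromatographic peak.
gaussian_area <- function(amplitude, sigma) amplitude * sigma * sqrt(2 * pi)

# A clean synthetic EIC: Gaussian peak sampled on a regular time grid.
gaussian_eic <- function(amplitude = 1e6, rt = 4.8, sigma = 0.05,
                         times = seq(4, 5.6, by = 0.01)) {
  structure(list(times = times,
                 intensities = amplitude * exp(-(times - rt)^2 / (2 * sigma^2)),
                 center_mz = 500, tol_ppm = 5),
            class = "eic")
}
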