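# Peak-list reading, S/N filtering, recalibration, pair matching, and
# replicate aggregation.

test_that("peak lists are read sorted, windowed, and validated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mz\tintensity", "1000.0\t5.0", "900.0\t2.0", "650.0\t9.0"), f)
  peaks <- read_peaklist(f)
  expect_equal(peaks$mz, c(900, 1000))
  expect_equal(peaks$intensity, c(2, 5))
  expect_equal(attr(peaks, "n_dropped"), 1) # 650 is below the 700 window

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1000\t1.0", "oops\tnope"), bad)
  expect_error(read_peaklist(bad), "line 2")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_peaklist(empty), "empty")
  expect_error(read_peaklist("no/such/file.tsv"), "no such file")

  # comma-separated input is accepted too
  fc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("800.5,3", "900.25,4"), fc)
  expect_equal(read_peaklist(fc)$mz, c(800.5, 900.25))
})

test_that("S/N filtering is strict and estimable from decoy peaks", {
  peaks <- tibble::tibble(mz = c(800, 900, 1000),
                          intensity = c(1, 2, 3),
                          snr = c(10, 3, 2.99))
  kept <- snr_filter(peaks, threshold = 3)
  expect_equal(kept$mz, 800) # S/N exactly 3 is dropped (strict >)
  expect_equal(nrow(snr_filter(peaks, threshold = 0.5)), 3)
  expect_warning(res <- snr_filter(peaks, threshold = 100), "no peaks")
  expect_equal(nrow(res), 0)
  expect_error(snr_filter(peaks, threshold = -1))

  # estimated S/N: analyte intensity over local median of non-library peaks
  lib <- build_library(calibrant_panel())
  target <- lib$light_mz[1]
  pk <- tibble::tibble(
    mz = c(target, target + 50.1, target + 60.3, target + 70.7),
    intensity = c(40, 2, 4, 8))
  est <- estimate_snr(pk, lib)
  expect_equal(est$snr[1], 10) # 40 / median(2, 4, 8)
  expect_error(snr_filter(pk, 3), "library")
  expect_equal(nrow(snr_filter(pk, 3, lib)), 1)
})

test_that("affine recalibration recovers drift and is idempotent", {
  lib <- build_library(calibrant_panel())
  theo <- sodiated_mz(calibrant_panel())
  peaks <- tibble::tibble(mz = sort(theo) + 0.05, intensity = 100)
  rc <- recalibrate(peaks)
  expect_equal(rc$fit$status, "ok")
  expect_equal(rc$fit$n_matched, 7)
  expect_equal(rc$fit$offset_da, 0.05, tolerance = 1e-6)
  expect_lt(rc$fit$max_residual, 1e-9)
  expect_equal(sort(rc$peaks$mz), sort(theo), tolerance = 1e-9)

  # second pass on calibrated data is a near-identity fit
  rc2 <- recalibrate(rc$peaks)
  expect_lt(abs(rc2$fit$offset_da), 1e-9)
  expect_equal(rc2$peaks$mz, rc$peaks$mz, tolerance = 1e-9)

  # slope-only (ppm) drift is recovered as well
  ppm_peaks <- tibble::tibble(mz = sort(theo) * (1 + 8e-6), intensity = 1)
  rc3 <- recalibrate(ppm_peaks)
  expect_lt(abs(rc3$fit$slope - 8e-6), 1e-9)
  expect_lt(rc3$fit$max_residual, 1e-6)

  # a single matched calibrant falls back to the identity transform
  one <- tibble::tibble(mz = theo[1] + 0.02, intensity = 1)
  expect_warning(rc4 <- recalibrate(one), "fewer than 2")
  expect_equal(rc4$fit$status, "identity")
  expect_equal(rc4$peaks$mz, one$mz)
  expect_equal(nrow(tidy(rc4)), 7)
})

test_that("pair matching resolves by ppm and flags failure modes", {
  lib <- build_library(c("H4N4F1", "H5N4Ge2"))
  l1 <- lib$light_mz[lib$name == "H4N4F1"]
  h1 <- lib$heavy_mz[lib$name == "H4N4F1"]
  # a peak 2.4 ppm off the light target matches at 10 ppm tolerance
  peaks <- tibble::tibble(mz = c(1647.5869, h1), intensity = c(1000, 500))
  mp <- match_pairs(peaks, lib, tol_ppm = 10)
  row <- mp[mp$glycan == "H4N4F1", ]
  expect_equal(row$status, "ok")
  expect_equal(row$ratio, 2)
  expect_lt(row$light_ppm, 3)
  expect_equal(mp$status[mp$glycan == "H5N4Ge2"], "light_missing")

  # heavy peak absent
  mp2 <- match_pairs(tibble::tibble(mz = l1, intensity = 10), lib)
  expect_equal(mp2$status[mp2$glycan == "H4N4F1"], "heavy_missing")
  expect_true(is.na(mp2$ratio[mp2$glycan == "H4N4F1"]))

  # two comparable peaks inside the tolerance raise ambiguity
  amb <- match_pairs(tibble::tibble(
    mz = c(l1, l1 + l1 * 5e-6, h1), intensity = c(100, 80, 50)), lib)
  expect_equal(amb$status[amb$glycan == "H4N4F1"], "ambiguous")
  # a dominated second peak (outside factor-2 intensity) does not
  okm <- match_pairs(tibble::tibble(
    mz = c(l1, l1 + l1 * 5e-6, h1), intensity = c(100, 10, 50)), lib)
  expect_equal(okm$status[okm$glycan == "H4N4F1"], "ok")

  # one observed peak claimed by two library entries is flagged for both
  twin_lib <- build_library(c("H5N4F1Ge1", "H6N4E1")) # exact isobars
  shared <- match_pairs(tibble::tibble(
    mz = c(twin_lib$light_mz[1], twin_lib$heavy_mz[1]),
    intensity = c(10, 5)), twin_lib)
  expect_true(all(shared$status %in% c("ambiguous")))
})

test_that("drifted synthetic spectra are fully recovered after recalibration", {
  design <- small_design(mice = 1, weeks = 15)
  lib <- build_library()
  truth <- simulate_abundances(design, noise_free_effects(), lib)
  rend <- render_peaklists(
    truth, lib, noise_free_spectrum(drift_da = 0.2, drift_ppm = 20),
    design, noise_free_effects())
  spot <- dplyr::filter(rend$peaks, spot_id == rend$manifest$spot_id[1])
  rc <- recalibrate(spot)
  mp <- match_pairs(rc$peaks, lib)
  expect_true(all(mp$status == "ok"))
  truth1 <- dplyr::filter(truth, sample_id == rend$manifest$sample_id[1])
  expect_equal(mp$ratio[match(truth1$glycan, mp$glycan)], truth1$true_ratio,
               tolerance = 1e-9)
})

test_that("replicate aggregation averages ok spots and reports the CV", {
  pairs <- tibble::tibble(
    sample_id = rep("s1", 3), glycan = "g",
    ratio = c(1, 2, 3), status = "ok")
  agg <- aggregate_replicates(pairs)
  expect_equal(agg$ratio, 2)
  expect_equal(agg$tech_cv, 0.5) # sample sd 1.0 over mean 2.0
  expect_equal(agg$n_rep, 3)

  const <- aggregate_replicates(dplyr::mutate(pairs, ratio = 2))
  expect_equal(const$ratio, 2)
  expect_equal(const$tech_cv, 0)

  # a missing spot reduces the replicate count, not the sample
  partial <- aggregate_replicates(dplyr::mutate(
    pairs, status = c("ok", "ok", "heavy_missing"), ratio = c(1, 3, NA)))
  expect_equal(partial$ratio, 2)
  expect_equal(partial$n_rep, 2)
  none <- aggregate_replicates(dplyr::mutate(pairs, status = "light_missing"))
  expect_true(is.na(none$ratio))
  expect_equal(none$n_rep, 0)
})
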