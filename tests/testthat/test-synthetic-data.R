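# Ground-truth simulation and peak-list rendering.

test_that("simulation is deterministic and honours degenerate settings", {
  design <- small_design()
  lib <- build_library()
  t1 <- simulate_abundances(design, effect_model(), lib)
  t2 <- simulate_abundances(design, effect_model(), lib)
  expect_identical(t1, t2)
  expect_false(identical(
    t1, simulate_abundances(small_design(seed = 8), effect_model(), lib)))

  # no biological noise, no outliers: AL mice sit exactly at baseline x sex
  eff0 <- noise_free_effects()
  truth <- simulate_abundances(design, eff0, lib)
  et <- attr(truth, "effects_table")
  al_m <- dplyr::filter(truth, group == "AL", sex == "M")
  expect_equal(al_m$true_ratio, et$baseline[match(al_m$glycan, et$glycan)])
  # fixed CR multiplier: CR/AL population ratio is exact
  eff07 <- noise_free_effects(cr_down = 0.7, cr_up = 0.7)
  truth07 <- simulate_abundances(design, eff07, lib)
  byg <- truth07 |>
    dplyr::filter(sex == "M", group != "QC") |>
    dplyr::group_by(glycan, group) |>
    dplyr::summarise(m = mean(true_ratio), .groups = "drop") |>
    tidyr::pivot_wider(names_from = group, values_from = m)
  expect_equal(byg$CR / byg$AL, rep(0.7, nrow(byg)), tolerance = 1e-12)
  # female fucosylation offset applies to fucosylated glycans only
  fem <- dplyr::filter(truth, group == "AL", sex == "F")
  fuc <- lib$fucosylated[match(fem$glycan, lib$name)]
  expect_equal(fem$true_ratio / al_m$true_ratio, ifelse(fuc, 1.3, 1))
})

test_that("rendered peak lists carry the programmed displacement and bleed", {
  design <- small_design(mice = 1, weeks = 15)
  lib <- build_library()
  truth <- simulate_abundances(design, noise_free_effects(), lib)

  shifted <- render_peaklists(
    truth, lib, noise_free_spectrum(drift_da = 0.5, n_decoys = 0),
    design, noise_free_effects())
  spot <- dplyr::filter(shifted$peaks, spot_id == shifted$peaks$spot_id[1])
  theo <- sort(c(lib$light_mz, lib$heavy_mz))
  expect_equal(sort(spot$mz) - theo, rep(0.5, length(theo)),
               tolerance = 1e-9)

  # excessive drift is refused as unmatchable
  expect_error(
    render_peaklists(truth, lib, noise_free_spectrum(drift_da = 5),
                     design, noise_free_effects()),
    "unmatchable")

  # positive heavy-channel bleed biases measured ratios upward by ~bleed x ratio
  clean <- render_peaklists(truth, lib, noise_free_spectrum(n_decoys = 0),
                            design, noise_free_effects())
  bled <- render_peaklists(
    truth, lib, noise_free_spectrum(n_decoys = 0, bleed = 0.08),
    design, noise_free_effects())
  ratio_of <- function(rend) {
    mp <- match_pairs(dplyr::filter(rend$peaks,
                                    spot_id == rend$manifest$spot_id[1]),
                      lib)
    mp$ratio[match(lib$name, mp$glycan)]
  }
  r_clean <- ratio_of(clean)
  r_bled <- ratio_of(bled)
  expect_equal(r_bled, r_clean / (1 + 0.08 * r_clean), tolerance = 1e-9)
})

test_that("datasets write with correct file counts and regenerate identically", {
  design <- small_design(mice = 2, weeks = 15, qc_replicates = 0)
  sim <- simulate_glycome_study(design, library = build_library(calibrant_panel()))
  # 2 groups x 2 sexes x 2 mice x 1 week x 3 spots
  expect_equal(nrow(sim$manifest), 2 * 2 * 2 * 3)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  expect_length(dir(file.path(dir, "peaks")), 24)
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                              show_col_types = FALSE)
  expect_equal(nrow(dplyr::distinct(manifest, sample_id)), 8)
  expect_error(write_dataset(sim, dir), "not empty")

  dir2 <- withr::local_tempdir()
  write_dataset(simulate_glycome_study(
    design, library = build_library(calibrant_panel())), dir2)
  for (f in c("manifest.tsv", "ground_truth.tsv", "parameters.tsv")) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
  f1 <- dir(file.path(dir, "peaks"), full.names = TRUE)
  f2 <- dir(file.path(dir2, "peaks"), full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("noise-free simulation round-trips exactly through the pipeline", {
  design <- small_design(mice = 2, weeks = c(15, 19))
  sim <- simulate_glycome_study(design, noise_free_effects(),
                                noise_free_spectrum())
  run <- run_pipeline(sim)
  joined <- dplyr::inner_join(
    tibble::as_tibble(run$quant),
    sim$truth[c("sample_id", "glycan", "true_ratio")],
    by = c("sample_id", "glycan"))
  expect_equal(nrow(joined), nrow(tibble::as_tibble(run$quant)))
  expect_true(all(abs(joined$ratio / joined$true_ratio - 1) < 1e-9))
  expect_equal(sum(run$qc$retained), nrow(run$library))
})

test_that("empirical CR/AL means track the programmed multipliers", {
  design <- study_design(mice_per_group = 10, weeks = 15, seed = 11)
  lib <- build_library()
  truth <- simulate_abundances(design, effect_model(outlier_prob = 0), lib)
  et <- attr(truth, "effects_table")
  est <- truth |>
    dplyr::filter(group != "QC") |>
    dplyr::group_by(glycan, group) |>
    dplyr::summarise(m = mean(true_ratio), se = stats::sd(true_ratio) /
                       sqrt(dplyr::n()), .groups = "drop") |>
    tidyr::pivot_wider(names_from = group, values_from = c(m, se)) |>
    dplyr::left_join(et, by = "glycan") |>
    dplyr::mutate(
      est = .data$m_CR / .data$m_AL,
      se_ratio = .data$est * sqrt((.data$se_CR / .data$m_CR)^2 +
                                    (.data$se_AL / .data$m_AL)^2),
      covered = abs(.data$est - .data$cr_mult) <= 3 * .data$se_ratio)
  expect_gte(mean(est$covered), 0.95)
})
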