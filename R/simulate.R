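# Synthetic-data generator: ground-truth light/heavy ratios for a two-diet
# longitudinal mouse study, rendered into MALDI-TOF-like peak lists.
#
# The generator exists so that every downstream stage (matching, QC, traits,
# statistics) can be validated against a known truth. Its defaults emulate
# the study design it models: ad libitum (AL) vs 30% calorie restriction
# (CR), both sexes, serum sampled at 7 time points, triplicate target spots
# per sample, and effect directions of a generalized CR decrease with an
# increase confined to O-acetylated glycans that carry only alpha-2,6-linked
# sialic acid, plus higher fucosylation in females. Effect magnitudes are
# synthetic choices (the directions, not the sizes, are what the emulated
# design reports).

#' Study design for the synthetic glycome experiment
#'
#' @param groups Diet groups; `"AL"` (ad libitum) and `"CR"` (calorie
#'   restriction).
#' @param sexes Sexes simulated; females get the fucosylation offset.
#' @param weeks Sampling time points in weeks of age, strictly increasing.
#' @param mice_per_group Mice per group x sex cell (default 30, as in a full
#'   cohort; scale down for quick runs).
#' @param replicates Technical replicate spots per serum sample (default 3).
#' @param qc_replicates Replicate spots of the pooled reference sample used
#'   as the reproducibility set for the CV filter (default 6; 0 disables).
#' @param seed Integer random seed; a fixed seed makes the whole simulation
#'   byte-identical.
#' @return A list of class `study_design`.
#' @export
study_design <- function(groups = c("AL", "CR"), sexes = c("M", "F"),
                         weeks = c(15, 19, 23, 27, 31, 35, 60),
                         mice_per_group = 30, replicates = 3,
                         qc_replicates = 6, seed = 1L) {
  stopifnot(mice_per_group >= 1, replicates >= 1, qc_replicates >= 0,
            length(weeks) >= 1, !is.unsorted(weeks, strictly = TRUE))
  structure(list(groups = groups, sexes = sexes, weeks = weeks,
                 mice_per_group = as.integer(mice_per_group),
                 replicates = as.integer(replicates),
                 qc_replicates = as.integer(qc_replicates),
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Effect model for the synthetic glycome experiment
#'
#' Per-glycan baseline ratios are log-normal; CR multiplies most glycans by a
#' factor below 1 and the O-acetylated glycans with exclusively
#' alpha-2,6-linked sialic acid (Ac >= 1 and no lactonized residue) by a
#' factor above 1; females get a multiplicative fucosylation offset on
#' fucose-carrying glycans. All magnitudes are configurable synthetic
#' defaults.
#'
#' @param cr_down CR multiplier for decreased glycans: a length-2 range to
#'   draw from uniformly per glycan (default `c(0.5, 0.9)`), or a single
#'   number applied to all of them.
#' @param cr_up CR multiplier for the O-acetylated alpha-2,6-only glycans
#'   (default range `c(1.2, 1.6)`, or a single number).
#' @param sex_fucosylation Multiplier applied to fucosylated glycans in
#'   females (default 1.3).
#' @param baseline_sdlog Log-scale spread of per-glycan baseline ratios
#'   around a median of 1 (default 0.4).
#' @param bio_cv Between-mouse biological coefficient of variation of the
#'   true ratio (default 0.20).
#' @param tech_cv Technical coefficient of variation of the measured ratio
#'   per spot (default 0.10).
#' @param outlier_prob Probability that a mouse x week x glycan true value is
#'   an aberrant measurement (default 0.02).
#' @param outlier_mult Multiplier applied to outliers (default 5).
#' @param trend_slope Per-week log-linear time trend of the true ratio
#'   (default 0, i.e. flat).
#' @return A list of class `effect_model`.
#' @export
effect_model <- function(cr_down = c(0.5, 0.9), cr_up = c(1.2, 1.6),
                         sex_fucosylation = 1.3, baseline_sdlog = 0.4,
                         bio_cv = 0.20, tech_cv = 0.10,
                         outlier_prob = 0.02, outlier_mult = 5,
                         trend_slope = 0) {
  stopifnot(all(cr_down > 0), all(cr_up > 0), sex_fucosylation > 0,
            bio_cv >= 0, bio_cv <= 1, tech_cv >= 0, tech_cv <= 1,
            outlier_prob >= 0, outlier_prob <= 1, outlier_mult > 0)
  structure(list(cr_down = cr_down, cr_up = cr_up,
                 sex_fucosylation = sex_fucosylation,
                 baseline_sdlog = baseline_sdlog,
                 bio_cv = bio_cv, tech_cv = tech_cv,
                 outlier_prob = outlier_prob, outlier_mult = outlier_mult,
                 trend_slope = trend_slope),
            class = "effect_model")
}

#' Spectrum rendering model
#'
#' @param jitter_ppm Gaussian m/z jitter per peak, as a standard deviation
#'   in ppm of the peak position (default 3, typical TOF reproducibility;
#'   jitter scales with m/z on a time-of-flight axis).
#' @param drift_da Global calibration offset in Da (default 0.05).
#' @param drift_ppm Global calibration slope in ppm (default 10).
#' @param n_decoys Number of random noise peaks per spectrum, placed away
#'   from library m/z positions (default 100).
#' @param decoy_intensity Median intensity of noise peaks relative to the
#'   heavy-channel scale (default 0.02).
#' @param intensity_scale Heavy-channel (internal standard) intensity scale
#'   (default 1000).
#' @param bleed Fraction of light-channel intensity bleeding into the heavy
#'   channel, modeling overlap of the light A+3 isotopologue with the heavy
#'   monoisotopic peak (default 0: the quantitation model applies no
#'   correction, so the default renders none).
#' @return A list of class `spectrum_model`.
#' @export
spectrum_model <- function(jitter_ppm = 3, drift_da = 0.05, drift_ppm = 10,
                           n_decoys = 100, decoy_intensity = 0.02,
                           intensity_scale = 1000, bleed = 0) {
  stopifnot(jitter_ppm >= 0, n_decoys >= 0, decoy_intensity >= 0,
            intensity_scale > 0, bleed >= 0, bleed < 1)
  structure(list(jitter_ppm = jitter_ppm, drift_da = drift_da,
                 drift_ppm = drift_ppm, n_decoys = as.integer(n_decoys),
                 decoy_intensity = decoy_intensity,
                 intensity_scale = intensity_scale, bleed = bleed),
            class = "spectrum_model")
}

# lognormal sdlog giving a target coefficient of variation
.cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Draw per-glycan effect parameters
#'
#' Assigns each library glycan a baseline ratio, its CR multiplier (below 1
#' for most glycans, above 1 for O-acetylated glycans carrying only
#' alpha-2,6-linked sialic acid), and whether the female fucosylation offset
#' applies. Deterministic given `seed`.
#'
#' @param library A [build_library()] result.
#' @param effects An [effect_model()].
#' @param seed Integer seed.
#' @return A tibble with columns `glycan`, `baseline`, `cr_mult`,
#'   `sex_affected`, `direction` (`"up"`/`"down"`).
#' @export
glycan_effects <- function(library, effects = effect_model(), seed = 1L) {
  n <- nrow(library)
  up <- library$acetylated & library$sialic_23 == 0
  withr::with_seed(seed, {
    baseline <- stats::rlnorm(n, meanlog = 0, sdlog = effects$baseline_sdlog)
    draw <- function(range, k) {
      if (length(range) == 1) rep(range, k) else stats::runif(k, range[1], range[2])
    }
    cr <- numeric(n)
    cr[up] <- draw(effects$cr_up, sum(up))
    cr[!up] <- draw(effects$cr_down, sum(!up))
  })
  tibble::tibble(glycan = library$name, baseline = baseline, cr_mult = cr,
                 sex_affected = library$fucosylated,
                 direction = ifelse(up, "up", "down"))
}

#' Simulate ground-truth light/heavy ratios
#'
#' For every mouse x week x glycan, the true ratio is
#' `baseline x CR multiplier (CR mice) x fucosylation offset (fucosylated
#' glycans in females) x exp(trend_slope x (week - first week)) x`
#' log-normal biological noise, with occasional multiplicative outliers.
#' A pooled reference sample (`group = "QC"`) at the per-glycan baseline is
#' appended when the design requests QC replicates.
#'
#' @param design A [study_design()].
#' @param effects An [effect_model()].
#' @param library A [build_library()] result.
#' @return A tibble with one row per sample x glycan: `sample_id`,
#'   `mouse_id`, `group`, `sex`, `week`, `glycan`, `true_ratio`,
#'   `is_outlier`. The per-glycan effect table is attached as attribute
#'   `effects_table`.
#' @export
simulate_abundances <- function(design = study_design(),
                                effects = effect_model(),
                                library = build_library()) {
  eff <- glycan_effects(library, effects, seed = design$seed)
  samples <- tidyr::expand_grid(
    group = design$groups, sex = design$sexes,
    mouse = seq_len(design$mice_per_group), week = design$weeks
  ) |>
    dplyr::mutate(
      mouse_id = sprintf("%s_%s_%02d", .data$group, .data$sex, .data$mouse),
      sample_id = sprintf("%s_w%02d", .data$mouse_id, .data$week)
    ) |>
    dplyr::select("sample_id", "mouse_id", "group", "sex", "week")

  truth <- tidyr::expand_grid(samples, glycan = eff$glycan) |>
    dplyr::left_join(eff, by = "glycan")
  sd_bio <- .cv_to_sdlog(effects$bio_cv)
  n <- nrow(truth)
  withr::with_seed(design$seed + 1L, {
    noise <- stats::rlnorm(n, meanlog = 0, sdlog = sd_bio)
    is_out <- stats::runif(n) < effects$outlier_prob
  })
  truth <- truth |>
    dplyr::mutate(
      true_ratio = .data$baseline *
        ifelse(.data$group == "CR", .data$cr_mult, 1) *
        ifelse(.data$sex_affected & .data$sex == "F",
               effects$sex_fucosylation, 1) *
        exp(effects$trend_slope * (.data$week - min(design$weeks))) *
        noise * ifelse(is_out, effects$outlier_mult, 1),
      is_outlier = is_out
    ) |>
    dplyr::select("sample_id", "mouse_id", "group", "sex", "week",
                  "glycan", "true_ratio", "is_outlier")

  if (design$qc_replicates > 0) {
    qc <- tibble::tibble(
      sample_id = "POOL_w00", mouse_id = "POOL", group = "QC", sex = "P",
      week = 0
    ) |>
      tidyr::expand_grid(eff["glycan"]) |>
      dplyr::mutate(true_ratio = eff$baseline[match(.data$glycan, eff$glycan)],
                    is_outlier = FALSE)
    truth <- dplyr::bind_rows(truth, qc)
  }
  attr(truth, "effects_table") <- eff
  truth
}

#' Render per-spot peak lists from ground truth
#'
#' Each sample is rendered into `replicates` technical spots. For every
#' glycan, the heavy (internal standard) peak gets unit-scale intensity times
#' log-normal technical noise and the light peak gets `true ratio x heavy
#' intensity` times technical noise, so that per-spot measured ratios have
#' coefficient of variation `tech_cv`. Peak positions are displaced by the
#' affine calibration drift plus Gaussian jitter; decoy noise peaks are
#' appended away from library positions. With `bleed > 0`, a fraction of each
#' light intensity is added to its heavy peak.
#'
#' @param truth A [simulate_abundances()] table.
#' @param library The [build_library()] used for simulation.
#' @param spectrum A [spectrum_model()].
#' @param design The [study_design()] (for replicate counts and seed).
#' @param effects The [effect_model()] (for the technical CV).
#' @return A list with `peaks` (long tibble: `spot_id`, `mz`, `intensity`)
#'   and `manifest` (tibble: `sample_id`, `mouse_id`, `group`, `sex`, `week`,
#'   `replicate`, `spot_id`).
#' @export
render_peaklists <- function(truth, library, spectrum = spectrum_model(),
                             design = study_design(),
                             effects = effect_model()) {
  mz_all <- sort(c(library$light_mz, library$heavy_mz))
  min_gap <- min(diff(mz_all))
  max_shift <- abs(spectrum$drift_da) +
    abs(spectrum$drift_ppm) * 1e-6 * .mz_window[2]
  if (max_shift > min_gap / 2) {
    stop(sprintf(
      "calibration drift (up to %.3f Da) exceeds half the minimum library spacing (%.3f Da); simulated peaks would be unmatchable",
      max_shift, min_gap), call. = FALSE)
  }

  manifest <- truth |>
    dplyr::distinct(.data$sample_id, .data$mouse_id, .data$group,
                    .data$sex, .data$week) |>
    dplyr::mutate(n_rep = ifelse(.data$group == "QC",
                                 design$qc_replicates, design$replicates)) |>
    tidyr::uncount(.data$n_rep, .id = "replicate") |>
    dplyr::mutate(spot_id = sprintf("%s_r%d", .data$sample_id, .data$replicate))

  spots <- manifest |>
    dplyr::left_join(truth, by = c("sample_id", "mouse_id", "group",
                                   "sex", "week"),
                     relationship = "many-to-many")
  n <- nrow(spots)
  sd_tech <- .cv_to_sdlog(effects$tech_cv) / sqrt(2) # per channel
  lib_idx <- match(spots$glycan, library$name)
  drift <- function(mz) mz * (1 + spectrum$drift_ppm * 1e-6) + spectrum$drift_da

  withr::with_seed(design$seed + 2L, {
    heavy_int <- spectrum$intensity_scale *
      stats::rlnorm(n, meanlog = 0, sdlog = sd_tech)
    light_int <- spots$true_ratio * heavy_int *
      stats::rlnorm(n, meanlog = 0, sdlog = sd_tech)
    heavy_int <- heavy_int + spectrum$bleed * light_int
    light_mz <- drift(library$light_mz[lib_idx]) *
      (1 + stats::rnorm(n, sd = spectrum$jitter_ppm * 1e-6))
    heavy_mz <- drift(library$heavy_mz[lib_idx]) *
      (1 + stats::rnorm(n, sd = spectrum$jitter_ppm * 1e-6))
    decoys <- .render_decoys(unique(manifest$spot_id), library, spectrum)
  })

  peaks <- tibble::tibble(
    spot_id = rep(spots$spot_id, 2),
    mz = c(light_mz, heavy_mz),
    intensity = c(light_int, heavy_int)
  ) |>
    dplyr::bind_rows(decoys) |>
    dplyr::arrange(.data$spot_id, .data$mz)

  list(peaks = peaks,
       manifest = dplyr::select(manifest, "sample_id", "mouse_id", "group",
                                "sex", "week", "replicate", "spot_id"))
}

.render_decoys <- function(spot_ids, library, spectrum) {
  if (spectrum$n_decoys == 0) return(NULL)
  lib_mz <- sort(c(library$light_mz, library$heavy_mz))
  n_tot <- length(spot_ids) * spectrum$n_decoys
  # oversample, then reject positions within 0.5 Da of any library peak
  mz <- stats::runif(ceiling(n_tot * 1.5), .mz_window[1], .mz_window[2])
  near <- findInterval(mz, lib_mz)
  d_lo <- abs(mz - lib_mz[pmax(near, 1)])
  d_hi <- abs(lib_mz[pmin(near + 1, length(lib_mz))] - mz)
  mz <- mz[pmin(d_lo, d_hi) > 0.5][seq_len(n_tot)]
  tibble::tibble(
    spot_id = rep(spot_ids, each = spectrum$n_decoys),
    mz = mz,
    intensity = spectrum$intensity_scale * spectrum$decoy_intensity *
      stats::rlnorm(n_tot, meanlog = 0, sdlog = 0.5)
  )
}

#' Simulate a complete synthetic glycome study
#'
#' Chains [simulate_abundances()] and [render_peaklists()].
#'
#' @inheritParams render_peaklists
#' @inheritParams simulate_abundances
#' @return A list of class `glycome_simulation` with elements `truth`,
#'   `peaks`, `manifest`, `library`, `design`, `effects`, `spectrum`.
#' @export
simulate_glycome_study <- function(design = study_design(),
                                   effects = effect_model(),
                                   spectrum = spectrum_model(),
                                   library = build_library()) {
  truth <- simulate_abundances(design, effects, library)
  rendered <- render_peaklists(truth, library, spectrum, design, effects)
  structure(list(truth = truth, peaks = rendered$peaks,
                 manifest = rendered$manifest, library = library,
                 design = design, effects = effects, spectrum = spectrum),
            class = "glycome_simulation")
}

#' Write a simulated dataset to disk
#'
#' Writes one two-column tab-separated peak-list file per spot, a sample
#' manifest, the ground-truth table, and a flat key-value parameter file
#' sufficient to regenerate the dataset byte-identically.
#'
#' @param sim A [simulate_glycome_study()] result.
#' @param dir Output directory (created if absent).
#' @param overwrite Allow writing into a non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, overwrite = FALSE) {
  stopifnot(inherits(sim, "glycome_simulation"))
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite) {
    stop("directory ", dir, " is not empty; use overwrite = TRUE",
         call. = FALSE)
  }
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  manifest <- sim$manifest |>
    dplyr::mutate(file = file.path("peaks", paste0(.data$spot_id, ".tsv")))
  for (grp in split(sim$peaks, sim$peaks$spot_id)) {
    readr::write_tsv(grp[c("mz", "intensity")],
                     file.path(dir, "peaks", paste0(grp$spot_id[1], ".tsv")))
  }
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "ground_truth.tsv"))
  params <- c(
    unlist(sim$design[c("mice_per_group", "replicates", "qc_replicates", "seed")]),
    weeks = paste(sim$design$weeks, collapse = ","),
    unlist(sim$effects, use.names = TRUE),
    unlist(sim$spectrum, use.names = TRUE),
    n_glycans = nrow(sim$library)
  )
  readr::write_tsv(tibble::tibble(key = names(params),
                                  value = as.character(params)),
                   file.path(dir, "parameters.tsv"))
  invisible(dir)
}
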