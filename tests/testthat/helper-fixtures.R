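# Shared fixtures: small designs and a noise-free rendering model so that
# round-trip tests are exact.

small_design <- function(mice = 3, weeks = c(15, 19), seed = 7, ...) {
  study_design(mice_per_group = mice, weeks = weeks, seed = seed, ...)
}

noise_free_effects <- function(...) {
  effect_model(bio_cv = 0, tech_cv = 0, outlier_prob = 0, ...)
}

noise_free_spectrum <- function(drift_da = 0, drift_ppm = 0, ...) {
  spectrum_model(jitter_ppm = 0, drift_da = drift_da, drift_ppm = drift_ppm,
                 ...)
}

# random valid compositions for property-style tests
random_compositions <- function(n, seed = 1) {
  withr::with_seed(seed, {
    purrr::map_chr(seq_len(n), function(i) {
      counts <- c(H = sample(2:9, 1), N = sample(2:6, 1),
                  F = sample(0:2, 1), E = sample(0:2, 1),
                  L = sample(0:1, 1), Ge = sample(0:2, 1),
                  Gl = sample(0:1, 1))
      counts["Ac"] <- sample(0:sum(counts[c("E", "L", "Ge", "Gl")]), 1)
      paste0(names(counts)[counts > 0], counts[counts > 0], collapse = "")
    })
  })
}
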