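# Peak-list ingestion, S/N filtering, affine mass recalibration against
# known calibrant glycans, light/heavy pair matching, and replicate
# aggregation.

#' Read a peak-list file
#'
#' Two-column (m/z, intensity) tab- or comma-separated text, one file per
#' target spot; a single header line is tolerated. Peaks outside the
#' acquisition window (700-3500 m/z) are dropped, with the count recorded in
#' the `n_dropped` attribute.
#'
#' @param file Path to the peak-list file.
#' @return A tibble (`mz`, `intensity`) sorted by m/z.
#' @export
read_peaklist <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file, call. = FALSE)
  lines <- readr::read_lines(file)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("empty peak list: ", file, call. = FALSE)
  }
  fields <- stringr::str_split(trimws(lines), "[\t,;]+|\\s+")
  parse_row <- function(f) suppressWarnings(as.numeric(f[1:2]))
  vals <- t(vapply(fields, parse_row, numeric(2)))
  bad <- which(rowSums(is.na(vals)) > 0 | lengths(fields) < 2)
  if (length(bad) > 0 && bad[1] == 1L && length(lines) > 1) {
    # tolerate one header line
    vals <- vals[-1, , drop = FALSE]
    lines <- lines[-1]
    bad <- which(rowSums(is.na(vals)) > 0) + 1L
  }
  if (length(bad) > 0) {
    stop(sprintf("malformed row at line %d of %s: '%s'",
                 bad[1], file, lines[if (bad[1] > length(lines)) length(lines) else bad[1]]),
         call. = FALSE)
  }
  peaks <- tibble::tibble(mz = vals[, 1], intensity = vals[, 2])
  inside <- peaks$mz >= .mz_window[1] & peaks$mz <= .mz_window[2]
  out <- dplyr::arrange(peaks[inside, ], .data$mz)
  attr(out, "n_dropped") <- sum(!inside)
  out
}

#' Estimate per-peak signal-to-noise
#'
#' When the acquisition software's S/N estimates are unavailable, the noise
#' level is taken as the median intensity of peaks that do not match the
#' library within 50 ppm, computed in 300 Da windows along the mass axis;
#' S/N is each peak's intensity divided by the local noise.
#'
#' @param peaks A peak tibble (`mz`, `intensity`).
#' @param library A [build_library()] result identifying analyte positions.
#' @param window Window width in Da for the local noise estimate.
#' @param exclude_ppm Peaks within this many ppm of a library light or heavy
#'   m/z are excluded from the noise estimate.
#' @return `peaks` with an `snr` column added.
#' @export
estimate_snr <- function(peaks, library, window = 300, exclude_ppm = 50) {
  lib_mz <- sort(c(library$light_mz, library$heavy_mz))
  is_noise <- !.near_any(peaks$mz, lib_mz, exclude_ppm)
  if (!any(is_noise)) {
    # every peak is an analyte: no noise floor is estimable
    return(dplyr::mutate(peaks, snr = Inf))
  }
  noise_at <- function(mz) {
    sel <- is_noise & abs(peaks$mz - mz) <= window / 2
    if (!any(sel)) sel <- is_noise
    if (!any(sel)) return(NA_real_)
    stats::median(peaks$intensity[sel])
  }
  noise <- vapply(peaks$mz, noise_at, numeric(1))
  dplyr::mutate(peaks, snr = .data$intensity / noise)
}

# TRUE where x is within tol_ppm of some reference value
.near_any <- function(x, ref, tol_ppm) {
  i <- findInterval(x, ref)
  d_lo <- abs(x - ref[pmax(i, 1)])
  d_hi <- abs(ref[pmin(i + 1, length(ref))] - x)
  pmin(d_lo, d_hi) / x * 1e6 <= tol_ppm
}

#' Filter peaks on signal-to-noise
#'
#' Retains peaks with S/N strictly greater than `threshold` (the
#' identification criterion is S/N > 3, so a peak at exactly the threshold
#' is dropped). If the peaks carry no `snr` column, it is estimated with
#' [estimate_snr()] (which then requires `library`).
#'
#' @param peaks A peak tibble, optionally with an `snr` column.
#' @param threshold S/N threshold (default 3; must be non-negative).
#' @param library Library for S/N estimation when `snr` is absent.
#' @return The filtered peak tibble.
#' @export
snr_filter <- function(peaks, threshold = 3, library = NULL) {
  stopifnot(threshold >= 0)
  if (!"snr" %in% names(peaks)) {
    if (is.null(library)) {
      stop("peaks carry no 'snr' column; supply 'library' to estimate it",
           call. = FALSE)
    }
    peaks <- estimate_snr(peaks, library)
  }
  out <- dplyr::filter(peaks, .data$snr > threshold)
  if (nrow(out) == 0) warning("no peaks above S/N threshold", call. = FALSE)
  out
}

#' Recalibrate the mass axis against calibrant glycans
#'
#' For each calibrant light m/z, the nearest observed peak within
#' `search_tol` Da is taken as its image; the mass error is regressed on
#' observed m/z (affine: offset + slope) by least squares, and the fitted
#' correction is subtracted from every peak. With fewer than two matched
#' calibrants the identity transform is applied and a warning status
#' recorded. A single matched pair would only support a constant offset and
#' none supports nothing; two or more support the affine model.
#'
#' @param peaks A peak tibble.
#' @param calibrants Character vector of calibrant compositions (default
#'   [calibrant_panel()]).
#' @param search_tol Pre-calibration search tolerance in Da (default 0.3).
#' @return A list of class `recalibration`: `peaks` (corrected tibble) and
#'   `fit`, a one-row tibble with `n_matched`, `offset_da`, `slope`,
#'   `rmse_pre`, `rmse_post`, `max_residual`, `status`
#'   (`"ok"`/`"identity"`), plus a `residuals` tibble attribute with
#'   per-calibrant pre/post errors.
#' @export
recalibrate <- function(peaks, calibrants = calibrant_panel(),
                        search_tol = 0.3) {
  theo <- sodiated_mz(calibrants)
  idx <- vapply(theo, function(m) {
    d <- abs(peaks$mz - m)
    j <- which.min(d)
    if (length(j) == 0 || d[j] > search_tol) NA_integer_ else j
  }, integer(1))
  ok <- !is.na(idx)
  res <- tibble::tibble(
    calibrant = calibrants, theoretical = theo,
    observed = ifelse(ok, peaks$mz[idx], NA_real_),
    error_pre = ifelse(ok, peaks$mz[idx] - theo, NA_real_)
  )
  if (sum(ok) < 2) {
    warning("fewer than 2 calibrants matched; applying identity calibration",
            call. = FALSE)
    fit <- tibble::tibble(n_matched = sum(ok), offset_da = 0, slope = 0,
                          rmse_pre = NA_real_, rmse_post = NA_real_,
                          max_residual = NA_real_, status = "identity")
    res$error_post <- res$error_pre
  } else {
    m <- stats::lm(error_pre ~ observed, data = res[ok, ])
    co <- stats::coef(m)
    correct <- function(mz) mz - (co[[1]] + co[[2]] * mz)
    peaks$mz <- correct(peaks$mz)
    res$error_post <- ifelse(ok, correct(res$observed) - theo, NA_real_)
    fit <- tibble::tibble(
      n_matched = sum(ok), offset_da = co[[1]], slope = co[[2]],
      rmse_pre = sqrt(mean(res$error_pre[ok]^2)),
      rmse_post = sqrt(mean(res$error_post[ok]^2)),
      max_residual = max(abs(res$error_post[ok])),
      status = "ok")
  }
  attr(fit, "residuals") <- res
  structure(list(peaks = peaks, fit = fit), class = "recalibration")
}

#' Match light/heavy peak pairs against the library
#'
#' For every library glycan, the nearest peak in ppm within `tol_ppm` of the
#' light m/z and of the heavy m/z is selected; the measured ratio is
#' light/heavy intensity. A match is flagged `ambiguous` when a second peak
#' lies within tolerance at a comparable intensity (within a factor of two),
#' or when one observed peak is claimed by more than one library entry;
#' ambiguity is reported, never silently resolved.
#'
#' @param peaks A recalibrated peak tibble.
#' @param library A [build_library()] result.
#' @param tol_ppm Matching tolerance in ppm (default 10).
#' @return A tibble with one row per library glycan: `glycan`,
#'   `light_intensity`, `heavy_intensity`, `ratio`, `light_ppm`,
#'   `heavy_ppm`, `status` (`ok`, `light_missing`, `heavy_missing`,
#'   `ambiguous`).
#' @export
match_pairs <- function(peaks, library, tol_ppm = 10) {
  pick <- function(target) {
    d_ppm <- abs(peaks$mz - target) / target * 1e6
    cand <- which(d_ppm <= tol_ppm)
    if (length(cand) == 0) {
      return(list(idx = NA_integer_, ppm = NA_real_, ambiguous = FALSE))
    }
    best <- cand[which.min(d_ppm[cand])]
    amb <- FALSE
    if (length(cand) > 1) {
      others <- setdiff(cand, best)
      rel <- peaks$intensity[others] / peaks$intensity[best]
      amb <- any(rel > 0.5 & rel < 2)
    }
    list(idx = best, ppm = d_ppm[best], ambiguous = amb)
  }
  light <- lapply(library$light_mz, pick)
  heavy <- lapply(library$heavy_mz, pick)
  li <- vapply(light, `[[`, integer(1), "idx")
  hi <- vapply(heavy, `[[`, integer(1), "idx")
  amb <- vapply(light, `[[`, logical(1), "ambiguous") |
    vapply(heavy, `[[`, logical(1), "ambiguous")
  # one observed peak claimed by several library entries
  claimed <- c(li, hi)
  shared <- claimed[!is.na(claimed)][duplicated(claimed[!is.na(claimed)])]
  amb <- amb | li %in% shared | hi %in% shared
  status <- dplyr::case_when(
    is.na(li) ~ "light_missing",
    is.na(hi) ~ "heavy_missing",
    amb ~ "ambiguous",
    TRUE ~ "ok"
  )
  tibble::tibble(
    glycan = library$name,
    light_intensity = ifelse(is.na(li), NA_real_, peaks$intensity[li]),
    heavy_intensity = ifelse(is.na(hi), NA_real_, peaks$intensity[hi]),
    ratio = ifelse(status == "ok",
                   peaks$intensity[li] / peaks$intensity[hi], NA_real_),
    light_ppm = vapply(light, `[[`, numeric(1), "ppm"),
    heavy_ppm = vapply(heavy, `[[`, numeric(1), "ppm"),
    status = status
  )
}

#' Aggregate replicate spots into per-sample ratios
#'
#' The per-sample value of each glycan is the arithmetic mean of its
#' measured ratio over replicate spots with `ok` status; the technical CV is
#' the sample standard deviation divided by the mean. Samples with no usable
#' replicate for a glycan yield a missing value.
#'
#' @param pair_table A tibble of [match_pairs()] rows across spots, carrying
#'   at least `sample_id`, `glycan`, `ratio`, `status`.
#' @return A tibble with `sample_id`, `glycan`, `ratio` (mean), `tech_cv`,
#'   `n_rep`.
#' @export
aggregate_replicates <- function(pair_table) {
  pair_table |>
    dplyr::group_by(.data$sample_id, .data$glycan) |>
    dplyr::summarise(
      n_rep = sum(.data$status == "ok"),
      tech_cv = ifelse(.data$n_rep >= 2,
                       stats::sd(.data$ratio[.data$status == "ok"]) /
                         mean(.data$ratio[.data$status == "ok"]),
                       NA_real_),
      ratio = ifelse(.data$n_rep >= 1,
                     mean(.data$ratio[.data$status == "ok"]), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::select("sample_id", "glycan", "ratio", "tech_cv", "n_rep")
}
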