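# Panel-level quality control: reproducibility CV filter, Tukey-fence
# outlier flagging, and assembly of the samples x glycans quantitation
# table.

#' Reproducibility CV filter
#'
#' Each glycan's coefficient of variation (sample standard deviation over
#' mean) across repeated measurements of a reproducibility set is compared
#' against a threshold; glycans with CV strictly below the threshold are
#' retained for quantification. Glycans with zero mean are dropped with a
#' distinct reason code.
#'
#' @param replicate_ratios Tibble with columns `glycan` and `ratio`, one row
#'   per repeated measurement (at least 3 per glycan expected).
#' @param threshold CV retention threshold as a fraction (default 0.25).
#' @return A QC report tibble: `glycan`, `cv`, `n`, `retained`, `reason`
#'   (`"ok"`, `"cv_above_threshold"`, `"zero_mean"`, `"too_few_replicates"`).
#' @examples
#' cv_filter(tibble::tibble(glycan = "g", ratio = c(1, 2, 3))) # CV 50%
#' @export
cv_filter <- function(replicate_ratios, threshold = 0.25) {
  stopifnot(threshold > 0)
  replicate_ratios |>
    dplyr::filter(!is.na(.data$ratio)) |>
    dplyr::group_by(.data$glycan) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ratio = mean(.data$ratio),
      cv = ifelse(.data$mean_ratio == 0, NA_real_,
                  stats::sd(.data$ratio) / .data$mean_ratio),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$mean_ratio == 0 ~ "zero_mean",
        .data$n < 2 ~ "too_few_replicates",
        .data$cv < threshold ~ "ok",
        TRUE ~ "cv_above_threshold"
      ),
      retained = .data$reason == "ok"
    ) |>
    dplyr::select("glycan", "cv", "n", "retained", "reason")
}

#' Tukey-fence outlier flags
#'
#' Values outside `[Q1 - k * IQR, Q3 + k * IQR]` with `IQR = Q3 - Q1` are
#' flagged, in a single pass. Quartiles use linear interpolation between
#' order statistics (position `(n - 1) * p + 1`, R quantile type 7). With
#' fewer than 4 non-missing values the stratum is passed through unflagged.
#'
#' @param values Numeric vector (one glycan within one stratum).
#' @param k Fence multiplier (default 1.5).
#' @return Logical vector, `TRUE` where the value is an outlier (`NA` values
#'   are never flagged).
#' @examples
#' iqr_outliers(c(1, 2, 3, 4, 100)) # flags 100
#' @export
iqr_outliers <- function(values, k = 1.5) {
  out <- rep(FALSE, length(values))
  obs <- !is.na(values)
  if (sum(obs) < 4) return(out)
  q <- stats::quantile(values[obs], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  out[obs] <- values[obs] < q[1] - k * iqr | values[obs] > q[2] + k * iqr
  out
}

#' Assemble the quantitation table
#'
#' Joins per-sample aggregated ratios with the sample manifest, restricts to
#' the CV-retained panel, and flags outlying cells per glycan within
#' (group x week) strata using [iqr_outliers()]. Flagged cells are kept in
#' the table but masked (`outlier = TRUE`) and excluded from downstream
#' statistics.
#'
#' @param aggregates An [aggregate_replicates()] tibble.
#' @param manifest Sample manifest with `sample_id`, `mouse_id`, `group`,
#'   `sex`, `week` (one row per sample).
#' @param qc A [cv_filter()] report; only retained glycans are kept
#'   (`NULL` keeps everything).
#' @param strata Columns defining the outlier-fencing stratum
#'   (default `c("group", "week")`, pooling sexes).
#' @param iqr_k Tukey fence multiplier (default 1.5).
#' @return A tibble of class `quant_table`, one row per sample x glycan:
#'   manifest keys, `glycan`, `ratio`, `tech_cv`, `n_rep`, `outlier`.
#'   Attributes: `qc` (the CV report) and `n_flagged`.
#' @export
assemble_quant_table <- function(aggregates, manifest, qc = NULL,
                                 strata = c("group", "week"), iqr_k = 1.5) {
  manifest <- dplyr::distinct(manifest, .data$sample_id, .data$mouse_id,
                              .data$group, .data$sex, .data$week)
  orphans <- setdiff(manifest$sample_id, aggregates$sample_id)
  extra <- setdiff(aggregates$sample_id, manifest$sample_id)
  if (length(orphans) > 0 || length(extra) > 0) {
    stop("manifest/aggregate mismatch; missing from aggregates: ",
         paste(orphans, collapse = ", "), "; unknown samples: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  quant <- dplyr::inner_join(manifest, aggregates, by = "sample_id")
  if (!is.null(qc)) {
    quant <- dplyr::semi_join(quant, dplyr::filter(qc, .data$retained),
                              by = "glycan")
  }
  quant <- quant |>
    dplyr::group_by(.data$glycan, dplyr::across(dplyr::all_of(strata))) |>
    dplyr::mutate(outlier = iqr_outliers(.data$ratio, k = iqr_k)) |>
    dplyr::ungroup()
  structure(quant, class = c("quant_table", class(quant)),
            qc = qc, n_flagged = sum(quant$outlier))
}
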