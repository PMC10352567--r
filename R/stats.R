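# AL-vs-CR comparisons per glycan and per derived trait: classical
# equal-variance two-sample t-tests per time point and pooled, significance
# stars on raw p-values (with Benjamini-Hochberg adjusted p-values as an
# auxiliary column), and the log10 heatmap matrix.

#' Unpaired Student's t-test
#'
#' Classical equal-variance two-sample t-test, two-sided, with
#' `n_x + n_y - 2` degrees of freedom. Welch's unequal-variance form is
#' available behind `var_equal = FALSE`.
#'
#' @param x,y Numeric vectors of the two groups (missing values dropped).
#' @param var_equal Pool variances (default `TRUE`, the classical Student
#'   form).
#' @return A one-row tibble: `t`, `df`, `p`, `mean_x`, `mean_y`, `sd_x`,
#'   `sd_y`, `n_x`, `n_y`, `reason` (`"ok"` or why the test is missing).
#' @examples
#' ttest_unpaired(c(1, 2, 3), c(4, 5, 6)) # t = -3.674, p = 0.0213
#' @export
ttest_unpaired <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  base <- tibble::tibble(
    t = NA_real_, df = NA_real_, p = NA_real_,
    mean_x = if (length(x)) mean(x) else NA_real_,
    mean_y = if (length(y)) mean(y) else NA_real_,
    sd_x = stats::sd(x), sd_y = stats::sd(y),
    n_x = length(x), n_y = length(y), reason = "ok")
  if (length(x) < 2 || length(y) < 2) {
    base$reason <- "fewer_than_2_per_group"
    return(base)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    base$t <- 0; base$df <- length(x) + length(y) - 2
    base$p <- if (mean(x) == mean(y)) 1 else NA_real_
    base$reason <- if (mean(x) == mean(y)) "ok" else "constant_data"
    return(base)
  }
  fit <- stats::t.test(x, y, var.equal = var_equal)
  base$t <- unname(fit$statistic)
  base$df <- unname(fit$parameter)
  base$p <- fit$p.value
  base
}

#' Significance stars for raw p-values
#'
#' `p < 0.05` one star up to `p < 0.0001` four stars; `"ns"` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.0001 ~ "****",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Compare AL vs CR for every glycan or trait
#'
#' Runs the unpaired t-test per unit within each stratum. Strata are the
#' seven time points plus a pooled stratum (`week = "pooled"`, treating
#' repeated measures as independent samples, with a per-mouse-mean
#' sensitivity mode available), optionally crossed with sex. Raw p-values
#' drive the stars; BH-adjusted p-values are reported alongside (adjusted
#' within each stratum x sex slice).
#'
#' @param data A `quant_table` (long, per-glycan) or `trait_table` (wide,
#'   per-trait) — trait tables are pivoted internally.
#' @param by_week Emit per-time-point strata (default `TRUE`).
#' @param pooled Emit the pooled-over-weeks stratum (default `TRUE`).
#' @param by_sex Stratify by sex in addition to pooled-sex results
#'   (default `FALSE`).
#' @param per_mouse_mean Average repeated measures per mouse before testing
#'   in the pooled stratum (default `FALSE`, matching a pooled analysis that
#'   treats time points as independent).
#' @param groups The two groups compared, reference first (default
#'   `c("AL", "CR")`; direction is the sign of `mean_CR - mean_AL`).
#' @return A tibble of class `glyco_comparisons`: `unit`, `week`
#'   (`"pooled"` or the week), `sex` (`"pooled"`, `"M"`, `"F"`), group
#'   means/sds/ns, `t`, `df`, `p`, `p_bh`, `stars`, `direction`.
#' @export
compare_groups <- function(data, by_week = TRUE, pooled = TRUE,
                           by_sex = FALSE, per_mouse_mean = FALSE,
                           groups = c("AL", "CR")) {
  long <- .as_unit_long(data)
  long <- dplyr::filter(long, .data$group %in% groups)
  sexes <- if (by_sex) c("pooled", unique(long$sex)) else "pooled"
  weeks <- c(if (pooled) "pooled",
             if (by_week) as.character(sort(unique(long$week))))
  grid <- tidyr::expand_grid(week_stratum = weeks, sex_stratum = sexes)
  res <- purrr::pmap_dfr(grid, function(week_stratum, sex_stratum) {
    d <- long
    if (week_stratum != "pooled") {
      d <- dplyr::filter(d, as.character(.data$week) == week_stratum)
    } else if (per_mouse_mean) {
      d <- d |>
        dplyr::group_by(.data$unit, .data$mouse_id, .data$group, .data$sex) |>
        dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                         .groups = "drop")
    }
    if (sex_stratum != "pooled") {
      d <- dplyr::filter(d, .data$sex == sex_stratum)
    }
    if (nrow(d) == 0) return(NULL)
    d |>
      dplyr::group_by(.data$unit) |>
      dplyr::group_modify(~ ttest_unpaired(
        .x$value[.x$group == groups[1]], .x$value[.x$group == groups[2]])) |>
      dplyr::ungroup() |>
      dplyr::mutate(week = week_stratum, sex = sex_stratum)
  })
  res |>
    dplyr::rename(mean_AL = "mean_x", mean_CR = "mean_y",
                  sd_AL = "sd_x", sd_CR = "sd_y",
                  n_AL = "n_x", n_CR = "n_y") |>
    dplyr::group_by(.data$week, .data$sex) |>
    dplyr::mutate(p_bh = stats::p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(stars = significance_stars(.data$p),
                  direction = sign(.data$mean_CR - .data$mean_AL)) |>
    dplyr::select("unit", "week", "sex", "mean_AL", "sd_AL", "n_AL",
                  "mean_CR", "sd_CR", "n_CR", "t", "df", "p", "p_bh",
                  "stars", "direction") |>
    structure(class = c("glyco_comparisons", class(res)))
}

# normalize quant (long) or trait (wide) tables to unit/value long form
.as_unit_long <- function(data) {
  data <- tibble::as_tibble(data)
  if (all(c("glycan", "ratio") %in% names(data))) {
    out <- data |>
      dplyr::filter(if ("outlier" %in% names(data)) !.data$outlier else TRUE) |>
      dplyr::transmute(unit = .data$glycan,
                       mouse_id = .data$mouse_id, group = .data$group,
                       sex = .data$sex, week = .data$week,
                       value = .data$ratio)
  } else {
    keys <- intersect(c("sample_id", "mouse_id", "group", "sex", "week"),
                      names(data))
    out <- data |>
      tidyr::pivot_longer(-dplyr::all_of(keys), names_to = "unit",
                          values_to = "value") |>
      dplyr::select(dplyr::all_of(setdiff(keys, "sample_id")),
                    "unit", "value")
  }
  dplyr::filter(out, !is.na(.data$value))
}

#' Log10 heatmap matrix of the quantitation table
#'
#' Samples x glycans matrix of log10-transformed ratios with deterministic
#' ordering: columns follow the library panel order, rows sort by group,
#' sex, week, mouse. Nonpositive or masked ratios become `NA` and are
#' counted.
#'
#' @param quant An [assemble_quant_table()] result.
#' @param library The matching [build_library()] (fixes column order;
#'   `NULL` sorts columns alphabetically).
#' @return A list of class `glyco_heatmap`: `matrix` (rows = samples),
#'   `annotations` (tibble of row keys), `n_masked`.
#' @export
heatmap_matrix <- function(quant, library = NULL) {
  quant <- tibble::as_tibble(quant)
  quant <- quant |>
    dplyr::mutate(value = ifelse(
      !is.na(.data$ratio) & .data$ratio > 0 &
        !(if ("outlier" %in% names(quant)) .data$outlier else FALSE),
      log10(.data$ratio), NA_real_))
  n_masked <- sum(is.na(quant$value) & !is.na(quant$ratio))
  ann <- quant |>
    dplyr::distinct(.data$sample_id, .data$group, .data$sex,
                    .data$week, .data$mouse_id) |>
    dplyr::arrange(.data$group, .data$sex, .data$week, .data$mouse_id)
  cols <- if (is.null(library)) sort(unique(quant$glycan)) else
    intersect(library$name, unique(quant$glycan))
  wide <- quant |>
    dplyr::select("sample_id", "glycan", "value") |>
    tidyr::pivot_wider(names_from = "glycan", values_from = "value")
  m <- as.matrix(wide[match(ann$sample_id, wide$sample_id),
                      cols, drop = FALSE])
  rownames(m) <- ann$sample_id
  structure(list(matrix = m, annotations = ann, n_masked = n_masked),
            class = "glyco_heatmap")
}
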