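# Derived glycosylation traits computed from the quantitation table via a
# declarative trait registry.
#
# Two trait kinds exist. "sum" traits add the IS-normalized ratios of every
# glycan satisfying a predicate (e.g. fucosylation = sum over F >= 1).
# "weighted_per_antenna" traits are abundance-weighted fractions,
# sum(numerator weight x ratio) / sum(denominator weight x ratio) over
# antenna-carrying glycans (e.g. galactosylation per antenna weights by
# galactose and antenna counts). Predicates and weights are expressions over
# the composition counts and structural features, so alternative formula
# sets can be swapped in without code changes.

#' Default registry of 18 derived glycosylation traits
#'
#' Covers fucosylation/afucosylation, the two per-antenna traits
#' (galactosylation, sialylation), the three structural classes, antennarity
#' (mono/bi/tri), the eight sialylation-derived traits (by linkage, by
#' sialic acid species, branched, O-acetylated, total, asialylation).
#'
#' @return A tibble with columns `trait`, `kind` (`"sum"` or
#'   `"weighted_per_antenna"`), `predicate`, `weight_num`, `weight_den` —
#'   the last three as expression strings over the fields `H`, `N`, `F`,
#'   `E`, `L`, `Ge`, `Gl`, `Ac`, `class`, `antennae`, `galactoses`,
#'   `sialic`, `sialic_23`, `sialic_26`, `neu5ac`, `neu5gc`, `branched`.
#' @export
default_trait_registry <- function() {
  tibble::tribble(
    ~trait, ~kind, ~predicate, ~weight_num, ~weight_den,
    "fucosylation", "sum", "F >= 1", NA, NA,
    "afucosylation", "sum", "F == 0", NA, NA,
    "galactosylation_per_antenna", "weighted_per_antenna",
      "antennae > 0", "galactoses", "antennae",
    "sialylation_per_antenna", "weighted_per_antenna",
      "antennae > 0", "sialic", "antennae",
    "high_mannose", "sum", "class == 'high_mannose'", NA, NA,
    "hybrid", "sum", "class == 'hybrid'", NA, NA,
    "complex", "sum", "class == 'complex'", NA, NA,
    "monoantennary", "sum", "antennae == 1", NA, NA,
    "biantennary", "sum", "antennae == 2", NA, NA,
    "triantennary", "sum", "antennae == 3", NA, NA,
    "a23_sialylation", "sum", "sialic_23 >= 1", NA, NA,
    "a26_sialylation", "sum", "sialic_26 >= 1", NA, NA,
    "neu5ac_sialylation", "sum", "neu5ac >= 1", NA, NA,
    "neu5gc_sialylation", "sum", "neu5gc >= 1", NA, NA,
    "branched_sialic", "sum", "branched", NA, NA,
    "oacetylated_sialylation", "sum", "Ac >= 1", NA, NA,
    "sialylation", "sum", "sialic >= 1", NA, NA,
    "asialylation", "sum", "sialic == 0", NA, NA
  )
}

# evaluate a registry expression string over the library feature table
.eval_registry_expr <- function(expr, features) {
  v <- rlang::eval_tidy(rlang::parse_expr(expr), data = features)
  if (length(v) == 1) v <- rep(v, nrow(features))
  v
}

#' Glycans contributing to each trait
#'
#' @param registry A trait registry tibble ([default_trait_registry()]).
#' @param library A [build_library()] result.
#' @return A tibble `trait`, `glycan`, `weight_num`, `weight_den` (weights
#'   are 1 for sum traits).
#' @export
trait_members <- function(registry, library) {
  features <- dplyr::left_join(
    tibble::as_tibble(library),
    parse_composition(library$name),
    by = "name")
  purrr::pmap_dfr(registry, function(trait, kind, predicate,
                                     weight_num, weight_den) {
    sel <- .eval_registry_expr(predicate, features)
    wn <- if (is.na(weight_num)) 1 else .eval_registry_expr(weight_num, features)
    wd <- if (is.na(weight_den)) 1 else .eval_registry_expr(weight_den, features)
    tibble::tibble(trait = trait, kind = kind,
                   glycan = features$name[sel],
                   weight_num = (wn * 1)[sel], weight_den = (wd * 1)[sel])
  })
}

#' Compute derived glycosylation traits
#'
#' For each sample, sum traits add the ratios of qualifying glycans and
#' weighted traits form sum(weight_num x ratio) / sum(weight_den x ratio);
#' outlier-masked and missing cells are excluded from both. A weighted trait
#' whose denominator vanishes for a sample is missing for that sample.
#'
#' @param quant An [assemble_quant_table()] result (or any tibble with
#'   `sample_id`, `glycan`, `ratio` and optionally `outlier`).
#' @param library The [build_library()] used for quantitation.
#' @param registry Trait registry (default [default_trait_registry()]).
#' @return A tibble of class `trait_table`: one row per sample with the
#'   manifest keys present in `quant` and one column per trait. The
#'   registry and the per-trait member list are attached as attributes
#'   `registry` and `members`.
#' @export
compute_traits <- function(quant, library,
                           registry = default_trait_registry()) {
  members <- trait_members(registry, library)
  keys <- intersect(c("sample_id", "mouse_id", "group", "sex", "week"),
                    names(quant))
  usable <- quant |>
    dplyr::filter(!is.na(.data$ratio)) |>
    dplyr::filter(if ("outlier" %in% names(quant)) !.data$outlier else TRUE)
  contrib <- dplyr::inner_join(usable, members, by = "glycan",
                               relationship = "many-to-many")
  values <- contrib |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys)), .data$trait) |>
    dplyr::summarise(
      value = if (dplyr::first(.data$kind) == "sum") {
        sum(.data$ratio)
      } else {
        den <- sum(.data$weight_den * .data$ratio)
        if (den == 0) NA_real_ else
          sum(.data$weight_num * .data$ratio) / den
      },
      .groups = "drop"
    )
  wide <- tidyr::pivot_wider(values, names_from = "trait",
                             values_from = "value")
  # traits with no qualifying glycan at all: emit explicit zero columns
  missing_traits <- setdiff(registry$trait, names(wide))
  for (tr in missing_traits) wide[[tr]] <- 0
  wide <- dplyr::select(wide, dplyr::all_of(c(keys, registry$trait)))
  structure(wide, class = c("trait_table", class(wide)),
            registry = registry, members = members)
}

#' Per-glycan view of the O-acetylated sialoglycans
#'
#' The O-acetylated trait aggregates few glycans, so their individual
#' ratios are also reported for inspection.
#'
#' @param quant An [assemble_quant_table()] result.
#' @param library The matching [build_library()].
#' @return The `quant` rows for acetylated glycans, with a
#'   `alpha26_only` flag (no lactonized alpha-2,3 residue).
#' @export
acetylated_glycans <- function(quant, library) {
  ac <- tibble::as_tibble(library) |>
    dplyr::filter(.data$acetylated) |>
    dplyr::transmute(glycan = .data$name,
                     alpha26_only = .data$sialic_23 == 0)
  dplyr::inner_join(tibble::as_tibble(quant), ac, by = "glycan")
}

#' Write a trait table with provenance header
#'
#' @param traits A [compute_traits()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_traits <- function(traits, path) {
  registry <- attr(traits, "registry")
  members <- attr(traits, "members")
  writeLines(c(
    "# derived glycosylation trait table",
    sprintf("# traits: %d; kinds: %s", nrow(registry),
            paste(unique(registry$kind), collapse = ", ")),
    if (!is.null(members)) sprintf(
      "# %s <- %s", registry$trait,
      vapply(registry$trait, function(tr) {
        paste(members$glycan[members$trait == tr], collapse = ",")
      }, character(1)))
  ), path)
  readr::write_tsv(tibble::as_tibble(traits), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Read back a trait table written by [export_traits()]
#'
#' @param path File path.
#' @return A tibble (provenance comments skipped).
#' @export
read_traits <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
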