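# Composition grammar and composition-level structure classification.

.comp_symbols <- c("H", "N", "F", "E", "L", "Ge", "Gl", "Ac")

#' Parse glycan composition strings
#'
#' A composition string is a concatenation of residue symbols each followed by
#' a positive integer count, e.g. `"H5N4F1Ge2Ac1"`. Recognised symbols are
#' `H`, `N`, `F`, `E`, `L`, `Ge`, `Gl` and the O-acetyl modification `Ac`;
#' two-letter symbols (`Ge`, `Gl`, `Ac`) are tokenized with longest match so
#' the grammar is unambiguous. The canonical name regenerated in the output
#' lists symbols in the fixed order H, N, F, E, L, Ge, Gl, Ac with zero counts
#' omitted; parsing a canonical name reproduces the counts exactly.
#'
#' O-acetyl groups ride on sialic acids, so `Ac` must not exceed the total
#' sialic count `E + L + Ge + Gl`.
#'
#' @param name Character vector of composition strings.
#' @return A tibble with one row per input: the canonical `name` and integer
#'   count columns `H`, `N`, `F`, `E`, `L`, `Ge`, `Gl`, `Ac`.
#' @examples
#' parse_composition(c("H4N4F1", "H5N4Ge2Ac1"))
#' @export
parse_composition <- function(name) {
  stopifnot(is.character(name), length(name) >= 1)
  rows <- lapply(name, .parse_one_composition)
  out <- dplyr::bind_rows(rows)
  out$name <- composition_name(out)
  dplyr::relocate(out, "name")
}

.parse_one_composition <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    stop("empty composition string", call. = FALSE)
  }
  counts <- stats::setNames(integer(length(.comp_symbols)), .comp_symbols)
  pos <- 1L
  n <- nchar(x)
  # longest-match tokenizer: try two-letter symbols before one-letter ones
  syms_by_len <- c("Ge", "Gl", "Ac", "H", "N", "F", "E", "L")
  while (pos <= n) {
    sym <- NULL
    for (s in syms_by_len) {
      if (startsWith(substr(x, pos, n), s)) { sym <- s; break }
    }
    if (is.null(sym)) {
      stop(sprintf("unknown symbol at position %d in '%s'", pos, x),
           call. = FALSE)
    }
    pos <- pos + nchar(sym)
    digits <- stringr::str_extract(substr(x, pos, n), "^[0-9]+")
    if (is.na(digits)) {
      stop(sprintf("missing count after '%s' at position %d in '%s'",
                   sym, pos, x), call. = FALSE)
    }
    cnt <- as.integer(digits)
    if (cnt < 1) {
      stop(sprintf("count must be positive for '%s' at position %d in '%s'",
                   sym, pos, x), call. = FALSE)
    }
    if (counts[[sym]] > 0) {
      stop(sprintf("symbol '%s' repeated at position %d in '%s'",
                   sym, pos - nchar(sym), x), call. = FALSE)
    }
    counts[[sym]] <- cnt
    pos <- pos + nchar(digits)
  }
  sialic <- counts[["E"]] + counts[["L"]] + counts[["Ge"]] + counts[["Gl"]]
  if (counts[["Ac"]] > sialic) {
    stop(sprintf(
      "'%s': Ac count (%d) exceeds sialic acid count (%d); O-acetyl groups ride on sialic acids",
      x, counts[["Ac"]], sialic), call. = FALSE)
  }
  tibble::as_tibble(as.list(counts))
}

#' Canonical composition name from counts
#'
#' @param comp A tibble with count columns `H`, `N`, `F`, `E`, `L`, `Ge`,
#'   `Gl`, `Ac` (as produced by [parse_composition()]).
#' @return Character vector of canonical names.
#' @export
composition_name <- function(comp) {
  vapply(seq_len(nrow(comp)), function(i) {
    parts <- vapply(.comp_symbols, function(s) {
      cnt <- comp[[s]][i]
      if (cnt > 0) paste0(s, cnt) else ""
    }, character(1))
    paste0(parts, collapse = "")
  }, character(1))
}

.as_composition <- function(comp) {
  if (is.character(comp)) comp <- parse_composition(comp)
  stopifnot(all(.comp_symbols %in% names(comp)))
  comp
}

#' Neutral monoisotopic mass of a composition
#'
#' The neutral mass is the sum of residue masses plus one water for the
#' free reducing end, plus 42.010565 Da per O-acetyl group.
#'
#' @param comp Character vector of composition strings, or a parsed
#'   composition tibble.
#' @return Numeric vector of neutral monoisotopic masses (Da).
#' @examples
#' neutral_mass("H4N4F1") # 1624.5973
#' @export
neutral_mass <- function(comp) {
  comp <- .as_composition(comp)
  rm <- .residue_masses()
  m <- rep(rm[["water"]], nrow(comp))
  for (s in .comp_symbols) m <- m + comp[[s]] * rm[[s]]
  unname(m)
}

#' Sodiated m/z of the native (light) glycan
#'
#' MALDI-TOF of derivatized glycans in positive mode detects the singly
#' sodiated species; the adduct mass is the electron-corrected Na+ mass
#' (22.98922 Da).
#'
#' @inheritParams neutral_mass
#' @return Numeric vector of `[M+Na]+` m/z values.
#' @examples
#' sodiated_mz("H4N4F1") # 1647.5865
#' @export
sodiated_mz <- function(comp) {
  neutral_mass(comp) + .mass_Na - .mass_e
}

#' Sodiated m/z of the heavy internal standard
#'
#' The internal-standard glycome is reduced with sodium borodeuteride, which
#' converts the reducing-end aldehyde to an alditol adding one hydrogen and
#' one deuterium: a constant +3.02193 Da shift (nominally +3 Da) relative to
#' the native glycan, identical for every composition.
#'
#' @inheritParams neutral_mass
#' @return Numeric vector of heavy-channel `[M+Na]+` m/z values.
#' @examples
#' internal_standard_mz("H4N4F1") - sodiated_mz("H4N4F1") # 3.02193
#' @export
internal_standard_mz <- function(comp) {
  sodiated_mz(comp) + .mass_H + .mass_D
}

#' Classify a composition into structural classes and derived features
#'
#' Classification is purely composition-based (MS1 cannot resolve topology):
#' \itemize{
#'   \item \strong{high_mannose}: N = 2, H >= 5, no fucose, no sialic acid;
#'   \item \strong{hybrid}: N = 3 and H >= 5;
#'   \item \strong{complex}: N >= 4, or N = 3 and H <= 4;
#'   \item \strong{other}: remaining compositions (paucimannose etc.).
#' }
#' Antenna count is `N - 2` for hybrid/complex glycans and 0 otherwise.
#' Galactose count is `min(max(H - 3, 0), antennae)` for complex and
#' `min(max(H - 5, 0), antennae)` for hybrid glycans (the trimannosyl core
#' accounts for 3 hexoses, plus 2 more mannoses on the untrimmed arm of a
#' hybrid glycan). A glycan carries branched (disialylated-antenna) sialic
#' acid when its sialic count exceeds a positive antenna count.
#'
#' @inheritParams neutral_mass
#' @return A tibble with columns `name`, `class`, `antennae`, `galactoses`,
#'   `sialic`, `sialic_23` (L+Gl), `sialic_26` (E+Ge), `neu5ac` (E+L),
#'   `neu5gc` (Ge+Gl), `branched`, `fucosylated`, `acetylated`.
#' @examples
#' classify_structure(c("H5N2", "H5N4Ge2", "H6N5Ge1Gl2"))
#' @export
classify_structure <- function(comp) {
  comp <- .as_composition(comp)
  if (any(comp$N < 2)) {
    bad <- composition_name(comp[comp$N < 2, ])
    stop("not an N-glycan core (HexNAc count < 2): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  comp |>
    dplyr::mutate(
      sialic = .data$E + .data$L + .data$Ge + .data$Gl,
      sialic_23 = .data$L + .data$Gl,
      sialic_26 = .data$E + .data$Ge,
      neu5ac = .data$E + .data$L,
      neu5gc = .data$Ge + .data$Gl,
      class = dplyr::case_when(
        .data$N == 2 & .data$H >= 5 & .data$F == 0 & .data$sialic == 0 ~ "high_mannose",
        .data$N == 3 & .data$H >= 5 ~ "hybrid",
        .data$N >= 4 | (.data$N == 3 & .data$H <= 4) ~ "complex",
        TRUE ~ "other"
      ),
      antennae = ifelse(.data$class %in% c("hybrid", "complex"),
                        .data$N - 2L, 0L),
      galactoses = dplyr::case_when(
        .data$class == "complex" ~ pmin(pmax(.data$H - 3L, 0L), .data$antennae),
        .data$class == "hybrid" ~ pmin(pmax(.data$H - 5L, 0L), .data$antennae),
        TRUE ~ 0L
      ),
      branched = .data$sialic > .data$antennae & .data$antennae > 0L,
      fucosylated = .data$F >= 1,
      acetylated = .data$Ac >= 1
    ) |>
    dplyr::select("name", "class", "antennae", "galactoses", "sialic",
                  "sialic_23", "sialic_26", "neu5ac", "neu5gc",
                  "branched", "fucosylated", "acetylated")
}
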