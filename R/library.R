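# Theoretical light/heavy mass library over a glycan panel.

#' Calibrant glycan compositions
#'
#' The seven derivatized glycans used for external mass calibration of serum
#' spectra, spanning the acquisition window from biantennary fucosylated to
#' disialylated species.
#'
#' @return Character vector of seven composition strings.
#' @export
calibrant_panel <- function() {
  c("H4N4F1", "H4N4Ge1", "H5N4F1Ge2", "H5N4Ge1",
    "H5N4Ge1Gl1", "H5N4Ge2", "H5N4Ge2Gl1")
}

#' Default serum N-glycan panel
#'
#' A 49-composition panel of mouse-serum N-glycans: the seven calibrants, the
#' named O-acetylated sialoglycans, and a plausible extension covering high
#' mannose, hybrid, and mono- to triantennary complex glycans with
#' Neu5Gc-dominant sialylation in both linkage forms, as typical of mouse
#' serum.
#'
#' @return Character vector of composition strings (canonical names).
#' @export
default_panel <- function() {
  unique(c(
    calibrant_panel(),
    # O-acetylated sialoglycans
    "H5N4Ge1Ac1", "H5N4Ge2Ac1", "H5N4Ge2Ac2",
    "H5N4Ge1Gl1Ac1", "H6N5Ge1Gl2Ac1",
    # high mannose
    "H5N2", "H6N2", "H7N2", "H8N2", "H9N2",
    # hybrid
    "H5N3", "H6N3", "H5N3Ge1", "H6N3Ge1",
    # monoantennary
    "H3N3", "H4N3", "H4N3Ge1",
    # biantennary neutral
    "H3N4", "H4N4", "H5N4", "H3N4F1", "H5N4F1",
    # biantennary sialylated
    "H5N4Gl1", "H5N4Gl2", "H5N4E1", "H5N4E2", "H5N4L1",
    "H5N4E1L1", "H5N4E1Ge1", "H4N4Gl1",
    # fucosylated sialylated
    "H5N4F1Ge1", "H5N4F1Gl1", "H5N4F1Ge1Gl1",
    # triantennary
    "H6N5", "H6N5F1", "H6N5Ge1", "H6N5Ge2", "H6N5Ge3",
    "H6N5Ge1Gl1", "H6N5Ge1Gl2", "H6N5Ge2Gl1", "H6N5F1Ge1"
  ))
}

#' Read a glycan panel file
#'
#' Plain-text panel: one composition string per line; blank lines and
#' `#` comments are ignored.
#'
#' @param path Path to the panel file.
#' @return Character vector of composition strings.
#' @export
read_panel <- function(path) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_trim(stringr::str_remove(lines, "#.*$"))
  lines[nzchar(lines)]
}

#' Build the theoretical light/heavy mass library
#'
#' Parses and classifies every panel composition, computes the sodiated light
#' m/z and heavy internal-standard m/z, restricts entries to the instrument
#' window (700-3500 m/z; out-of-window entries are dropped with a warning),
#' sorts by light m/z, and cross-compares all light and heavy m/z values to
#' report near-isobaric collisions closer than `tol_ppm`.
#'
#' @param panel Character vector of composition strings (duplicates are an
#'   error), default [default_panel()].
#' @param tol_ppm Matching tolerance in parts per million used for the
#'   collision scan (default 10).
#' @return A tibble of class `glycan_library`, one row per glycan, with
#'   columns `name`, `light_mz`, `heavy_mz` and the [classify_structure()]
#'   feature columns. Attributes: `tol_ppm`, and `collisions`, a tibble of
#'   library m/z pairs closer than `tol_ppm`.
#' @examples
#' lib <- build_library(calibrant_panel())
#' attr(lib, "collisions")
#' @export
build_library <- function(panel = default_panel(), tol_ppm = 10) {
  stopifnot(length(panel) >= 1, tol_ppm > 0)
  comp <- parse_composition(panel)
  dup <- duplicated(comp$name)
  if (any(dup)) {
    stop("duplicate compositions in panel: ",
         paste(unique(comp$name[dup]), collapse = ", "), call. = FALSE)
  }
  lib <- classify_structure(comp) |>
    dplyr::mutate(light_mz = sodiated_mz(comp),
                  heavy_mz = internal_standard_mz(comp)) |>
    dplyr::relocate("name", "light_mz", "heavy_mz")
  outside <- lib$light_mz < .mz_window[1] | lib$heavy_mz > .mz_window[2]
  if (any(outside)) {
    warning("excluding ", sum(outside), " glycan(s) outside the ",
            .mz_window[1], "-", .mz_window[2], " m/z window: ",
            paste(lib$name[outside], collapse = ", "), call. = FALSE)
    lib <- lib[!outside, ]
  }
  lib <- dplyr::arrange(lib, .data$light_mz)

  # collision scan over the pooled light+heavy m/z list
  mz_all <- tibble::tibble(
    name = rep(lib$name, 2),
    channel = rep(c("light", "heavy"), each = nrow(lib)),
    mz = c(lib$light_mz, lib$heavy_mz)
  ) |> dplyr::arrange(.data$mz)
  d_ppm <- diff(mz_all$mz) / mz_all$mz[-nrow(mz_all)] * 1e6
  hit <- which(d_ppm < tol_ppm)
  collisions <- tibble::tibble(
    name_a = mz_all$name[hit], channel_a = mz_all$channel[hit],
    name_b = mz_all$name[hit + 1], channel_b = mz_all$channel[hit + 1],
    mz_a = mz_all$mz[hit], mz_b = mz_all$mz[hit + 1],
    delta_ppm = d_ppm[hit]
  )
  structure(lib, class = c("glycan_library", class(lib)),
            tol_ppm = tol_ppm, collisions = collisions)
}

#' Write a library to a tab-separated file
#'
#' @param lib A [build_library()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_library <- function(lib, path) {
  out <- tibble::as_tibble(lib) |>
    dplyr::select("name", "light_mz", "heavy_mz", "class", "antennae",
                  "galactoses", "sialic_23", "sialic_26", "neu5ac",
                  "neu5gc", "acetylated", "fucosylated")
  readr::write_tsv(out, path)
  invisible(path)
}
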