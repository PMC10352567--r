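# broom-style tidiers and package-level imports.

#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a mass library
#'
#' @param x A `glycan_library`.
#' @param ... Unused.
#' @return A plain tibble of library rows.
#' @method tidy glycan_library
#' @export
tidy.glycan_library <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "glycan_library")
  attr(out, "collisions") <- NULL
  attr(out, "tol_ppm") <- NULL
  tibble::as_tibble(out)
}

#' Library collision summary
#'
#' @param x A `glycan_library`.
#' @param ... Unused.
#' @return One-row tibble: `n_glycans`, `mz_min`, `mz_max`, `n_collisions`,
#'   `tol_ppm`.
#' @method glance glycan_library
#' @export
glance.glycan_library <- function(x, ...) {
  tibble::tibble(n_glycans = nrow(x), mz_min = min(x$light_mz),
                 mz_max = max(x$heavy_mz),
                 n_collisions = nrow(attr(x, "collisions")),
                 tol_ppm = attr(x, "tol_ppm"))
}

#' Tidy a recalibration fit
#'
#' @param x A [recalibrate()] result.
#' @param ... Unused.
#' @return The per-calibrant residual tibble.
#' @method tidy recalibration
#' @export
tidy.recalibration <- function(x, ...) {
  attr(x$fit, "residuals")
}

#' One-row recalibration summary
#'
#' @param x A [recalibrate()] result.
#' @param ... Unused.
#' @return The fit tibble (`n_matched`, `offset_da`, `slope`, residual
#'   summaries, `status`).
#' @method glance recalibration
#' @export
glance.recalibration <- function(x, ...) {
  tibble::as_tibble(x$fit)
}

#' Tidy comparison results
#'
#' @param x A `glyco_comparisons` tibble.
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy glyco_comparisons
#' @export
tidy.glyco_comparisons <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Pipeline-run summary
#'
#' @param x A `glyco_run`.
#' @param ... Unused.
#' @return The one-row summary tibble with counts of samples, spots,
#'   retained glycans and flagged cells.
#' @method glance glyco_run
#' @export
glance.glyco_run <- function(x, ...) {
  x$summary
}
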